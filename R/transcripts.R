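#' Transcript sets
#'
#' Several stages exchange a flat "transcript set": a data.frame with one
#' row per exon, columns `transcript_id`, `seqid`, `strand`, `start`, `end`
#' and optionally `gene_id`, `source`. Exon rows of one transcript are
#' non-overlapping; order within the frame is by (transcript_id, start).
#'
#' @param pred a `gene_predictions` object from [assemble()].
#' @param source value for the `source` column.
#' @return a transcript-set data.frame.
#' @export
predictions_to_transcripts <- function(pred, source = "AG") {
  rows <- list()
  for (g in pred$genes) {
    for (tr in g$transcripts) {
      ex <- tr$exons[order(tr$exons$start), , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = tr$transcript_id, gene_id = g$gene_id,
        seqid = g$seqid, strand = g$strand, start = ex$start, end = ex$end,
        source = source, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_transcripts())
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

empty_transcripts <- function() {
  data.frame(transcript_id = character(), gene_id = character(),
             seqid = character(), strand = character(), start = integer(),
             end = integer(), source = character(), stringsAsFactors = FALSE)
}

#' Convert a transcript set to GFF3 gene/mRNA/exon features
#'
#' @param ts a transcript-set data.frame.
#' @param evidence_counts optional named integer (per transcript_id) written
#'   as `evidence_introns=` attribute on mRNA lines.
#' @export
transcripts_to_gff <- function(ts, evidence_counts = NULL) {
  if (!nrow(ts)) return(empty_gff())
  if (is.null(ts$gene_id)) ts$gene_id <- ts$transcript_id
  if (is.null(ts$source)) ts$source <- "genechain"
  rows <- list()
  for (gid in unique(ts$gene_id)) {
    gt <- ts[ts$gene_id == gid, , drop = FALSE]
    rows[[length(rows) + 1L]] <- gff_features(
      seqid = gt$seqid[1L], type = "gene", start = min(gt$start),
      end = max(gt$end), strand = gt$strand[1L], source = gt$source[1L],
      attributes = make_attr(ID = gid))
    for (tid in unique(gt$transcript_id)) {
      tt <- gt[gt$transcript_id == tid, , drop = FALSE]
      ec <- if (!is.null(evidence_counts) && tid %in% names(evidence_counts))
        as.integer(evidence_counts[[tid]]) else NULL
      rows[[length(rows) + 1L]] <- gff_features(
        seqid = tt$seqid[1L], type = "mRNA", start = min(tt$start),
        end = max(tt$end), strand = tt$strand[1L], source = tt$source[1L],
        attributes = if (is.null(ec)) make_attr(ID = tid, Parent = gid)
        else make_attr(ID = tid, Parent = gid, evidence_introns = ec))
      rows[[length(rows) + 1L]] <- gff_features(
        seqid = tt$seqid, type = "exon", start = tt$start, end = tt$end,
        strand = tt$strand, source = tt$source,
        attributes = make_attr(Parent = tid))
      rows[[length(rows) + 1L]] <- gff_features(
        seqid = tt$seqid, type = "CDS", start = tt$start, end = tt$end,
        strand = tt$strand, source = tt$source,
        attributes = make_attr(Parent = tid))
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Build a transcript set from GFF3 mRNA/exon features
#'
#' @param features a `gff_features` data.frame (gene/mRNA/exon rows with
#'   ID/Parent links; exon rows without Parent are grouped by their ID).
#' @export
transcripts_from_gff <- function(features) {
  ex <- features[features$type == "exon", , drop = FALSE]
  if (!nrow(ex)) return(empty_transcripts())
  tid <- gff_attr(ex, "Parent")
  if (anyNA(tid)) tid[is.na(tid)] <- gff_attr(ex, "ID")[is.na(tid)]
  mr <- features[features$type == "mRNA", , drop = FALSE]
  gid_of <- if (nrow(mr)) stats::setNames(gff_attr(mr, "Parent"),
                                          gff_attr(mr, "ID")) else character()
  gene_id <- ifelse(tid %in% names(gid_of), gid_of[tid], tid)
  out <- data.frame(transcript_id = tid, gene_id = gene_id, seqid = ex$seqid,
                    strand = ex$strand, start = ex$start, end = ex$end,
                    source = ex$source, stringsAsFactors = FALSE)
  out <- out[order(out$transcript_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Introns implied by a transcript set: one row per (transcript, gap).
transcript_introns <- function(ts) {
  rows <- lapply(split(seq_len(nrow(ts)), ts$transcript_id), function(idx) {
    tt <- ts[idx[order(ts$start[idx])], , drop = FALSE]
    if (nrow(tt) < 2L) return(NULL)
    data.frame(transcript_id = tt$transcript_id[1L], seqid = tt$seqid[1L],
               strand = tt$strand[1L], start = tt$end[-nrow(tt)] + 1L,
               end = tt$start[-1L] - 1L, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(transcript_id = character(), seqid = character(),
                      strand = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# Canonical structure string of one transcript (exact exon chain identity).
transcript_structure_key <- function(ts) {
  vapply(split(seq_len(nrow(ts)), ts$transcript_id), function(idx) {
    tt <- ts[idx[order(ts$start[idx])], , drop = FALSE]
    paste(tt$seqid[1L], tt$strand[1L],
          paste(tt$start, tt$end, sep = "-", collapse = ","))
  }, "")
}

# Spliced (mature) sequence of a transcript, 5'->3'.
transcript_sequence <- function(ts_one, genome) {
  tt <- ts_one[order(ts_one$start), , drop = FALSE]
  s <- paste(substring(genome$seq, tt$start, tt$end), collapse = "")
  if (tt$strand[1L] == "-") s <- revcomp(s)
  s
}
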