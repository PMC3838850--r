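#' Run the full prediction pipeline
#'
#' Orchestrates the stages: filter alignments -> cluster by splice-site
#' compatibility -> infer consensus evidence introns (-> EST transcripts
#' and longest-ORF CDSs in the AS modes) -> evidence-anchored chaining
#' (-> AS1/AS2 combination) -> optional evaluation. Intermediate artifacts
#' are written as GFF3 when `outdir` is given, and stage counts are
#' collected in the returned log.
#'
#' @param genome a [genome_sequence()].
#' @param alignments list of `spliced_alignment` objects.
#' @param params a [model_params()].
#' @param mode `"introns_only"`, `"AS1"` or `"AS2"`.
#' @param config a [cluster_config()].
#' @param truth optional annotation transcript set; when given an accuracy
#'   report is included.
#' @param outdir optional output directory for GFF3 artifacts.
#' @param k_per_class forwarded to [enumerate_all_candidates()].
#' @return list with `transcripts` (final transcript set), `introns`,
#'   `clusters`, `predictions`, `report` (or NULL) and `log` (stage counts).
#' @export
run_pipeline <- function(genome, alignments, params,
                         mode = c("introns_only", "AS1", "AS2"),
                         config = cluster_config(), truth = NULL,
                         outdir = NULL, k_per_class = Inf) {
  mode <- match.arg(mode)
  log <- list(alignments_in = length(alignments))
  flt <- filter_alignments(alignments, config)
  log$alignments_kept <- length(flt$kept)
  clusters <- cluster_alignments(flt$kept, config)
  log$clusters <- length(clusters)
  introns <- if (length(clusters))
    do.call(rbind, c(lapply(clusters, infer_introns, genome = genome,
                            config = config, params = params),
                     list(make.row.names = FALSE)))
  else empty_evidence()
  introns <- validate_evidence(introns, genome, params$gene_model)$accepted
  log$introns_accepted <- nrow(introns)
  candidates <- enumerate_all_candidates(genome, params, k_per_class)
  log$exon_candidates <- nrow(candidates)
  est_ts <- NULL
  if (mode %in% c("AS1", "AS2")) {
    est_rows <- lapply(clusters, function(cl) {
      ri <- infer_introns(cl, genome, config, params)
      assemble_est_transcripts(cl, ri)
    })
    est_ts <- if (length(est_rows))
      do.call(rbind, c(est_rows, list(make.row.names = FALSE)))
    else NULL
    log$est_transcripts <- if (is.null(est_ts)) 0L
    else length(unique(est_ts$transcript_id))
  }
  pred <- assemble(candidates, introns, params$gene_model,
                   params$intron_bonus)
  ag_ts <- predictions_to_transcripts(pred, source = "AG")
  final <- switch(mode,
    introns_only = ag_ts,
    AS1 = {
      cds <- est_cds_transcripts(est_ts, genome)
      as1_combine(cds, ag_ts)
    },
    AS2 = {
      cds <- est_cds_transcripts(est_ts, genome)
      if (is.null(cds) || !nrow(cds)) ag_ts
      else {
        bins <- as2_bin(cds)
        as2_run(bins, cds, candidates, introns, params$gene_model,
                params$intron_bonus, genome = genome, params = params)
      }
    })
  log$genes <- length(unique(final$transcript_id))
  report <- if (!is.null(truth))
    evaluate_predictions(final, truth, mode = "gene") else NULL
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_introns_gff(introns, file.path(outdir, "evidence_introns.gff3"))
    write_gff3(candidates_to_gff(candidates),
               file.path(outdir, "exon_candidates.gff3"))
    write_gff3(transcripts_to_gff(final),
               file.path(outdir, "predictions.gff3"))
    if (!is.null(est_ts) && nrow(est_ts))
      write_gff3(transcripts_to_gff(est_ts[, c("transcript_id", "seqid",
                                               "strand", "start", "end")]),
                 file.path(outdir, "est_transcripts.gff3"))
  }
  list(transcripts = final, introns = introns, clusters = clusters,
       predictions = pred, est_transcripts = est_ts, report = report,
       log = log)
}

# Longest-ORF CDS projection of EST transcripts: for each EST transcript,
# extract the longest ORF of the spliced sequence and map it back to
# genomic CDS exons.
est_cds_transcripts <- function(est_ts, genome) {
  if (is.null(est_ts) || !nrow(est_ts)) return(empty_transcripts())
  rows <- list()
  for (tid in unique(est_ts$transcript_id)) {
    tt <- est_ts[est_ts$transcript_id == tid, , drop = FALSE]
    tt <- tt[order(tt$start), , drop = FALSE]
    seq <- transcript_sequence(tt, genome)
    orf <- longest_orf(seq)
    if (is.null(orf)) next
    strand <- tt$strand[1L]
    gd <- if (strand == "-") rev(seq_len(nrow(tt))) else seq_len(nrow(tt))
    ex <- tt[gd, , drop = FALSE]
    blocks <- mature_to_blocks(ex, strand, orf$start, orf$end)
    rows[[tid]] <- data.frame(
      transcript_id = paste0(tid, ".cds"), gene_id = tid,
      seqid = tt$seqid[1L], strand = strand,
      start = blocks[, 1L], end = blocks[, 2L], source = "est_cds",
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty_transcripts())
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
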