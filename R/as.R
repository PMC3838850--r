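#' AS1: combine EST transcripts with non-overlapping chained predictions
#'
#' EST-derived transcripts take precedence wherever expression data fully
#' covers a region: every chained gene prediction sharing same-strand exonic
#' overlap (>= 1 bp) with an EST transcript is removed, and the survivors
#' are combined with the EST transcripts.
#'
#' @param est_transcripts transcript-set data.frame of EST-derived
#'   transcripts (source tag is set to `"AS1"`).
#' @param ag_genes transcript-set data.frame of chained predictions.
#' @return combined transcript-set data.frame.
#' @export
as1_combine <- function(est_transcripts, ag_genes) {
  if (is.null(est_transcripts) || !nrow(est_transcripts)) {
    if (nrow(ag_genes)) ag_genes$source <- "AG"
    return(ag_genes)
  }
  est <- est_transcripts
  est$source <- "AS1"
  if (is.null(ag_genes) || !nrow(ag_genes)) return(est)
  drop_gene <- rep(FALSE, nrow(ag_genes))
  for (key in unique(paste(ag_genes$seqid, ag_genes$strand))) {
    gi <- which(paste(ag_genes$seqid, ag_genes$strand) == key)
    ei <- which(paste(est$seqid, est$strand) == key)
    if (!length(ei)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(ag_genes$start[gi], ag_genes$end[gi]),
      IRanges::IRanges(est$start[ei], est$end[ei]))
    drop_gene[gi[unique(S4Vectors::queryHits(ov))]] <- TRUE
  }
  # drop whole transcripts (and their genes) having any overlapping exon
  bad_tid <- unique(ag_genes$transcript_id[drop_gene])
  if (!is.null(ag_genes$gene_id)) {
    bad_gid <- unique(ag_genes$gene_id[ag_genes$transcript_id %in% bad_tid])
    keep <- !(ag_genes$gene_id %in% bad_gid)
  } else keep <- !(ag_genes$transcript_id %in% bad_tid)
  kept <- ag_genes[keep, , drop = FALSE]
  if (nrow(kept)) kept$source <- "AG"
  cols <- union(names(est), names(kept))
  for (cn in setdiff(cols, names(est))) est[[cn]] <- NA
  for (cn in setdiff(cols, names(kept))) kept[[cn]] <- NA
  out <- rbind(est[, cols, drop = FALSE], kept[, cols, drop = FALSE])
  out <- out[order(out$seqid, out$start, out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' AS2 bin assignment for overlapping CDS transcripts
#'
#' Overlapping CDS transcripts at one locus are assigned to separate bins;
#' the number of bins equals the transcript count of the locus with the
#' most alternative transcripts. Loci with fewer transcripts than bins have
#' their CDSs re-used cyclically so that every bin holds one CDS per locus.
#' Within a locus, CDSs fill bins longest-first.
#'
#' @param cds_by_locus named list: per locus, a character vector of
#'   transcript ids; or a transcript-set data.frame (loci are derived by
#'   same-strand exon overlap clustering).
#' @param cds_transcripts transcript-set data.frame (needed to order by
#'   length when `cds_by_locus` is a list of ids).
#' @return list with `n_bins` and `assignment`: per locus, a character
#'   matrix-free list of length `n_bins` giving the transcript id placed in
#'   each bin.
#' @export
as2_bin <- function(cds_by_locus, cds_transcripts = NULL) {
  if (is.data.frame(cds_by_locus)) {
    cds_transcripts <- cds_by_locus
    cl <- cluster_into_genes(cds_by_locus)
    cds_by_locus <- cl
  }
  stopifnot(length(cds_by_locus) >= 1L)
  tlen <- if (!is.null(cds_transcripts))
    vapply(split(cds_transcripts$end - cds_transcripts$start + 1L,
                 cds_transcripts$transcript_id), sum, 1L)
  else NULL
  n_bins <- max(lengths(cds_by_locus))
  assignment <- lapply(cds_by_locus, function(tids) {
    o <- if (!is.null(tlen))
      order(-tlen[tids], tids)   # longest first, ties by id
    else order(tids)
    tids <- tids[o]
    tids[((seq_len(n_bins) - 1L) %% length(tids)) + 1L]  # cyclic re-use
  })
  list(n_bins = n_bins, assignment = assignment)
}

#' AS2: run the chainer once per bin with CDS + unassociated intron evidence
#'
#' For each bin, that bin's CDS transcripts are injected as boosted
#' candidates (their introns joining the evidence set), the unassociated
#' evidence introns (those not contained in any CDS transcript of the
#' binned loci) are added, and the chainer is run; the union of per-bin
#' transcripts with exact-duplicate exon structures removed is returned in
#' deterministic order.
#'
#' @param bins output of [as2_bin()].
#' @param cds_transcripts transcript-set data.frame of CDS transcripts.
#' @param candidates `exon_candidates` data.frame.
#' @param evidence_introns data.frame of evidence introns.
#' @param rules a [gene_model_rules()] list.
#' @param intron_bonus see [assemble()].
#' @param boost score for injected CDS exons.
#' @param genome,params optional, forwarded to [inject_cds_evidence()].
#' @return transcript-set data.frame with `source = "AS2"`.
#' @export
as2_run <- function(bins, cds_transcripts, candidates, evidence_introns,
                    rules = gene_model_rules(), intron_bonus = 1e6,
                    boost = 100, genome = NULL, params = NULL) {
  # unassociated introns: evidence introns not contained within the span of
  # any CDS transcript
  unassoc <- evidence_introns
  if (!is.null(unassoc) && nrow(unassoc) && nrow(cds_transcripts)) {
    spans <- do.call(rbind, lapply(
      split(seq_len(nrow(cds_transcripts)), cds_transcripts$transcript_id),
      function(idx) data.frame(
        seqid = cds_transcripts$seqid[idx[1L]],
        strand = cds_transcripts$strand[idx[1L]],
        start = min(cds_transcripts$start[idx]),
        end = max(cds_transcripts$end[idx]))))
    contained <- vapply(seq_len(nrow(unassoc)), function(k) {
      any(spans$seqid == unassoc$seqid[k] &
            spans$strand == unassoc$strand[k] &
            spans$start <= unassoc$start[k] & spans$end >= unassoc$end[k])
    }, TRUE)
    unassoc <- unassoc[!contained, , drop = FALSE]
  }
  out <- list()
  for (b in seq_len(bins$n_bins)) {
    tids <- vapply(bins$assignment, `[[`, "", b)
    cds_b <- cds_transcripts[cds_transcripts$transcript_id %in% tids, ,
                             drop = FALSE]
    inj <- inject_cds_evidence(cds_b, candidates, boost = boost,
                               genome = genome, params = params)
    ev <- rbind(unassoc[, c("seqid", "start", "end", "strand", "support")],
                inj$introns[, c("seqid", "start", "end", "strand", "support")])
    ev <- validate_evidence(ev, genome, rules)$accepted
    pred <- assemble(inj$candidates, ev, rules, intron_bonus)
    ts <- predictions_to_transcripts(pred, source = "AS2")
    if (nrow(ts)) {
      ts$transcript_id <- paste0("bin", b, ".", ts$transcript_id)
      ts$gene_id <- paste0("bin", b, ".", ts$gene_id)
      out[[b]] <- ts
    }
  }
  if (!length(out)) return(empty_transcripts())
  all_ts <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  # remove exact-duplicate structures (identical exon coordinate chains)
  keys <- transcript_structure_key(all_ts)
  first_tid <- names(keys)[!duplicated(keys)]
  res <- all_ts[all_ts$transcript_id %in% first_tid, , drop = FALSE]
  res <- res[order(res$seqid, res$start, res$transcript_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
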