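#' Cluster transcripts into genes by exon overlap
#'
#' A gene is a connected component of transcripts under same-strand exon
#' overlap (>= 1 bp).
#'
#' @param ts transcript-set data.frame.
#' @return named list: per gene cluster, the character vector of its
#'   transcript ids (deterministic order by leftmost exon).
#' @export
cluster_into_genes <- function(ts) {
  if (!nrow(ts)) return(list())
  tids <- unique(ts$transcript_id)
  idx_of <- match(ts$transcript_id, tids)
  n <- length(tids)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (key in unique(paste(ts$seqid, ts$strand))) {
    rows <- which(paste(ts$seqid, ts$strand) == key)
    ir <- IRanges::IRanges(ts$start[rows], ts$end[rows])
    ov <- IRanges::findOverlaps(ir, ir)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    for (k in seq_along(qh)) {
      a <- idx_of[rows[qh[k]]]; b <- idx_of[rows[sh[k]]]
      if (a != b) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  comp <- vapply(seq_len(n), find, 1L)
  left <- vapply(split(ts$start, idx_of), min, 1L)
  groups <- split(tids, comp)
  o <- order(vapply(groups, function(g) min(left[match(g, tids)]), 1L))
  groups <- groups[o]
  names(groups) <- sprintf("locus%03d", seq_along(groups))
  groups
}

#' Project a gene cluster onto the genome
#'
#' Union of all member exon intervals, merged and sorted.
#'
#' @param ts transcript-set data.frame restricted to one gene cluster.
#' @return data.frame with `start`, `end` (disjoint, ascending).
#' @export
project_gene <- function(ts) {
  r <- IRanges::reduce(IRanges::IRanges(ts$start, ts$end))
  data.frame(start = IRanges::start(r), end = IRanges::end(r))
}

#' Multi-level prediction accuracy
#'
#' Compares predicted and annotated transcript sets at the nucleotide,
#' exon, intron, gene and transcript levels. In `gene` mode transcripts of
#' each gene cluster are projected to the genome and features compared on
#' the projections (introns and transcripts are compared on the transcript
#' structures). In `btp` mode a best-transcript-pair mapping is first
#' established per overlapping cluster pair and all measures are computed
#' over matched pairs only, which gauges the connectivity of predictions.
#'
#' Definitions per level: SN = TP/(TP+FN), SP = TP/(TP+FP),
#' SS = (SN+SP)/2, W = predicted features with zero overlap to any
#' annotated feature / predicted total, M = annotated features with zero
#' overlap / annotated total. Exon and intron TPs are exact-boundary
#' matches; a gene is found iff overlapped by a predicted gene with >= 1
#' same-strand exonic bp; a transcript is a TP iff its complete intron
#' chain and CDS boundaries match exactly. Undefined ratios (0/0) are
#' reported as 0 and flagged degenerate.
#'
#' @param pred,annot transcript-set data.frames.
#' @param mode `"gene"` or `"btp"`.
#' @param btp_threshold split/join overlap threshold, see [btp_map()].
#' @return an `accuracy_report` data.frame (one row per level).
#' @export
evaluate_predictions <- function(pred, annot, mode = c("gene", "btp"),
                                 btp_threshold = 0.5) {
  mode <- match.arg(mode)
  for (ts in list(pred, annot)) {
    if (nrow(ts)) {
      bad <- vapply(split(ts$strand, ts$transcript_id),
                    function(s) length(unique(s)) != 1L, TRUE)
      if (any(bad)) stop("contradictory strands within transcript: ",
                         names(bad)[bad][1L])
    }
  }
  if (mode == "btp") return(evaluate_btp(pred, annot, btp_threshold))
  pg <- cluster_into_genes(pred)
  ag <- cluster_into_genes(annot)
  pred_proj <- cluster_projections(pred, pg)
  annot_proj <- cluster_projections(annot, ag)
  report <- rbind(
    nucleotide_level(pred_proj, annot_proj),
    exon_level(pred_proj, annot_proj),
    intron_level(pred, annot),
    gene_level(pred_proj, annot_proj),
    transcript_level(pred, annot))
  finish_report(report, mode = "gene_projection")
}

# Per-cluster projected exon intervals with seqid/strand, flattened.
cluster_projections <- function(ts, clusters) {
  rows <- lapply(names(clusters), function(cl) {
    sub <- ts[ts$transcript_id %in% clusters[[cl]], , drop = FALSE]
    p <- project_gene(sub)
    data.frame(cluster = cl, seqid = sub$seqid[1L], strand = sub$strand[1L],
               start = p$start, end = p$end, stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(cluster = character(), seqid = character(),
                      strand = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# Base-level TP/FP/FN on projected coding bases (same strand + seqid).
nucleotide_level <- function(pp, ap) {
  tp <- 0L
  for (key in union(paste(pp$seqid, pp$strand), paste(ap$seqid, ap$strand))) {
    pi <- which(paste(pp$seqid, pp$strand) == key)
    ai <- which(paste(ap$seqid, ap$strand) == key)
    if (!length(pi) || !length(ai)) next
    inter <- IRanges::intersect(
      IRanges::reduce(IRanges::IRanges(pp$start[pi], pp$end[pi])),
      IRanges::reduce(IRanges::IRanges(ap$start[ai], ap$end[ai])))
    tp <- tp + sum(IRanges::width(inter))
  }
  ptot <- sum(pp$end - pp$start + 1L)
  atot <- sum(ap$end - ap$start + 1L)
  level_row("nucleotide", tp, fp = ptot - tp, fn = atot - tp,
            w = if (ptot > 0) (ptot - tp) / ptot else NA,
            m = if (atot > 0) (atot - tp) / atot else NA)
}

exon_level <- function(pp, ap) {
  pk <- paste(pp$seqid, pp$strand, pp$start, pp$end)
  ak <- paste(ap$seqid, ap$strand, ap$start, ap$end)
  tp <- sum(pk %in% ak)
  feat_row("exon", pp, ap, tp)
}

intron_level <- function(pred, annot) {
  pin <- unique_introns(pred)
  ain <- unique_introns(annot)
  pk <- paste(pin$seqid, pin$strand, pin$start, pin$end)
  ak <- paste(ain$seqid, ain$strand, ain$start, ain$end)
  tp <- sum(pk %in% ak)
  feat_row("intron", pin, ain, tp)
}

unique_introns <- function(ts) {
  ti <- transcript_introns(ts)
  if (!nrow(ti)) return(ti)
  ti[!duplicated(paste(ti$seqid, ti$strand, ti$start, ti$end)), ,
     drop = FALSE]
}

# Shared feature-row logic: W/M are zero-overlap fractions.
feat_row <- function(level, pf, af, tp) {
  ptot <- nrow(pf); atot <- nrow(af)
  w <- if (ptot > 0) mean(!feature_overlaps(pf, af)) else NA
  m <- if (atot > 0) mean(!feature_overlaps(af, pf)) else NA
  level_row(level, tp, fp = ptot - tp, fn = atot - tp, w = w, m = m)
}

# For each row of a, does any row of b overlap it (same seqid+strand)?
feature_overlaps <- function(a, b) {
  if (!nrow(a)) return(logical())
  if (!nrow(b)) return(rep(FALSE, nrow(a)))
  out <- rep(FALSE, nrow(a))
  for (key in unique(paste(a$seqid, a$strand))) {
    ai <- which(paste(a$seqid, a$strand) == key)
    bi <- which(paste(b$seqid, b$strand) == key)
    if (!length(bi)) next
    cnt <- IRanges::countOverlaps(IRanges::IRanges(a$start[ai], a$end[ai]),
                                  IRanges::IRanges(b$start[bi], b$end[bi]))
    out[ai] <- cnt > 0L
  }
  out
}

gene_level <- function(pp, ap) {
  if (!nrow(ap)) afound <- logical()
  else afound <- vapply(split(seq_len(nrow(ap)), ap$cluster), function(idx)
    any(feature_overlaps(ap[idx, , drop = FALSE], pp)), TRUE)
  if (!nrow(pp)) pfound <- logical()
  else pfound <- vapply(split(seq_len(nrow(pp)), pp$cluster), function(idx)
    any(feature_overlaps(pp[idx, , drop = FALSE], ap)), TRUE)
  tp_sn <- sum(afound); tp_sp <- sum(pfound)
  atot <- length(afound); ptot <- length(pfound)
  # gene level: SN and SP numerators count found genes on each side
  data.frame(level = "gene",
             SN = ratio(tp_sn, atot), SP = ratio(tp_sp, ptot),
             W = if (ptot > 0) mean(!pfound) else NA,
             M = if (atot > 0) mean(!afound) else NA,
             TP = tp_sn, FP = ptot - tp_sp, FN = atot - tp_sn,
             degenerate = atot == 0L || ptot == 0L,
             stringsAsFactors = FALSE)
}

transcript_level <- function(pred, annot) {
  pk <- transcript_structure_key(pred)
  ak <- transcript_structure_key(annot)
  tp <- sum(pk %in% ak)
  ptot <- length(pk); atot <- length(ak)
  # zero-overlap W/M at transcript level uses transcript spans
  pspan <- transcript_spans(pred); aspan <- transcript_spans(annot)
  w <- if (ptot > 0) mean(!feature_overlaps(pspan, aspan)) else NA
  m <- if (atot > 0) mean(!feature_overlaps(aspan, pspan)) else NA
  level_row("transcript", tp, fp = ptot - tp, fn = atot - tp, w = w, m = m)
}

transcript_spans <- function(ts) {
  if (!nrow(ts))
    return(data.frame(seqid = character(), strand = character(),
                      start = integer(), end = integer()))
  sp <- lapply(split(seq_len(nrow(ts)), ts$transcript_id), function(idx)
    data.frame(seqid = ts$seqid[idx[1L]], strand = ts$strand[idx[1L]],
               start = min(ts$start[idx]), end = max(ts$end[idx])))
  do.call(rbind, c(sp, list(make.row.names = FALSE)))
}

ratio <- function(num, den) if (den > 0) num / den else 0

level_row <- function(level, tp, fp, fn, w, m) {
  data.frame(level = level,
             SN = ratio(tp, tp + fn), SP = ratio(tp, tp + fp),
             W = w, M = m, TP = tp, FP = fp, FN = fn,
             degenerate = (tp + fn) == 0L || (tp + fp) == 0L,
             stringsAsFactors = FALSE)
}

finish_report <- function(report, mode) {
  report$SS <- (report$SN + report$SP) / 2
  report$W[is.na(report$W)] <- 0
  report$M[is.na(report$M)] <- 0
  report$mode <- mode
  report <- report[, c("level", "mode", "SN", "SP", "SS", "W", "M",
                       "TP", "FP", "FN", "degenerate")]
  class(report) <- c("accuracy_report", "data.frame")
  report
}

#' @export
print.accuracy_report <- function(x, digits = 3, ...) {
  cat(sprintf("Accuracy report (%s)\n", x$mode[1L]))
  df <- as.data.frame(x)
  for (cn in c("SN", "SP", "SS", "W", "M"))
    df[[cn]] <- round(df[[cn]], digits)
  print(df[, c("level", "SN", "SP", "SS", "W", "M", "TP", "FP", "FN")],
        row.names = FALSE)
  flagged <- df$level[df$degenerate]
  if (length(flagged))
    cat("note: degenerate (0/0) ratios reported as 0 at:",
        paste(flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Best-transcript-pair mapping between two gene clusters
#'
#' Greedy maximum-weight one-to-one matching on shared same-strand exonic
#' base overlap; afterwards an unmatched transcript may attach to an
#' already-matched partner (split/join case) when the shared overlap
#' exceeds `threshold` of the smaller transcript's coding length.
#'
#' @param pred_cluster,annot_cluster transcript-set data.frames (one gene
#'   cluster each).
#' @param threshold split/join attachment fraction (default 0.5).
#' @return list with `pairs` (data.frame pred_id, annot_id, overlap,
#'   relation) and `unmatched_pred`, `unmatched_annot` id vectors.
#' @export
btp_map <- function(pred_cluster, annot_cluster, threshold = 0.5) {
  pids <- unique(pred_cluster$transcript_id)
  aids <- unique(annot_cluster$transcript_id)
  wmat <- matrix(0L, length(pids), length(aids),
                 dimnames = list(pids, aids))
  plen <- integer(length(pids)); names(plen) <- pids
  alen <- integer(length(aids)); names(alen) <- aids
  for (p in pids) {
    pe <- pred_cluster[pred_cluster$transcript_id == p, , drop = FALSE]
    plen[p] <- sum(pe$end - pe$start + 1L)
    for (a in aids) {
      ae <- annot_cluster[annot_cluster$transcript_id == a, , drop = FALSE]
      alen[a] <- sum(ae$end - ae$start + 1L)
      if (pe$strand[1L] != ae$strand[1L] || pe$seqid[1L] != ae$seqid[1L])
        next
      inter <- IRanges::intersect(
        IRanges::reduce(IRanges::IRanges(pe$start, pe$end)),
        IRanges::reduce(IRanges::IRanges(ae$start, ae$end)))
      wmat[p, a] <- sum(IRanges::width(inter))
    }
  }
  pairs <- data.frame(pred_id = character(), annot_id = character(),
                      overlap = integer(), relation = character(),
                      stringsAsFactors = FALSE)
  free_p <- pids; free_a <- aids
  repeat {
    if (!length(free_p) || !length(free_a)) break
    sub <- wmat[free_p, free_a, drop = FALSE]
    if (max(sub) <= 0L) break
    hit <- which(sub == max(sub), arr.ind = TRUE)[1L, ]
    p <- free_p[hit[1L]]; a <- free_a[hit[2L]]
    pairs <- rbind(pairs, data.frame(pred_id = p, annot_id = a,
                                     overlap = sub[hit[1L], hit[2L]],
                                     relation = "one_to_one"))
    free_p <- setdiff(free_p, p); free_a <- setdiff(free_a, a)
  }
  # split/join attachments
  for (a in free_a) {
    cand <- setdiff(pids, free_p)
    if (!length(cand)) break
    ovs <- wmat[cand, a]
    best <- cand[which.max(ovs)]
    need <- threshold * min(alen[a], plen[best])
    if (max(ovs) > need) {
      pairs <- rbind(pairs, data.frame(pred_id = best, annot_id = a,
                                       overlap = max(ovs),
                                       relation = "join"))
      free_a <- setdiff(free_a, a)
    }
  }
  for (p in free_p) {
    cand <- setdiff(aids, free_a)
    if (!length(cand)) break
    ovs <- wmat[p, cand]
    best <- cand[which.max(ovs)]
    need <- threshold * min(plen[p], alen[best])
    if (max(ovs) > need) {
      pairs <- rbind(pairs, data.frame(pred_id = p, annot_id = best,
                                       overlap = max(ovs),
                                       relation = "split"))
      free_p <- setdiff(free_p, p)
    }
  }
  list(pairs = pairs, unmatched_pred = free_p, unmatched_annot = free_a)
}

# BTP-mode evaluation: aggregate feature counts over matched pairs only.
evaluate_btp <- function(pred, annot, threshold = 0.5) {
  both <- rbind(pred[, c("transcript_id", "seqid", "strand", "start", "end")],
                annot[, c("transcript_id", "seqid", "strand", "start", "end")])
  # pair up overlapping pred/annot clusters
  pg <- cluster_into_genes(pred)
  ag <- cluster_into_genes(annot)
  counts <- list(nt = c(0L, 0L, 0L), ex = c(0L, 0L, 0L),
                 int = c(0L, 0L, 0L), tr = c(0L, 0L, 0L))  # tp, ptot, atot
  wz <- c(0L, 0L); mz <- c(0L, 0L)    # zero-overlap pred / annot exons
  for (acl in names(ag)) {
    asub <- annot[annot$transcript_id %in% ag[[acl]], , drop = FALSE]
    # find overlapping predicted cluster(s)
    for (pcl in names(pg)) {
      psub <- pred[pred$transcript_id %in% pg[[pcl]], , drop = FALSE]
      if (!any(feature_overlaps(asub, psub))) next
      bm <- btp_map(psub, asub, threshold)
      for (k in seq_len(nrow(bm$pairs))) {
        pe <- psub[psub$transcript_id == bm$pairs$pred_id[k], , drop = FALSE]
        ae <- asub[asub$transcript_id == bm$pairs$annot_id[k], , drop = FALSE]
        inter <- IRanges::intersect(
          IRanges::reduce(IRanges::IRanges(pe$start, pe$end)),
          IRanges::reduce(IRanges::IRanges(ae$start, ae$end)))
        counts$nt <- counts$nt + c(sum(IRanges::width(inter)),
                                   sum(pe$end - pe$start + 1L),
                                   sum(ae$end - ae$start + 1L))
        pk <- paste(pe$start, pe$end); ak <- paste(ae$start, ae$end)
        counts$ex <- counts$ex + c(sum(pk %in% ak), length(pk), length(ak))
        pint <- transcript_introns(pe); aint <- transcript_introns(ae)
        pik <- paste(pint$start, pint$end); aik <- paste(aint$start, aint$end)
        counts$int <- counts$int + c(sum(pik %in% aik), length(pik),
                                     length(aik))
        exact <- length(pk) == length(ak) && all(pk == ak)
        counts$tr <- counts$tr + c(as.integer(exact), 1L, 1L)
        wz <- wz + c(sum(!feature_overlaps(pe, ae)), length(pk))
        mz <- mz + c(sum(!feature_overlaps(ae, pe)), length(ak))
      }
    }
  }
  rows <- rbind(
    level_row("nucleotide", counts$nt[1L], counts$nt[2L] - counts$nt[1L],
              counts$nt[3L] - counts$nt[1L],
              w = ratio(counts$nt[2L] - counts$nt[1L], counts$nt[2L]),
              m = ratio(counts$nt[3L] - counts$nt[1L], counts$nt[3L])),
    level_row("exon", counts$ex[1L], counts$ex[2L] - counts$ex[1L],
              counts$ex[3L] - counts$ex[1L],
              w = ratio(wz[1L], wz[2L]), m = ratio(mz[1L], mz[2L])),
    level_row("intron", counts$int[1L], counts$int[2L] - counts$int[1L],
              counts$int[3L] - counts$int[1L], w = NA, m = NA),
    level_row("transcript", counts$tr[1L], counts$tr[2L] - counts$tr[1L],
              counts$tr[3L] - counts$tr[1L], w = NA, m = NA))
  finish_report(rows, mode = "BTP")
}

#' Intron-fraction titration experiment
#'
#' Random subsets of the evidence introns (a grid of fractions, `n_reps`
#' seeded replicates each) are given to the chainer and the resulting
#' predictions evaluated against the truth annotation; reports the mean
#' accuracy SS = (SN+SP)/2 at the gene, exon and nucleotide levels per
#' fraction. Mirrors the observation that the benefit of EST-confirmed
#' introns grows with the number supplied.
#'
#' @param candidates `exon_candidates` (precomputed once).
#' @param truth annotation transcript-set data.frame.
#' @param introns full evidence-intron data.frame.
#' @param fractions numeric vector in `[0,1]`.
#' @param n_reps replicates per fraction.
#' @param seed integer seed.
#' @param rules,intron_bonus chaining settings.
#' @return data.frame with columns `fraction`, `SSg`, `SSe`, `SSn` (means
#'   over replicates).
#' @export
titration_experiment <- function(candidates, truth, introns,
                                 fractions = seq(0, 1, by = 0.25),
                                 n_reps = 3L, seed = 1L,
                                 rules = gene_model_rules(),
                                 intron_bonus = 1e6) {
  res <- list()
  n <- nrow(introns)
  for (f in fractions) {
    ss <- matrix(0, n_reps, 3L)
    for (r in seq_len(n_reps)) {
      set.seed(seed + 7919L * r + round(1e4 * f))
      k <- round(f * n)
      sub <- if (k > 0L) introns[sort(sample.int(n, k)), , drop = FALSE]
      else introns[0, , drop = FALSE]
      pred <- assemble(candidates, sub, rules, intron_bonus)
      ts <- predictions_to_transcripts(pred)
      rep <- evaluate_predictions(ts, truth, mode = "gene")
      ss[r, ] <- rep$SS[match(c("gene", "exon", "nucleotide"), rep$level)]
    }
    res[[length(res) + 1L]] <- data.frame(
      fraction = f, SSg = mean(ss[, 1L]), SSe = mean(ss[, 2L]),
      SSn = mean(ss[, 3L]))
  }
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}
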