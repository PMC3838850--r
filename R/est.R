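#' EST clustering configuration
#'
#' @param min_identity minimum alignment identity to retain (0.95 default;
#'   0.98 is typical for human-style data).
#' @param min_coverage alignments are kept only when coverage is *strictly*
#'   greater than this fraction of the EST length.
#' @param boundary_tolerance maximum disagreement (bases) between splice
#'   sites still considered the same site.
#' @param min_intron_support minimum number of supporting alignments for an
#'   inferred intron.
#' @param shift_window maximum shift (bases) applied to a consensus intron
#'   to reach canonical GT..AG boundaries.
#' @export
cluster_config <- function(min_identity = 0.95, min_coverage = 0.90,
                           boundary_tolerance = 3L, min_intron_support = 1L,
                           shift_window = 5L) {
  stopifnot(min_identity >= 0, min_identity <= 1,
            min_coverage >= 0, min_coverage <= 1,
            boundary_tolerance >= 0, shift_window >= 0,
            min_intron_support >= 1)
  list(min_identity = min_identity, min_coverage = min_coverage,
       boundary_tolerance = as.integer(boundary_tolerance),
       min_intron_support = as.integer(min_intron_support),
       shift_window = as.integer(shift_window))
}

#' Filter spliced alignments on identity and coverage
#'
#' Kept iff `identity >= min_identity` and `coverage > min_coverage`
#' (coverage strictly greater).
#'
#' @param alignments list of `spliced_alignment` objects.
#' @param config a [cluster_config()].
#' @return list with `kept` and `discarded` alignment lists.
#' @export
filter_alignments <- function(alignments, config = cluster_config()) {
  ok <- vapply(alignments, function(a)
    a$identity >= config$min_identity && a$coverage > config$min_coverage,
    TRUE)
  list(kept = alignments[ok], discarded = alignments[!ok])
}

#' Cluster alignments by shared splice sites
#'
#' Spliced alignments sharing at least one splice site (gap boundary, same
#' side, same strand and seqid) within `boundary_tolerance` are linked;
#' clusters are the connected components. Unspliced alignments are attached
#' to the same-strand cluster with the largest span overlap, or form
#' singleton clusters when none overlaps.
#'
#' @param alignments list of kept `spliced_alignment` objects.
#' @param config a [cluster_config()].
#' @return list of `est_cluster` objects: `cluster_id`, `seqid`, `strand`,
#'   `members` (alignment list), `span` (c(start,end)).
#' @export
cluster_alignments <- function(alignments, config = cluster_config()) {
  n <- length(alignments)
  if (n == 0L) return(list())
  gaps <- lapply(alignments, alignment_gaps)
  spliced <- vapply(gaps, nrow, 1L) > 0L
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  tol <- config$boundary_tolerance
  si <- which(spliced)
  if (length(si) > 1L) {
    # site table: (alignment, side, position)
    site_df <- do.call(rbind, lapply(si, function(i) {
      g <- gaps[[i]]
      rbind(data.frame(aln = i, side = "d", pos = g[, 1L]),
            data.frame(aln = i, side = "a", pos = g[, 2L]))
    }))
    for (sd in c("d", "a")) {
      s <- site_df[site_df$side == sd, ]
      if (nrow(s) < 2L) next
      o <- order(s$pos)
      s <- s[o, ]
      for (k in 2:nrow(s)) {
        # link to all previous sites within tolerance
        j <- k - 1L
        while (j >= 1L && s$pos[k] - s$pos[j] <= tol) {
          a1 <- s$aln[k]; a2 <- s$aln[j]
          if (a1 != a2 &&
              alignments[[a1]]$strand == alignments[[a2]]$strand &&
              alignments[[a1]]$seqid == alignments[[a2]]$seqid)
            union(a1, a2)
          j <- j - 1L
        }
      }
    }
  }
  comp <- vapply(seq_len(n), find, 1L)
  # attach unspliced to overlapping spliced component (largest overlap, same
  # strand/seqid); remaining unspliced form their own components
  spans <- t(vapply(alignments, function(a)
    c(a$blocks[1L, 1L], a$blocks[nrow(a$blocks), 2L]), c(1L, 1L)))
  for (i in which(!spliced)) {
    best <- 0L; best_comp <- NA_integer_
    for (j in si) {
      if (alignments[[j]]$strand != alignments[[i]]$strand ||
          alignments[[j]]$seqid != alignments[[i]]$seqid) next
      ov <- min(spans[i, 2L], spans[j, 2L]) - max(spans[i, 1L], spans[j, 1L]) + 1L
      if (ov > best) { best <- ov; best_comp <- comp[j] }
    }
    if (!is.na(best_comp)) comp[i] <- best_comp
  }
  ids <- sort(unique(comp))
  out <- lapply(seq_along(ids), function(k) {
    idx <- which(comp == ids[k])
    mem <- alignments[idx]
    span <- c(min(spans[idx, 1L]), max(spans[idx, 2L]))
    structure(list(cluster_id = sprintf("cluster%03d", k),
                   seqid = mem[[1L]]$seqid, strand = mem[[1L]]$strand,
                   members = mem, span = span),
              class = "est_cluster")
  })
  # deterministic order by span start
  out[order(vapply(out, function(cl) cl$span[1L], 1L))]
}

#' @export
print.est_cluster <- function(x, ...) {
  cat(sprintf("<est_cluster> %s [%s] %d-%d: %d member(s)\n", x$cluster_id,
              x$strand, x$span[1L], x$span[2L], length(x$members)))
  invisible(x)
}

#' Infer consensus evidence introns from an EST cluster
#'
#' Candidate introns are the block gaps of the cluster members; gaps whose
#' boundaries agree within `boundary_tolerance` are merged (modal
#' coordinates, ties to the smallest). Each merged intron is then shifted
#' within `±shift_window` to the position with canonical GT..AG boundaries
#' on the cluster strand, choosing the shift maximizing the donor+acceptor
#' PWM score when `params` is given (otherwise the smallest |shift|).
#' Introns that cannot be canonicalized, or with support below
#' `min_intron_support`, are dropped.
#'
#' @param cluster an `est_cluster`.
#' @param genome a [genome_sequence()].
#' @param config a [cluster_config()].
#' @param params optional [model_params()] for PWM-guided shifting.
#' @return data.frame of evidence introns (`seqid`, `start`, `end`,
#'   `strand`, `support`).
#' @export
infer_introns <- function(cluster, genome, config = cluster_config(),
                          params = NULL) {
  gaps <- lapply(cluster$members, alignment_gaps)
  ng <- vapply(gaps, nrow, 1L)
  if (sum(ng) == 0L) return(empty_evidence())
  g <- do.call(rbind, gaps[ng > 0L])
  member <- rep(seq_along(cluster$members)[ng > 0L], ng[ng > 0L])
  # merge gaps whose boundaries agree within tolerance (union-find)
  m <- nrow(g)
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  tol <- config$boundary_tolerance
  o <- order(g[, 1L])
  for (x in seq_len(m - 1L)) {
    for (y in (x + 1L):m) {
      if (g[o[y], 1L] - g[o[x], 1L] > tol) break
      if (abs(g[o[y], 2L] - g[o[x], 2L]) <= tol) {
        rx <- find(o[x]); ry <- find(o[y])
        if (rx != ry) parent[max(rx, ry)] <- min(rx, ry)
      }
    }
  }
  comp <- vapply(seq_len(m), find, 1L)
  out <- list()
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    support <- length(unique(member[idx]))
    if (support < config$min_intron_support) next
    # modal (start,end) pair; ties to smallest
    key <- paste(g[idx, 1L], g[idx, 2L])
    tab <- table(key)
    win <- names(tab)[tab == max(tab)]
    win <- sort(win)[1L]
    se <- as.integer(strsplit(win, " ", fixed = TRUE)[[1L]])
    shifted <- canonical_shift(se[1L], se[2L], cluster$strand, genome,
                               config$shift_window, params)
    if (is.null(shifted)) next
    out[[length(out) + 1L]] <- data.frame(
      seqid = cluster$seqid, start = shifted[1L], end = shifted[2L],
      strand = cluster$strand, support = support, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty_evidence())
  res <- do.call(rbind, out)
  # merging may have produced identical refined introns; merge support
  res <- validate_evidence(res, genome,
                           gene_model_rules(min_intron_len = 4L,
                                            max_intron_len = max(res$end - res$start + 1L, 6L) + 1L)
  )$accepted
  res[order(res$start, res$end), , drop = FALSE]
}

# Shift intron (start,end) by the same s in -w..w so its boundaries are
# canonical in gene direction: "+" introns read GT..AG on the forward
# strand; "-" introns read CT..AC forward (GT..AG on the reverse
# complement). Returns c(start,end) or NULL.
canonical_shift <- function(start, end, strand, genome, w, params = NULL) {
  L <- genome$length
  shifts <- (-w):w
  cand <- list()
  for (s in shifts) {
    st <- start + s; en <- end + s
    if (st < 1L || en > L || st >= en) next
    don <- substr(genome$seq, st, st + 1L)
    acc <- substr(genome$seq, en - 1L, en)
    ok <- if (strand == "+") don == "GT" && acc == "AG"
    else don == "CT" && acc == "AC"
    if (!ok) next
    sc <- if (!is.null(params)) {
      dpos <- if (strand == "+") st else en
      apos <- if (strand == "+") en - 1L else st + 1L
      d <- score_pwm(params$pwms$donor, genome, dpos, strand)
      a <- score_pwm(params$pwms$acceptor, genome, apos, strand)
      sum(c(d, a), na.rm = TRUE)
    } else -abs(s)
    cand[[length(cand) + 1L]] <- c(st, en, sc, abs(s), s)
  }
  if (!length(cand)) return(NULL)
  cm <- do.call(rbind, cand)
  o <- order(-cm[, 3L], cm[, 4L], cm[, 5L])
  as.integer(cm[o[1L], 1:2])
}

#' Assemble the minimal set of non-mergeable EST transcripts
#'
#' Cluster members are re-expressed over the refined introns (each member
#' gap is replaced by the refined intron it supports). Structures are then
#' merged greedily to a fixpoint: two structures merge iff their overlap
#' implies no conflict (no intron of one intersecting exonic sequence of
#' the other, no boundary disagreement). The result is a set in which no
#' two transcripts are mergeable, in deterministic order (longest span
#' first, then leftmost).
#'
#' @param cluster an `est_cluster`.
#' @param introns data.frame of refined introns from [infer_introns()].
#' @return a transcript-set data.frame (exon rows with `transcript_id`,
#'   `seqid`, `strand`, `start`, `end`, `supporting_ests`).
#' @export
assemble_est_transcripts <- function(cluster, introns) {
  tol_introns <- introns
  members <- cluster$members
  structs <- lapply(members, function(a) {
    span <- c(a$blocks[1L, 1L], a$blocks[nrow(a$blocks), 2L])
    gaps <- alignment_gaps(a)
    ints <- integer(0)
    if (nrow(gaps) && nrow(tol_introns)) {
      for (k in seq_len(nrow(gaps))) {
        # refined intron nearest to this gap (boundary agreement)
        d <- abs(tol_introns$start - gaps[k, 1L]) +
          abs(tol_introns$end - gaps[k, 2L])
        j <- which.min(d)
        if (length(j)) ints <- c(ints, j)
      }
    }
    list(span = span, introns = sort(unique(ints)), ests = a$est_id)
  })
  mergeable <- function(x, y) {
    ov <- c(max(x$span[1L], y$span[1L]), min(x$span[2L], y$span[2L]))
    if (ov[1L] > ov[2L]) return(FALSE)          # disjoint spans: not merged
    for (j in x$introns) {
      i1 <- tol_introns[j, ]
      if (i1$end < ov[1L] || i1$start > ov[2L]) next  # outside overlap
      if (!(j %in% y$introns)) return(FALSE)    # y has exon over x's intron
    }
    for (j in y$introns) {
      i1 <- tol_introns[j, ]
      if (i1$end < ov[1L] || i1$start > ov[2L]) next
      if (!(j %in% x$introns)) return(FALSE)
    }
    TRUE
  }
  merge2 <- function(x, y) {
    list(span = c(min(x$span[1L], y$span[1L]), max(x$span[2L], y$span[2L])),
         introns = sort(unique(c(x$introns, y$introns))),
         ests = sort(unique(c(x$ests, y$ests))))
  }
  repeat {
    # deterministic order: longest span first, then leftmost
    o <- order(-vapply(structs, function(s) diff(s$span) + 1L, 1L),
               vapply(structs, function(s) s$span[1L], 1L))
    structs <- structs[o]
    merged <- FALSE
    for (x in seq_along(structs)) {
      if (merged) break
      for (y in seq_along(structs)) {
        if (y <= x) next
        if (mergeable(structs[[x]], structs[[y]])) {
          structs[[x]] <- merge2(structs[[x]], structs[[y]])
          structs[[y]] <- NULL
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  rows <- list()
  for (k in seq_along(structs)) {
    s <- structs[[k]]
    tid <- sprintf("%s.t%d", cluster$cluster_id, k)
    ints <- tol_introns[s$introns, , drop = FALSE]
    ints <- ints[order(ints$start), , drop = FALSE]
    starts <- c(s$span[1L], ints$end + 1L)
    ends <- c(ints$start - 1L, s$span[2L])
    rows[[k]] <- data.frame(
      transcript_id = tid, seqid = cluster$seqid, strand = cluster$strand,
      start = starts, end = ends,
      supporting_ests = paste(s$ests, collapse = ","),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$transcript_id, out$start), , drop = FALSE]
}

#' Longest open reading frame of a spliced transcript sequence
#'
#' Scans the three forward frames for the longest ATG..stop open reading
#' frame (stop codon included); ties go to the 5'-most start.
#'
#' @param transcript_seq character string (exons concatenated,
#'   strand-corrected so it reads 5'->3').
#' @return list with `start`, `end` (1-based inclusive, stop included),
#'   `frame` (0..2) and `length`; or NULL when no complete ORF exists.
#' @export
longest_orf <- function(transcript_seq) {
  seq <- toupper(transcript_seq)
  n <- nchar(seq)
  best <- NULL
  codons <- function(from) {
    n3 <- (n - from + 1L) %/% 3L
    if (n3 < 1L) return(character())
    substring(seq, from + 3L * (0:(n3 - 1L)), from + 3L * (0:(n3 - 1L)) + 2L)
  }
  for (f in 0:2) {
    cs <- codons(f + 1L)
    if (!length(cs)) next
    is_start <- cs == "ATG"
    is_stop <- cs %in% c("TAA", "TAG", "TGA")
    open_at <- NA_integer_
    for (k in seq_along(cs)) {
      if (is.na(open_at) && is_start[k]) open_at <- k
      if (!is.na(open_at) && is_stop[k]) {
        len <- (k - open_at + 1L) * 3L
        start <- f + 1L + (open_at - 1L) * 3L
        if (is.null(best) || len > best$length ||
            (len == best$length && start < best$start))
          best <- list(start = start, end = start + len - 1L, frame = f,
                       length = len)
        open_at <- NA_integer_
      }
    }
  }
  best
}

#' Length-modulo-3 profile of a set of introns
#'
#' Real spliceosomal introns are frame-agnostic, so the three length classes
#' (length mod 3 = 0, 1, 2) should each hold about a third of the introns; a
#' skewed profile indicates annotation or alignment artefacts.
#'
#' @param introns data.frame with `start`, `end` (or a numeric vector of
#'   intron lengths).
#' @return named numeric `c(mod0=, mod1=, mod2=)` summing to 1.
#' @export
mod3_profile <- function(introns) {
  len <- if (is.data.frame(introns)) introns$end - introns$start + 1L
  else as.integer(introns)
  if (!length(len)) stop("mod3_profile requires at least one intron")
  cls <- len %% 3L
  c(mod0 = mean(cls == 0L), mod1 = mean(cls == 1L), mod2 = mean(cls == 2L))
}

#' Write evidence introns as GFF3
#' @param introns data.frame from [infer_introns()]/[validate_evidence()].
#' @param path output path.
#' @export
write_introns_gff <- function(introns, path) {
  if (!nrow(introns)) return(write_gff3(empty_gff(), path))
  write_gff3(gff_features(
    seqid = introns$seqid, type = "intron", start = introns$start,
    end = introns$end, strand = introns$strand, source = "est",
    attributes = sprintf("ID=intron%04d;support=%d",
                         seq_len(nrow(introns)), introns$support)), path)
}

#' Read evidence introns from GFF3
#' @param path GFF3 file with intron features.
#' @export
read_introns_gff <- function(path) {
  f <- read_gff3(path, feature_filter = "intron")
  if (!nrow(f)) return(empty_evidence())
  sup <- suppressWarnings(as.integer(gff_attr(f, "support")))
  sup[is.na(sup)] <- 1L
  data.frame(seqid = f$seqid, start = f$start, end = f$end,
             strand = f$strand, support = sup, stringsAsFactors = FALSE)
}
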