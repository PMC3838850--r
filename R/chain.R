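#' Validate evidence introns against the genome and gene model
#'
#' Introns with out-of-bounds length, undefined strand or coordinates
#' outside the genome are rejected with a reason; exact duplicates are
#' merged with summed support.
#'
#' @param introns data.frame with columns `start`, `end`, `strand` and
#'   optionally `seqid`, `support` (default 1).
#' @param genome a [genome_sequence()] (or NULL to skip the bounds check).
#' @param rules a [gene_model_rules()] list.
#' @return list with `accepted` (merged data.frame) and `rejected`
#'   (data.frame with a `reason` column).
#' @export
validate_evidence <- function(introns, genome = NULL,
                              rules = gene_model_rules()) {
  if (is.null(introns) || !nrow(introns))
    return(list(accepted = empty_evidence(), rejected = empty_evidence(TRUE)))
  introns <- as.data.frame(introns)
  if (is.null(introns$support)) introns$support <- 1L
  if (is.null(introns$seqid))
    introns$seqid <- if (!is.null(genome)) genome$id else NA_character_
  len <- introns$end - introns$start + 1L
  reason <- rep(NA_character_, nrow(introns))
  reason[is.na(introns$strand)] <- "undefined strand"
  reason[is.na(reason) & len < rules$min_intron_len] <- "below min_intron_len"
  reason[is.na(reason) & len > rules$max_intron_len] <- "above max_intron_len"
  if (!is.null(genome))
    reason[is.na(reason) &
             (introns$start < 1L | introns$end > genome$length)] <-
      "outside genome"
  rejected <- introns[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  acc <- introns[is.na(reason), , drop = FALSE]
  if (nrow(acc)) {
    key <- paste(acc$seqid, acc$start, acc$end, acc$strand)
    agg <- rowsum(as.integer(acc$support), key)
    first <- !duplicated(key)
    acc <- acc[first, , drop = FALSE]
    acc$support <- as.integer(agg[paste(acc$seqid, acc$start, acc$end,
                                        acc$strand), 1L])
    acc <- acc[order(acc$seqid, acc$start, acc$end), , drop = FALSE]
  }
  rownames(acc) <- NULL
  rownames(rejected) <- NULL
  list(accepted = acc, rejected = rejected)
}

empty_evidence <- function(with_reason = FALSE) {
  out <- data.frame(seqid = character(), start = integer(), end = integer(),
                    strand = character(), support = integer(),
                    stringsAsFactors = FALSE)
  if (with_reason) out$reason <- character()
  out
}

# Exon classes that may open (genomically leftmost of a gene) or close
# (rightmost) on a given strand. A minus-strand gene runs right-to-left, so
# its genomic-left end is the Terminal exon and its genomic-right the First.
opener_classes <- function(strand) {
  if (strand == "+") c("First", "Single") else c("Terminal", "Single")
}
closer_classes <- function(strand) {
  if (strand == "+") c("Terminal", "Single") else c("First", "Single")
}

# Is the genomic join left -> right a valid intra-gene transition?
# In gene direction the upstream exon is `left` on "+" and `right` on "-".
join_ok <- function(left, right, allowed) {
  if (left$strand != right$strand) return(FALSE)
  if (left$strand == "+") {
    tr <- paste0(left$exon_class, "->", right$exon_class)
    tr %in% allowed && left$remainder == right$frame
  } else {
    tr <- paste0(right$exon_class, "->", left$exon_class)
    tr %in% allowed && right$remainder == left$frame
  }
}

#' Assemble gene structures from scored exon candidates
#'
#' Dynamic-programming exon chaining: returns the chain set maximizing
#' `sum(exon scores) + intron_bonus * n_matched`, where `n_matched` counts
#' joins whose implied intron exactly matches an evidence intron (same
#' boundaries and strand). Joins must satisfy frame continuity, the allowed
#' class transitions and the intron length bounds; consecutive genes are
#' separated by at least `min_intergenic` bases (enforced across strands).
#' With the default dominating `intron_bonus` the objective is
#' lexicographic: evidence-intron count first, then score, so exons with
#' evidence-compatible splice sites are always joined when a valid gene
#' model allows it.
#'
#' @param candidates an `exon_candidates` data.frame (one seqid).
#' @param evidence_introns data.frame with `start`, `end`, `strand` (and
#'   optionally `support`); NULL or 0-row for pure ab initio chaining.
#' @param rules a [gene_model_rules()] list.
#' @param intron_bonus score added per matched evidence intron.
#' @return an object of class `gene_predictions`.
#' @export
assemble <- function(candidates, evidence_introns = NULL,
                     rules = gene_model_rules(), intron_bonus = 1e6) {
  if (is.null(candidates) || !nrow(candidates))
    return(gene_predictions(list(), objective = 0, seqid = NA_character_))
  n_evid <- if (is.null(evidence_introns)) 0L else nrow(evidence_introns)
  if (n_evid > 0L) {
    bound <- sum(abs(candidates$score)) + 1
    if (intron_bonus <= bound && intron_bonus > 0)
      warning("intron_bonus (", intron_bonus, ") does not dominate total ",
              "candidate score (", round(bound, 2), "); evidence-intron ",
              "count is not guaranteed to take lexicographic priority")
  }
  o <- order(candidates$end, candidates$start, candidates$frame)
  cd <- candidates[o, , drop = FALSE]
  n <- nrow(cd)
  st <- cd$start; en <- cd$end; strand <- cd$strand
  cls <- cd$exon_class; frame <- cd$frame; rem <- cd$remainder
  score <- cd$score
  ekey <- if (n_evid)
    paste(evidence_introns$start, evidence_introns$end,
          evidence_introns$strand) else character()
  is_opener <- (strand == "+" & cls %in% c("First", "Single")) |
    (strand == "-" & cls %in% c("Terminal", "Single"))
  is_closer <- (strand == "+" & cls %in% c("Terminal", "Single")) |
    (strand == "-" & cls %in% c("First", "Single"))
  if (rules$allow_partial_genes) {
    is_opener[] <- TRUE
    is_closer[] <- TRUE
  }
  allowed <- rules$allowed_transitions
  # transition lookup: plus joins need class[l]->class[r], minus class[r]->class[l]
  dp_obj <- rep(-Inf, n); dp_evid <- integer(n); dp_score <- numeric(n)
  parent <- rep(NA_integer_, n); is_break <- logical(n)
  # prefix best over closed (closer) candidates in end order, for gene breaks
  best_closed_obj <- -Inf; best_closed_idx <- NA_integer_
  closed_obj <- rep(-Inf, n); closed_idx <- rep(NA_integer_, n)
  # pointer over candidates sorted by end (they already are)
  for (i in seq_len(n)) {
    # --- gene break predececessors: closers with end <= st[i] - min_intergenic - 1
    lim <- st[i] - rules$min_intergenic - 1L
    kk <- findInterval(lim, en)   # candidates 1..kk have end <= lim
    best_obj <- -Inf; best_parent <- NA_integer_; best_break <- FALSE
    best_evid <- 0L; best_scr <- 0
    if (is_opener[i]) {
      best_obj <- score[i]; best_parent <- NA_integer_; best_break <- FALSE
      best_evid <- 0L; best_scr <- score[i]
    }
    if (kk >= 1L && is_opener[i]) {
      co <- closed_obj[kk]; ci <- closed_idx[kk]
      if (!is.na(ci) && co > -Inf) {
        val <- co + score[i]
        if (val > best_obj ||
            (val == best_obj && dp_evid_safe(dp_evid, ci) > best_evid)) {
          best_obj <- val; best_parent <- ci; best_break <- TRUE
          best_evid <- dp_evid[ci]; best_scr <- dp_score[ci] + score[i]
        }
      }
    }
    # --- intra-gene joins: predecessors with end in [st-max_intron-1, st-min_intron-1]
    lo <- st[i] - rules$max_intron_len - 1L
    hi <- st[i] - rules$min_intron_len - 1L
    if (hi >= 1L) {
      jlo <- findInterval(lo - 1L, en) + 1L
      jhi <- findInterval(hi, en)
      if (jhi >= jlo) {
        js <- jlo:jhi
        js <- js[strand[js] == strand[i] & dp_obj[js] > -Inf]
        if (length(js)) {
          if (strand[i] == "+") {
            okt <- paste0(cls[js], "->", cls[i]) %in% allowed &
              rem[js] == frame[i]
          } else {
            okt <- paste0(cls[i], "->", cls[js]) %in% allowed &
              rem[i] == frame[js]
          }
          js <- js[okt]
          if (length(js)) {
            gkey <- paste(en[js] + 1L, st[i] - 1L, strand[i])
            match_ev <- if (n_evid) gkey %in% ekey else rep(FALSE, length(js))
            vals <- dp_obj[js] + score[i] + intron_bonus * match_ev
            ev <- dp_evid[js] + as.integer(match_ev)
            scr <- dp_score[js] + score[i]
            # deterministic pick: objective, evidence, score, later end, earlier start
            ordp <- order(-vals, -ev, -scr, -en[js], st[js], js)
            b <- ordp[1L]
            if (vals[b] > best_obj ||
                (vals[b] == best_obj && ev[b] > best_evid) ||
                (vals[b] == best_obj && ev[b] == best_evid &&
                 scr[b] > best_scr)) {
              best_obj <- vals[b]; best_parent <- js[b]; best_break <- FALSE
              best_evid <- ev[b]; best_scr <- scr[b]
            }
          }
        }
      }
    }
    dp_obj[i] <- best_obj
    dp_evid[i] <- best_evid
    dp_score[i] <- best_scr
    parent[i] <- best_parent
    is_break[i] <- best_break
    # update closed prefix
    if (is_closer[i] && dp_obj[i] > -Inf) {
      if (dp_obj[i] > best_closed_obj ||
          (dp_obj[i] == best_closed_obj && !is.na(best_closed_idx) &&
           dp_evid[i] > dp_evid[best_closed_idx])) {
        best_closed_obj <- dp_obj[i]; best_closed_idx <- i
      }
    }
    closed_obj[i] <- best_closed_obj
    closed_idx[i] <- best_closed_idx
  }
  ends <- which(is_closer & dp_obj > -Inf)
  if (!length(ends) || max(dp_obj[ends]) < 0)
    return(gene_predictions(list(), objective = 0, seqid = cd$seqid[1L]))
  ordf <- order(-dp_obj[ends], -dp_evid[ends], -dp_score[ends], en[ends],
                st[ends], ends)
  last <- ends[ordf[1L]]
  # traceback
  chain <- integer(); breaks <- logical()
  i <- last
  while (!is.na(i)) {
    chain <- c(i, chain)
    breaks <- c(is_break[i], breaks)
    i <- parent[i]
  }
  build_predictions(cd, chain, breaks, ekey, intron_bonus,
                    objective = dp_obj[last])
}

dp_evid_safe <- function(v, i) if (is.na(i)) -1L else v[i]

# Build gene_predictions from a genomic-order chain of candidate row indices
# and per-link break flags (breaks[1] refers to the link *into* chain[1] and
# is always a start).
build_predictions <- function(cd, chain, breaks, ekey, intron_bonus,
                              objective) {
  gene_starts <- c(1L, which(breaks[-1L]) + 1L)
  gene_ends <- c(gene_starts[-1L] - 1L, length(chain))
  genes <- vector("list", length(gene_starts))
  for (g in seq_along(gene_starts)) {
    idx <- chain[gene_starts[g]:gene_ends[g]]
    rows <- cd[idx, , drop = FALSE]
    strand <- rows$strand[1L]
    introns <- if (nrow(rows) > 1L)
      data.frame(start = rows$end[-nrow(rows)] + 1L,
                 end = rows$start[-1L] - 1L, strand = strand,
                 stringsAsFactors = FALSE)
    else data.frame(start = integer(), end = integer(), strand = character(),
                    stringsAsFactors = FALSE)
    n_ev <- if (nrow(introns))
      sum(paste(introns$start, introns$end, introns$strand) %in% ekey)
    else 0L
    # exons in gene direction
    gene_rows <- if (strand == "-") rows[rev(seq_len(nrow(rows))), ] else rows
    rownames(gene_rows) <- NULL
    genes[[g]] <- list(
      gene_id = sprintf("gene%04d", g),
      seqid = rows$seqid[1L], strand = strand,
      start = min(rows$start), end = max(rows$end),
      transcripts = list(list(
        transcript_id = sprintf("gene%04d.t1", g),
        exons = gene_rows, introns = introns,
        total_score = sum(rows$score),
        evidence_intron_count = as.integer(n_ev))))
  }
  gene_predictions(genes, objective = objective,
                   seqid = if (length(genes)) genes[[1L]]$seqid else NA)
}

gene_predictions <- function(genes, objective, seqid) {
  structure(list(genes = genes, objective = objective, seqid = seqid),
            class = "gene_predictions")
}

#' @export
print.gene_predictions <- function(x, ...) {
  nt <- sum(vapply(x$genes, function(g) length(g$transcripts), 1L))
  cat(sprintf("<gene_predictions> %d gene(s), %d transcript(s), objective %g\n",
              length(x$genes), nt, x$objective))
  for (g in x$genes)
    for (tr in g$transcripts)
      cat(sprintf("  %s [%s] %d-%d: %d exon(s), score %.2f, evidence introns %d\n",
                  tr$transcript_id, g$strand, g$start, g$end,
                  nrow(tr$exons), tr$total_score, tr$evidence_intron_count))
  invisible(x)
}

#' @export
summary.gene_predictions <- function(object, ...) {
  tr <- unlist(lapply(object$genes, `[[`, "transcripts"), recursive = FALSE)
  data.frame(
    genes = length(object$genes),
    transcripts = length(tr),
    exons = sum(vapply(tr, function(t) nrow(t$exons), 1L)),
    evidence_introns = sum(vapply(tr, `[[`, 1L, "evidence_intron_count")),
    total_score = sum(vapply(tr, `[[`, 1, "total_score")))
}

#' Exhaustive chaining oracle
#'
#' Enumerates every rule-valid chain over at most 15 candidates and returns
#' the objective-maximal one. Used in tests as an independent check on
#' [assemble()]; refuses larger instances.
#'
#' @inheritParams assemble
#' @export
oracle_assemble <- function(candidates, evidence_introns = NULL,
                            rules = gene_model_rules(), intron_bonus = 1e6) {
  if (is.null(candidates) || !nrow(candidates))
    return(gene_predictions(list(), objective = 0, seqid = NA_character_))
  n <- nrow(candidates)
  if (n > 15L) stop("oracle_assemble refuses instances with > 15 candidates")
  o <- order(candidates$start, candidates$end, candidates$frame)
  cd <- candidates[o, , drop = FALSE]
  ekey <- if (!is.null(evidence_introns) && nrow(evidence_introns))
    paste(evidence_introns$start, evidence_introns$end,
          evidence_introns$strand) else character()
  best <- list(obj = 0, evid = 0L, score = 0, sel = integer(),
               breaks = logical())
  cv <- list(start = cd$start, end = cd$end, strand = cd$strand,
             class = cd$exon_class, frame = cd$frame, rem = cd$remainder,
             score = cd$score)
  bits <- bitwShiftL(1L, 0:(n - 1L))
  for (mask in seq_len(2L^n - 1L)) {
    sel <- which(bitwAnd(mask, bits) != 0L)
    res <- chain_value(cv, sel, ekey, rules, intron_bonus)
    if (is.null(res)) next
    if (res$obj > best$obj ||
        (res$obj == best$obj && res$evid > best$evid) ||
        (res$obj == best$obj && res$evid == best$evid &&
         res$score > best$score)) {
      best <- c(res, list(sel = sel))
    }
  }
  if (!length(best$sel))
    return(gene_predictions(list(), objective = 0, seqid = cd$seqid[1L]))
  build_predictions(cd, best$sel, c(FALSE, best$breaks), ekey, intron_bonus,
                    objective = best$obj)
}

# Validity + objective of one ordered candidate subset (indices `sel`,
# sorted by start, into the vector list `cv`). Returns NULL when invalid.
# Independent re-statement of the chain rules used for exhaustive
# enumeration.
chain_value <- function(cv, sel, ekey, rules, intron_bonus) {
  m <- length(sel)
  i1 <- sel[1L]; im <- sel[m]
  if (!rules$allow_partial_genes) {
    if (!cv$class[i1] %in% opener_classes(cv$strand[i1])) return(NULL)
    if (!cv$class[im] %in% closer_classes(cv$strand[im])) return(NULL)
  }
  evid <- 0L
  breaks <- logical(if (m > 1L) m - 1L else 0L)
  if (m > 1L) {
    for (p in seq_len(m - 1L)) {
      l <- sel[p]; r <- sel[p + 1L]
      gap <- cv$start[r] - cv$end[l] - 1L
      if (gap < 0L) return(NULL)
      same_strand <- cv$strand[l] == cv$strand[r]
      tr_ok <- same_strand && (
        if (cv$strand[l] == "+")
          paste0(cv$class[l], "->", cv$class[r]) %in%
            rules$allowed_transitions && cv$rem[l] == cv$frame[r]
        else
          paste0(cv$class[r], "->", cv$class[l]) %in%
            rules$allowed_transitions && cv$rem[r] == cv$frame[l])
      can_join <- gap >= rules$min_intron_len &&
        gap <= rules$max_intron_len && tr_ok
      ev_match <- can_join &&
        paste(cv$end[l] + 1L, cv$start[r] - 1L, cv$strand[l]) %in% ekey
      can_break <- gap >= rules$min_intergenic &&
        (rules$allow_partial_genes ||
           (cv$class[l] %in% closer_classes(cv$strand[l]) &&
              cv$class[r] %in% opener_classes(cv$strand[r])))
      if (ev_match) {
        breaks[p] <- FALSE
        evid <- evid + 1L
      } else if (can_join) {
        breaks[p] <- FALSE
      } else if (can_break) {
        breaks[p] <- TRUE
      } else return(NULL)
    }
  }
  sc <- sum(cv$score[sel])
  list(obj = sc + intron_bonus * evid, evid = evid, score = sc,
       breaks = breaks)
}

#' Inject EST-derived CDS transcripts as boosted exon candidates
#'
#' Each CDS exon of each transcript is added as an `ExonCandidate` of the
#' appropriate class (Single / First / Internal / Terminal by position in
#' the transcript) with score `boost` (+ its coding score when `genome` and
#' `params` are supplied); the transcript's introns are returned for the
#' evidence set. A boosted duplicate of an existing candidate raises that
#' candidate's score instead of being added twice. Transcripts whose exon
#' arithmetic cannot yield a frame-consistent CDS are rejected with a
#' reason.
#'
#' @param cds_transcripts a transcript set data.frame (exon rows with
#'   `transcript_id`, `seqid`, `strand`, `start`, `end`) holding CDS exons.
#' @param candidates existing `exon_candidates` data.frame.
#' @param boost score assigned to injected/boosted candidates.
#' @param genome,params optional; when given, injected candidates also carry
#'   their coding score.
#' @return list with `candidates` (augmented), `introns` (data.frame) and
#'   `rejected` (data.frame transcript_id/reason).
#' @export
inject_cds_evidence <- function(cds_transcripts, candidates, boost = 100,
                                genome = NULL, params = NULL) {
  if (is.null(cds_transcripts) || !nrow(cds_transcripts))
    return(list(candidates = candidates,
                introns = empty_evidence(),
                rejected = data.frame(transcript_id = character(),
                                      reason = character())))
  pre <- NULL
  pre_rc <- NULL
  if (!is.null(genome) && !is.null(params)) {
    pre <- coding_precompute(params$coding, encode_seq(genome$seq))
    pre_rc <- coding_precompute(params$coding, encode_seq(revcomp(genome$seq)))
  }
  new_rows <- list(); introns <- list(); rejected <- list()
  for (tid in unique(cds_transcripts$transcript_id)) {
    tr <- cds_transcripts[cds_transcripts$transcript_id == tid, , drop = FALSE]
    tr <- tr[order(tr$start), , drop = FALSE]
    strand <- tr$strand[1L]
    total_len <- sum(tr$end - tr$start + 1L)
    if (total_len %% 3L != 0L) {
      rejected[[tid]] <- "CDS length not divisible by 3"
      next
    }
    m <- nrow(tr)
    gd <- if (strand == "-") rev(seq_len(m)) else seq_len(m)  # gene order
    classes <- if (m == 1L) "Single"
    else c("First", rep("Internal", max(0L, m - 2L)), "Terminal")
    frames <- integer(m)
    f <- 0L
    for (k in seq_len(m)) {
      frames[k] <- f
      f <- remainder_of(tr$end[gd[k]] - tr$start[gd[k]] + 1L, f)
    }
    if (f != 0L) {
      rejected[[tid]] <- "frame does not close at terminal exon"
      next
    }
    for (k in seq_len(m)) {
      row <- tr[gd[k], ]
      len <- row$end - row$start + 1L
      cscore <- 0
      if (!is.null(pre)) {
        if (strand == "+") {
          cscore <- coding_score_interval(pre, row$start, row$end, frames[k])
        } else {
          L <- genome$length
          cscore <- coding_score_interval(pre_rc, mirror_pos(row$end, L),
                                          mirror_pos(row$start, L), frames[k])
        }
      }
      new_rows[[length(new_rows) + 1L]] <- data.frame(
        seqid = row$seqid, start = row$start, end = row$end, strand = strand,
        exon_class = classes[k], frame = frames[k],
        remainder = remainder_of(len, frames[k]),
        score = boost + cscore, five_pos = NA_integer_,
        three_pos = NA_integer_, five_score = 0, three_score = 0,
        coding_score = cscore, stringsAsFactors = FALSE)
    }
    if (m > 1L)
      introns[[tid]] <- data.frame(
        seqid = tr$seqid[1L], start = tr$end[-m] + 1L,
        end = tr$start[-1L] - 1L, strand = strand, support = 1L,
        stringsAsFactors = FALSE)
  }
  newc <- if (length(new_rows)) do.call(rbind, new_rows) else NULL
  out <- candidates
  if (!is.null(newc)) {
    # dedup injected rows among themselves, keep max score
    nkey <- paste(newc$start, newc$end, newc$strand, newc$exon_class,
                  newc$frame)
    newc <- newc[order(nkey, -newc$score), , drop = FALSE]
    newc <- newc[!duplicated(paste(newc$start, newc$end, newc$strand,
                                   newc$exon_class, newc$frame)), ,
                 drop = FALSE]
    if (nrow(out)) {
      okey <- paste(out$start, out$end, out$strand, out$exon_class, out$frame)
      nkey <- paste(newc$start, newc$end, newc$strand, newc$exon_class,
                    newc$frame)
      hit <- match(nkey, okey)
      dup <- !is.na(hit)
      if (any(dup))
        out$score[hit[dup]] <- pmax(out$score[hit[dup]], newc$score[dup])
      newc <- newc[!dup, , drop = FALSE]
    }
    if (nrow(newc)) {
      cols <- intersect(names(out), names(newc))
      if (!nrow(out)) out <- newc
      else out <- rbind(out[, cols, drop = FALSE], newc[, cols, drop = FALSE])
    }
    out <- out[order(out$start, out$end, out$frame), , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("exon_candidates", "data.frame")
  }
  intr <- if (length(introns)) do.call(rbind, c(introns, list(make.row.names = FALSE)))
  else empty_evidence()
  rej <- data.frame(transcript_id = names(rejected),
                    reason = unlist(rejected, use.names = FALSE),
                    stringsAsFactors = FALSE)
  if (!nrow(rej)) rej <- data.frame(transcript_id = character(),
                                    reason = character())
  list(candidates = out, introns = intr, rejected = rej)
}
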