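#' Find scored signal sites on one strand
#'
#' Scans for canonical cores (GT donors, AG acceptors, ATG starts,
#' TAA/TAG/TGA stops), scores donors/acceptors/starts with the trained PWMs
#' and keeps sites at or above the per-kind threshold. Stops are positional
#' matches with score 0 (no PWM). Positions are forward-strand coordinates of
#' the core's first base *in gene direction* (for `strand = "-"` that is the
#' forward coordinate of the gene-direction first core base).
#'
#' @param genome a [genome_sequence()].
#' @param params a [model_params()] object.
#' @param strand `"+"` or `"-"`.
#' @return named list of data.frames (`donor`, `acceptor`, `start`, `stop`)
#'   with columns `pos`, `score`, sorted by forward position.
#' @export
find_signals <- function(genome, params, strand = "+") {
  work <- working_sequence(genome, strand)
  sig <- find_signals_work(work$enc, work$seq, params)
  out <- lapply(sig, function(df) {
    if (strand == "-") df$pos <- mirror_pos(df$pos, genome$length)
    df[order(df$pos), , drop = FALSE]
  })
  out
}

working_sequence <- function(genome, strand) {
  seq <- if (strand == "-") revcomp(genome$seq) else genome$seq
  list(seq = seq, enc = encode_seq(seq))
}

# Signals in working (gene-direction) coordinates.
find_signals_work <- function(enc, seq, params) {
  core_pos <- function(core) {
    hits <- gregexpr(core, seq, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) integer() else as.integer(hits)
  }
  score_kind <- function(kind, core) {
    pos <- core_pos(core)
    if (!length(pos))
      return(data.frame(pos = integer(), score = numeric()))
    sc <- score_pwm_at(params$pwms[[kind]], enc, pos)
    keep <- !is.na(sc) & sc >= params$signal_thresholds[[kind]]
    data.frame(pos = pos[keep], score = sc[keep])
  }
  stops <- sort(unique(c(core_pos("TAA"), core_pos("TAG"), core_pos("TGA"))))
  list(donor = score_kind("donor", "GT"),
       acceptor = score_kind("acceptor", "AG"),
       start = score_kind("start", "ATG"),
       stop = data.frame(pos = stops, score = rep(0, length(stops))))
}

#' Enumerate and score candidate exons on one strand
#'
#' Builds the four exon classes from signal sites:
#' First = start..donor, Internal = acceptor..donor, Terminal =
#' acceptor..stop (stop codon included), Single = start..stop. Each class is
#' produced in every admissible frame; each scores
#' `five_site + three_site + coding + exon_weight`. Candidates with an
#' in-frame stop codon strictly inside the reading are excluded, as are
#' candidates outside the configured length bounds or scoring below
#' `exon_score_threshold`.
#' `frame` is the GFF phase of the exon's gene-direction first base (bases
#' completing the upstream codon); `remainder` is the phase handed to the
#' next exon, `(3 - ((len - frame) mod 3)) mod 3`. Terminal and Single exons
#' end on an in-frame stop, First and Single have frame 0.
#'
#' @param signals output of [find_signals()] for the same strand.
#' @param genome a [genome_sequence()].
#' @param params a [model_params()] object.
#' @param strand `"+"` or `"-"`.
#' @return an `exon_candidates` data.frame with forward-strand `start`,
#'   `end`, plus `strand`, `exon_class`, `frame`, `remainder`, `score`,
#'   `five_pos`, `three_pos`, `five_score`, `three_score`, `coding_score`.
#' @export
enumerate_exons <- function(signals, genome, params, strand = "+") {
  L <- genome$length
  work <- working_sequence(genome, strand)
  to_work <- function(p) if (strand == "-") mirror_pos(p, L) else p
  sig <- lapply(signals, function(df) {
    df$wpos <- to_work(df$pos)
    df[order(df$wpos), , drop = FALSE]
  })
  pre <- coding_precompute(params$coding, work$enc)
  stops_by_phase <- split_stops(sig$stop$wpos)
  gm <- params$gene_model
  rows <- rbind(
    enum_first(sig, stops_by_phase, gm),
    enum_internal(sig, stops_by_phase, gm),
    enum_terminal(sig, stops_by_phase, gm),
    enum_single(sig, stops_by_phase, gm))
  if (is.null(rows) || nrow(rows) == 0L) return(empty_candidates())
  # coding score in working coordinates
  cs <- coding_score_vec(pre, rows$wstart, rows$wend, rows$frame)
  ew <- if (is.null(params$exon_weight)) 0 else params$exon_weight
  total <- rows$five_score + rows$three_score + cs + ew
  keep <- total >= params$exon_score_threshold
  rows <- rows[keep, , drop = FALSE]
  cs <- cs[keep]; total <- total[keep]
  if (!nrow(rows)) return(empty_candidates())
  if (strand == "+") {
    start <- rows$wstart; end <- rows$wend
    five_pos <- rows$five_wpos; three_pos <- rows$three_wpos
  } else {
    start <- mirror_pos(rows$wend, L); end <- mirror_pos(rows$wstart, L)
    five_pos <- mirror_pos(rows$five_wpos, L)
    three_pos <- mirror_pos(rows$three_wpos, L)
  }
  out <- data.frame(seqid = genome$id, start = start, end = end,
                    strand = strand, exon_class = rows$exon_class,
                    frame = rows$frame, remainder = rows$remainder,
                    score = total, five_pos = five_pos,
                    three_pos = three_pos, five_score = rows$five_score,
                    three_score = rows$three_score, coding_score = cs,
                    stringsAsFactors = FALSE)
  out <- out[order(out$start, out$end, out$frame), ]
  rownames(out) <- NULL
  class(out) <- c("exon_candidates", "data.frame")
  out
}

empty_candidates <- function() {
  out <- data.frame(seqid = character(), start = integer(), end = integer(),
                    strand = character(), exon_class = character(),
                    frame = integer(), remainder = integer(),
                    score = numeric(), five_pos = integer(),
                    three_pos = integer(), five_score = numeric(),
                    three_score = numeric(), coding_score = numeric(),
                    stringsAsFactors = FALSE)
  class(out) <- c("exon_candidates", "data.frame")
  out
}

remainder_of <- function(len, frame) (3L - ((len - frame) %% 3L)) %% 3L

# Stop-codon positions split by position mod 3 (working coordinates).
split_stops <- function(stop_pos) {
  lapply(0:2, function(r) sort(stop_pos[stop_pos %% 3L == r]))
}

# First in-frame stop at or after `from`: codon start positions p with
# p %% 3 == from %% 3. Returns NA when none. Vectorised over `from`.
next_stop <- function(stops_by_phase, from) {
  out <- rep(NA_integer_, length(from))
  for (r in 0:2) {
    sel <- which(from %% 3L == r)
    if (!length(sel)) next
    sp <- stops_by_phase[[r + 1L]]
    if (!length(sp)) next
    idx <- findInterval(from[sel] - 1L, sp) + 1L
    ok <- idx <= length(sp)
    out[sel[ok]] <- sp[idx[ok]]
  }
  out
}

# TRUE when some in-frame stop codon lies fully inside: exists stop p with
# first_codon <= p <= last_allowed. Vectorised.
has_internal_stop <- function(stops_by_phase, first_codon, last_allowed) {
  ns <- next_stop(stops_by_phase, first_codon)
  !is.na(ns) & ns <= last_allowed
}

# Candidate assembly helpers; all in working coordinates. Each returns a
# data.frame wstart, wend, exon_class, frame, remainder, five/three pos+score.
cand_frame <- function(wstart, wend, class, frame, five_wpos, five_score,
                       three_wpos, three_score) {
  len <- wend - wstart + 1L
  data.frame(wstart = wstart, wend = wend, exon_class = class,
             frame = frame, remainder = remainder_of(len, frame),
             five_wpos = five_wpos, five_score = five_score,
             three_wpos = three_wpos, three_score = three_score,
             stringsAsFactors = FALSE)
}

enum_first <- function(sig, stops, gm) {
  st <- sig$start; dn <- sig$donor
  if (!nrow(st) || !nrow(dn)) return(NULL)
  # pairs: exon = s .. d-1, length = d - s in bounds
  pairs <- interval_pairs(st$wpos, dn$wpos, gm$min_exon_len,
                          gm$max_exon_len)
  if (!nrow(pairs)) return(NULL)
  s <- st$wpos[pairs[, 1L]]; d <- dn$wpos[pairs[, 2L]]
  len <- d - s
  ok <- len >= gm$min_exon_len & len <= gm$max_exon_len
  s <- s[ok]; d <- d[ok]
  if (!length(s)) return(NULL)
  # no in-frame stop within s .. d-1 (frame 0; codons from s)
  bad <- has_internal_stop(stops, s, d - 3L)
  s <- s[!bad]; d <- d[!bad]
  if (!length(s)) return(NULL)
  i_s <- match(s, sig$start$wpos); i_d <- match(d, sig$donor$wpos)
  cand_frame(s, d - 1L, "First", 0L, s, sig$start$score[i_s],
             d, sig$donor$score[i_d])
}

enum_internal <- function(sig, stops, gm) {
  ac <- sig$acceptor; dn <- sig$donor
  if (!nrow(ac) || !nrow(dn)) return(NULL)
  # exon = a+2 .. d-1; len = d - a - 2
  pairs <- interval_pairs(ac$wpos, dn$wpos, gm$min_exon_len + 2L,
                          gm$max_exon_len + 2L)
  if (!nrow(pairs)) return(NULL)
  a <- ac$wpos[pairs[, 1L]]; d <- dn$wpos[pairs[, 2L]]
  len <- d - a - 2L
  ok <- len >= gm$min_exon_len & len <= gm$max_exon_len
  a <- a[ok]; d <- d[ok]
  if (!length(a)) return(NULL)
  out <- vector("list", 3L)
  for (f in 0:2) {
    first_codon <- a + 2L + f
    bad <- has_internal_stop(stops, first_codon, d - 3L)
    aa <- a[!bad]; dd <- d[!bad]
    if (!length(aa)) next
    i_a <- match(aa, sig$acceptor$wpos); i_d <- match(dd, sig$donor$wpos)
    out[[f + 1L]] <- cand_frame(aa + 2L, dd - 1L, "Internal", f,
                                aa, sig$acceptor$score[i_a],
                                dd, sig$donor$score[i_d])
  }
  do.call(rbind, out)
}

enum_terminal <- function(sig, stops, gm) {
  ac <- sig$acceptor
  if (!nrow(ac)) return(NULL)
  out <- vector("list", 3L)
  for (f in 0:2) {
    a <- ac$wpos
    first_codon <- a + 2L + f
    t <- next_stop(stops, first_codon)     # first in-frame stop = exon end
    ok <- !is.na(t)
    a <- a[ok]; t <- t[ok]
    len <- t + 2L - (a + 2L) + 1L
    ok2 <- len >= gm$min_exon_len & len <= gm$max_exon_len
    a <- a[ok2]; t <- t[ok2]
    if (!length(a)) next
    i_a <- match(a, sig$acceptor$wpos)
    out[[f + 1L]] <- cand_frame(a + 2L, t + 2L, "Terminal", f,
                                a, sig$acceptor$score[i_a], t, 0)
  }
  do.call(rbind, out)
}

enum_single <- function(sig, stops, gm) {
  st <- sig$start
  if (!nrow(st)) return(NULL)
  s <- st$wpos
  t <- next_stop(stops, s)
  ok <- !is.na(t)
  s <- s[ok]; t <- t[ok]
  len <- t + 2L - s + 1L
  ok2 <- len >= gm$min_exon_len & len <= gm$max_exon_len & len %% 3L == 0L
  s <- s[ok2]; t <- t[ok2]
  if (!length(s)) return(NULL)
  i_s <- match(s, sig$start$wpos)
  cand_frame(s, t + 2L, "Single", 0L, s, sig$start$score[i_s], t, 0)
}

# All (i, j) index pairs with b[j] - a[i] in [lo, hi]; a, b sorted ascending.
interval_pairs <- function(a, b, lo, hi) {
  if (!length(a) || !length(b))
    return(matrix(integer(), ncol = 2L))
  from <- findInterval(a + lo - 1L, b) + 1L       # first j with b[j] >= a+lo
  to <- findInterval(a + hi, b)                   # last  j with b[j] <= a+hi
  n <- pmax(0L, to - from + 1L)
  i <- rep.int(seq_along(a), n)
  j <- unlist(lapply(which(n > 0L), function(k) from[k]:to[k]), use.names = FALSE)
  cbind(i, as.integer(j))
}

coding_score_vec <- function(pre, s, e, frame) {
  r <- ((-s - frame) %% 3L) + 1L
  lo <- ifelse(s > 1L, pre$cum[cbind(r, pmax(s - 1L, 1L))], 0)
  pre$cum[cbind(r, e)] - lo
}

#' Keep the top-k candidates per exon class
#'
#' Ties on score are broken by smaller start, then smaller end; the result
#' keeps the stable `(start, end, frame)` order.
#'
#' @param candidates an `exon_candidates` data.frame.
#' @param k_per_class maximum number of candidates kept per class
#'   (`Inf` keeps all).
#' @export
top_k_filter <- function(candidates, k_per_class) {
  stopifnot(k_per_class >= 1)
  if (!nrow(candidates) || is.infinite(k_per_class)) return(candidates)
  keep <- unlist(lapply(split(seq_len(nrow(candidates)),
                              candidates$exon_class), function(idx) {
    o <- idx[order(-candidates$score[idx], candidates$start[idx],
                   candidates$end[idx])]
    o[seq_len(min(k_per_class, length(o)))]
  }), use.names = FALSE)
  out <- candidates[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export exon candidates to GFF3 features
#' @param candidates an `exon_candidates` data.frame.
#' @export
candidates_to_gff <- function(candidates) {
  if (!nrow(candidates)) return(empty_gff())
  gff_features(seqid = candidates$seqid, type = "exon",
               start = candidates$start, end = candidates$end,
               score = candidates$score, strand = candidates$strand,
               source = "genechain",
               attributes = sprintf("class=%s;frame=%d;remainder=%d",
                                    candidates$exon_class, candidates$frame,
                                    candidates$remainder))
}
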