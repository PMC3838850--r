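#' Markov-chain coding potential
#'
#' A frame-specific order-k Markov chain trained on coding sequence is
#' compared against a single background chain trained on non-coding
#' sequence; a region's coding score is the summed per-base
#' log2-likelihood ratio. Codon phase of a base is its offset within the
#' codon (0,1,2); phase advances cyclically along the sequence.
#'
#' @param cds_seqs character vector of coding sequences, each starting at
#'   codon phase 0 and of length divisible by 3 (ACGT only).
#' @param noncoding_seqs character vector of non-coding training sequences.
#' @param order Markov order k (>= 0).
#' @param pseudocount smoothing added to every transition count.
#' @return an object of class `coding_model` with log2 transition
#'   probability arrays `coding_logp` (4^k x 4 x 3 frames) and
#'   `background_logp` (4^k x 4).
#' @export
train_coding_model <- function(cds_seqs, noncoding_seqs, order = 4L,
                               pseudocount = 0.5) {
  if (order < 0) stop("Markov order must be >= 0")
  if (length(cds_seqs) == 0L || length(noncoding_seqs) == 0L)
    stop("empty coding-model training data")
  if (any(nchar(cds_seqs) %% 3 != 0))
    stop("CDS training sequences must have length divisible by 3")
  k <- as.integer(order)
  nctx <- 4L^k
  cod <- array(0, dim = c(nctx, 4L, 3L))
  for (s in cds_seqs) {
    enc <- encode_seq(s)
    if (anyNA(enc)) stop("coding training sequences must contain only ACGT")
    tc <- transition_counts(enc, k, frames = TRUE)
    cod <- cod + tc
  }
  bg <- matrix(0, nctx, 4L)
  for (s in noncoding_seqs) {
    enc <- encode_seq(s)
    enc <- enc[!is.na(enc)]
    bg <- bg + transition_counts(enc, k, frames = FALSE)
  }
  norm_logp <- function(cnt) {
    p <- matrix(cnt, nrow = nctx, ncol = 4L) + pseudocount
    unname(log2(p / rowSums(p)))
  }
  coding_logp <- array(0, dim = c(nctx, 4L, 3L))
  for (f in 1:3) coding_logp[, , f] <- norm_logp(cod[, , f])
  structure(list(order = k, pseudocount = pseudocount,
                 coding_logp = coding_logp,
                 background_logp = norm_logp(bg)),
            class = "coding_model")
}

#' @export
print.coding_model <- function(x, ...) {
  cat(sprintf("<coding_model> order %d, pseudocount %g\n", x$order,
              x$pseudocount))
  invisible(x)
}

# Count order-k transitions. With frames=TRUE, returns a 4^k x 4 x 3 array
# where slice f holds transitions emitting a base of codon phase f-1
# (phase of base i in a phase-0 sequence is (i-1) %% 3).
transition_counts <- function(enc, k, frames) {
  n <- length(enc)
  nctx <- 4L^k
  if (frames) out <- array(0, dim = c(nctx, 4L, 3L))
  else out <- matrix(0, nctx, 4L)
  if (n < k + 1L) return(out)
  ctx <- context_index(enc, k)            # context index for each position
  pos <- (k + 1L):n
  emit <- enc[pos]
  cx <- ctx[pos]
  ok <- !is.na(emit) & !is.na(cx)
  if (frames) {
    ph <- ((pos - 1L) %% 3L) + 1L
    for (f in 1:3) {
      sel <- ok & ph == f
      if (any(sel))
        out[, , f] <- out[, , f] +
          as.matrix(table(factor(cx[sel], levels = 1:nctx),
                          factor(emit[sel], levels = 1:4)))
    }
  } else {
    if (any(ok))
      out <- out + as.matrix(table(factor(cx[ok], levels = 1:nctx),
                                   factor(emit[ok], levels = 1:4)))
  }
  out
}

# 1-based context index of the k bases preceding each position (NA where the
# context is incomplete or contains N).
context_index <- function(enc, k) {
  n <- length(enc)
  if (k == 0L) return(rep(1L, n))
  idx <- rep(NA_real_, n)
  valid <- rep(TRUE, n)
  acc <- rep(0, n)
  for (j in 1:k) {
    prev <- c(rep(NA_integer_, j), enc[seq_len(n - j)])
    valid <- valid & !is.na(prev)
    acc <- acc + ifelse(is.na(prev), 0, (prev - 1L)) * 4^(j - 1L)
  }
  idx[valid] <- acc[valid] + 1
  idx[seq_len(min(k, n))] <- NA
  as.integer(idx)
}

#' Score the coding potential of a genomic interval
#'
#' @param model a [train_coding_model()] object.
#' @param genome a [genome_sequence()].
#' @param start,end forward coordinates, 1-based inclusive.
#' @param strand `"+"` or `"-"`; on `"-"` the reverse complement is scored
#'   and `start`/`end` still refer to forward coordinates.
#' @param frame phase of the interval's first base in gene direction: the
#'   number of bases completing the upstream codon, so the first full codon
#'   begins `frame` bases in (GFF phase convention).
#' @return summed log2 coding/background likelihood ratio. Positions whose
#'   Markov context is incomplete (interval edge, N) contribute 0.
#' @export
score_coding <- function(model, genome, start, end, strand = "+", frame = 0L) {
  stopifnot(start <= end, frame %in% 0:2)
  if (start < 1L || end > genome$length) stop("interval out of bounds")
  if (strand == "-") {
    seq <- revcomp(genome$seq)
    s <- mirror_pos(end, genome$length)
    e <- mirror_pos(start, genome$length)
  } else {
    seq <- genome$seq
    s <- start; e <- end
  }
  pre <- coding_precompute(model, encode_seq(seq))
  coding_score_interval(pre, s, e, frame)
}

# Precompute per-position log-ratio rows for the 3 codon-phase classes plus
# the 3 phase-rotation cumulative sums used for O(1) interval scores.
coding_precompute <- function(model, enc) {
  n <- length(enc)
  k <- model$order
  ctx <- context_index(enc, k)
  lr <- matrix(0, 3L, n)   # lr[f, i]: ratio if base i has codon phase f-1
  ok <- !is.na(enc) & !is.na(ctx)
  io <- which(ok)
  nctx <- 4L^k
  bgm <- matrix(model$background_logp, nrow = nctx, ncol = 4L)
  bgv <- bgm[cbind(ctx[io], enc[io])]
  for (f in 1:3) {
    cm <- matrix(model$coding_logp[, , f], nrow = nctx, ncol = 4L)
    lr[f, io] <- cm[cbind(ctx[io], enc[io])] - bgv
  }
  # cum[r+1, i] = sum_{j<=i} lr[((j + r) mod 3) + 1, j]
  cum <- matrix(0, 3L, n)
  i <- seq_len(n)
  for (r in 0:2) {
    rows <- ((i + r) %% 3L) + 1L
    cum[r + 1L, ] <- cumsum(lr[cbind(rows, i)])
  }
  list(cum = cum, n = n)
}

# Interval score in working coordinates. Phase of base i in [s,e] with GFF
# phase `frame` is (i - s - frame) mod 3, i.e. rotation r = (-s - frame) mod 3.
coding_score_interval <- function(pre, s, e, frame) {
  r <- ((-s - frame) %% 3L) + 1L
  lo <- if (s > 1L) pre$cum[r, s - 1L] else 0
  pre$cum[r, e] - lo
}
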