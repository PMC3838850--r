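#' Position weight matrices for gene signals
#'
#' A PWM scores a fixed window around a signal's consensus core (GT for
#' donors, AG for acceptors, ATG for translation starts) as summed
#' log2(p_position / p_background). `offset` is the number of window bases
#' upstream of the core's first base, so the window anchored at core
#' position `pos` spans `[pos - offset, pos - offset + width - 1]`.
#'
#' @param aligned_windows character vector of equal-length training windows
#'   (ACGT only), all aligned on the signal.
#' @param signal_kind one of `"donor"`, `"acceptor"`, `"start"`, `"stop"`.
#' @param background base frequencies, named `A,C,G,T`; must sum to 1.
#' @param pseudocount added to each base count at each position.
#' @param offset context bases upstream of the consensus core's first base.
#' @return an object of class `pwm` with elements `signal_kind`, `offset`,
#'   `width`, `log_odds` (width x 4 matrix, columns A,C,G,T), `background`,
#'   `pseudocount`, `n_train`.
#' @export
train_pwm <- function(aligned_windows, signal_kind,
                      background = c(A = .25, C = .25, G = .25, T = .25),
                      pseudocount = 0.5, offset = 0L) {
  if (length(aligned_windows) == 0L) stop("empty PWM training set")
  w <- unique(nchar(aligned_windows))
  if (length(w) != 1L) stop("PWM training windows have unequal lengths")
  if (any(grepl("[^ACGT]", aligned_windows)))
    stop("PWM training windows must contain only ACGT")
  stopifnot(abs(sum(background) - 1) < 1e-8, pseudocount >= 0)
  n <- length(aligned_windows)
  mat <- matrix(unlist(strsplit(aligned_windows, "", fixed = TRUE)),
                nrow = n, byrow = TRUE)
  counts <- sapply(c("A", "C", "G", "T"), function(b) colSums(mat == b))
  counts <- matrix(counts, ncol = 4L, dimnames = list(NULL, c("A", "C", "G", "T")))
  p <- (counts + pseudocount) / (n + 4 * pseudocount)
  log_odds <- log2(sweep(p, 2L, background[c("A", "C", "G", "T")], "/"))
  structure(list(signal_kind = signal_kind, offset = as.integer(offset),
                 width = w, log_odds = log_odds,
                 background = background, pseudocount = pseudocount,
                 n_train = n),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s: width %d, offset %d, trained on %d windows\n",
              x$signal_kind, x$width, x$offset, x$n_train))
  invisible(x)
}

#' Score a PWM at one genomic position
#'
#' The window is anchored so the consensus core starts at `pos` (forward
#' coordinates). On the reverse strand the reverse complement is scored, with
#' `pos` the forward coordinate of the core's first base in gene direction.
#' Returns `NA` ("no signal") when the window runs out of bounds or contains
#' an N.
#'
#' @param pwm a [train_pwm()] object.
#' @param genome a [genome_sequence()].
#' @param pos 1-based forward coordinate of the core's first base.
#' @param strand `"+"` or `"-"`.
#' @export
score_pwm <- function(pwm, genome, pos, strand = "+") {
  if (strand == "-") {
    seq <- revcomp(genome$seq)
    pos <- mirror_pos(pos, genome$length)
  } else seq <- genome$seq
  enc <- encode_seq(seq)
  score_pwm_at(pwm, enc, pos)
}

# Vectorised PWM scoring over encoded sequence; positions are coordinates of
# the core's first base in the *working* (already strand-oriented) sequence.
score_pwm_at <- function(pwm, enc, positions) {
  L <- length(enc)
  from <- positions - pwm$offset
  ok <- from >= 1L & (from + pwm$width - 1L) <= L
  sc <- rep(NA_real_, length(positions))
  if (!any(ok)) return(sc)
  idx <- which(ok)
  total <- numeric(length(idx))
  bad <- logical(length(idx))
  for (j in seq_len(pwm$width)) {
    b <- enc[from[idx] + j - 1L]
    nab <- is.na(b)
    bad <- bad | nab
    contrib <- pwm$log_odds[j, ]
    v <- contrib[b]
    v[nab] <- 0
    total <- total + v
  }
  total[bad] <- NA_real_
  sc[idx] <- total
  sc
}

# Default window geometries (GeneID-like shapes).
# donor:    3 exonic | GT + 4 intronic          -> width 9,  offset 3
# acceptor: 18 intronic | AG | 3 exonic         -> width 23, offset 18
# start:    6 upstream | ATG | 3 downstream     -> width 12, offset 6
signal_geometry <- function(kind) {
  switch(kind,
         donor    = list(offset = 3L,  width = 9L,  core = "GT"),
         acceptor = list(offset = 18L, width = 23L, core = "AG"),
         start    = list(offset = 6L,  width = 12L, core = "ATG"),
         stop     = list(offset = 0L,  width = 3L,  core = NA_character_),
         stop("unknown signal kind: ", kind))
}
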