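#' Model parameter bundle
#'
#' Bundles the trained signal PWMs, the coding model, per-signal score
#' thresholds, the exon score threshold, the evidence-intron bonus and the
#' gene-model rules used by the chainer.
#'
#' @param pwms named list with elements `donor`, `acceptor`, `start`
#'   (each a [train_pwm()] object).
#' @param coding a [train_coding_model()] object.
#' @param signal_thresholds named numeric, minimum PWM score per signal kind.
#' @param exon_weight constant added to every candidate exon's score before
#'   the cutoff (negative: each exon must carry that much signal+coding
#'   evidence to enter a chain; controls ab initio over-prediction).
#' @param exon_score_threshold candidates scoring below this (after
#'   `exon_weight`) are dropped.
#' @param intron_bonus score added per evidence-matched intron join; the
#'   default dominates any realistic summed exon score, making the chaining
#'   objective lexicographic (evidence-intron count first, score second).
#' @param gene_model a [gene_model_rules()] list.
#' @return an object of class `model_params`.
#' @export
model_params <- function(pwms, coding,
                         signal_thresholds = c(donor = 0, acceptor = 0,
                                               start = 0),
                         exon_weight = -20,
                         exon_score_threshold = 0,
                         intron_bonus = 1e6,
                         gene_model = gene_model_rules()) {
  for (kind in c("donor", "acceptor", "start"))
    if (is.null(pwms[[kind]])) stop("missing pwm: ", kind)
  if (intron_bonus < 0) stop("intron_bonus must be >= 0")
  structure(list(pwms = pwms, coding = coding,
                 signal_thresholds = signal_thresholds,
                 exon_weight = exon_weight,
                 exon_score_threshold = exon_score_threshold,
                 intron_bonus = intron_bonus,
                 gene_model = gene_model),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  for (kind in names(x$pwms))
    cat(sprintf("  pwm %-8s width %2d offset %2d (threshold %g)\n", kind,
                x$pwms[[kind]]$width, x$pwms[[kind]]$offset,
                x$signal_thresholds[[kind]]))
  cat(sprintf("  coding model order %d\n", x$coding$order))
  cat(sprintf("  exon weight %g, score threshold %g, intron bonus %g\n",
              x$exon_weight, x$exon_score_threshold, x$intron_bonus))
  cat(sprintf("  introns %d..%d bp, intergenic >= %d bp\n",
              x$gene_model$min_intron_len, x$gene_model$max_intron_len,
              x$gene_model$min_intergenic))
  invisible(x)
}

#' Gene-model rules for the chainer
#'
#' @param allowed_transitions character vector of allowed exon-class
#'   transitions in gene direction, as `"From->To"`.
#' @param min_intron_len,max_intron_len allowed implied intron lengths (bp).
#' @param min_intergenic minimum gap between consecutive genes (bp).
#' @param min_exon_len,max_exon_len candidate exon length bounds (bp).
#' @param allow_partial_genes when TRUE, chains may open/close with any exon
#'   class (genes truncated at sequence edges).
#' @export
gene_model_rules <- function(allowed_transitions = c("First->Internal",
                                                     "First->Terminal",
                                                     "Internal->Internal",
                                                     "Internal->Terminal"),
                             min_intron_len = 30L, max_intron_len = 5000L,
                             min_intergenic = 200L,
                             min_exon_len = 10L, max_exon_len = 10000L,
                             allow_partial_genes = FALSE) {
  stopifnot(min_intron_len >= 4L, max_intron_len > min_intron_len,
            min_exon_len >= 1L, max_exon_len >= min_exon_len,
            min_intergenic >= 1L)
  list(allowed_transitions = allowed_transitions,
       min_intron_len = as.integer(min_intron_len),
       max_intron_len = as.integer(max_intron_len),
       min_intergenic = as.integer(min_intergenic),
       min_exon_len = as.integer(min_exon_len),
       max_exon_len = as.integer(max_exon_len),
       allow_partial_genes = isTRUE(allow_partial_genes))
}

#' Save / load model parameters
#'
#' Plain-text sectioned format (`[pwm.donor]`, `[pwm.acceptor]`,
#' `[pwm.start]`, `[coding]`, `[gene_model]`, `[chaining]`) with
#' full-precision numerics; the round trip is lossless.
#'
#' @param params a [model_params()] object.
#' @param path file path.
#' @export
save_params <- function(params, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  num <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  for (kind in c("donor", "acceptor", "start")) {
    p <- params$pwms[[kind]]
    w("[pwm.%s]", kind)
    w("offset %d", p$offset)
    w("width %d", p$width)
    w("n_train %d", p$n_train)
    w("pseudocount %s", num(p$pseudocount))
    w("background %s", num(p$background))
    for (i in seq_len(p$width)) w("logodds %s", num(p$log_odds[i, ]))
  }
  cm <- params$coding
  nctx <- 4L^cm$order
  w("[coding]")
  w("order %d", cm$order)
  w("pseudocount %s", num(cm$pseudocount))
  for (f in 1:3) {
    slice <- matrix(cm$coding_logp[, , f], nrow = nctx, ncol = 4L)
    for (i in seq_len(nctx)) w("coding %d %s", f, num(slice[i, ]))
  }
  bgm <- matrix(cm$background_logp, nrow = nctx, ncol = 4L)
  for (i in seq_len(nctx)) w("background_row %s", num(bgm[i, ]))
  gm <- params$gene_model
  w("[gene_model]")
  w("allowed_transitions %s", paste(gm$allowed_transitions, collapse = " "))
  w("min_intron_len %d", gm$min_intron_len)
  w("max_intron_len %d", gm$max_intron_len)
  w("min_intergenic %d", gm$min_intergenic)
  w("min_exon_len %d", gm$min_exon_len)
  w("max_exon_len %d", gm$max_exon_len)
  w("allow_partial_genes %d", as.integer(gm$allow_partial_genes))
  w("[chaining]")
  w("signal_thresholds %s", num(params$signal_thresholds[c("donor", "acceptor", "start")]))
  w("exon_weight %s", num(params$exon_weight))
  w("exon_score_threshold %s", num(params$exon_score_threshold))
  w("intron_bonus %s", num(params$intron_bonus))
  invisible(path)
}

#' @rdname save_params
#' @export
load_params <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sec_at <- grepl("^\\[", lines)
  sec <- cumsum(sec_at)
  sections <- split(lines, sec)
  names(sections) <- vapply(sections, function(b) gsub("\\[|\\]", "", b[1L]), "")
  getsec <- function(name) {
    if (is.null(sections[[name]])) stop("missing section: ", name)
    sections[[name]][-1L]
  }
  field <- function(block, key) {
    hit <- block[startsWith(block, paste0(key, " "))]
    if (!length(hit)) stop("missing field '", key, "'")
    sub(paste0("^", key, " "), "", hit)
  }
  nums <- function(s) as.numeric(strsplit(s, " ", fixed = TRUE)[[1L]])
  pwms <- list()
  for (kind in c("donor", "acceptor", "start")) {
    nm <- paste0("pwm.", kind)
    if (is.null(sections[[nm]])) stop("missing pwm: ", kind)
    b <- getsec(nm)
    width <- as.integer(field(b, "width"))
    lo <- t(vapply(field(b, "logodds"), nums, numeric(4L)))
    if (nrow(lo) != width) stop("pwm ", kind, ": width/logodds mismatch")
    dimnames(lo) <- list(NULL, c("A", "C", "G", "T"))
    bgv <- nums(field(b, "background"))
    names(bgv) <- c("A", "C", "G", "T")
    pwms[[kind]] <- structure(
      list(signal_kind = kind, offset = as.integer(field(b, "offset")),
           width = width, log_odds = lo, background = bgv,
           pseudocount = nums(field(b, "pseudocount")),
           n_train = as.integer(field(b, "n_train"))),
      class = "pwm")
  }
  b <- getsec("coding")
  order <- as.integer(field(b, "order"))
  nctx <- 4L^order
  crows <- field(b, "coding")
  cm_arr <- array(0, dim = c(nctx, 4L, 3L))
  vals <- lapply(crows, nums)
  frames <- vapply(vals, function(v) as.integer(v[1L]), 1L)
  for (f in 1:3) {
    rows <- do.call(rbind, lapply(vals[frames == f], function(v) v[-1L]))
    if (is.null(rows) || nrow(rows) != nctx)
      stop("coding section: wrong number of rows for frame ", f)
    cm_arr[, , f] <- rows
  }
  bg <- do.call(rbind, lapply(field(b, "background_row"), nums))
  if (nrow(bg) != nctx) stop("coding section: wrong background row count")
  coding <- structure(list(order = order,
                           pseudocount = nums(field(b, "pseudocount")),
                           coding_logp = cm_arr, background_logp = bg),
                      class = "coding_model")
  b <- getsec("gene_model")
  gm <- gene_model_rules(
    allowed_transitions = strsplit(field(b, "allowed_transitions"), " ")[[1L]],
    min_intron_len = as.integer(field(b, "min_intron_len")),
    max_intron_len = as.integer(field(b, "max_intron_len")),
    min_intergenic = as.integer(field(b, "min_intergenic")),
    min_exon_len = as.integer(field(b, "min_exon_len")),
    max_exon_len = as.integer(field(b, "max_exon_len")),
    allow_partial_genes = as.integer(field(b, "allow_partial_genes")) == 1L)
  b <- getsec("chaining")
  st <- nums(field(b, "signal_thresholds"))
  names(st) <- c("donor", "acceptor", "start")
  ib <- nums(field(b, "intron_bonus"))
  if (ib < 0) stop("invalid intron_bonus: must be >= 0")
  model_params(pwms = pwms, coding = coding, signal_thresholds = st,
               exon_weight = nums(field(b, "exon_weight")),
               exon_score_threshold = nums(field(b, "exon_score_threshold")),
               intron_bonus = ib, gene_model = gm)
}
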