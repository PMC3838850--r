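# Independent brute-force oracles and random-instance generators used
# across the suite. These deliberately avoid the package's optimised code
# paths (substring scans, plain loops) so they can serve as references.

ACGT <- c("A", "C", "G", "T")

rand_seq <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(ACGT, n, replace = TRUE, prob = p), collapse = "")
}

# Slow per-position PWM score by direct substring comparison.
slow_pwm_score <- function(pwm, seq, pos) {
  from <- pos - pwm$offset
  if (from < 1L || from + pwm$width - 1L > nchar(seq)) return(NA_real_)
  win <- substr(seq, from, from + pwm$width - 1L)
  ch <- strsplit(win, "")[[1L]]
  if (any(!ch %in% ACGT)) return(NA_real_)
  sum(vapply(seq_along(ch), function(i) pwm$log_odds[i, ch[i]], 0))
}

# Slow order-k coding score with explicit context walk; frame is GFF phase.
slow_coding_score <- function(model, seq, start, end, frame) {
  k <- model$order
  enc <- match(strsplit(seq, "")[[1L]], ACGT)
  total <- 0
  for (i in start:end) {
    if (i - k < 1L) next
    ctx_b <- enc[(i - k):(i - 1L)]
    if (k > 0 && any(is.na(ctx_b))) next
    if (is.na(enc[i])) next
    ctx <- if (k == 0L) 1L else sum((rev(ctx_b) - 1L) * 4L^(0:(k - 1L))) + 1L
    phase <- ((i - start - frame) %% 3L) + 1L
    total <- total + model$coding_logp[ctx, enc[i], phase] -
      model$background_logp[ctx, enc[i]]
  }
  total
}

# Exhaustive exon enumeration for small sequences: tries every
# (5'site, 3'site, frame) triple and applies the definitions directly.
slow_enumerate <- function(seq, params, strand, genome_id = "g") {
  gm <- params$gene_model
  L <- nchar(seq)
  work <- if (strand == "-") genechain::revcomp(seq) else seq
  find_all <- function(core) {
    hits <- gregexpr(core, work, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) integer() else as.integer(hits)
  }
  site_score <- function(kind, pos) {
    sc <- slow_pwm_score(params$pwms[[kind]], work, pos)
    if (is.na(sc) || sc < params$signal_thresholds[[kind]]) NA_real_ else sc
  }
  donors <- find_all("GT"); acceptors <- find_all("AG")
  starts <- find_all("ATG")
  stops <- sort(unique(c(find_all("TAA"), find_all("TAG"), find_all("TGA"))))
  has_stop_between <- function(first_codon, last_allowed) {
    any(stops >= first_codon & stops <= last_allowed &
          (stops - first_codon) %% 3L == 0L)
  }
  first_stop <- function(from) {
    s <- stops[stops >= from & (stops - from) %% 3L == 0L]
    if (length(s)) s[1L] else NA_integer_
  }
  ew <- params$exon_weight
  rows <- list()
  add <- function(ws, we, class, frame, s5, s3) {
    len <- we - ws + 1L
    if (len < gm$min_exon_len || len > gm$max_exon_len) return()
    cs <- slow_coding_score(params$coding, work, ws, we, frame)
    total <- s5 + s3 + cs + ew
    if (total < params$exon_score_threshold) return()
    if (strand == "+") { fs <- ws; fe <- we }
    else { fs <- L - we + 1L; fe <- L - ws + 1L }
    rows[[length(rows) + 1L]] <<- data.frame(
      seqid = genome_id, start = fs, end = fe, strand = strand,
      exon_class = class, frame = frame,
      remainder = (3L - ((len - frame) %% 3L)) %% 3L, score = total,
      stringsAsFactors = FALSE)
  }
  for (s in starts) {
    s5 <- site_score("start", s)
    if (is.na(s5)) next
    for (d in donors) {
      if (d <= s) next
      s3 <- site_score("donor", d)
      if (is.na(s3)) next
      if (has_stop_between(s, d - 3L)) next
      add(s, d - 1L, "First", 0L, s5, s3)
    }
    t <- first_stop(s)
    if (!is.na(t)) add(s, t + 2L, "Single", 0L, s5, 0)
  }
  for (a in acceptors) {
    s5 <- site_score("acceptor", a)
    if (is.na(s5)) next
    for (f in 0:2) {
      for (d in donors) {
        if (d <= a + 2L + f) next
        s3 <- site_score("donor", d)
        if (is.na(s3)) next
        if (has_stop_between(a + 2L + f, d - 3L)) next
        add(a + 2L, d - 1L, "Internal", f, s5, s3)
      }
      t <- first_stop(a + 2L + f)
      if (!is.na(t)) add(a + 2L, t + 2L, "Terminal", f, s5, 0)
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out[order(out$start, out$end, out$frame), ]
}

# Random chaining instance for DP-vs-oracle tests: candidates with
# consistent frame arithmetic plus evidence introns (some matching implied
# gaps, some spurious).
chain_rules <- function() {
  genechain::gene_model_rules(min_intron_len = 20L, max_intron_len = 2000L,
                              min_intergenic = 100L, min_exon_len = 5L,
                              max_exon_len = 5000L)
}

random_instance <- function(seed, n = NULL) {
  set.seed(seed)
  if (is.null(n)) n <- sample(5:9, 1L)
  pos <- sort(sample.int(3000L, n))
  rows <- lapply(seq_len(n), function(i) {
    len <- sample(10:120, 1L)
    class <- sample(c("First", "Internal", "Terminal", "Single"), 1L)
    frame <- switch(class,
                    First = 0L, Single = 0L,
                    Internal = sample(0:2, 1L),
                    Terminal = len %% 3L)   # forces remainder 0
    data.frame(seqid = "t", start = pos[i] * 3L,
               end = pos[i] * 3L + len - 1L, strand = sample(c("+", "-"), 1L),
               exon_class = class, frame = frame,
               remainder = (3L - ((len - frame) %% 3L)) %% 3L,
               score = round(stats::runif(1, -2, 10), 3),
               stringsAsFactors = FALSE)
  })
  cand <- do.call(rbind, rows)
  cand <- cand[cand$start <= cand$end, ]
  cand <- cand[order(cand$start, cand$end), ]
  rownames(cand) <- NULL
  # evidence: implied gaps of some same-strand pairs + spurious introns
  ev <- list()
  for (k in seq_len(nrow(cand) - 1L)) {
    for (j in (k + 1L):nrow(cand)) {
      if (cand$strand[k] != cand$strand[j]) next
      gap_s <- cand$end[k] + 1L; gap_e <- cand$start[j] - 1L
      if (gap_e < gap_s) next
      if (stats::runif(1) < 0.25)
        ev[[length(ev) + 1L]] <- data.frame(
          seqid = "t", start = gap_s, end = gap_e,
          strand = cand$strand[k], support = 1L)
    }
  }
  if (stats::runif(1) < 0.5)
    ev[[length(ev) + 1L]] <- data.frame(seqid = "t", start = 5L, end = 80L,
                                        strand = "+", support = 1L)
  evidence <- if (length(ev)) do.call(rbind, ev) else NULL
  list(candidates = cand, evidence = evidence)
}

total_evidence_count <- function(pred) {
  sum(vapply(pred$genes, function(g)
    sum(vapply(g$transcripts, `[[`, 1L, "evidence_intron_count")), 1L))
}

# Exon structure signature of a prediction set, for bit-exact comparisons.
prediction_signature <- function(pred) {
  sig <- lapply(pred$genes, function(g)
    lapply(g$transcripts, function(tr)
      paste(g$strand, paste(sort(tr$exons$start), sort(tr$exons$end),
                            sep = "-", collapse = ","))))
  unlist(sig)
}

tiny_params <- function(order = 0L) {
  pwms <- list(
    donor = genechain::train_pwm(c("AAAGTAAGT", "CCCGTAAGT"), "donor",
                                 pseudocount = 0.5, offset = 3L),
    acceptor = genechain::train_pwm(
      c(paste0(strrep("T", 18L), "AGGAA"), paste0(strrep("C", 18L), "AGGCC")),
      "acceptor", pseudocount = 0.5, offset = 18L),
    start = genechain::train_pwm(c("GCCACCATGGCC", "ACCACCATGGAA"), "start",
                                 pseudocount = 0.5, offset = 6L))
  coding <- genechain::train_coding_model(
    c("ATGGCCGCCAAATAA"), c("TTTTGGGGAAAACCCC"), order = order,
    pseudocount = 0.5)
  genechain::model_params(pwms, coding, exon_weight = 0)
}

small_closed_loop_config <- function(seed) {
  genechain::sim_config(genome_length = 30000L, n_genes = 8L,
                        est_error_rate = 0, est_len_range = c(10000L, 10000L),
                        truncated_fraction = 0, unspliced_fraction = 0,
                        est_per_gene_range = c(6L, 10L), seed = seed)
}
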