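test_that("train_pwm matches the closed-form count formula", {
  p <- train_pwm(c("GT", "GT"), "donor", pseudocount = 0)
  expect_equal(unname(p$log_odds[1, "G"]), log2(1 / 0.25))
  expect_equal(unname(p$log_odds[2, "T"]), 2)

  # per-position uniform letters + uniform background -> all zeros
  p0 <- train_pwm(c("AA", "CC", "GG", "TT"), "donor", pseudocount = 0)
  expect_equal(max(abs(p0$log_odds)), 0)

  p1 <- train_pwm(c("GA", "GC"), "donor", pseudocount = 1)
  expect_equal(unname(p1$log_odds[2, "A"]), log2(((1 + 1) / (2 + 4)) / 0.25))
  expect_equal(unname(p1$log_odds[2, "T"]), log2(((0 + 1) / (2 + 4)) / 0.25))

  expect_error(train_pwm(c("GT", "GTT"), "donor"), "unequal")
  expect_error(train_pwm(character(), "donor"), "empty")
  expect_error(train_pwm(c("GN"), "donor"), "ACGT")
})

test_that("score_pwm agrees with a slow reference, is maximal on its own training window, and returns NA out of window", {
  set.seed(3)
  g <- genome_sequence("g", rand_seq(400))
  p <- train_pwm(c("AAAGTAAGT", "CCCGTAAGT", "ACAGTATGT"), "donor",
                 pseudocount = 0.5, offset = 3L)
  for (pos in c(4L, 50L, 200L, 392L)) {
    expect_equal(score_pwm(p, g, pos), slow_pwm_score(p, g$seq, pos))
  }
  expect_true(is.na(score_pwm(p, g, 2L)))     # window out of bounds
  expect_true(is.na(score_pwm(p, g, 400L)))

  # self-score maximality: a PWM from one window scores that window at the
  # per-position maximum
  w <- "ACAGTAAGT"
  p1 <- train_pwm(w, "donor", pseudocount = 0, offset = 3L)
  gw <- genome_sequence("w", paste0("TTTT", w, "TTTT"))
  expect_equal(score_pwm(p1, gw, 8L), sum(apply(p1$log_odds, 1, max)))

  # all-zero PWM scores 0 everywhere
  p0 <- train_pwm(c("AA", "CC", "GG", "TT"), "donor", pseudocount = 0)
  expect_equal(score_pwm(p0, g, 100L), 0)
})

test_that("reverse-strand PWM scores mirror forward scores on the reverse complement", {
  set.seed(9)
  g <- genome_sequence("g", rand_seq(300))
  grc <- genome_sequence("grc", revcomp(g$seq))
  p <- train_pwm(c("AAAGTAAGT", "CCCGTAAGT"), "donor", pseudocount = 0.5,
                 offset = 3L)
  for (pos in c(20L, 111L, 250L)) {
    mirrored <- g$length - pos + 1L
    expect_equal(score_pwm(p, g, pos, "-"),
                 score_pwm(p, grc, mirrored, "+"))
  }
})

test_that("windows containing N score NA", {
  g <- genome_sequence("g", paste0(strrep("A", 10), "N", strrep("A", 10)))
  p <- train_pwm("AAAA", "donor", pseudocount = 0.5, offset = 1L)
  expect_true(is.na(score_pwm(p, g, 11L)))
  expect_false(is.na(score_pwm(p, g, 5L)))
})

test_that("coding model transition counts match a hand tally (order 1)", {
  cds <- "ATGGCCAAATAG"
  m <- train_coding_model(cds, "ACGTACGTACGT", order = 1L, pseudocount = 0.5)
  # hand tally of frame-specific order-1 transitions in ATGGCCAAATAG:
  # position (1-based) i emits base i with context base i-1 and phase (i-1)%%3
  enc <- match(strsplit(cds, "")[[1L]], ACGT)
  counts <- array(0, dim = c(4, 4, 3))
  for (i in 2:nchar(cds)) {
    f <- ((i - 1) %% 3) + 1
    counts[enc[i - 1], enc[i], f] <- counts[enc[i - 1], enc[i], f] + 1
  }
  for (f in 1:3) {
    expected <- log2((counts[, , f] + 0.5) /
                       (rowSums(counts[, , f]) + 2))
    expect_equal(unname(m$coding_logp[, , f]), unname(expected))
  }
})

test_that("identical coding and background training data score ~0 and score_coding is additive", {
  # frame-symmetric training input: every codon phase sees each base once,
  # so the frame-specific coding chains equal the pooled background chain
  sym <- "AAACCCGGGTTT"
  m <- train_coding_model(sym, sym, order = 0L, pseudocount = 0.5)
  g <- genome_sequence("g", "ATGGCAGCTAAACCC")
  expect_equal(score_coding(m, g, 1, 15, "+", 0), 0, tolerance = 1e-12)

  set.seed(5)
  g2 <- genome_sequence("g2", rand_seq(120))
  m2 <- train_coding_model("ATGGCCGCCGCCAAATAA", "TTTTAAAATTTTAAAA",
                           order = 1L, pseudocount = 0.5)
  s_all <- score_coding(m2, g2, 11, 70, "+", 1L)
  split_at <- 40L
  len1 <- split_at - 11L + 1L
  f2 <- (3L - ((len1 - 1L) %% 3L)) %% 3L   # phase handed across the split
  s_parts <- score_coding(m2, g2, 11, split_at, "+", 1L) +
    score_coding(m2, g2, split_at + 1L, 70, "+", f2)
  expect_equal(s_all, s_parts, tolerance = 1e-10)
})

test_that("score_coding equals the slow reference on both strands and all frames", {
  set.seed(21)
  g <- genome_sequence("g", rand_seq(200))
  m <- train_coding_model(c("ATGGCCGCCAAAGCGTAA", "ATGCCCAAATAA"),
                          c(rand_seq(300), rand_seq(150)),
                          order = 2L, pseudocount = 0.5)
  for (f in 0:2) {
    expect_equal(score_coding(m, g, 21, 90, "+", f),
                 slow_coding_score(m, g$seq, 21, 90, f), tolerance = 1e-10)
    rc <- revcomp(g$seq)
    expect_equal(score_coding(m, g, 21, 90, "-", f),
                 slow_coding_score(m, rc, 200 - 90 + 1, 200 - 21 + 1, f),
                 tolerance = 1e-10)
  }
  expect_error(score_coding(m, g, 0, 10, "+", 0), "bounds")
  expect_error(train_coding_model("ATGTAA", "AAAA", order = -1), ">= 0")
  expect_error(train_coding_model("ATGA", "AAAA", order = 0), "divisible")
})

test_that("model parameters round-trip losslessly through the text format", {
  p <- tiny_params(order = 1L)
  f <- withr::local_tempfile(fileext = ".par")
  save_params(p, f)
  q <- load_params(f)
  expect_equal(q$pwms$donor$log_odds, p$pwms$donor$log_odds)
  expect_equal(q$pwms$acceptor$log_odds, p$pwms$acceptor$log_odds)
  expect_equal(q$pwms$start$log_odds, p$pwms$start$log_odds)
  expect_equal(q$coding$coding_logp, p$coding$coding_logp)
  expect_equal(q$coding$background_logp, p$coding$background_logp)
  expect_equal(q$signal_thresholds, p$signal_thresholds)
  expect_equal(q$exon_weight, p$exon_weight)
  expect_equal(q$intron_bonus, p$intron_bonus)
  expect_equal(q$gene_model, p$gene_model)
})

test_that("parameter files missing sections or with invalid values are rejected", {
  p <- tiny_params()
  f <- withr::local_tempfile(fileext = ".par")
  save_params(p, f)
  lines <- readLines(f)
  drop <- grep("^\\[pwm.donor\\]", lines)
  stopnext <- grep("^\\[pwm.acceptor\\]", lines)
  writeLines(lines[-(drop:(stopnext - 1L))], f)
  expect_error(load_params(f), "missing pwm: donor")

  save_params(p, f)
  lines <- readLines(f)
  lines[grep("^intron_bonus", lines)] <- "intron_bonus -5"
  writeLines(lines, f)
  expect_error(load_params(f), "intron_bonus")
})
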