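test_that("validate_evidence rejects malformed introns and merges duplicates", {
  g <- genome_sequence("g", strrep("A", 1000))
  rules <- gene_model_rules(min_intron_len = 30L, max_intron_len = 500L)
  introns <- data.frame(
    seqid = "g",
    start = c(201L, 201L, 100L, 950L, 400L),
    end   = c(300L, 300L, 101L, 1200L, 360L),
    strand = c("+", "+", "+", "+", NA),
    support = c(1L, 1L, 1L, 1L, 1L))
  v <- validate_evidence(introns, g, rules)
  expect_equal(nrow(v$accepted), 1L)
  expect_equal(v$accepted$start, 201L)
  expect_equal(v$accepted$support, 2L)          # duplicates merged
  expect_setequal(v$rejected$reason,
                  c("below min_intron_len", "outside genome",
                    "undefined strand"))
  # rejection is data, not failure
  expect_s3_class(v$rejected, "data.frame")
})

test_that("empty candidate list assembles to an empty prediction set", {
  out <- assemble(genechain:::empty_candidates())
  expect_length(out$genes, 0L)
  expect_equal(out$objective, 0)
})

test_that("a single Single-class candidate forms a one-gene chain", {
  cand <- data.frame(seqid = "t", start = 100L, end = 199L, strand = "+",
                     exon_class = "Single", frame = 0L, remainder = 0L,
                     score = 5)
  out <- assemble(cand, rules = chain_rules())
  expect_length(out$genes, 1L)
  expect_equal(out$genes[[1L]]$transcripts[[1L]]$exons$start, 100L)
  expect_equal(out$objective, 5)
})

test_that("an evidence intron redirects the chain even when a higher-scoring alternative exists", {
  # two First exons share frame continuity with the Terminal exon; the
  # higher-scoring one implies intron (211,300), the lower-scoring one the
  # evidence intron (201,300)
  cand <- data.frame(
    seqid = "t",
    start = c(4L, 5L, 301L),
    end = c(200L, 210L, 400L),
    strand = "+",
    exon_class = c("First", "First", "Terminal"),
    frame = c(0L, 0L, 1L),
    remainder = c(1L, 1L, 0L),
    score = c(3, 5, 4))
  rules <- chain_rules()
  # sanity: without evidence the higher-scoring First wins
  base <- assemble(cand, NULL, rules, intron_bonus = 1e6)
  expect_equal(prediction_signature(base), "+ 5-210,301-400")
  ev <- data.frame(seqid = "t", start = 201L, end = 300L, strand = "+",
                   support = 1L)
  out <- assemble(cand, ev, rules, intron_bonus = 1e6)
  expect_equal(prediction_signature(out), "+ 4-200,301-400")
  expect_equal(total_evidence_count(out), 1L)
  # exhaustive enumeration agrees
  orc <- oracle_assemble(cand, ev, rules, intron_bonus = 1e6)
  expect_equal(out$objective, orc$objective)
  # with intron_bonus 0 the evidence is ignored and score wins again
  out0 <- assemble(cand, ev, rules, intron_bonus = 0)
  expect_equal(prediction_signature(out0), prediction_signature(base))
})

test_that("assemble matches the exhaustive oracle on random instances", {
  for (seed in 1:40) {
    inst <- random_instance(seed)
    fast <- assemble(inst$candidates, inst$evidence, chain_rules(), 1e6)
    slow <- oracle_assemble(inst$candidates, inst$evidence, chain_rules(), 1e6)
    expect_equal(fast$objective, slow$objective,
                 info = paste("seed", seed))
  }
})

test_that("with no evidence, bonus value is irrelevant and chaining is pure score maximisation", {
  for (seed in 41:55) {
    inst <- random_instance(seed)
    a <- assemble(inst$candidates, NULL, chain_rules(), 1e6)
    b <- assemble(inst$candidates, inst$candidates[0, ], chain_rules(), 0)
    expect_identical(prediction_signature(a), prediction_signature(b))
    expect_equal(a$objective, b$objective)
  }
})

test_that("adding an evidence intron never decreases the matched-evidence count", {
  for (seed in 56:70) {
    inst <- random_instance(seed)
    if (is.null(inst$evidence) || nrow(inst$evidence) < 2L) next
    rules <- chain_rules()
    sub <- inst$evidence[-nrow(inst$evidence), , drop = FALSE]
    n_sub <- total_evidence_count(assemble(inst$candidates, sub, rules, 1e6))
    n_all <- total_evidence_count(assemble(inst$candidates, inst$evidence,
                                           rules, 1e6))
    expect_gte(n_all, n_sub)
  }
})

test_that("assembly is strand-mirror symmetric", {
  mirror_instance <- function(inst, L) {
    cd <- inst$candidates
    new <- cd
    new$start <- L - cd$end + 1L
    new$end <- L - cd$start + 1L
    new$strand <- ifelse(cd$strand == "+", "-", "+")
    new <- new[order(new$start, new$end), ]
    rownames(new) <- NULL
    ev <- inst$evidence
    if (!is.null(ev)) {
      ev2 <- ev
      ev2$start <- L - ev$end + 1L
      ev2$end <- L - ev$start + 1L
      ev2$strand <- ifelse(ev$strand == "+", "-", "+")
      ev <- ev2
    }
    list(candidates = new, evidence = ev)
  }
  for (seed in 71:85) {
    inst <- random_instance(seed)
    L <- max(inst$candidates$end) + 100L
    mirr <- mirror_instance(inst, L)
    a <- assemble(inst$candidates, inst$evidence, chain_rules(), 1e6)
    b <- assemble(mirr$candidates, mirr$evidence, chain_rules(), 1e6)
    expect_equal(a$objective, b$objective, info = paste("seed", seed))
    expect_equal(total_evidence_count(a), total_evidence_count(b))
  }
})

test_that("a bonus that does not dominate the candidate scores triggers a warning", {
  cand <- data.frame(seqid = "t", start = c(1L, 200L), end = c(90L, 290L),
                     strand = "+", exon_class = c("First", "Terminal"),
                     frame = c(0L, 0L), remainder = c(0L, 0L),
                     score = c(50, 60))
  ev <- data.frame(seqid = "t", start = 91L, end = 199L, strand = "+",
                   support = 1L)
  expect_warning(assemble(cand, ev, chain_rules(), intron_bonus = 10),
                 "dominate")
})

test_that("oracle refuses oversized instances", {
  cand <- do.call(rbind, lapply(1:16, function(i)
    data.frame(seqid = "t", start = i * 300L, end = i * 300L + 50L,
               strand = "+", exon_class = "Single", frame = 0L,
               remainder = 0L, score = 1)))
  expect_error(oracle_assemble(cand), "15")
})

test_that("inject_cds_evidence adds classed candidates, introns and boosts duplicates", {
  cand <- genechain:::empty_candidates()
  out <- inject_cds_evidence(genechain:::empty_transcripts(), cand)
  expect_equal(nrow(out$candidates), 0L)
  expect_equal(nrow(out$introns), 0L)

  cds <- data.frame(transcript_id = "c1", seqid = "g", strand = "+",
                    start = c(101L, 301L), end = c(199L, 400L))
  # 99 + 100 = 199 bases: not divisible by 3 -> rejected
  bad <- inject_cds_evidence(cds, cand)
  expect_equal(bad$rejected$transcript_id, "c1")
  expect_equal(nrow(bad$candidates), 0L)

  cds$end <- c(200L, 400L)   # 100 + 100 -> not %3; fix to 99+102 instead
  cds <- data.frame(transcript_id = "c1", seqid = "g", strand = "+",
                    start = c(101L, 301L), end = c(199L, 402L))
  ok <- inject_cds_evidence(cds, cand, boost = 42)
  expect_equal(nrow(ok$candidates), 2L)
  expect_setequal(ok$candidates$exon_class, c("First", "Terminal"))
  expect_equal(nrow(ok$introns), 1L)
  expect_equal(ok$introns$start, 200L)
  expect_equal(ok$introns$end, 300L)
  first <- ok$candidates[ok$candidates$exon_class == "First", ]
  term <- ok$candidates[ok$candidates$exon_class == "Terminal", ]
  expect_equal(first$frame, 0L)
  expect_equal(term$frame, first$remainder)    # frame continuity
  expect_equal(term$remainder, 0L)
  expect_equal(first$score, 42)

  # boosted duplicate of an existing candidate: score raised, not re-added
  existing <- ok$candidates
  existing$score <- 1
  again <- inject_cds_evidence(cds, existing, boost = 42)
  expect_equal(nrow(again$candidates), 2L)
  expect_true(all(again$candidates$score == 42))
  # idempotent when existing score is higher
  existing$score <- 99
  keep <- inject_cds_evidence(cds, existing, boost = 42)
  expect_true(all(keep$candidates$score == 99))
})

test_that("minus-strand CDS injection assigns classes in gene direction", {
  cds <- data.frame(transcript_id = "m1", seqid = "g", strand = "-",
                    start = c(101L, 301L), end = c(199L, 402L))
  out <- inject_cds_evidence(cds, genechain:::empty_candidates(), boost = 10)
  # genomically-left exon is the Terminal one on the minus strand
  left <- out$candidates[out$candidates$start == 101L, ]
  right <- out$candidates[out$candidates$start == 301L, ]
  expect_equal(left$exon_class, "Terminal")
  expect_equal(right$exon_class, "First")
  expect_equal(right$frame, 0L)
})
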