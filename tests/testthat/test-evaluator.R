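mk_tr <- function(id, starts, ends, strand = "+", seqid = "g") {
  data.frame(transcript_id = id, gene_id = id, seqid = seqid, strand = strand,
             start = as.integer(starts), end = as.integer(ends),
             source = "x", stringsAsFactors = FALSE)
}

test_that("transcripts cluster into genes by same-strand exon overlap", {
  a <- mk_tr("a", c(101, 301), c(200, 400))
  b <- mk_tr("b", c(150, 301), c(200, 450))          # shares exon interval
  cl <- cluster_into_genes(rbind(a, b))
  expect_length(cl, 1L)
  expect_setequal(cl[[1L]], c("a", "b"))

  # intron-nested, no exon overlap -> two genes
  host <- mk_tr("host", c(101, 501), c(200, 600))
  nested <- mk_tr("nested", c(251), c(350))
  expect_length(cluster_into_genes(rbind(host, nested)), 2L)

  # opposite strands never cluster
  c1 <- mk_tr("c1", 101, 200)
  c2 <- mk_tr("c2", 150, 250, strand = "-")
  expect_length(cluster_into_genes(rbind(c1, c2)), 2L)
})

test_that("gene projection merges exon intervals like a per-base union", {
  ts <- rbind(mk_tr("a", c(1, 30), c(10, 45)), mk_tr("b", c(5, 60), c(20, 70)))
  p <- project_gene(ts)
  expect_equal(p$start, c(1L, 30L, 60L))
  expect_equal(p$end, c(20L, 45L, 70L))
  # per-base oracle
  bases <- rep(FALSE, 100)
  for (k in seq_len(nrow(ts))) bases[ts$start[k]:ts$end[k]] <- TRUE
  expect_equal(sum(p$end - p$start + 1L), sum(bases))
})

test_that("a perfect prediction scores 1 everywhere and 0 wrong/missing", {
  annot <- rbind(mk_tr("t1", c(101, 301), c(200, 400)),
                 mk_tr("t2", c(1001, 1301), c(1100, 1400), strand = "-"))
  rep <- evaluate_predictions(annot, annot)
  expect_true(all(rep$SN == 1))
  expect_true(all(rep$SP == 1))
  expect_true(all(rep$SS == 1))
  expect_true(all(rep$W == 0))
  expect_true(all(rep$M == 0))
  expect_true(all(rep$SS == (rep$SN + rep$SP) / 2))
})

test_that("the two-exon hand-count toy yields the hand-derived report", {
  annot <- mk_tr("a1", c(101, 301), c(200, 400))
  pred <- mk_tr("p1", c(101, 301), c(200, 450))
  rep <- evaluate_predictions(pred, annot)
  ex <- rep[rep$level == "exon", ]
  expect_equal(ex$SN, 0.5)
  expect_equal(ex$SP, 0.5)
  expect_equal(ex$TP, 1L)
  nt <- rep[rep$level == "nucleotide", ]
  expect_equal(nt$TP, 200L)
  expect_equal(nt$FP, 50L)
  expect_equal(nt$FN, 0L)
  expect_equal(nt$SN, 1)
  expect_equal(nt$SP, 200 / 250)
  # neither feature has zero overlap
  expect_equal(ex$W, 0)
  expect_equal(ex$M, 0)
})

test_that("an empty prediction reports SN=0, M=1 and degenerate (not NaN) SP", {
  annot <- mk_tr("a1", c(101, 301), c(200, 400))
  rep <- evaluate_predictions(genechain:::empty_transcripts(), annot)
  expect_true(all(rep$SN == 0))
  expect_true(all(rep$SP == 0))
  expect_true(all(rep$M[rep$level != "intron"] == 1))
  expect_true(all(rep$degenerate))
  expect_false(any(is.nan(rep$SP)))
})

test_that("evaluation is symmetric under swapping prediction and annotation", {
  set.seed(77)
  mk_rand <- function(pfx, n) {
    rows <- lapply(seq_len(n), function(i) {
      s <- sample.int(5000L, 1L)
      nex <- sample(1:3, 1L)
      starts <- s + cumsum(c(0L, rep(200L, nex - 1L)))
      mk_tr(paste0(pfx, i), starts, starts + sample(50:150, nex, TRUE),
            strand = sample(c("+", "-"), 1L))
    })
    do.call(rbind, rows)
  }
  a <- mk_rand("a", 5L)
  b <- mk_rand("b", 4L)
  r1 <- evaluate_predictions(a, b)
  r2 <- evaluate_predictions(b, a)
  expect_equal(r1$SN, r2$SP)
  expect_equal(r1$SP, r2$SN)
  expect_equal(r1$W, r2$M)
  expect_equal(r1$M, r2$W)
  expect_equal(r1$TP[r1$level != "gene"], r2$TP[r2$level != "gene"])
})

test_that("nucleotide counts match a per-base bitmap oracle", {
  set.seed(13)
  for (rep_i in 1:3) {
    mk_rand <- function(pfx, n) {
      rows <- lapply(seq_len(n), function(i) {
        s <- sample.int(3000L, 1L)
        nex <- sample(1:3, 1L)
        starts <- s + cumsum(c(0L, rep(150L, nex - 1L)))
        mk_tr(paste0(pfx, i), starts, starts + sample(40:120, nex, TRUE))
      })
      do.call(rbind, rows)
    }
    pred <- mk_rand("p", 4L)
    annot <- mk_rand("a", 4L)
    r <- evaluate_predictions(pred, annot)
    nt <- r[r$level == "nucleotide", ]
    pb <- rep(FALSE, 10000); ab <- rep(FALSE, 10000)
    for (k in seq_len(nrow(pred))) pb[pred$start[k]:pred$end[k]] <- TRUE
    for (k in seq_len(nrow(annot))) ab[annot$start[k]:annot$end[k]] <- TRUE
    expect_equal(nt$TP, sum(pb & ab))
    expect_equal(nt$FP, sum(pb & !ab))
    expect_equal(nt$FN, sum(!pb & ab))
  }
})

test_that("count identities TP+FN == annotated and TP+FP == predicted hold per level", {
  annot <- rbind(mk_tr("t1", c(101, 301), c(200, 400)),
                 mk_tr("t2", c(900), c(1000)))
  pred <- rbind(mk_tr("p1", c(101, 311), c(200, 400)),
                mk_tr("p2", c(2000), c(2100)))
  rep <- evaluate_predictions(pred, annot)
  for (lvl in c("nucleotide", "exon", "intron", "transcript")) {
    row <- rep[rep$level == lvl, ]
    p_tot <- switch(lvl,
                    nucleotide = sum(pred$end - pred$start + 1),
                    exon = nrow(pred), intron = 1L, transcript = 2L)
    a_tot <- switch(lvl,
                    nucleotide = sum(annot$end - annot$start + 1),
                    exon = nrow(annot), intron = 1L, transcript = 2L)
    expect_equal(row$TP + row$FP, p_tot, info = lvl)
    expect_equal(row$TP + row$FN, a_tot, info = lvl)
  }
})

test_that("btp_map pairs transcripts greedily and handles split/join cases", {
  p1 <- mk_tr("p1", 101, 200)
  a1 <- mk_tr("a1", 150, 250)
  bm <- btp_map(p1, a1)
  expect_equal(nrow(bm$pairs), 1L)
  expect_equal(bm$pairs$relation, "one_to_one")
  expect_equal(bm$pairs$overlap, 51L)

  # two predictions each covering half of one annotated transcript: split
  p2 <- rbind(mk_tr("pa", 101, 200), mk_tr("pb", 201, 300))
  a2 <- mk_tr("aa", 101, 300)
  bm2 <- btp_map(p2, a2)
  expect_equal(sum(bm2$pairs$relation == "one_to_one"), 1L)
  expect_equal(sum(bm2$pairs$relation == "split"), 1L)
  expect_length(bm2$unmatched_pred, 0L)

  # zero overlap -> never paired
  p3 <- mk_tr("p3", 101, 200)
  a3 <- mk_tr("a3", 5000, 5100)
  bm3 <- btp_map(p3, a3)
  expect_equal(nrow(bm3$pairs), 0L)
  expect_equal(bm3$unmatched_pred, "p3")
  expect_equal(bm3$unmatched_annot, "a3")
})

test_that("BTP-mode evaluation restricts measures to matched pairs", {
  # one well-predicted gene and one annotated gene missed entirely:
  # gene-mode SN suffers, BTP-mode (connectivity of what was predicted) does not
  annot <- rbind(mk_tr("t1", c(101, 301), c(200, 400)),
                 mk_tr("t2", c(5001, 5301), c(5100, 5400)))
  pred <- mk_tr("p1", c(101, 301), c(200, 400))
  gene_mode <- evaluate_predictions(pred, annot, mode = "gene")
  btp <- evaluate_predictions(pred, annot, mode = "btp")
  expect_lt(gene_mode$SN[gene_mode$level == "exon"], 1)
  expect_equal(btp$SN[btp$level == "exon"], 1)
  expect_equal(btp$SP[btp$level == "exon"], 1)
  expect_equal(btp$SN[btp$level == "transcript"], 1)
  expect_equal(btp$mode[1L], "BTP")
})

test_that("contradictory strands within one transcript are an input error", {
  bad <- rbind(mk_tr("x", 101, 200), mk_tr("x", 301, 400, strand = "-"))
  good <- mk_tr("a", 101, 200)
  expect_error(evaluate_predictions(bad, good), "contradictory strands")
})

test_that("titration with identical seeds is deterministic and fraction 0 is the ab initio baseline", {
  cfg <- sim_config(genome_length = 30000L, n_genes = 8L, seed = 42L)
  sim <- simulate_genome(cfg)
  params <- train_from_truth(sim)
  cand <- enumerate_all_candidates(sim$genome, params)
  intr <- genechain:::unique_introns(sim$transcripts)
  intr$support <- 1L
  t1 <- titration_experiment(cand, sim$transcripts, intr,
                             fractions = c(0, 1), n_reps = 2L, seed = 9L)
  t2 <- titration_experiment(cand, sim$transcripts, intr,
                             fractions = c(0, 1), n_reps = 2L, seed = 9L)
  expect_identical(t1, t2)
  base <- evaluate_predictions(
    predictions_to_transcripts(assemble(cand, NULL, params$gene_model)),
    sim$transcripts)
  expect_equal(t1$SSe[t1$fraction == 0],
               base$SS[base$level == "exon"])
})
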