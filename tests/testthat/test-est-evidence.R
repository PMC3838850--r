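mk_aln <- function(id, blocks, strand = "+", identity = 0.99, coverage = 0.99,
                   seqid = "g") {
  spliced_alignment(id, seqid, strand, do.call(rbind, blocks), identity,
                    coverage)
}

test_that("alignment filter applies the identity/coverage thresholds with strict coverage inequality", {
  cfg <- cluster_config(min_identity = 0.95, min_coverage = 0.90)
  a1 <- mk_aln("a1", list(c(1, 100)), identity = 0.94, coverage = 0.95)
  a2 <- mk_aln("a2", list(c(1, 100)), identity = 0.99, coverage = 0.91)
  a3 <- mk_aln("a3", list(c(1, 100)), identity = 0.99, coverage = 0.90)
  a4 <- mk_aln("a4", list(c(1, 100)), identity = 0.95, coverage = 0.901)
  f <- filter_alignments(list(a1, a2, a3, a4), cfg)
  expect_setequal(vapply(f$kept, `[[`, "", "est_id"), c("a2", "a4"))
  expect_setequal(vapply(f$discarded, `[[`, "", "est_id"), c("a1", "a3"))
  # human-style stricter identity
  cfg98 <- cluster_config(min_identity = 0.98)
  f98 <- filter_alignments(list(a1, a2, a4), cfg98)
  expect_setequal(vapply(f98$kept, `[[`, "", "est_id"), "a2")
  # idempotence
  f2 <- filter_alignments(f$kept, cfg)
  expect_length(f2$discarded, 0L)
})

test_that("clustering links alignments sharing a splice site and attaches unspliced ESTs by overlap and strand", {
  A <- mk_aln("A", list(c(101, 200), c(301, 400)))
  B <- mk_aln("B", list(c(151, 200), c(301, 350), c(401, 500)))
  C <- mk_aln("C", list(c(551, 600), c(701, 800)))
  cl <- cluster_alignments(list(A, B, C))
  expect_length(cl, 2L)
  expect_setequal(vapply(cl[[1L]]$members, `[[`, "", "est_id"), c("A", "B"))
  expect_setequal(vapply(cl[[2L]]$members, `[[`, "", "est_id"), "C")

  U_same <- mk_aln("U", list(c(120, 180)))
  U_opp <- mk_aln("V", list(c(120, 180)), strand = "-")
  cl2 <- cluster_alignments(list(A, B, U_same, U_opp))
  memb <- lapply(cl2, function(x) sort(vapply(x$members, `[[`, "", "est_id")))
  expect_true(list(c("A", "B", "U")) %in% memb ||
                any(vapply(memb, identical, TRUE, c("A", "B", "U"))))
  expect_true(any(vapply(memb, identical, TRUE, "V")))

  # boundary tolerance: sites differing by <= tol are the same site
  B2 <- mk_aln("B2", list(c(101, 198), c(303, 400)))   # both sites off by <=3
  cl3 <- cluster_alignments(list(A, B2), cluster_config(boundary_tolerance = 3))
  expect_length(cl3, 1L)
  cl4 <- cluster_alignments(list(A, B2), cluster_config(boundary_tolerance = 1))
  expect_length(cl4, 2L)
})

test_that("clustering is invariant to input order", {
  set.seed(8)
  alns <- list(
    mk_aln("x1", list(c(101, 200), c(301, 400))),
    mk_aln("x2", list(c(120, 200), c(301, 420))),
    mk_aln("x3", list(c(901, 1000), c(1101, 1200))),
    mk_aln("x4", list(c(950, 1000), c(1101, 1250))),
    mk_aln("x5", list(c(140, 190))))
  ref <- cluster_alignments(alns)
  ref_sets <- lapply(ref, function(cl)
    sort(vapply(cl$members, `[[`, "", "est_id")))
  for (i in 1:5) {
    perm <- cluster_alignments(sample(alns))
    perm_sets <- lapply(perm, function(cl)
      sort(vapply(cl$members, `[[`, "", "est_id")))
    expect_setequal(perm_sets, ref_sets)
  }
})

test_that("infer_introns builds consensus introns, shifts to canonical boundaries, drops non-canonical gaps", {
  # genome with GT at 201-202 and AG at 299-300
  seq <- paste0(strrep("C", 200), "GT", strrep("A", 96), "AG",
                strrep("C", 100))
  g <- genome_sequence("g", seq)
  A <- mk_aln("A", list(c(101, 200), c(301, 400)))
  B <- mk_aln("B", list(c(101, 200), c(301, 380)))
  cl <- cluster_alignments(list(A, B))[[1L]]
  intr <- infer_introns(cl, g)
  expect_equal(nrow(intr), 1L)
  expect_equal(intr$start, 201L)
  expect_equal(intr$end, 300L)
  expect_equal(intr$support, 2L)

  # a member whose gap is off by 2 merges and lands on the canonical site
  C <- mk_aln("C", list(c(101, 202), c(303, 400)))   # gap (203,302)
  cl2 <- cluster_alignments(list(A, C))[[1L]]
  intr2 <- infer_introns(cl2, g, cluster_config(boundary_tolerance = 3))
  expect_equal(nrow(intr2), 1L)
  expect_equal(c(intr2$start, intr2$end), c(201L, 300L))

  # no GT..AG anywhere within the shift window -> dropped
  g2 <- genome_sequence("g2", strrep("C", 600))
  cl3 <- cluster_alignments(list(A))[[1L]]
  expect_equal(nrow(infer_introns(cl3, g2)), 0L)
})

test_that("minus-strand introns are canonical on the reverse complement", {
  # forward CT...AC corresponds to GT..AG in gene direction on '-'
  seq <- paste0(strrep("G", 200), "CT", strrep("T", 96), "AC",
                strrep("G", 100))
  g <- genome_sequence("g", seq)
  A <- mk_aln("A", list(c(101, 200), c(301, 400)), strand = "-")
  cl <- cluster_alignments(list(A))[[1L]]
  intr <- infer_introns(cl, g)
  expect_equal(nrow(intr), 1L)
  expect_equal(intr$strand, "-")
  intron_seq <- genome_subseq(g, intr$start, intr$end, "-")
  expect_equal(substr(intron_seq, 1, 2), "GT")
  expect_equal(substr(intron_seq, nchar(intron_seq) - 1, nchar(intron_seq)),
               "AG")
})

test_that("EST transcript assembly merges compatible structures to a non-mergeable set", {
  seq <- paste0(strrep("C", 200), "GT", strrep("A", 96), "AG",
                strrep("C", 197), "GT", strrep("A", 97), "AG",
                strrep("C", 200))
  g <- genome_sequence("g", seq)
  # staggered members with identical intron chains -> one transcript
  A <- mk_aln("A", list(c(101, 200), c(301, 400)))
  B <- mk_aln("B", list(c(151, 200), c(301, 499)))
  cl <- cluster_alignments(list(A, B))[[1L]]
  intr <- infer_introns(cl, g)
  ts <- assemble_est_transcripts(cl, intr)
  expect_length(unique(ts$transcript_id), 1L)
  expect_equal(min(ts$start), 101L)
  expect_equal(max(ts$end), 499L)
  expect_equal(nrow(ts), 2L)   # two exons around the shared intron

  # conflicting intron boundaries -> two transcripts
  Cc <- mk_aln("C", list(c(101, 230), c(321, 400)))  # different, non-mergeable
  cl2 <- cluster_alignments(list(A, Cc),
                            cluster_config(boundary_tolerance = 0))
  if (length(cl2) == 1L) {
    intr2 <- infer_introns(cl2[[1L]], g,
                           cluster_config(boundary_tolerance = 0,
                                          shift_window = 0))
    ts2 <- assemble_est_transcripts(cl2[[1L]], intr2)
    expect_length(unique(ts2$transcript_id), 2L)
  }
})

test_that("pairwise non-mergeability holds after assembly (A~B, B~C compatible, A~C conflicting)", {
  # introns: i1 = (201,300), i2 = (501,600); A supports i1, C supports i2
  # differently-placed (conflict), B overlaps both but only supports i1
  seq <- paste0(strrep("C", 200), "GT", strrep("A", 96), "AG",
                strrep("C", 200), "GT", strrep("A", 96), "AG",
                strrep("C", 200))
  g <- genome_sequence("g", seq)
  A <- mk_aln("A", list(c(101, 200), c(301, 450)))
  B <- mk_aln("B", list(c(121, 200), c(301, 480)))
  Cc <- mk_aln("C", list(c(301, 500), c(601, 700)))   # exon across (501,600)? no: gap (501,600)
  cl <- cluster_alignments(list(A, B, Cc))
  # A,B share site; C shares no site but overlaps; C spliced so it stays separate
  all_ts <- do.call(rbind, lapply(cl, function(x)
    assemble_est_transcripts(x, infer_introns(x, g))))
  # no two output transcripts are mergeable: check pairwise intron conflict
  tids <- unique(all_ts$transcript_id)
  if (length(tids) > 1L) {
    for (i in seq_along(tids)) for (j in seq_along(tids)) {
      if (i >= j) next
      t1 <- all_ts[all_ts$transcript_id == tids[i], ]
      t2 <- all_ts[all_ts$transcript_id == tids[j], ]
      ov <- min(max(t1$end), max(t2$end)) - max(min(t1$start), min(t2$start))
      if (ov < 0) next
      i1 <- genechain:::transcript_introns(t1)
      i2 <- genechain:::transcript_introns(t2)
      same <- nrow(i1) == nrow(i2) &&
        (nrow(i1) == 0 || all(paste(i1$start, i1$end) == paste(i2$start, i2$end)))
      expect_false(same)
    }
  }
})

test_that("longest_orf scans all frames with 5'-most tie-break", {
  orf <- longest_orf("AAATGAAACCCTAGAA")
  expect_equal(orf$start, 3L)
  expect_equal(orf$end, 14L)
  expect_equal(orf$length, 12L)
  expect_equal(substr("AAATGAAACCCTAGAA", orf$start, orf$end), "ATGAAACCCTAG")

  expect_null(longest_orf("CCCCCCCCCC"))
  expect_null(longest_orf("ATGAAACCC"))    # no stop -> no complete ORF

  # two equal-length ORFs: the 5'-most wins
  two <- paste0("ATGAAATAA", "C", "ATGCCCTAA")
  orf2 <- longest_orf(two)
  expect_equal(orf2$start, 1L)
})

test_that("mod3_profile computes length-class fractions", {
  intr <- data.frame(start = c(1, 1, 1, 1), end = c(9, 12, 10, 11))
  expect_equal(unname(mod3_profile(intr)), c(0.5, 0.25, 0.25))
  expect_equal(unname(mod3_profile(rep(30L, 5))), c(1, 0, 0))
  expect_error(mod3_profile(integer()), "at least one")
  expect_equal(sum(mod3_profile(sample(20:200, 50))), 1)
})
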