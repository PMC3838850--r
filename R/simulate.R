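#' Simulation configuration
#'
#' Defaults emulate a compact, intron-rich genome (worm-like scale): ~30
#' genes per 100 kb, 2-6 coding exons of 80-250 bp separated by 50-500 bp
#' canonical GT..AG introns, codon-biased CDS, and single-pass EST reads of
#' 300-800 bp sampled from mature transcripts.
#'
#' @param genome_length total sequence length (bp).
#' @param n_genes number of non-overlapping genes to place.
#' @param exon_count_range,exon_len_range,intron_len_range inclusive ranges.
#' @param isoform_prob probability a gene (with >= 3 exons) carries a second,
#'   exon-skipping isoform.
#' @param gc_content intergenic GC fraction.
#' @param est_per_gene_range,est_len_range EST sampling ranges.
#' @param est_error_rate per-base substitution rate on ESTs (drives the
#'   simulated alignment identity).
#' @param unspliced_fraction fraction of ESTs drawn from within one exon.
#' @param truncated_fraction fraction of ESTs with unaligned tails
#'   (coverage below 1, emulating vector/low-quality ends).
#' @param min_intergenic_gap minimum gap placed between genes (bp).
#' @param seed integer; the same seed yields byte-identical outputs.
#' @export
sim_config <- function(genome_length = 100000L, n_genes = 30L,
                       exon_count_range = c(2L, 6L),
                       exon_len_range = c(80L, 250L),
                       intron_len_range = c(50L, 500L),
                       isoform_prob = 0.2, gc_content = 0.42,
                       est_per_gene_range = c(5L, 15L),
                       est_len_range = c(300L, 800L),
                       est_error_rate = 0.01, unspliced_fraction = 0.1,
                       truncated_fraction = 0.05,
                       min_intergenic_gap = 400L, seed = 1L) {
  stopifnot(genome_length > 0, n_genes >= 0,
            exon_count_range[1L] >= 1L,
            exon_len_range[1L] >= 10L,
            intron_len_range[1L] >= 30L,
            isoform_prob >= 0, isoform_prob <= 1,
            gc_content > 0, gc_content < 1,
            est_error_rate >= 0, est_error_rate <= 1,
            unspliced_fraction >= 0, unspliced_fraction <= 1)
  list(genome_length = as.integer(genome_length), n_genes = as.integer(n_genes),
       exon_count_range = as.integer(exon_count_range),
       exon_len_range = as.integer(exon_len_range),
       intron_len_range = as.integer(intron_len_range),
       isoform_prob = isoform_prob, gc_content = gc_content,
       est_per_gene_range = as.integer(est_per_gene_range),
       est_len_range = as.integer(est_len_range),
       est_error_rate = est_error_rate,
       unspliced_fraction = unspliced_fraction,
       truncated_fraction = truncated_fraction,
       min_intergenic_gap = as.integer(min_intergenic_gap),
       seed = as.integer(seed))
}

# Codon usage for simulated CDS: strongly biased sense-codon table so the
# coding Markov model has signal to learn. Weights loosely follow
# highly-expressed-gene usage (GC-ended codons favoured).
sim_codon_table <- function() {
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  w <- rep(1, length(codons))
  names(w) <- codons
  w[substr(codons, 3L, 3L) %in% c("C", "G")] <- 1.5
  w[c("GCC", "GAG", "AAG", "CTG", "GAC", "TTC", "ATC", "AAC", "GGC",
      "CAG", "GTG", "ACC", "TCC", "CGC", "TAC", "TGC", "CAC", "ATG")] <- 2.2
  w / sum(w)
}

sample_bases <- function(n, gc) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Consensus string with per-base noise; replacement letters drawn from
# `alphabet` (restricting to A/C/G at exonic positions cannot create a stop
# codon's leading T, but transcripts are verified afterwards anyway).
noisy_consensus <- function(consensus, noise = 0.15, alphabet = c("A", "C", "G", "T")) {
  ch <- strsplit(consensus, "", fixed = TRUE)[[1L]]
  flip <- stats::runif(length(ch)) < noise
  ch[flip] <- sample(alphabet, sum(flip), replace = TRUE)
  paste(ch, collapse = "")
}

# Pyrimidine-rich acceptor tract.
sample_ppt <- function(n) {
  paste(sample(c("T", "C", "A", "G"), n, replace = TRUE,
               prob = c(.42, .26, .16, .16)), collapse = "")
}

#' Simulate a genome with known gene structures
#'
#' Places `n_genes` non-overlapping multi-exon genes on both strands with
#' canonical GT..AG introns carrying planted consensus splice contexts
#' (GTAAGT donors, pyrimidine tract + CAG acceptors, Kozak-like start
#' context), codon-biased CDS free of internal stops, and, with probability
#' `isoform_prob`, a second exon-skipping isoform (the skipped internal
#' exon has length divisible by 3 so frame is preserved).
#'
#' @param config a [sim_config()].
#' @return list with `genome` (a [genome_sequence()]), `truth`
#'   (gff_features: gene/mRNA/exon rows) and `transcripts` (transcript-set
#'   data.frame of the truth).
#' @export
simulate_genome <- function(config = sim_config()) {
  set.seed(config$seed)
  genes <- lapply(seq_len(config$n_genes), function(i) sim_gene(config, i))
  glens <- vapply(genes, `[[`, 1L, "glen")
  gap_min <- config$min_intergenic_gap
  spare <- config$genome_length - sum(glens) -
    gap_min * (config$n_genes + 1L)
  if (spare < 0)
    stop("simulation config infeasible: genes do not fit in genome_length")
  ngaps <- config$n_genes + 1L
  extra <- if (spare > 0 && ngaps > 0)
    as.integer(stats::rmultinom(1L, spare, rep(1, ngaps))[, 1L])
  else rep(0L, ngaps)
  gaps <- gap_min + extra
  seq_parts <- character(0)
  truth_rows <- list()
  ts_rows <- list()
  pos <- 1L
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    seq_parts <- c(seq_parts, sample_bases(gaps[i], config$gc_content))
    pos <- pos + gaps[i]
    placed <- place_gene(g, pos, i)
    seq_parts <- c(seq_parts, placed$seq)
    truth_rows[[i]] <- placed$gff
    ts_rows[[i]] <- placed$ts
    pos <- pos + g$glen
  }
  seq_parts <- c(seq_parts, sample_bases(gaps[length(gaps)], config$gc_content))
  tail_fill <- config$genome_length - (pos - 1L + gaps[length(gaps)])
  if (tail_fill > 0L)
    seq_parts <- c(seq_parts, sample_bases(tail_fill, config$gc_content))
  genome <- genome_sequence("sim1", paste(seq_parts, collapse = ""))
  truth <- if (length(truth_rows))
    do.call(rbind, c(truth_rows, list(make.row.names = FALSE)))
  else empty_gff()
  class(truth) <- c("gff_features", "data.frame")
  ts <- if (length(ts_rows))
    do.call(rbind, c(ts_rows, list(make.row.names = FALSE)))
  else empty_transcripts()
  list(genome = genome, truth = truth, transcripts = ts)
}

# One gene in gene-direction local coordinates. Retries until all isoform
# CDSs are stop-free.
sim_gene <- function(config, idx) {
  for (try in 1:100) {
    n_ex <- sample_range(config$exon_count_range)
    ex_len <- vapply(seq_len(n_ex), function(.) sample_range(config$exon_len_range), 1L)
    want_iso <- n_ex >= 3L && stats::runif(1) < config$isoform_prob
    skip_k <- NA_integer_
    if (want_iso) {
      skip_k <- sample(2:(n_ex - 1L), 1L)
      ex_len[skip_k] <- ex_len[skip_k] + (3L - ex_len[skip_k] %% 3L) %% 3L
    }
    total <- sum(ex_len)
    add <- (3L - total %% 3L) %% 3L
    ex_len[n_ex] <- ex_len[n_ex] + add
    total <- total + add
    n_cod <- total %/% 3L
    if (n_cod < 3L) next
    tab <- sim_codon_table()
    cds <- paste0("ATG",
                  paste(sample(names(tab), n_cod - 2L, replace = TRUE,
                               prob = tab), collapse = ""),
                  "TAA")
    # exonic splice-context overwrites (gene direction)
    cds_ch <- strsplit(cds, "", fixed = TRUE)[[1L]]
    offs <- cumsum(c(0L, ex_len))[seq_len(n_ex)]   # 0-based exon starts in CDS
    for (k in seq_len(n_ex - 1L)) {               # donor side: last 3 exon bases
      e <- offs[k] + ex_len[k]
      cds_ch[(e - 2L):e] <- strsplit(noisy_consensus("CAG", 0.5, c("A", "C", "G")),
                                     "", fixed = TRUE)[[1L]]
    }
    for (k in 2:max(2L, n_ex)) {                  # acceptor side: first exon base
      if (k > n_ex) break
      cds_ch[offs[k] + 1L] <- sample(c("G", "A", "C"), 1L, prob = c(.5, .25, .25))
    }
    cds <- paste(cds_ch, collapse = "")
    # verify both isoforms are clean CDS
    if (!cds_ok(cds)) next
    if (want_iso) {
      keep <- setdiff(seq_len(n_ex), skip_k)
      iso_cds <- paste(vapply(keep, function(k)
        substr(cds, offs[k] + 1L, offs[k] + ex_len[k]), ""), collapse = "")
      if (!cds_ok(iso_cds)) next
    }
    in_len <- vapply(seq_len(n_ex - 1L), function(.)
      sample_range(config$intron_len_range), 1L)
    introns <- vapply(in_len, function(l) sim_intron(l), "")
    utr5 <- noisy_consensus("GCCACC", 0.3)
    # gene-direction sequence: 6 bp start context + exons/introns
    parts <- character(0)
    for (k in seq_len(n_ex)) {
      parts <- c(parts, substr(cds, offs[k] + 1L, offs[k] + ex_len[k]))
      if (k < n_ex) parts <- c(parts, introns[k])
    }
    gseq <- paste0(utr5, paste(parts, collapse = ""))
    strand <- sample(c("+", "-"), 1L)
    return(list(idx = idx, strand = strand, seq = gseq,
                glen = nchar(gseq), n_ex = n_ex, ex_len = ex_len,
                in_len = in_len, utr = 6L, skip_k = skip_k))
  }
  stop("failed to simulate a stop-free gene after 100 attempts")
}

sample_range <- function(r) if (r[1L] == r[2L]) r[1L] else sample(r[1L]:r[2L], 1L)

cds_ok <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) return(FALSE)
  cods <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  sum(cods %in% c("TAA", "TAG", "TGA")) == 1L &&
    cods[length(cods)] %in% c("TAA", "TAG", "TGA")
}

sim_intron <- function(len) {
  head <- paste0("GT", noisy_consensus("AAGT", 0.45))
  tail <- paste0(sample_ppt(15L), noisy_consensus("C", 0.35, c("C", "T")), "AG")
  mid_len <- len - nchar(head) - nchar(tail)
  paste0(head, sample_bases(mid_len, 0.40), tail)
}

# Place a gene at forward position P; returns forward-strand sequence, truth
# GFF rows and transcript rows.
place_gene <- function(g, P, idx) {
  glen <- g$glen
  fseq <- if (g$strand == "-") revcomp(g$seq) else g$seq
  # local gene-direction exon intervals (1-based within g$seq)
  offs <- cumsum(c(0L, g$ex_len))[seq_len(g$n_ex)]
  local_starts <- g$utr + offs + 1L +
    c(0L, cumsum(g$in_len))[seq_len(g$n_ex)]
  local_ends <- local_starts + g$ex_len - 1L
  to_fwd <- function(ls, le) {
    if (g$strand == "+") c(P + ls - 1L, P + le - 1L)
    else c(P + glen - le, P + glen - ls)
  }
  ivs <- t(mapply(to_fwd, local_starts, local_ends))
  gid <- sprintf("g%03d", idx)
  iso_sets <- list(seq_len(g$n_ex))
  if (!is.na(g$skip_k)) iso_sets[[2L]] <- setdiff(seq_len(g$n_ex), g$skip_k)
  rows <- list()
  ts <- list()
  gene_start <- min(ivs[, 1L]); gene_end <- max(ivs[, 2L])
  rows[[1L]] <- gff_features("sim1", "gene", gene_start, gene_end,
                             source = "sim", strand = g$strand,
                             attributes = make_attr(ID = gid))
  for (t in seq_along(iso_sets)) {
    tid <- sprintf("%s.t%d", gid, t)
    sel <- iso_sets[[t]]
    tiv <- ivs[sel, , drop = FALSE]
    o <- order(tiv[, 1L])
    rows[[length(rows) + 1L]] <- gff_features(
      "sim1", "mRNA", min(tiv[, 1L]), max(tiv[, 2L]), source = "sim",
      strand = g$strand, attributes = make_attr(ID = tid, Parent = gid))
    rows[[length(rows) + 1L]] <- gff_features(
      "sim1", "exon", tiv[o, 1L], tiv[o, 2L], source = "sim",
      strand = g$strand, attributes = make_attr(Parent = tid))
    ts[[t]] <- data.frame(transcript_id = tid, gene_id = gid, seqid = "sim1",
                          strand = g$strand, start = tiv[o, 1L],
                          end = tiv[o, 2L], source = "truth",
                          stringsAsFactors = FALSE)
  }
  list(seq = fseq,
       gff = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       ts = do.call(rbind, c(ts, list(make.row.names = FALSE))))
}

#' Simulate EST alignments from a truth annotation
#'
#' ESTs are contiguous windows of mature isoform sequences; alignments are
#' emitted as exact projections of the truth exon blocks (no aligner in the
#' loop). Identity is sampled from the per-base error rate; coverage is the
#' aligned fraction of the EST, 1 except for a `truncated_fraction` of
#' reads with simulated unaligned tails.
#'
#' @param sim output of [simulate_genome()].
#' @param config a [sim_config()].
#' @param with_seqs when TRUE, also return EST sequences (with simulated
#'   substitution errors) suitable for FASTA export.
#' @return list with `alignments` (list of `spliced_alignment`) and
#'   optionally `seqs` (named character).
#' @export
simulate_ests <- function(sim, config = sim_config(), with_seqs = FALSE) {
  set.seed(config$seed + 104729L)
  ts <- sim$transcripts
  genome <- sim$genome
  alignments <- list()
  seqs <- character()
  n_id <- 0L
  for (gid in unique(ts$gene_id)) {
    tids <- unique(ts$transcript_id[ts$gene_id == gid])
    n_est <- sample_range(config$est_per_gene_range)
    for (e in seq_len(n_est)) {
      tid <- if (length(tids) == 1L) tids else sample(tids, 1L)
      tt <- ts[ts$transcript_id == tid, , drop = FALSE]
      tt <- tt[order(tt$start), , drop = FALSE]
      strand <- tt$strand[1L]
      ex_fwd <- tt[, c("start", "end")]
      # gene-direction exon order
      gd <- if (strand == "-") rev(seq_len(nrow(ex_fwd))) else seq_len(nrow(ex_fwd))
      ex_len <- (ex_fwd$end - ex_fwd$start + 1L)[gd]
      Lm <- sum(ex_len)
      unspliced <- stats::runif(1) < config$unspliced_fraction
      if (unspliced) {
        k <- sample(seq_along(ex_len), 1L)
        le <- min(sample_range(config$est_len_range), ex_len[k])
        lo_in_ex <- if (ex_len[k] > le) sample.int(ex_len[k] - le + 1L, 1L) else 1L
        a <- sum(ex_len[seq_len(k - 1L)]) + lo_in_ex
        b <- a + le - 1L
      } else {
        le <- min(sample_range(config$est_len_range), Lm)
        a <- if (Lm > le) sample.int(Lm - le + 1L, 1L) else 1L
        b <- a + le - 1L
      }
      blocks <- mature_to_blocks(ex_fwd[gd, , drop = FALSE], strand, a, b)
      n_id <- n_id + 1L
      est_id <- sprintf("est%05d", n_id)
      le <- b - a + 1L
      identity <- if (config$est_error_rate == 0) 1
      else max(0, 1 - stats::rbinom(1L, le, config$est_error_rate) / le)
      coverage <- if (stats::runif(1) < config$truncated_fraction)
        stats::runif(1, 0.5, 0.9) else 1
      alignments[[est_id]] <- spliced_alignment(
        est_id = est_id, seqid = genome$id, strand = strand,
        blocks = blocks, identity = identity, coverage = coverage)
      if (with_seqs) {
        s <- paste(substring(genome$seq, blocks[, 1L], blocks[, 2L]),
                   collapse = "")
        if (strand == "-") s <- revcomp(s)
        if (config$est_error_rate > 0) {
          ch <- strsplit(s, "", fixed = TRUE)[[1L]]
          err <- which(stats::runif(length(ch)) < config$est_error_rate)
          if (length(err))
            ch[err] <- sample(c("A", "C", "G", "T"), length(err), replace = TRUE)
          s <- paste(ch, collapse = "")
        }
        seqs[est_id] <- s
      }
    }
  }
  out <- list(alignments = alignments)
  if (with_seqs) out$seqs <- seqs
  out
}

# Map a mature-coordinate window [a,b] (gene direction) to forward-strand
# genomic blocks. `ex` holds exon forward intervals in gene order.
mature_to_blocks <- function(ex, strand, a, b) {
  cum <- cumsum(ex$end - ex$start + 1L)
  lo <- c(1L, cum[-length(cum)] + 1L)
  blocks <- list()
  for (k in seq_len(nrow(ex))) {
    s <- max(a, lo[k]); e <- min(b, cum[k])
    if (s > e) next
    off_s <- s - lo[k]; off_e <- e - lo[k]
    if (strand == "+") {
      blocks[[length(blocks) + 1L]] <- c(ex$start[k] + off_s, ex$start[k] + off_e)
    } else {
      blocks[[length(blocks) + 1L]] <- c(ex$end[k] - off_e, ex$end[k] - off_s)
    }
  }
  m <- do.call(rbind, blocks)
  m <- m[order(m[, 1L]), , drop = FALSE]
  colnames(m) <- c("start", "end")
  m
}

#' Train model parameters from a truth annotation
#'
#' Trains the donor/acceptor/start PWMs on the truth splice windows, the
#' coding model on truth CDS against intergenic+intronic background, and
#' returns a complete [model_params()] ready for [predict_genes()].
#'
#' @param sim output of [simulate_genome()] (or a list with `genome` and
#'   `transcripts`).
#' @param order,pseudocount coding-model settings.
#' @param rules gene-model rules stored in the result.
#' @export
train_from_truth <- function(sim, order = 4L, pseudocount = 0.5,
                             rules = gene_model_rules()) {
  genome <- sim$genome
  ts <- sim$transcripts
  intr <- unique_introns(ts)
  if (nrow(intr) < 20L)
    stop("insufficient training examples: need >= 20 truth introns, have ",
         nrow(intr))
  L <- genome$length
  rc <- revcomp(genome$seq)
  wseq <- function(strand) if (strand == "-") rc else genome$seq
  wpos <- function(p, strand) if (strand == "-") mirror_pos(p, L) else p
  window_at <- function(strand, core_fwd_pos, kind) {
    geo <- signal_geometry(kind)
    wp <- wpos(core_fwd_pos, strand)
    s <- wp - geo$offset; e <- s + geo$width - 1L
    if (s < 1L || e > L) return(NA_character_)
    w <- substr(wseq(strand), s, e)
    if (grepl("[^ACGT]", w)) return(NA_character_)
    w
  }
  donors <- acceptors <- character()
  for (k in seq_len(nrow(intr))) {
    st <- intr$strand[k]
    dpos <- if (st == "+") intr$start[k] else intr$end[k]
    apos <- if (st == "+") intr$end[k] - 1L else intr$start[k] + 1L
    donors <- c(donors, window_at(st, dpos, "donor"))
    acceptors <- c(acceptors, window_at(st, apos, "acceptor"))
  }
  starts <- character()
  cds_seqs <- character()
  for (tid in unique(ts$transcript_id)) {
    tt <- ts[ts$transcript_id == tid, , drop = FALSE]
    st <- tt$strand[1L]
    spos <- if (st == "+") min(tt$start) else max(tt$end)
    starts <- c(starts, window_at(st, spos, "start"))
    cds_seqs <- c(cds_seqs, transcript_sequence(tt, genome))
  }
  donors <- donors[!is.na(donors)]
  acceptors <- acceptors[!is.na(acceptors)]
  starts <- starts[!is.na(starts)]
  if (length(donors) < 10L || length(acceptors) < 10L || length(starts) < 5L)
    stop("insufficient training examples for signal models")
  # background: intergenic regions (complement of gene spans) + introns
  spans <- transcript_spans(ts)
  cov <- IRanges::reduce(IRanges::IRanges(spans$start, spans$end))
  gaps <- IRanges::gaps(cov, start = 1L, end = L)
  bg <- substring(genome$seq, IRanges::start(gaps), IRanges::end(gaps))
  bg <- bg[nchar(bg) >= 50L]
  intr_seq <- substring(genome$seq, intr$start, intr$end)
  cds_seqs <- cds_seqs[nchar(cds_seqs) %% 3L == 0L & !grepl("[^ACGT]", cds_seqs)]
  base_freq <- table(factor(strsplit(paste(bg, collapse = ""), "")[[1L]],
                            levels = c("A", "C", "G", "T")))
  background <- as.numeric(base_freq) / sum(base_freq)
  names(background) <- c("A", "C", "G", "T")
  pwms <- list(
    donor = train_pwm(donors, "donor", background, pseudocount = 0.5,
                      offset = signal_geometry("donor")$offset),
    acceptor = train_pwm(acceptors, "acceptor", background, pseudocount = 0.5,
                         offset = signal_geometry("acceptor")$offset),
    start = train_pwm(starts, "start", background, pseudocount = 0.5,
                      offset = signal_geometry("start")$offset))
  coding <- train_coding_model(cds_seqs, c(bg, intr_seq), order = order,
                               pseudocount = pseudocount)
  model_params(pwms = pwms, coding = coding, gene_model = rules)
}

#' Predict gene structures on a genome
#'
#' Runs signal detection, exon enumeration and evidence-anchored chaining
#' on both strands.
#'
#' @param genome a [genome_sequence()].
#' @param params a [model_params()].
#' @param evidence_introns optional data.frame of evidence introns.
#' @param k_per_class optional [top_k_filter()] bound per exon class.
#' @return a `gene_predictions` object.
#' @export
predict_genes <- function(genome, params, evidence_introns = NULL,
                          k_per_class = Inf) {
  cands <- enumerate_all_candidates(genome, params, k_per_class)
  ev <- if (!is.null(evidence_introns) && nrow(evidence_introns))
    validate_evidence(evidence_introns, genome, params$gene_model)$accepted
  else NULL
  assemble(cands, ev, params$gene_model, params$intron_bonus)
}

#' Enumerate scored exon candidates on both strands
#' @inheritParams predict_genes
#' @export
enumerate_all_candidates <- function(genome, params, k_per_class = Inf) {
  cands <- rbind(
    enumerate_exons(find_signals(genome, params, "+"), genome, params, "+"),
    enumerate_exons(find_signals(genome, params, "-"), genome, params, "-"))
  cands <- cands[order(cands$start, cands$end, cands$frame), , drop = FALSE]
  rownames(cands) <- NULL
  class(cands) <- c("exon_candidates", "data.frame")
  top_k_filter(cands, k_per_class)
}
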