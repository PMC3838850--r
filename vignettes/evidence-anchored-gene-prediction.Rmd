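---
title: "Evidence-anchored exon chaining: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence-anchored exon chaining: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genechain)
```

## The problem

A first-pass annotation of a newly sequenced genome needs protein-coding
gene models before curated resources exist. Purely ab initio gene finders
score candidate exons from sequence statistics alone and assemble them by
dynamic programming; they are fast but over-predict (low specificity) and
drop correct exons that happen to score poorly (imperfect sensitivity).
Spliced EST-to-genome alignments, on the other hand, pinpoint splice sites
and introns with high precision wherever expression data exists, but cover
only part of the genome.

`genechain` combines the two: an ab initio exon scorer and chainer in the
GeneID tradition, plus an EST-evidence side that filters spliced
alignments, clusters them by splice-site compatibility and distils a set
of *evidence introns*. During chain assembly these introns act as anchors:
the optimizer maximizes, lexicographically, (1) the number of
evidence-confirmed introns built into the gene models and (2) the summed
exon score. Exons whose splice sites are compatible with an EST-confirmed
intron are therefore always joined when a valid gene model allows it, even
when a higher-scoring incompatible alternative exists.

## Signal and content models

**Splice/translation signals.** Donor (GT), acceptor (AG) and start (ATG)
sites are scored with position weight matrices over fixed windows:

* donor: 3 exonic + GT + 4 intronic bases (width 9, offset 3),
* acceptor: 18 intronic bases + AG + 3 exonic (width 23, offset 18),
* start: 6 upstream + ATG + 3 downstream (width 12, offset 6),
* stop: positional match to TAA/TAG/TGA, no PWM.

Entries are `log2(p_position / p_background)`; a window's score is the sum
over positions. Windows containing N, or running off the sequence, score
"no signal" and are skipped — conservative handling of undefined letters.
Only canonical cores are considered; GC–AG and AT–AC introns are out of
scope.

**Coding potential.** A frame-specific Markov chain of order `k` (default
4, pseudocount 0.5) trained on coding sequence is compared against a
single background chain trained on non-coding sequence; an interval's
score in a reading frame is the summed per-base log2 likelihood ratio.
"Frame" follows the GFF phase convention: the number of bases at the exon
start that complete the upstream codon. Cumulative-sum precomputation
makes interval scores O(1), so enumerating tens of thousands of candidates
is cheap.

## Exon candidates

Four classes are enumerated from the detected signals — First
(start..donor), Internal (acceptor..donor), Terminal (acceptor..stop,
stop codon included) and Single (start..stop) — in every admissible frame.
A candidate containing an in-frame stop strictly inside its reading is
discarded; Terminal and Single exons end at the *first* in-frame stop.
Each candidate scores

```
score = five_site + three_site + coding + exon_weight
```

and is kept when the total reaches `exon_score_threshold` (default 0) and
its length lies within the configured bounds (default 10–10,000 bp).

`exon_weight` (default −20 bits) is the classic gene-finder exon-weight
offset: each exon must justify itself with at least that much signal and
coding evidence before it can enter a chain. Without it, score-maximal
chaining happily assembles chains of weakly positive noise exons across
intergenic sequence. The default was calibrated once against the score
distributions of trained models under the simulator's default conditions
(true exons score roughly 40–110 bits, noise candidates mostly below 20)
and is configurable in the parameter file.

Stops that would span an intron junction are *not* checked at chain time.
This matches classic chainer behaviour and keeps the DP cost linear in the
number of join pairs; it is a documented limitation.

## The chaining objective

Candidates (both strands together) are sorted by end coordinate and
assembled by a best-chain-ending-here recurrence. A join of two
same-strand candidates is feasible when the implied intron length lies in
`[min_intron_len, max_intron_len]`, the class transition is allowed
(First→Internal, First→Terminal, Internal→Internal, Internal→Terminal;
Single stands alone), and the upstream exon's remainder equals the
downstream exon's frame. On the minus strand the gene runs right-to-left,
so the genomic-leftmost exon of a gene is its Terminal and transitions and
frame continuity are checked in gene direction. Consecutive genes must be
separated by at least `min_intergenic` bases, enforced across strands, and
a gene must open with First/Single and close with Terminal/Single (in gene
direction) unless `allow_partial_genes` is set.

The objective is

```
sum(exon scores) + intron_bonus * #{joins whose implied intron exactly
                                    matches an evidence intron}
```

with `intron_bonus = 1e6` by default. At run time the chainer asserts that
the bonus dominates the total absolute candidate score and warns if it
does not; under domination the objective is exactly lexicographic —
evidence-intron count first, score second — which realizes the anchoring
contract without a two-key DP. Evidence matching is exact on both
boundaries and the strand: tolerance for alignment wobble belongs to the
EST module, which has already refined the introns. Ties are broken
deterministically (more evidence, higher raw score, smaller span, leftmost
start). An exhaustive enumeration oracle (`oracle_assemble`, ≤15
candidates) double-checks the DP in the test suite.

Whether the original modified chainer forces evidence joins as a hard
constraint or a dominating soft bonus is not decidable from its
description; the anchoring behaviour ("always joined together if they
conform to a valid gene model") is reproduced by the dominating-bonus
reading, which also degrades gracefully when evidence is inconsistent with
every valid gene model.

## EST evidence

Alignments (a GFF3 `match_part` dialect, so any spliced aligner can feed
the pipeline) are kept when identity ≥ `min_identity` (default 0.95; 0.98
is typical for human-grade data) and coverage — the aligned fraction of
the EST — is strictly greater than `min_coverage` (default 0.90). Spliced
alignments sharing a splice site within `boundary_tolerance` (default
3 nt; the magnitude of tolerable misalignment is a package choice, surfaced
in the configuration) are linked, clusters are connected components, and
unspliced alignments attach to the same-strand cluster with the largest
span overlap.

Within a cluster, member gaps whose boundaries agree within the tolerance
are merged (modal coordinates, ties to the smallest), then shifted as a
unit within ±`shift_window` (default 5 nt) to canonical GT..AG boundaries,
choosing the shift with the best donor+acceptor PWM score when models are
available and the smallest |shift| otherwise. Gaps that cannot be
canonicalized, or with support below `min_intron_support`, are dropped.
This consensus-and-shift procedure replaces a full multiple-alignment
splice refinement engine while keeping the same input/output contract: the
chainer only consumes the refined introns.

Cluster members re-expressed over the refined introns are merged greedily
to a fixpoint (two structures merge iff their overlap implies no intron
conflict), giving a minimal set of non-mergeable transcripts in
deterministic longest-first order. For the isoform procedures, each EST
transcript's CDS is taken as its longest ATG..stop ORF over the three
forward frames (5'-most on ties).

## Alternative isoforms: AS1 and AS2

*AS1* trusts expression data outright: chained predictions with any
same-strand exonic overlap (≥1 bp, the minimal reading of "overlap") to an
EST transcript are removed and the EST transcripts take their place;
regions without EST coverage keep the chained predictions.

*AS2* stays chainer-centric: overlapping EST CDSs at a locus are dealt
into bins (as many bins as the most isoform-rich locus; loci with fewer
transcripts re-use theirs cyclically, longest first, so every bin covers
every locus), and the chainer runs once per bin with that bin's CDS exons
injected as boosted candidates, their introns as evidence, plus all
*unassociated* introns — evidence introns not contained in any binned CDS
span, the minimal reading of "unassociated". Exact-duplicate transcripts
(identical exon coordinate chains) are removed from the union;
near-duplicates are deliberately retained.

## Evaluation

`evaluate_predictions` compares two transcript sets at five levels. Genes
are clusters of transcripts under same-strand exon overlap; in gene mode
each cluster is projected to the genome (union of exon intervals) and
nucleotide counts and exact-boundary exon matches are computed on the
projections, while introns and transcripts are compared on the transcript
structures (transcript TP = exact intron chain and CDS boundary match).
SN = TP/(TP+FN), SP = TP/(TP+FP), SS = (SN+SP)/2; W and M are the
fractions of predicted (respectively annotated) features with zero overlap
to the other side. SP is TP-based at every level: a true-negative count is
undefined for exon- or transcript-valued features, and published accuracy
tables in this tradition are only consistent with the TP-based form even
where a TN formula is printed. Undefined 0/0 ratios are reported as 0 and
flagged degenerate, never NaN. A gene counts as found on any same-strand
exonic overlap; this is deliberately permissive and matches how very high
gene-level sensitivities arise in published comparisons.

BTP (best transcript pair) mode first matches predicted to annotated
transcripts per overlapping cluster pair — greedy maximum shared
coding-base overlap, then split/join attachments when the shared overlap
exceeds half the smaller transcript's coding length (threshold
configurable; the published procedure states the one-to-many case without
a magnitude) — and aggregates the same measures over matched pairs only,
gauging connectivity of what was predicted rather than genome-wide
completeness.

`titration_experiment` feeds seeded random subsets of the evidence introns
to the chainer over a fraction grid and reports mean SS at the gene, exon
and nucleotide levels, reproducing the expected monotone benefit of
evidence.

## The simulator and what it does (not) show

`simulate_genome` places non-overlapping multi-exon genes on both strands:
codon-biased stop-free CDS, canonical GT..AG introns with planted but
noisy consensus contexts (GTAAGT donors, pyrimidine tract + CAG acceptors,
Kozak-like start context), uniform intron lengths, and optional
exon-skipping second isoforms (the skipped exon's length is a multiple of
3, so frame is preserved; transcripts are re-verified stop-free).
`simulate_ests` samples windows of mature isoform sequences and emits
alignments as exact truth projections — no aligner runs in the loop, which
keeps tests hermetic; an EST FASTA can be produced for users who want to
exercise a real aligner externally. Identity derives from the per-base
error rate; coverage is the aligned EST fraction, below 1 only for a
configurable fraction of reads with simulated unaligned tails.

Default conditions: 100 kb, 30 genes, 2–6 exons of 80–250 bp, introns
50–500 bp, 20% isoform probability, 5–15 ESTs of 300–800 bp per gene, 1%
EST error. Consensus noise and codon bias were fixed once so that trained
models give a realistic ab initio operating point (exon-level SS roughly
0.85–0.95 rather than saturated at 1), leaving the evidence contribution
observable. The acceptance experiments run at these scales: the titration
on the 100 kb default (10 replicates per fraction), the closed loop on a
60 kb / 18-gene instance with full-length zero-error ESTs.

What passing tests show: the DP is exactly optimal and evidence-maximal;
the EST contract recovers planted introns perfectly under full coverage
and zero error; accuracy rises monotonically with evidence. What they do
not show: performance under real alignment artefacts (the simulator emits
truth projections), non-canonical splicing, overlapping genes, UTR
structure (the simulated mature transcripts are pure CDS), paralogy, or
sequencing chemistry error profiles.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive forward-strand everywhere; minus
  features carry forward coordinates with `strand = "-"`. No half-open
  interval appears in any interface.
* The parameter file stores all matrices at full precision (`%.17g`);
  round trips are bit-exact, and a reloaded model reproduces predictions
  identically.
* Candidate ties in `top_k_filter` break by smaller start then smaller
  end; chain ties as described above; EST-transcript merge order is
  longest-span-first then leftmost.
* Empty inputs are data, not errors: an empty candidate set assembles to
  an empty prediction set, rejected evidence introns come back with reason
  strings, and empty predictions evaluate to SN = 0 with the degenerate
  flag rather than NaN.
* `oracle_assemble` refuses instances above 15 candidates (combinatorial
  guard); it exists for verification, not production use.

## Known limitations

UTR exons, promoter and polyadenylation signals are not modelled (the
gene-model treatment of such signals in the parent tools is inherited
conceptually but intentionally not guessed at); junction-spanning stop
codons are not checked; no suboptimal chain sampling or posterior
decoding; intron inference is consensus-based, not a re-implementation of
a multiple-alignment splice refiner; FASTA/GFF3 are the only formats in
v1.
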