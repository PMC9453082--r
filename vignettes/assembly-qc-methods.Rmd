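---
title: "Methods: evaluating Nanopore-only fungal assemblies with asmqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating Nanopore-only fungal assemblies with asmqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmqc)
```

## The evaluation problem

A haploid filamentous fungus (30–50 Mb genome) sequenced on a single
Nanopore flow cell yields a few million long reads. Assembling those reads
with an overlap-layout assembler and polishing the consensus gives a draft
whose quality depends almost entirely on two inputs the analyst controls:
which reads go in (length/quality filtering, how much coverage) and how the
result is screened afterwards. `asmqc` implements the screening side as
reusable statistics. This vignette records the models behind each
statistic, the tunable parameters and their defaults, the behaviour of the
simulators used for testing, and the numerical conventions.

## Read-set statistics

**Nx.** For a multiset of lengths, sort descending and accumulate; Nx is
the first length at which the running sum reaches x% of the total. N50
summarizes the read-length distribution; N99 is the contiguity measure for
assemblies (the minimum contig length needed to cover 99% of the genome —
more sensitive to small trailing contigs than N50). The cumulative sum is
carried in double precision so integer inputs near `.Machine$integer.max`
totals do not overflow; the returned value keeps the input type.

**Read quality.** A read's quality is computed in error space:
per-base Phred scores become probabilities $p_i = 10^{-q_i/10}$, and
$Q = -10\log_{10}(\bar p)$. This is the convention of the standard
long-read QC tools, and it is deliberately pessimistic relative to the
arithmetic mean of Phred scores: one Q5 stretch drags down a read full of
Q15 bases. Because summary tables in the literature rarely state whether
"mean read quality" averaged per-read Q values or pooled all bases,
`readset_summary()` reports both (`mean_read_q`, `pooled_base_q`) and
labels the primary convention in `q_definition`.

**Filtering.** `filter_reads()` keeps reads with length ≥ 10 kb and
Q ≥ 7, both inclusive. Q7 corresponds to a mean error probability of
$10^{-0.7} \approx 0.1995$, i.e. roughly 80% accuracy — the common
pre-assembly cutoff for this data type expressed on the percent-identity
scale. Both thresholds are arguments.

**Subsampling.** Coverage subsets are drawn by a seeded permutation of the
reads, filled until the cumulative base count first reaches
`target_cov * genome_size`. The alternative — accepting each read with
probability target/total — only hits the target in expectation;
shuffle-then-fill guarantees it exactly once reached and makes the subset a
deterministic function of (input order, seed). The last selected read is
minimal in the sense that dropping it falls below the target.

## Average mapping completeness

Mapping the (filtered) reads back to the assembly and asking how much of
each read the aligner could place is a completeness measure that covers the
whole genome, not only annotated genes. For each primary mapped alignment
the terminal clipped fraction is

$$f = \frac{\text{leading clip} + \text{trailing clip}}{\text{full read length}},$$

and completeness is $1 - \bar f$ over reads. Three accounting decisions are
worth stating because alignment dialects differ:

* **Only primary alignments contribute** — one observation per read.
  Secondary and supplementary records would double-count the read; they are
  tallied as `n_skipped`.
* **Hard clips count as clipped bases** and are added back to the
  denominator. The full read length is the read as sequenced; whether the
  aligner stored the clipped bases (S) or dropped them (H) is an encoding
  detail, and an aligner that hard-clips would otherwise look spuriously
  complete.
* **Unmapped reads are excluded from the mean** and reported as a separate
  percentage (`unmapped_fraction()`, 100·unmapped/(unmapped + primary)). A
  read the aligner placed nowhere carries different information than a read
  partially placed, and folding it in as $f=1$ would conflate the two.

PAF input is normalized to the same record model: the unaligned query ends
(`qstart`, `qlen − qend`) become terminal soft clips around the `cg:Z:`
CIGAR. A PAF record without a CIGAR tag cannot support clip or depth
statistics, so downstream operations raise an explicit error rather than
silently skipping it; a SAM record with CIGAR `*` is retained but counted
as skipped.

## Telomere detection

Filamentous fungal telomeres are tandem arrays of TTAGGG; an assembled
chromosome should show a burst of exact motif copies at each end.
`asmqc` counts *exact* occurrences (N never matches, overlaps allowed) of
TTAGGG and its reverse complement CCCTAA — the motif set is its own
reverse complement, so calls are strand-invariant — and reports them two
ways:

* `scan_windows()`: sliding windows of 100 b every 25 b, each counting
  occurrences **fully contained** in the window (a partially overhanging
  motif is a partial match and does not count). This is the
  genome-browser track, written as bedGraph (0-based half-open).
* `classify_ends()`: an end is telomeric when ≥ `min_copies` occurrences
  lie entirely within the terminal `end_window` bases.

The calling thresholds are genuinely open — published telomere tables are
produced by eye from the window plots — so the defaults are explicit
stand-ins chosen to separate the two regimes by a wide margin:
`end_window = 1000` b and `min_copies = 5`. A real array covers a 100 b
window with ≥ 16 copies, while the expected number of exact 6-mers from
both motifs in 1 kb of random sequence is $2 \times 995 \times 4^{-6}
\approx 0.49$, and reaching 5 is vanishingly unlikely. Both parameters are
arguments and CLI flags. Mitochondrial and purely ribosomal contigs are
excluded by an explicit id list (they are identified by external
annotation, which is out of scope), and the report totals always satisfy
`total = 2·both_ends + one_end`.

## Coverage triage and the 67% rule

Contig read coverage in a haploid assembly typically separates into a
plateau of large nuclear contigs at a common depth, a few small contigs far
above it (mtDNA, rRNA arrays, collapsed repeats), and low-coverage contigs
that are often assembly artifacts. The triage rule is a single cutoff:
contigs below 67% of the plateau depth are candidate artifacts, contigs
above 2× candidate high-copy sequence. It is a deliberately naive screen —
in genomes with substantial repeat content or real aneuploidy it must be
reviewed — which is why every constant is exposed.

Published analyses locate the plateau by eye; `plateau_mean()` makes that
reproducible with a procedure of this package's own design: take contigs
≥ 50 kb (shorter contigs have noisy mean depths and are often exactly the
artifacts under test), compute the length-weighted **median** depth, keep
the long contigs within [0.5, 1.5]× of it, and return their
length-weighted **mean**. The weighted median makes the initial location
robust to a high-copy outlier; the band then trims anything that is not
plateau before averaging. On the four-contig worked example
(5 Mb at 100×, 4 Mb at 98×, 0.2 Mb at 40×, 0.05 Mb at 400×) this gives
(5·100 + 4·98)/9 ≈ 99.11× and labels `{true, true, artifact, high_copy}`.

Boundary convention: a contig exactly at the artifact cutoff is classified
`true` (strict `<`), reading "below 67%" as the excluded region. Depth
itself counts only reference-consuming aligned bases (M/=/X): deletion and
skip operations advance the reference but have no read support at those
positions. Classification is scale-invariant — multiplying all depths and
the plateau by a constant preserves labels.

Per-contig uniformity is screened with a robust outlier rule: bins whose
depth exceeds median + 3·(1.4826·MAD) are flagged. Median/MAD rather than
mean/SD because the spikes being hunted (terminal rRNA arrays) would
inflate an SD-based threshold; when the MAD degenerates to zero only bins
strictly above the median can flag, so constant tracks flag nothing.

## Indel profiling

Small indels — concentrated in homopolymer runs — are the dominant residual
error of nanopore consensus sequences and are disruptive out of proportion
to their count because they frameshift gene models. The spot check
implemented here aligns a few trusted single-copy gene sequences globally
against their assembled copies and counts indel events by class.

The aligner is standard affine-gap global alignment (delegated to
`Biostrings::pairwiseAlignment`): match +1, mismatch −2, a gap of length
$L$ costs $4 + 2L$. The gap penalties are deliberately strong relative to
the match score so that one multi-base gap beats scattered single-base
gaps, which matches how consensus errors present. All four scores are
arguments. Each maximal gap run is one event, reported in ungapped
reference coordinates with the reference (sequence A) defining
insertion/deletion polarity.

An event is **homopolymeric** when its bases are a single repeated base
*b* and the maximal run of *b* in the reference touching the event
position, combined with the event bases, reaches `min_run = 3`; everything
else is **random**. The run-length threshold has no canonical published
value — manual curation in alignment viewers never states one — so 3 is an
explicit stand-in (the shortest run most practitioners would call a
homopolymer) and is an argument. Homopolymeric + random always equals the
total event count. Swapping the pair order flips insertion/deletion kinds
but preserves the class counts, which the tests assert.

## The simulators, and what passing tests show

Every analysis module has a seeded generator producing fixtures with
planted truth:

* `simulate_reads()`: log-normal lengths (default meanlog `log(15000)`,
  sdlog 0.6, giving an N50 in the low tens of kb) and per-base Phred
  scores drawn around a per-read mean (default Q12 ± 1.5) — the regime of
  a good fungal Nanopore run. Only N50-scale summaries of real runs are
  published, not distribution families; log-normal is a pragmatic,
  long-tailed stand-in.
* `make_assembly_with_telomeres()`: random interior, exact motif arrays at
  the ends as specified.
* `simulate_clipped_alignments()`: per-read total clip fraction from
  Uniform(0, 2·mean), split randomly between the ends; the realized mean
  after rounding clips to whole bases is recorded.
  `simulate_tiling_alignments()` lays abutting reads so depths are exact
  integers with no sampling noise.
* `plant_indels()`: single-base events inside homopolymer runs ≥ 3 and
  2-base mixed-base events in repeat-free context, all ≥ 10 b apart so the
  aligner recovers each event in isolation.

Generators are pure functions of (specification, seed): they save and
restore the caller's RNG state, and identical seeds give byte-identical
fixtures. What the simulators do **not** emulate: position-dependent error
profiles, chimeric reads, adapter remnants, heterozygosity, or genuine
repeat structure. Passing the planted-truth suite therefore demonstrates
that the statistics are computed correctly, not that their defaults are
optimal for any particular real genome — on real data the telomere and
plateau thresholds in particular deserve a look at the window track and
the depth histogram before trusting the calls.

## Problem sizes and numerical conventions

The test and acceptance suites run at desk scale: 1000 random multisets of
up to 10⁴ lengths for the Nx oracle check, 1000 simulated alignments for
clip-fraction recovery (the estimate must fall within two standard errors
of the planted 10%), six-contig assemblies for telomere truth, a 5 kb gene
with 3 + 2 planted indels, and 200 random pairs ≤ 20 b for the
alignment-score oracle (run with `gap_open = 0`, where affine scoring
reduces to the linear-gap dynamic program the oracle implements). The
read-length median check uses 2000 reads, where the sample median of the
log-normal has a relative standard error well under 1%.

Conventions: coordinates are 0-based half-open internally (SAM's 1-based
POS is converted on read); Phred encoding is fixed at ASCII−33 (no +64
auto-detection — all Nanopore FASTQ is Sanger-offset); lowercase bases are
upcased on input and characters outside {A,C,G,T,N} rejected, because
motif matching is exact; FASTQ records are written directly by the package
(the Biostrings FASTQ writer mishandles reads beyond ~20 kb, which real
Nanopore read sets routinely exceed); gzip input is detected from content.
Ties in Nx sorting cannot affect the result (only lengths enter);
alignment traceback ties are resolved deterministically by the underlying
aligner, so repeated runs are identical.
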