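---
title: "Models and methods behind linkamp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind linkamp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linkamp)
```

# The problem

Wild virus communities and other ultra-low-input samples yield picograms to
nanograms of DNA, far below what sequencing library preparation needs.
Linker amplification (LA) closes the gap: DNA is sheared to 400–800 bp,
blunt-end repaired, ligated to a hemi-phosphorylated linker, size-selected,
and PCR-amplified from a single primer. PCR is not composition-neutral —
per-cycle amplification efficiency depends on fragment GC content — so the
amplified library over- and under-represents parts of the template. An
optimized LA protocol keeps this distortion within about 0.5–1.5-fold;
`linkamp` provides the machinery to design such protocols, to simulate
them, and to measure the distortion on sequence data.

# The simulator

The synthetic-data generator is a first-class module: every analysis stage
in the package is exercised against libraries whose ground truth is known
exactly.

**Genomes.** `generate_genome()` concatenates segments with exact GC base
counts (`round(gc * length)` strong bases, placed uniformly; each strong
base G or C with probability 1/2). The default isolate stand-in,
`gc_gradient()`, is 25 segments of 2 kb stepping GC linearly from 0.31 to
0.55 — a 50 kb genome whose windowed GC span matches a phage-isolate-like
range, with a smooth landscape so that window GC and local fragment GC
agree. The community stand-in, `gc_community()`, places segment GC at the
quantiles of a truncated normal (mode 0.43, sd 0.13, span 0.12–0.84): a
peaked bulk with thin tails, the shape of read-GC histograms of dsDNA
virus communities. The peaked shape matters — with a uniform GC spread the
normalizing mean amplification factor is dragged down by the
low-efficiency tails and even mid-GC bins show fold values above 1.5.
Synthetic genomes are labelled as such; no real genome sequence ships with
the package.

**Shearing.** Fragment lengths uniform on [400, 800] bp, starts uniform,
linear coordinates (0-based half-open internally; exported TSVs are
1-based inclusive).

**Amplification.** Deterministic in expectation: a fragment of GC fraction
$g$ with copy number $c$ leaves $C$ cycles with $c\,(1+e(g))^C$ copies.
All stochasticity is confined to read sampling; this makes analytic
recovery targets exact and is sufficient to reproduce the bias
phenomenology — per-cycle branching randomness averages out at library
scale. Three efficiency models are provided:

* **bell** (default): $e(g) = e_{\max}\exp(-(g-g_{opt})^2/2\sigma^2)$,
  peaking at intermediate GC so both GC extremes are under-amplified;
* **flat**: $e(g) = e_{\max}$, the no-bias control;
* **linear**: $e(g) = e_{\max} g$, a monotone toy model.

The defaults $e_{\max}=0.9$, $g_{opt}=0.47$, $\sigma=0.45$ are calibrated
so that a 25-cycle amplification keeps fold representation within
[0.5, 1.5] across GC 0.31–0.55 — the bias regime of an optimized LA
protocol. The width matters: a narrow bell (for example $\sigma = 0.12$)
compounds over 25 cycles to fold ratios in the thousands, which is
whole-genome-amplification territory, not LA. No functional form for
GC-dependent efficiency is established empirically; the bell is a labelled
stand-in whose parameters are configuration, not truth.

**Reconditioning.** Modeled exactly as "+`recond_cycles` (default 3) extra
cycles after a 10-fold dilution"; the dilution rescales yield only and is
recorded in metadata. Whether dilution has any compositional effect beyond
the extra cycles is unknown; we model none. Heteroduplex structure (the
mechanistic motivation for reconditioning) is not modeled. A
polymerase-specific enrichment of rare sequences has been observed for one
enzyme; no mechanism for it is modeled here.

**Read sampling.** Fragments are drawn with probability proportional to
copy number; each read covers its whole fragment on a random strand.
Substitution errors (default $10^{-3}$ per base) and ambiguous bases
(default $10^{-4}$) are injected after the barcode + linker prefix is
attached, so demultiplexing sees realistic prefixes; Phred qualities are
Gaussian (mean 35, sd 3, clipped to [2, 40]). With probability `dup_rate`
(default 0.05) a read is re-emitted verbatim and flagged, emulating
emulsion-PCR replicates. A complete truth table (placement, strand,
treatment, duplicate flag) accompanies every read set. Features of real
454 data the simulator does **not** emulate: homopolymer-length errors,
flowgram-specific quality decay, partial-fragment reads, chimeras. Passing
tests therefore demonstrate correctness of the analysis machinery under a
known generative model, not robustness to every 454 artefact.

# Protocol design calculators

**Barcodes.** 5 bp, uppercase ACGT, four rules: no consecutive duplicate
nucleotides; pairwise Hamming distance at least 2; no 3' C (the linker
starts with a 5' C); no 5' G (the emulsion-PCR primers end in 3' G).
`design_barcodes()` enumerates all valid 5-mers, shuffles them with a
seed, and accepts greedily under the Hamming constraint — simple,
reproducible, and ample at this scale (hundreds of candidates for tens of
barcodes). The bundled reference design's 17 unique barcodes all validate,
with minimum pairwise distance exactly 2.

**Cycle recommendation.** The titration convention maps input mass to a
cycle range: 1–10 ng → 15–20, 0.1–1 ng → 18–25, 10–100 pg → 22–30,
< 10 pg → 25–35 cycles. The printed ranges overlap at interval boundaries;
`recommend_cycles()` resolves boundaries downward (a boundary mass gets
the fewer-cycle range), since titration aims for the lowest cycle number
that yields high-molecular-weight product. Three candidate cycle numbers
are proposed per range — minimum, rounded midpoint, maximum — matching the
practice of testing three cycle numbers. Masses above 10 ng return the
lowest range with a warning flag.

**Linker.** `validate_linker()` checks the annealing geometry of the
hemi-phosphorylated linker: the unphosphorylated reverse strand must be
the reverse complement of a terminal segment of the phosphorylated
forward strand. For the default pair the match is 22 nt at the forward
strand's 5' end, leaving a 4 nt single-stranded 3' overhang — the
asymmetry that promotes unidirectional ligation.

**Demultiplexing.** A read is assigned when its 5' prefix matches exactly
one barcode (optionally barcode + linker) within `max_mismatch`; ties go
to the unassigned bin with an ambiguity flag, and counts are conserved.
The default is `max_mismatch = 0`: no mismatch tolerance is established
for this protocol, so the package does not guess one; callers can relax
it explicitly.

# Read quality control

Whole-read filters in a fixed attribution order: (i) any ambiguous base;
(ii) length beyond ±2 SD of the batch mean; (iii) per-read mean Phred
quality beyond ±2 SD of the batch mean; (iv) duplicate (non-kept member of
a duplicate group). "Batch" is the input file/treatment; means and SDs are
computed once on the full input, before any removal. Because the criteria
are applied as alternatives, the order only affects which criterion a
multiply-failing read is attributed to; the fixed order makes the report
counts well-defined and disjoint.

The duplicate rule — identical first 20 bases and lengths within 2%, keep
the longest member (ties to the lexicographically smallest id) — is a
deterministic desk-scale approximation of the emPCR-replicate definition
used by cd-hit-454; both thresholds are configurable. QC is not exactly
idempotent (re-running recomputes the ±2 SD bands on the filtered
population); on simulator output a second pass removes under 5% of
survivors.

# Depth and GC-bias analysis

Per-base depth comes from read placements (simulator truth, or external
alignments converted to 0-based half-open intervals — the package contains
no aligner). Depth is scaled by `raw / total_nt × scale_factor`, where
`scale_factor` defaults to the mean total nucleotide count across the
treatments being compared, putting differently sized libraries on one
scale. Windowed statistics use 500 bp windows; the window step defaults to
50 bp and is pinned explicitly in the analyses (tiling, step = 500, where
independence between windows matters). Windows below 7× mean depth are
masked: at low coverage, effort scaling inflates relative depth and
corrupts cross-treatment comparisons.

The genome GC-bias curve bins unmasked windows by GC (2% bins by default)
and reports amplified ÷ unamplified mean window depth per bin; the
community curve bins per-read GC (1% bins, ambiguous bases excluded from
both numerator and denominator) and normalizes a treatment's relative
frequencies to the equal-weight average of the unamplified treatments'
frequencies (averaged per treatment, not pooled — so an unamplified
library with more reads does not dominate the reference). Bins with an
empty reference are reported as undefined, never interpolated. Both curves
carry delta-method standard errors of the ratio estimates.

# Statistics over the treatment design

**Bias areas.** The magnitude of bias between two curves is the trapezoid
integral of `|difference|` over the shared defined grid. The deviation of
an amplified treatment from the unamplified control is the *signed
difference* of scaled window depths (not a ratio): differences are what
an area between curves integrates naturally, and they remain defined at
zero reference depth.

**Paired tests.** Two-tailed paired Student's t-tests (delegating to
`stats::t.test`) with explicit degenerate handling: zero-variance
differences report p = 1 when all differences are zero and the limit 0
otherwise, with a flag.

**Comparison plans.** `enumerate_pairs()` reconstructs the four pairwise
schemes over the design metadata. Treatments under 100 post-QC reads are
excluded as failed libraries; in the bundled reference design this removes
one replicate pair (3 and 4 reads) and reproduces the replicate-wise
reconditioned-vs-not scheme at n = 14 pairs, and drops the affected
cycle-number group so the cycle-group scheme has C(4,2) = 6 pairs. These
exclusion rules are documented reconstructions — the source design reports
the pair counts but not the exclusion rationale — and the threshold is
configurable. For the split-by-reconditioning scheme the package emits all
like-status group pairs (6 per status); the design's reported n = 3 for
that scheme cannot be derived from the stated definitions, so the
operational definition is kept.

**Calibration caveat.** Effort scaling couples windows: when the analysis
windows tile the whole genome, the scaled window-depth differences between
two treatments sum to exactly zero by construction, and even when windows
only *capture most of the read mass*, dividing by the per-treatment total
acts approximately as mean-centering of the window residuals — either way
the window-paired t-statistic's numerator is shrunk and the test is
severely conservative. The paired t is therefore calibrated only when the
window set samples the genome sparsely: windows spaced farther apart than
a read length (no shared reads) and covering a small fraction of the
genome (so the scaling total is dominated by non-window regions), with
sequencing yield treated as Poisson rather than fixed (removing the
multinomial competition among windows). Under that design the simulated
null rejects at the nominal 5% rate; under dense tiling the test errs
toward *not* rejecting, which is the conservative direction for claiming
treatment differences but should be kept in mind when interpreting null
results.

# Diversity analyses

**Clustering.** Greedy incremental clustering in decreasing length order
(ties broken by id): a sequence joins the first representative whose
identity meets the threshold, else founds a cluster. Identity is global
(Needleman–Wunsch) alignment matches divided by the shorter sequence's
length — the cd-hit convention, stated here because the convention is
implicit in the tools it stands in for. Banded alignment is unnecessary at
desk scale; alignments are vectorized against all word-sharing
representatives in one call. For nucleotide clustering with
`both_strands`, the reverse complement is also tried (defaults mirror
standard settings: 90% identity, word size 8 for nucleotide singletons;
60% identity, word size 4 for proteins). The k-mer prefilter only skips
alignments for representative pairs sharing no word; it is a heuristic
shortcut and the test suite pins its agreement with an exhaustive
all-pairs oracle.

**Protein path.** Assembly and gene prediction are out of scope; for
protein-cluster analyses the package accepts protein sequences directly
and offers `translate_longest_orf()` — longest stop-free codon stretch
over six frames — as a per-read stand-in. This diverges deliberately from
a read → contig → predicted-gene path and is labelled as such. Reads are
not mapped back to cluster representatives; membership comes from the
clustering itself.

**Rarefaction.** Reads are subsampled without replacement at increasing
effort (default 5000-read steps, 100 replicates); at each effort the
distinct clusters with more than 20 members (eligibility fixed on the full
data; "more than 20" is read strictly, the bound is configurable) are
counted. The spread shown is the replicate SD. The analytic companion
`rarefaction_expected()` gives the hypergeometric closed form
$\sum_c [1 - \binom{N-n_c}{m}/\binom{N}{m}]$, computed on log scale; the
suite checks the sampler against it within 3 SE, which doubles as the
proof that sampling is truly without replacement.

**Singletons.** The singleton fraction is the share of reads in
single-member clusters at 90% nucleotide identity considering both
strands — a proxy for the rare fraction of a community.

# Problem sizes and numerical choices

The shipped analyses and tests run at desk scale, chosen as the smallest
sizes at which the statistical claims are resolvable: 50 kb genomes,
2×10⁴-fragment pools, 10⁵ reads for bias-recovery checks (≈1200× coverage,
so bin-level sampling error is small relative to the bias signal), 20-seed
batteries for distributional properties, 1000 replicates for test
calibration, and a few hundred sequences for clustering oracles. Window
and bin estimates carry delta-method SEs; agreement criteria use 3-SE
bands, with the rule-of-three bound (3/n replicates) where an observed
spread is zero. Ties are broken deterministically everywhere
(lexicographic ids, first-passing representative), and all generators
derive per-stage seeds from a single integer seed by fixed offsets.

# Known limitations

* The GC-efficiency bell is a stand-in; real polymerase-and-template
  efficiency surfaces are not identified by this package.
* A single bell cannot simultaneously reproduce appreciable bias across a
  31–55% isolate GC range and tails at 12%/84% GC that stay above
  0.5-fold: with the default width, the simulated community tails are
  suppressed more deeply than an optimized real protocol's. The bounded
  0.5–1.5 regime holds for the community's GC bulk and the isolate range.
* Amplification is expectation-scale: stochastic jackpot effects of early
  cycles are not modeled (deliberately — LA's observed biases are
  systematic, not stochastic).
* The duplicate rule and greedy clustering are desk-scale stand-ins for
  cd-hit-family tools; they agree with exhaustive oracles at test scale
  but are not optimized for millions of reads.
* No read mapping, assembly, gene prediction, or GC-correction of
  downstream abundances: the package quantifies bias, it does not remove
  it.
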