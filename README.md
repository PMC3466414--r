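# linkamp

Quantitative assessment of linker-amplification (LA) bias for low-input
metagenomics.

Wild virus communities and other ultra-low-input samples typically yield
1 pg–1 ng of DNA — orders of magnitude below what sequencing library
preparation requires. Linker amplification closes the gap: shear to
400–800 bp, ligate a hemi-phosphorylated linker, size-select, and
PCR-amplify from a single primer for 15–35 cycles, optionally finishing
with a 3-cycle "reconditioning" PCR in fresh reagents. The catch is that
per-cycle PCR efficiency depends on fragment G+C content, so after `C`
cycles a fragment of GC fraction `g` is represented in proportion to
`(1 + e(g))^C` — the library systematically over- and under-represents
parts of the genome or community. An optimized LA protocol keeps this
distortion within roughly 0.5–1.5-fold; this package is the toolkit for
designing such protocols and measuring that distortion.

For microbial/viral ecologists and sequencing-methods developers, it
provides:

* **protocol design** — 5 bp barcode validation and design (no consecutive
  duplicate bases, pairwise Hamming distance ≥ 2, no 3' C, no 5' G),
  input-mass → PCR-cycle recommendation, linker geometry validation,
  barcode demultiplexing;
* **a generative simulator** — shearing, GC-dependent amplification
  (`copies × (1 + e(g))^C`, with a calibrated bell-shaped `e(g)` by
  default), reconditioning, and read sampling with sequencing errors,
  ambiguous bases and emulsion-PCR duplicates, all truth-tagged;
* **read QC** — the four whole-read filters (ambiguous bases, ±2 SD
  length, ±2 SD mean quality, duplicate removal) with disjoint accounting;
* **bias quantification** — per-base depth, sequencing-effort scaling,
  500 bp sliding windows, low-coverage masking, genome and community
  "GC-bias curves" (fold representation per GC bin relative to
  unamplified controls) with standard errors, plus the analytic expected
  curve for simulator validation;
* **statistics** — trapezoid bias areas, paired two-tailed t-tests with
  degenerate handling, and enumeration of the four pairwise comparison
  schemes over a treatment design (a reference 41-treatment design ships
  with the package);
* **diversity** — cd-hit-style greedy identity clustering, rarefaction
  with its hypergeometric closed form, and singleton fractions.

## Worked example

Simulate a 25-cycle amplification of an isolate-like genome and recover
its GC-bias curve against an unamplified control:

```r
library(linkamp)

# an isolate-like 50 kb genome, GC 31-55%
genome <- generate_genome(gc_gradient(), seed = 1)

# shear, amplify 25 cycles under the default GC-efficiency bell
pool <- shear(genome, n_fragments = 5000, seed = 1)
amp  <- amplify(pool, amplification_model("bell"),
                protocol_config(cycles = 25))

# sample reads from the amplified and the unamplified pool
amp_rd <- sample_reads(amp, genome, 2e4, treatment = "cyc25", seed = 2,
                       emit_sequences = FALSE)
un_rd  <- sample_reads(pool, genome, 2e4, treatment = "unamp", seed = 3,
                       emit_sequences = FALSE)

# depth -> effort scaling -> 500 bp windows -> GC-bias curve
d_amp <- compute_depth(amp_rd$truth, genome$length)
d_un  <- compute_depth(un_rd$truth,  genome$length)
sf <- mean(c(sum(d_amp), sum(d_un)))
t_amp <- window_stats(scale_depth(d_amp, sum(d_amp), sf), genome, 500, 500)
t_un  <- window_stats(scale_depth(d_un,  sum(d_un),  sf), genome, 500, 500)
curve <- genome_gc_bias(mask_low_coverage(t_amp), mask_low_coverage(t_un),
                        bins = seq(0.31, 0.55, by = 0.04))
subset(curve, !undefined)[, c("bin_low", "bin_high", "fold", "se_fold")]
#>   bin_low bin_high  fold se_fold
#> 1    0.31     0.35 0.669  0.0524
#> 2    0.35     0.39 0.892  0.0474
#> 3    0.39     0.43 1.068  0.0397
#> 4    0.43     0.47 1.164  0.0549
#> 5    0.47     0.51 1.184  0.0593
#> 6    0.51     0.55 1.105  0.0659
```

Low-GC regions are under-represented (0.67-fold at 31–35% GC), the
optimum slightly over-represented (1.18-fold near 47% GC), and everything
stays inside the 0.5–1.5 band that characterizes an optimized LA
protocol. Protocol design is one call:

```r
recommend_cycles(0.005)   # 5 pg of input DNA
#> 25-35 cycles, candidates 25, 30, 35
```

## The analysis workflow

The numbered scripts under `analysis/` re-enact the full assessment on
simulated data, writing tables under `results/analysis/`:
`01_simulate.R` (treatment grid + truth tables), `02_qc.R` (demultiplex +
QC), `03_depth_bias.R` (depth and genome GC-bias curves; amplified
treatments land at 0.52–1.39-fold), `04_community_gcbias.R` (community
curves: the 31–55% GC core stays at 0.71–1.51-fold while the thin GC
tails are under-represented), `05_bias_stats.R` (paired tests and
trapezoid areas over the four comparison schemes, 14 replicate-wise
pairs), `06_diversity.R` (protein-cluster rarefaction and singleton
fractions).

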