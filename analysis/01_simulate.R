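#!/usr/bin/env Rscript
# Step 1 — simulate the full treatment grid.
#
# Builds two synthetic references — an isolate-like 50 kb genome whose
# windowed GC spans ~31-55%, and a community-like genome spanning ~15-80% —
# then runs every amplified treatment of the bundled reference design
# (15-30 cycles, with/without 3-cycle reconditioning, triplicates) plus the
# unamplified controls through the simulator: shearing to 400-800 bp,
# GC-dependent bell-model amplification, and read sampling with emPCR
# duplicates. Read counts are a tenth of the design's post-QC counts with
# a floor of 1250 reads (~15x coverage, the coverage the protocol itself
# recommends to avoid scaling artifacts); the design's two failed
# libraries (3 and 4 reads) are simulated at their real size so the
# downstream exclusion rules bite. Truth tables are written per
# treatment; two treatments are also written as FASTQ to exercise IO.

library(linkamp)

seed <- 20260920L
out <- "results/analysis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

md <- la_treatments()
iso <- md[md$sample_set == "isolate", ]
model <- amplification_model("bell")
lnk <- default_linker()

genome <- generate_genome(gc_gradient(), id = "isolate50k", seed = seed)
write_genome_fasta(genome, file.path(out, "isolate_genome.fasta"))
cat(sprintf("isolate genome: %d bp, overall GC %.3f\n", genome$length,
            genome$gc_cum[genome$length + 1] / genome$length))

pool <- shear(genome, 20000, seed = seed + 1L)
cat(sprintf("sheared pool: %d fragments, mean length %.0f bp\n",
            nrow(pool), mean(pool$end - pool$start)))

config <- c(
  sprintf("seed\t%d", seed),
  sprintf("model\tbell e_max=%.2f g_opt=%.2f sigma=%.2f",
          model$e_max, model$g_opt, model$sigma),
  "shear\t400-800 bp",
  "read_scale\t0.1x of design post-QC counts")
writeLines(config, file.path(out, "simulation_config.tsv"))

sim_reads <- integer(nrow(iso))
for (i in seq_len(nrow(iso))) {
  row <- iso[i, ]
  prot <- protocol_config(
    cycles = row$cycles, input_mass = row$input_ng,
    reconditioned = row$reconditioned,
    barcode = if (is.na(row$barcode)) NULL else row$barcode,
    linker = if (is.na(row$barcode)) NULL else lnk)
  amp <- amplify(pool, model, prot)
  n_reads <- if (row$reads < 100) row$reads else max(1250L, round(row$reads / 10))
  rd <- sample_reads(amp, genome, n_reads, treatment = row$treatment,
                     seed = seed + 100L + i, emit_sequences = FALSE)
  sim_reads[i] <- nrow(rd$truth)
  write_truth(rd$truth, file.path(out, paste0("truth_", row$treatment, ".tsv")))
}
sim_md <- iso
sim_md$design_reads <- sim_md$reads
sim_md$reads <- sim_reads
write.table(sim_md, file.path(out, "sim_metadata.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("simulated %d isolate treatments (truth tables under %s)\n",
            nrow(iso), out))

# two barcoded treatments with full sequences, for the demux/QC step
for (tr in c("cyc15A", "cyc25A")) {
  row <- iso[iso$treatment == tr, ]
  prot <- protocol_config(cycles = row$cycles, input_mass = row$input_ng,
                          barcode = row$barcode, linker = lnk)
  amp <- amplify(pool, model, prot)
  rd <- sample_reads(amp, genome, 800, treatment = tr,
                     seed = seed + 300L + row$cycles)
  write_fastq(rd$reads, file.path(out, paste0("reads_", tr, ".fastq")))
  write_truth(rd$truth, file.path(out, paste0("truth_full_", tr, ".tsv")))
}
cat("wrote barcoded FASTQ for cyc15A and cyc25A\n")

# community-like genome for the read-level GC analysis: peaked GC bulk
# with thin tails spanning ~12-84%, as in virome read-GC histograms
community <- generate_genome(gc_community(), id = "community50k",
                             seed = seed + 5L)
write_genome_fasta(community, file.path(out, "community_genome.fasta"))
cat(sprintf("community genome: %d bp, windowed GC %.2f-%.2f\n",
            community$length,
            min(window_stats(rep(1, community$length), community, 500, 250)$gc),
            max(window_stats(rep(1, community$length), community, 500, 250)$gc)))
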