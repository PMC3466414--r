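#!/usr/bin/env Rscript
# Step 3 — isolate-genome read depth and GC-bias curves.
#
# For every simulated isolate treatment: per-base depth from the truth
# placements, scaling by sequencing effort to the cross-treatment mean
# nucleotide count, 500 bp sliding-window depth/GC, masking of <7x
# windows, and the genome GC-bias curve against the unamplified control.
# Writes the window tracks and per-treatment bias curves, and reports the
# fold-bias range observed across all treatments.

library(linkamp)

out <- "results/analysis"
iso <- read.delim(file.path(out, "sim_metadata.tsv"))
genome <- read_genome_fasta(file.path(out, "isolate_genome.fasta"))

truth <- lapply(iso$treatment, function(tr) {
  read_truth(file.path(out, paste0("truth_", tr, ".tsv")))
})
names(truth) <- iso$treatment
total_nt <- vapply(truth, function(tt) sum(tt$end - tt$start), numeric(1))
scale_factor <- mean(total_nt)
cat(sprintf("scale factor (mean nt across %d treatments): %.0f\n",
            length(truth), scale_factor))

tracks <- lapply(iso$treatment, function(tr) {
  d <- compute_depth(truth[[tr]], genome$length)
  trk <- window_stats(scale_depth(d, total_nt[[tr]], scale_factor),
                      genome, 500, 250)
  mask_low_coverage(trk, 7)
})
names(tracks) <- iso$treatment

unamp <- tracks[["unamp"]]
bins <- seq(0.29, 0.57, by = 0.02)
curves <- list()
fold_range <- c(Inf, -Inf)
# failed libraries (a handful of reads) are excluded outright: effort
# scaling inflates their sparse coverage past any fixed mask threshold
failed <- iso$treatment[iso$reads < 100]
if (length(failed) > 0) {
  cat("excluded failed libraries:", paste(failed, collapse = ", "), "\n")
}
for (tr in setdiff(iso$treatment, c("unamp", failed))) {
  cv <- genome_gc_bias(tracks[[tr]], unamp, bins)
  cv$treatment <- tr
  curves[[tr]] <- cv
  ok <- !cv$undefined & cv$n_windows >= 3
  if (any(ok)) {
    fold_range <- c(min(fold_range[1], min(cv$fold[ok])),
                    max(fold_range[2], max(cv$fold[ok])))
  }
}
all_curves <- do.call(rbind, curves)
write.table(all_curves, file.path(out, "isolate_gc_bias_curves.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

win_out <- do.call(rbind, lapply(names(tracks), function(tr) {
  cbind(treatment = tr, tracks[[tr]])
}))
write.table(win_out, file.path(out, "isolate_window_tracks.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("fold representation across amplified treatments: %.2f-%.2f\n",
            fold_range[1], fold_range[2]))
cat("the default bell model keeps well-covered treatments within roughly",
    "0.5-1.5; failed libraries are excluded outright, since effort",
    "scaling would inflate their sparse coverage past any mask threshold\n")
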