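#' Per-read GC fraction
#'
#' `(G + C) / (A + C + G + T)` per sequence; ambiguous bases are excluded
#' from numerator and denominator. Reads consisting only of ambiguous bases
#' get `NA` with a warning and should be skipped downstream.
#'
#' @param sequence Character vector of read sequences.
#' @return Numeric vector of GC fractions in `[0, 1]` (or `NA`).
#' @export
read_gc <- function(sequence) {
  stopifnot(is.character(sequence), all(nzchar(sequence)))
  x <- Biostrings::DNAStringSet(sequence)
  f <- Biostrings::letterFrequency(x, letters = c("A", "C", "G", "T"))
  denom <- rowSums(f)
  gc <- (f[, "G"] + f[, "C"]) / denom
  if (any(denom == 0)) {
    warning(sum(denom == 0), " read(s) with no unambiguous bases; GC is NA")
  }
  unname(gc)
}

#' Per-bin relative frequency of read GC values
#'
#' @param gc Numeric vector of per-read GC fractions (NAs dropped).
#' @param bins GC bin edges.
#' @return Numeric vector of per-bin fractions summing to 1.
#' @export
gc_rel_freq <- function(gc, bins) {
  gc <- gc[!is.na(gc)]
  stopifnot(length(gc) > 0L, length(bins) >= 2L)
  idx <- findInterval(gc, bins, rightmost.closed = TRUE)
  counts <- tabulate(idx[idx >= 1L & idx <= length(bins) - 1L],
                     nbins = length(bins) - 1L)
  counts / sum(counts)
}

#' Community GC-bias curve (read-level fold representation)
#'
#' Bins each treatment's reads by GC and normalizes the treatment's per-bin
#' relative frequency to the reference's, where the reference per-bin
#' frequency is the equal-weight mean of the unamplified treatments'
#' relative frequencies (treatments averaged, not reads pooled). Bins empty
#' in the reference are flagged undefined and never interpolated.
#'
#' @param treatment_gc Numeric vector: per-read GC of the treatment.
#' @param reference_gc List of numeric vectors: per-read GC of each
#'   unamplified reference treatment.
#' @param bins GC bin edges; default 1%-wide bins anchored at 0 spanning
#'   `[0, 1]`.
#' @return Data frame of class `gc_bias_curve`: `bin_low`, `bin_high`,
#'   `rel_freq`, `ref_freq`, `fold`, `se_fold` (binomial delta-method SE),
#'   `undefined`. Rows where both treatment and reference are empty are
#'   dropped.
#' @export
fold_curve <- function(treatment_gc, reference_gc, bins = seq(0, 1, by = 0.01)) {
  stopifnot(is.list(reference_gc), length(reference_gc) >= 1L)
  p_t <- gc_rel_freq(treatment_gc, bins)
  p_refs <- vapply(reference_gc, gc_rel_freq, numeric(length(bins) - 1L),
                   bins = bins)
  if (is.null(dim(p_refs))) p_refs <- matrix(p_refs, ncol = length(reference_gc))
  p_r <- rowMeans(p_refs)
  if (all(p_r == 0)) stop("all reference GC bins empty")
  n_t <- sum(!is.na(treatment_gc))
  n_r <- sum(vapply(reference_gc, function(g) sum(!is.na(g)), numeric(1)))
  fold <- ifelse(p_r > 0, p_t / p_r, NA_real_)
  # multinomial delta-method SE on the ratio of bin frequencies
  se <- ifelse(p_r > 0 & p_t > 0,
               fold * sqrt((1 - p_t) / (n_t * p_t) + (1 - p_r) / (n_r * p_r)),
               NA_real_)
  out <- data.frame(bin_low = bins[-length(bins)], bin_high = bins[-1],
                    rel_freq = p_t, ref_freq = p_r, fold = fold,
                    se_fold = se, undefined = is.na(fold))
  out <- out[out$rel_freq > 0 | out$ref_freq > 0, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gc_bias_curve", "data.frame")
  out
}
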