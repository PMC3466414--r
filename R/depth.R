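#' Per-base read depth from placements
#'
#' Counts, for every genome position, the number of read placements
#' covering it. Placements are intervals in 0-based half-open coordinates
#' (the simulator truth convention); alignments imported from SAM/TSV
#' should be converted accordingly. Coverage is computed with
#' [IRanges::coverage()]. The genome is linear: placements must lie within
#' `[0, genome_length)`.
#'
#' @param placements Data frame with columns `start`, `end` (0-based
#'   half-open) and optionally `read_id` (used in error messages).
#' @param genome_length Genome length in bp.
#' @return Integer vector of length `genome_length`; its sum equals the
#'   total number of aligned nucleotides.
#' @export
compute_depth <- function(placements, genome_length) {
  stopifnot(is.data.frame(placements),
            all(c("start", "end") %in% names(placements)))
  bad <- which(placements$start < 0 | placements$end > genome_length |
                 placements$start >= placements$end)
  if (length(bad) > 0L) {
    id <- if ("read_id" %in% names(placements)) placements$read_id[bad[1]]
          else paste("row", bad[1])
    stop("placement out of range [0, ", genome_length, "): ", id)
  }
  ir <- IRanges::IRanges(start = placements$start + 1L,
                         end = placements$end)
  as.integer(IRanges::coverage(ir, width = genome_length))
}

#' Import read placements from SAM/BAM
#'
#' Reads alignments produced elsewhere (the package contains no aligner)
#' and converts them to the placement data frame [compute_depth()]
#' expects: 0-based half-open reference intervals spanning the
#' reference-consumed length of each alignment. Unmapped records are
#' dropped. Plain-text SAM is converted on the fly. Requires the
#' `Rsamtools` package.
#'
#' @param path SAM or BAM file path.
#' @return Data frame with columns `read_id`, `genome_id`, `start`, `end`,
#'   `strand`.
#' @export
read_placements_sam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("read_placements_sam requires the Rsamtools package")
  }
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "cigar", "flag"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  mapped <- !is.na(b$pos) & bitwAnd(b$flag, 4L) == 0L
  width <- cigar_ref_width(b$cigar[mapped])
  data.frame(read_id = b$qname[mapped],
             genome_id = as.character(b$rname[mapped]),
             start = b$pos[mapped] - 1L,
             end = b$pos[mapped] - 1L + width,
             strand = ifelse(bitwAnd(b$flag[mapped], 16L) > 0L, "-", "+"))
}

# reference-consumed width of CIGAR strings (M, D, N, =, X operations)
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    len <- as.integer(sub("[MIDNSHP=X]", "", ops))
    op <- sub("[0-9]+", "", ops)
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Scale raw depth by sequencing effort
#'
#' Divides per-base depth by the treatment's total aligned nucleotides and
#' multiplies by a common scale factor (conventionally the mean total
#' nucleotide count across the treatments being compared), putting all
#' treatments on a relatable read-depth scale.
#'
#' @param raw Numeric vector of per-base depth.
#' @param total_nt Total aligned nucleotides of this treatment (> 0);
#'   defaults to `sum(raw)`.
#' @param scale_factor Common scale factor (default `total_nt`, i.e. no
#'   rescaling).
#' @return Numeric vector, `raw / total_nt * scale_factor`.
#' @export
scale_depth <- function(raw, total_nt = sum(raw), scale_factor = total_nt) {
  if (total_nt <= 0) stop("total_nt must be positive")
  raw / total_nt * scale_factor
}

#' Sliding-window depth and GC track
#'
#' Tiles the genome with windows of `window_size` starting every `step`
#' bases (last window start at `L - window_size`, 0-based), and computes
#' per-window mean scaled depth and GC fraction of the genomic window
#' sequence. Windows are unmasked initially; see [mask_low_coverage()].
#'
#' @param scaled Numeric per-base (scaled) depth, length = genome length.
#' @param genome A `genome_model` (or any object with `length` and `gc_cum`
#'   fields as produced by [generate_genome()]).
#' @param window_size Window width in bp (default 500).
#' @param step Window start spacing in bp (default 50).
#' @return A `window_track` data frame: `start` (0-based), `center`,
#'   `mean_depth`, `gc`, `mask`; attributes `window_size` and `step`.
#' @export
window_stats <- function(scaled, genome, window_size = 500L, step = 50L) {
  L <- genome$length
  stopifnot(length(scaled) == L, window_size <= L, step >= 1L)
  starts <- seq.int(0L, L - window_size, by = step)
  cum_d <- c(0, cumsum(scaled))
  mean_depth <- (cum_d[starts + window_size + 1L] - cum_d[starts + 1L]) /
    window_size
  gc <- interval_gc(genome, starts, starts + window_size)
  structure(data.frame(start = starts,
                       center = starts + window_size / 2,
                       mean_depth = mean_depth, gc = gc, mask = FALSE),
            window_size = window_size, step = step,
            class = c("window_track", "data.frame"))
}

#' Mask low-coverage windows
#'
#' Marks windows with mean depth strictly below `threshold` as masked;
#' masked windows are excluded from downstream bias statistics. Low-coverage
#' regions otherwise inflate scaled depths of shallowly sequenced
#' treatments and confound cross-treatment tests.
#'
#' @param track A `window_track`.
#' @param threshold Depth threshold (default 7; strictly `<` is masked).
#' @return The track with its `mask` column updated.
#' @export
mask_low_coverage <- function(track, threshold = 7) {
  stopifnot(inherits(track, "window_track"))
  track$mask <- track$mean_depth < threshold
  track
}

#' Genome GC-bias curve from window tracks
#'
#' Bins unmasked windows by GC fraction and reports, per bin, the ratio of
#' the amplified treatment's mean window depth to the unamplified
#' reference's — the fold representation as a function of GC. Windows
#' masked in either track are excluded. Bins with no unamplified windows
#' are flagged undefined. Both tracks must come from the same genome and
#' windowing.
#'
#' @param amp,unamp `window_track`s of the amplified treatment and the
#'   unamplified reference.
#' @param bins Numeric GC bin edges (fractions); default 2%-wide bins over
#'   the observed window-GC range.
#' @return Data frame: `bin_low`, `bin_high`, `fold`, `n_windows`,
#'   `mean_amp`, `mean_unamp`, `se_fold` (delta-method standard error of
#'   the ratio of means), `undefined`.
#' @export
genome_gc_bias <- function(amp, unamp, bins = NULL) {
  stopifnot(inherits(amp, "window_track"), inherits(unamp, "window_track"),
            nrow(amp) == nrow(unamp), all(amp$start == unamp$start))
  ok <- !amp$mask & !unamp$mask
  if (!any(ok)) stop("all windows masked")
  if (is.null(bins)) {
    rng <- range(amp$gc[ok])
    bins <- seq(floor(rng[1] * 50) / 50, ceiling(rng[2] * 50) / 50, by = 0.02)
  }
  idx <- findInterval(amp$gc, bins, rightmost.closed = TRUE)
  nb <- length(bins) - 1L
  out <- data.frame(bin_low = bins[-length(bins)], bin_high = bins[-1],
                    fold = NA_real_, n_windows = 0L, mean_amp = NA_real_,
                    mean_unamp = NA_real_, se_fold = NA_real_)
  for (b in seq_len(nb)) {
    sel <- ok & idx == b
    m <- sum(sel)
    out$n_windows[b] <- m
    if (m == 0L) next
    ma <- mean(amp$mean_depth[sel])
    mu <- mean(unamp$mean_depth[sel])
    out$mean_amp[b] <- ma
    out$mean_unamp[b] <- mu
    if (mu > 0) {
      out$fold[b] <- ma / mu
      if (m >= 2L) {
        va <- stats::var(amp$mean_depth[sel]) / m
        vu <- stats::var(unamp$mean_depth[sel]) / m
        out$se_fold[b] <- sqrt(va / mu^2 + ma^2 * vu / mu^4)
      }
    }
  }
  out$undefined <- is.na(out$fold)
  if (all(out$undefined)) stop("all GC bins undefined")
  out
}
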