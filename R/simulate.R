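#' Describe a segmented GC landscape
#'
#' Convenience constructor for genome GC profiles: `n_segments` segments of
#' equal length with target GC fractions stepping linearly from `gc_from` to
#' `gc_to`. The defaults emulate a phage-isolate-like genome whose windowed
#' GC spans roughly 31-55%.
#'
#' @param n_segments Number of segments.
#' @param segment_length Length of each segment (bp).
#' @param gc_from,gc_to Endpoints of the GC gradient (fractions).
#' @return Data frame with columns `length` and `gc`.
#' @export
gc_gradient <- function(n_segments = 25L, segment_length = 2000L,
                        gc_from = 0.31, gc_to = 0.55) {
  data.frame(length = rep.int(segment_length, n_segments),
             gc = seq(gc_from, gc_to, length.out = n_segments))
}

#' Describe a community-like GC landscape
#'
#' Segment GC targets follow the quantiles of a truncated normal
#' distribution: a peaked bulk at moderate GC with thin tails reaching the
#' extremes, the shape typical of read-level GC histograms of dsDNA virus
#' communities (wide total span, most mass near the mode). Deterministic.
#'
#' @param n_segments Number of segments.
#' @param segment_length Length of each segment (bp).
#' @param gc_mean,gc_sd Mode and spread of the GC distribution.
#' @param gc_range Truncation bounds of the GC span.
#' @return Data frame with columns `length` and `gc`.
#' @export
gc_community <- function(n_segments = 33L, segment_length = 1500L,
                         gc_mean = 0.43, gc_sd = 0.13,
                         gc_range = c(0.12, 0.84)) {
  p <- (seq_len(n_segments) - 0.5) / n_segments
  gc <- pmin(pmax(stats::qnorm(p, gc_mean, gc_sd), gc_range[1]), gc_range[2])
  data.frame(length = rep.int(segment_length, n_segments), gc = gc)
}

#' Generate a synthetic genome with a prescribed GC landscape
#'
#' Builds each segment with an exact GC base count (`round(gc * length)`
#' strong bases placed uniformly at random, each G or C with equal
#' probability; weak bases A or T likewise), so the realized segment GC is
#' within rounding error of its target. Deterministic for a given seed.
#'
#' @param segments Data frame with columns `length` (bp, each >= 30) and
#'   `gc` (target fraction in `[0, 1]`), e.g. from [gc_gradient()].
#' @param id Genome identifier.
#' @param seed Integer seed.
#' @return List of class `genome_model`: `id`, `sequence` (character),
#'   `segments` (with realized `gc_realized` column), `length`, and `gc_cum`
#'   (cumulative GC count, used for fast window/fragment GC).
#' @export
generate_genome <- function(segments, id = "synthetic_genome", seed = 1L) {
  stopifnot(is.data.frame(segments), all(c("length", "gc") %in% names(segments)),
            all(segments$gc >= 0 & segments$gc <= 1))
  if (any(segments$length < 30L)) {
    stop("segment lengths below 30 bp cannot realize a GC target reliably")
  }
  seqs <- withr_seed(seed, lapply(seq_len(nrow(segments)), function(i) {
    len <- segments$length[i]
    n_gc <- round(segments$gc[i] * len)
    base <- character(len)
    pos_gc <- sample.int(len, n_gc)
    base[pos_gc] <- sample(c("G", "C"), n_gc, replace = TRUE)
    base[-pos_gc] <- sample(c("A", "T"), len - n_gc, replace = TRUE)
    if (n_gc == 0L) base <- sample(c("A", "T"), len, replace = TRUE)
    paste(base, collapse = "")
  }))
  sequence <- paste(unlist(seqs), collapse = "")
  is_gc <- strsplit(sequence, "")[[1]] %in% c("G", "C")
  segments$gc_realized <- vapply(seq_len(nrow(segments)), function(i) {
    off <- c(0L, cumsum(segments$length))[i]
    mean(is_gc[(off + 1L):(off + segments$length[i])])
  }, numeric(1))
  stopifnot(all(abs(segments$gc_realized - segments$gc) <= 0.03))
  structure(list(id = id, sequence = sequence, segments = segments,
                 length = nchar(sequence),
                 gc_cum = c(0L, cumsum(as.integer(is_gc)))),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model '%s': %d bp, %d segments, GC %.3f\n",
              x$id, x$length, nrow(x$segments),
              x$gc_cum[length(x$gc_cum)] / x$length))
  invisible(x)
}

# GC fraction of [start, end) intervals (0-based half-open) via cumulative counts
interval_gc <- function(genome, start, end) {
  (genome$gc_cum[end + 1L] - genome$gc_cum[start + 1L]) / (end - start)
}

#' Shear a genome into a fragment pool
#'
#' Fragment lengths are uniform on `[size_low, size_high]` and start
#' positions uniform over the genome (linear coordinates; fragments never
#' span the genome end). All fragments start with copy number 1.
#'
#' @param genome A `genome_model`.
#' @param n_fragments Number of fragments (> 0).
#' @param size_low,size_high Shear size range in bp (defaults 400-800).
#' @param seed Integer seed.
#' @return A `fragment_pool`: data frame with columns `start` (0-based),
#'   `end` (exclusive), `gc`, `copies`, plus attributes `genome_id` and
#'   `protocol` (NULL until amplified).
#' @export
shear <- function(genome, n_fragments, size_low = 400L, size_high = 800L,
                  seed = 1L) {
  stopifnot(inherits(genome, "genome_model"), n_fragments >= 1L,
            size_low >= 30L, size_high >= size_low,
            size_high <= genome$length)
  pool <- withr_seed(seed, {
    len <- size_low +
      sample.int(size_high - size_low + 1L, n_fragments, replace = TRUE) - 1L
    start <- vapply(len, function(l) sample.int(genome$length - l + 1L, 1L) - 1L,
                    integer(1))
    data.frame(start = start, end = start + len)
  })
  pool$gc <- interval_gc(genome, pool$start, pool$end)
  pool$copies <- rep(1, n_fragments)
  structure(pool, genome_id = genome$id, protocol = NULL,
            class = c("fragment_pool", "data.frame"))
}

#' GC-dependent amplification efficiency model
#'
#' Per-cycle amplification efficiency as a function of fragment GC:
#' * `bell`: `e(g) = e_max * exp(-(g - g_opt)^2 / (2 sigma^2))` — efficiency
#'   peaks at an intermediate GC and falls off at both extremes, the
#'   phenomenology in which both high- and low-GC fragments end up
#'   under-represented;
#' * `flat`: `e(g) = e_max` for all g (no compositional bias);
#' * `linear`: `e(g) = e_max * g` (monotone toy model).
#'
#' The defaults (`e_max = 0.9`, `g_opt = 0.47`, `sigma = 0.45`) are
#' calibrated so that a 25-cycle amplification keeps fold representation
#' within `[0.5, 1.5]` across GC 0.31-0.55, the bias regime of an optimized
#' linker-amplification protocol.
#'
#' @param mode One of "bell", "flat", "linear".
#' @param e_max Peak efficiency in `[0, 1]`.
#' @param g_opt GC fraction of peak efficiency (bell mode).
#' @param sigma Width of the efficiency bell (GC units).
#' @return List of class `amplification_model`.
#' @export
amplification_model <- function(mode = c("bell", "flat", "linear"),
                                e_max = 0.9, g_opt = 0.47, sigma = 0.45) {
  mode <- match.arg(mode)
  stopifnot(e_max >= 0, e_max <= 1, sigma > 0, g_opt >= 0, g_opt <= 1)
  structure(list(mode = mode, e_max = e_max, g_opt = g_opt, sigma = sigma),
            class = "amplification_model")
}

#' Per-cycle efficiency at given GC fractions
#' @param model An `amplification_model`.
#' @param g Numeric vector of GC fractions in `[0, 1]`.
#' @return Numeric vector of efficiencies in `[0, 1]`.
#' @export
efficiency <- function(model, g) {
  stopifnot(inherits(model, "amplification_model"), all(g >= 0 & g <= 1))
  switch(model$mode,
         bell = model$e_max * exp(-(g - model$g_opt)^2 / (2 * model$sigma^2)),
         flat = rep(model$e_max, length(g)),
         linear = model$e_max * g)
}

#' Protocol configuration for one amplification treatment
#'
#' @param cycles Large-scale PCR cycle count (>= 0; 0 = unamplified control).
#' @param input_mass Input DNA mass in ng (recorded; `NA` allowed).
#' @param reconditioned Whether a reconditioning PCR is applied: the product
#'   is diluted `recond_dilution`-fold into fresh reaction mix and amplified
#'   for `recond_cycles` further cycles. Dilution rescales absolute yield
#'   only; relative fragment representation is unaffected.
#' @param recond_cycles Reconditioning cycle count (default 3).
#' @param recond_dilution Dilution fold before reconditioning (default 10).
#' @param barcode Sample barcode (or `NULL`).
#' @param linker A `linker_spec` (or `NULL`).
#' @return List of class `protocol_config`.
#' @export
protocol_config <- function(cycles, input_mass = NA_real_,
                            reconditioned = FALSE, recond_cycles = 3L,
                            recond_dilution = 10, barcode = NULL,
                            linker = NULL) {
  stopifnot(cycles >= 0, recond_cycles >= 0, recond_dilution > 0)
  structure(list(cycles = as.integer(cycles), input_mass = input_mass,
                 reconditioned = isTRUE(reconditioned),
                 recond_cycles = as.integer(recond_cycles),
                 recond_dilution = recond_dilution,
                 barcode = barcode, linker = linker),
            class = "protocol_config")
}

#' Total cycle count applied by a protocol
#'
#' The large-scale cycles plus, for reconditioned treatments, the
#' reconditioning cycles.
#' @param protocol A `protocol_config`.
#' @return Integer.
#' @export
effective_cycles <- function(protocol) {
  stopifnot(inherits(protocol, "protocol_config"))
  protocol$cycles +
    if (protocol$reconditioned) protocol$recond_cycles else 0L
}

#' Amplify a fragment pool
#'
#' Deterministic expectation-scale amplification: each fragment's copy
#' number is multiplied by `(1 + e(gc))^C`, where `e` is the per-cycle
#' efficiency of `model` and `C = effective_cycles(protocol)`. Zero cycles
#' is the identity (unamplified control). The reconditioning dilution is
#' recorded in metadata only — it rescales yield, not composition.
#' Stochasticity in the simulator is confined to read sampling.
#'
#' @param pool A `fragment_pool`.
#' @param model An `amplification_model`.
#' @param protocol A `protocol_config`.
#' @return The amplified `fragment_pool` (attribute `protocol` set).
#' @export
amplify <- function(pool, model, protocol) {
  stopifnot(inherits(pool, "fragment_pool"),
            inherits(model, "amplification_model"),
            inherits(protocol, "protocol_config"))
  C <- effective_cycles(protocol)
  pool$copies <- pool$copies * (1 + efficiency(model, pool$gc))^C
  attr(pool, "protocol") <- protocol
  attr(pool, "model") <- model
  pool
}

#' Analytic expected fold representation per GC bin
#'
#' For each GC bin, the copy-weighted mean of the per-fragment growth
#' factor `(1 + e(g))^C` over fragments in the bin, divided by the
#' pool-wide copy-weighted mean — the fold representation an unbiased
#' read-sampling step is expected to recover relative to the unamplified
#' pool. Copy weights are the pool's pre-amplification copy numbers. A flat
#' model gives exactly 1 in every occupied bin; empty bins are `NA` and
#' flagged undefined.
#'
#' @param model An `amplification_model`.
#' @param protocol A `protocol_config`.
#' @param pool The *unamplified* `fragment_pool`.
#' @param bins Numeric vector of GC bin edges (fractions, increasing).
#' @return Data frame: `bin_low`, `bin_high`, `fold`, `n_fragments`,
#'   `undefined`.
#' @export
expected_fold_bias <- function(model, protocol, pool, bins) {
  stopifnot(inherits(pool, "fragment_pool"), nrow(pool) > 0L,
            length(bins) >= 2L, !is.unsorted(bins))
  C <- effective_cycles(protocol)
  w <- (1 + efficiency(model, pool$gc))^C
  pool_mean <- sum(pool$copies * w) / sum(pool$copies)
  idx <- findInterval(pool$gc, bins, rightmost.closed = TRUE)
  nb <- length(bins) - 1L
  fold <- rep(NA_real_, nb)
  nfrag <- integer(nb)
  for (b in seq_len(nb)) {
    sel <- idx == b
    nfrag[b] <- sum(sel)
    if (nfrag[b] > 0L) {
      fold[b] <- (sum(pool$copies[sel] * w[sel]) / sum(pool$copies[sel])) /
        pool_mean
    }
  }
  data.frame(bin_low = bins[-length(bins)], bin_high = bins[-1],
             fold = fold, n_fragments = nfrag, undefined = is.na(fold))
}

#' Sample sequencing reads from a fragment pool
#'
#' Draws `n_reads` fragments with probability proportional to copy number;
#' each read covers its whole fragment on a uniformly chosen strand.
#' Sequencing substitutions are introduced at `error_rate` per base and
#' ambiguous bases (N) at `ambig_rate` per base; per-base Phred qualities
#' are Gaussian (`quality_mean`, `quality_sd`), clipped to `[2, 40]`. With
#' probability `dup_rate` a read is emitted a second time verbatim and
#' flagged as a duplicate (emulating emulsion-PCR replicates). When the
#' protocol carries a barcode and/or linker, reads are prefixed with
#' barcode + amplification primer. A complete truth table (one row per
#' emitted read) records the placement.
#'
#' @param pool An (amplified) `fragment_pool`.
#' @param genome The `genome_model` the pool was sheared from.
#' @param n_reads Number of primary reads (>= 1); duplicates are extra.
#' @param treatment Treatment label recorded in read ids and truth rows.
#' @param error_rate,ambig_rate Per-base substitution / N rates (applied to
#'   the whole emitted read, barcode/linker prefix included).
#' @param dup_rate Per-read duplicate emission probability.
#' @param quality_mean,quality_sd Gaussian quality model (Phred scale).
#' @param protocol A `protocol_config` supplying barcode/linker prefixes;
#'   defaults to the pool's amplification protocol.
#' @param emit_sequences When `FALSE`, skip sequence/quality realization and
#'   return the truth table only (fast path for depth analyses).
#' @param seed Integer seed.
#' @return List with `reads` (data frame `id`, `sequence`, `quality`, or
#'   `NULL`) and `truth` (data frame `read_id`, `genome_id`, `fragment`,
#'   `start`, `end`, `strand`, `treatment`, `is_duplicate`).
#' @export
sample_reads <- function(pool, genome, n_reads, treatment = "sample",
                         error_rate = 0.001, ambig_rate = 1e-4,
                         dup_rate = 0.05, quality_mean = 35, quality_sd = 3,
                         protocol = attr(pool, "protocol"),
                         emit_sequences = TRUE, seed = 1L) {
  stopifnot(inherits(pool, "fragment_pool"), n_reads >= 1L)
  if (sum(pool$copies) <= 0) stop("fragment pool has zero total copies")
  withr_seed(seed, {
    frag <- sample.int(nrow(pool), n_reads, replace = TRUE,
                       prob = pool$copies)
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    is_dup <- stats::rbinom(n_reads, 1L, dup_rate) == 1L
    ids <- sprintf("%s_r%06d", treatment, seq_len(n_reads))
    truth <- data.frame(read_id = ids,
                        genome_id = attr(pool, "genome_id"),
                        fragment = frag,
                        start = pool$start[frag], end = pool$end[frag],
                        strand = strand, treatment = treatment,
                        is_duplicate = FALSE)
    reads <- NULL
    if (emit_sequences) {
      seqs <- substring(genome$sequence, pool$start[frag] + 1L,
                        pool$end[frag])
      neg <- strand == "-"
      if (any(neg)) {
        seqs[neg] <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(seqs[neg])))
      }
      prefix <- read_prefix(protocol)
      if (nzchar(prefix)) seqs <- paste0(prefix, seqs)
      seqs <- inject_errors(seqs, error_rate, ambig_rate)
      qual <- random_quality_strings(nchar(seqs), quality_mean, quality_sd)
      reads <- data.frame(id = ids, sequence = seqs, quality = qual)
    }
    if (any(is_dup)) {
      dup_truth <- truth[is_dup, , drop = FALSE]
      dup_truth$read_id <- paste0(dup_truth$read_id, "_dup")
      dup_truth$is_duplicate <- TRUE
      truth <- rbind(truth, dup_truth)
      if (emit_sequences) {
        dup_reads <- reads[is_dup, , drop = FALSE]
        dup_reads$id <- paste0(dup_reads$id, "_dup")
        reads <- rbind(reads, dup_reads)
      }
    }
    rownames(truth) <- NULL
    if (!is.null(reads)) rownames(reads) <- NULL
    list(reads = reads, truth = truth)
  })
}

read_prefix <- function(protocol) {
  if (is.null(protocol)) return("")
  paste0(if (is.null(protocol$barcode)) "" else protocol$barcode,
         if (is.null(protocol$linker)) "" else
           protocol$linker$amplification_primer)
}

# substitution errors then ambiguous-base replacement, per base
inject_errors <- function(seqs, error_rate, ambig_rate) {
  if (error_rate > 0) {
    n_err <- stats::rbinom(length(seqs), nchar(seqs), error_rate)
    for (i in which(n_err > 0L)) {
      pos <- sample.int(nchar(seqs[i]), n_err[i])
      chars <- strsplit(seqs[i], "")[[1]]
      for (p in pos) {
        chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
      }
      seqs[i] <- paste(chars, collapse = "")
    }
  }
  if (ambig_rate > 0) {
    n_amb <- stats::rbinom(length(seqs), nchar(seqs), ambig_rate)
    for (i in which(n_amb > 0L)) {
      pos <- sample.int(nchar(seqs[i]), n_amb[i])
      chars <- strsplit(seqs[i], "")[[1]]
      chars[pos] <- "N"
      seqs[i] <- paste(chars, collapse = "")
    }
  }
  seqs
}

random_quality_strings <- function(lengths, mean, sd) {
  total <- sum(lengths)
  q <- pmin(pmax(round(stats::rnorm(total, mean, sd)), 2L), 40L)
  codes <- intToUtf8(q + 33L, multiple = FALSE)
  starts <- cumsum(c(1L, lengths[-length(lengths)]))
  substring(codes, starts, starts + lengths - 1L)
}

#' Simulate one complete treatment
#'
#' Convenience driver: shear, amplify under the treatment's protocol, and
#' sample reads. Per-stage seeds are derived from the single `seed` by fixed
#' offsets so a treatment is reproducible end to end.
#'
#' @param genome A `genome_model`.
#' @param protocol A `protocol_config`.
#' @param model An `amplification_model`.
#' @param n_fragments,n_reads Pool and read sizes.
#' @param treatment Treatment label.
#' @param seed Integer seed.
#' @param size_low,size_high Shear range (bp).
#' @param ... Passed on to [sample_reads()].
#' @return List: `pool` (unamplified), `amplified`, `reads`, `truth`.
#' @export
simulate_treatment <- function(genome, protocol, model, n_fragments, n_reads,
                               treatment = "sample", seed = 1L,
                               size_low = 400L, size_high = 800L, ...) {
  pool <- shear(genome, n_fragments, size_low, size_high, seed = seed + 11L)
  amp <- amplify(pool, model, protocol)
  rd <- sample_reads(amp, genome, n_reads, treatment = treatment,
                     seed = seed + 17L, ...)
  list(pool = pool, amplified = amp, reads = rd$reads, truth = rd$truth)
}
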