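#' Quality-control filter for pyrosequencing read batches
#'
#' Applies the four whole-read removal criteria used for low-input virome
#' libraries, in fixed attribution order: a read is removed if it
#' (i) contains any non-ACGT base, (ii) deviates from the batch mean read
#' length by more than `sd_mult` standard deviations, (iii) deviates from
#' the batch mean of per-read mean Phred quality by more than `sd_mult`
#' standard deviations, or (iv) is a non-kept member of a duplicate group
#' (see [find_duplicates()], the emulsion-PCR replicate stand-in). Batch
#' means and SDs are computed once on the full input set ("per plate" =
#' per input batch); each removed read is attributed to the first criterion
#' it fails, so the report counts are disjoint and sum to the input count.
#'
#' @param reads Data frame with columns `id`, `sequence` and optionally
#'   `quality` (Phred+33 strings). Without qualities, criterion (iii) is
#'   skipped with a warning.
#' @param sd_mult SD multiplier for criteria (ii) and (iii) (default 2).
#' @param dup_prefix,dup_len_tol Duplicate-rule parameters, passed to
#'   [find_duplicates()].
#' @return List with `reads` (the survivors) and `report` (a `qc_report`:
#'   counts per criterion plus batch statistics).
#' @export
qc_filter <- function(reads, sd_mult = 2, dup_prefix = 20L,
                      dup_len_tol = 0.02) {
  stopifnot(is.data.frame(reads), nrow(reads) > 0L,
            all(c("id", "sequence") %in% names(reads)))
  n <- nrow(reads)
  len <- nchar(reads$sequence)
  has_q <- "quality" %in% names(reads) && !all(is.na(reads$quality))
  meanq <- if (has_q) mean_quality(reads$quality) else rep(NA_real_, n)
  if (!has_q) warning("no qualities supplied; quality criterion skipped")

  mu_len <- mean(len); sd_len <- stats::sd(len)
  mu_q <- if (has_q) mean(meanq) else NA_real_
  sd_q <- if (has_q) stats::sd(meanq) else NA_real_

  fail_ambig <- grepl("[^ACGT]", reads$sequence)
  fail_len <- if (n > 1L && sd_len > 0) abs(len - mu_len) > sd_mult * sd_len
              else rep(FALSE, n)
  fail_qual <- if (has_q && n > 1L && sd_q > 0) abs(meanq - mu_q) > sd_mult * sd_q
               else rep(FALSE, n)
  dup <- find_duplicates(reads, prefix_len = dup_prefix, len_tol = dup_len_tol)
  fail_dup <- !dup$keep

  # first-failure attribution, order (i) -> (iv)
  cause <- rep(NA_character_, n)
  cause[fail_dup] <- "duplicate"
  cause[fail_qual] <- "quality"
  cause[fail_len] <- "length"
  cause[fail_ambig] <- "ambiguous"
  keep <- is.na(cause)

  report <- structure(list(
    input_count = n,
    removed_ambiguous = sum(cause == "ambiguous", na.rm = TRUE),
    removed_length = sum(cause == "length", na.rm = TRUE),
    removed_quality = sum(cause == "quality", na.rm = TRUE),
    removed_duplicate = sum(cause == "duplicate", na.rm = TRUE),
    output_count = sum(keep),
    batch_stats = list(mean_length = mu_len, sd_length = sd_len,
                       mean_quality = mu_q, sd_quality = sd_q)),
    class = "qc_report")
  stopifnot(report$input_count == report$output_count +
              report$removed_ambiguous + report$removed_length +
              report$removed_quality + report$removed_duplicate)
  list(reads = reads[keep, , drop = FALSE], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0("QC: %d in -> %d out (ambiguous %d, length %d, ",
                     "quality %d, duplicate %d)\n"),
              x$input_count, x$output_count, x$removed_ambiguous,
              x$removed_length, x$removed_quality, x$removed_duplicate))
  invisible(x)
}

#' Serialize a QC report as JSON
#' @param report A `qc_report`.
#' @param path Output path.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Group duplicate reads (emulsion-PCR replicate stand-in)
#'
#' Two reads belong to the same duplicate group when their first
#' `prefix_len` bases match exactly and their lengths differ by at most
#' `len_tol` (relative to the longer read). Grouping is greedy over reads
#' sorted by decreasing length (ties broken by id): each read joins the
#' first existing group whose kept representative satisfies both rules,
#' else founds a new group. The longest member of each group is kept (ties:
#' lexicographically smallest id). Reads shorter than `prefix_len` form
#' singleton groups. This is a deterministic desk-scale approximation of
#' the cd-hit-454 emPCR replicate definition.
#'
#' @param reads Data frame with `id` and `sequence`.
#' @param prefix_len Exact-match prefix length (default 20).
#' @param len_tol Maximum relative length difference (default 0.02).
#' @return Data frame aligned with `reads`: columns `id`, `group` (integer)
#'   and `keep` (logical, TRUE for the kept representative).
#' @export
find_duplicates <- function(reads, prefix_len = 20L, len_tol = 0.02) {
  stopifnot(is.data.frame(reads), all(c("id", "sequence") %in% names(reads)))
  n <- nrow(reads)
  len <- nchar(reads$sequence)
  ord <- order(-len, reads$id)
  group <- integer(n)
  prefix <- substr(reads$sequence, 1L, prefix_len)
  next_group <- 0L
  # representative (first = longest) read index per group
  rep_idx <- integer(0)
  buckets <- new.env(parent = emptyenv())
  for (i in ord) {
    assigned <- FALSE
    if (len[i] >= prefix_len) {
      key <- prefix[i]
      cand <- if (!is.null(buckets[[key]])) buckets[[key]] else integer(0)
      for (g in cand) {
        r <- rep_idx[g]
        if (abs(len[i] - len[r]) / max(len[i], len[r]) <= len_tol) {
          group[i] <- g
          assigned <- TRUE
          break
        }
      }
      if (!assigned) {
        next_group <- next_group + 1L
        group[i] <- next_group
        rep_idx[next_group] <- i
        buckets[[key]] <- c(cand, next_group)
      }
    } else {
      next_group <- next_group + 1L
      group[i] <- next_group
      rep_idx[next_group] <- i
    }
  }
  keep <- logical(n)
  keep[rep_idx] <- TRUE
  data.frame(id = reads$id, group = group, keep = keep)
}
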