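#' Demultiplex barcoded reads
#'
#' Assigns each read to the treatment whose barcode matches the read's 5'
#' prefix within `max_mismatch` substitutions (optionally also requiring the
#' linker sequence that follows the barcode to match within the same
#' budget). Assigned reads have the barcode+linker prefix stripped. Reads
#' matching no barcode, or two barcodes at equal distance, go to the
#' unassigned bin (ties are flagged ambiguous). Read counts are conserved:
#' assigned + unassigned = input.
#'
#' @param reads Data frame with columns `id`, `sequence` (and optionally
#'   `quality`, stripped in step with the sequence).
#' @param barcodes Named character vector: treatment label -> barcode.
#'   Barcodes must be unique.
#' @param linker A `linker_spec` or `NULL`; when supplied, its
#'   `amplification_primer` is the sequence expected between barcode and
#'   insert.
#' @param max_mismatch Maximum substitutions tolerated (default 0).
#' @param check_linker Whether the linker segment must also match (default
#'   `TRUE` when a linker is supplied).
#' @return List with `assigned` (named list of data frames, one per
#'   treatment), `unassigned` (data frame with an `ambiguous` column) and
#'   `counts` (named integer vector, including `unassigned`).
#' @export
demultiplex <- function(reads, barcodes, linker = NULL, max_mismatch = 0L,
                        check_linker = !is.null(linker)) {
  stopifnot(is.data.frame(reads), all(c("id", "sequence") %in% names(reads)))
  if (anyDuplicated(barcodes)) stop("barcodes must be unique")
  if (is.null(names(barcodes)) || any(!nzchar(names(barcodes)))) {
    stop("barcodes must be named by treatment label")
  }
  bc_len <- unique(nchar(barcodes))
  if (length(bc_len) != 1L) stop("barcodes must share one length")
  lnk <- if (!is.null(linker)) linker$amplification_primer else ""
  strip_len <- bc_len + nchar(lnk)

  n <- nrow(reads)
  prefix_bc <- substr(reads$sequence, 1L, bc_len)
  dist_to <- function(bc) {
    mapply(function(p) sum(strsplit(p, "")[[1]] != strsplit(bc, "")[[1]]),
           prefix_bc)
  }
  D <- vapply(barcodes, dist_to, numeric(n))
  if (n == 1L) D <- matrix(D, nrow = 1L, dimnames = list(NULL, names(barcodes)))
  if (check_linker && nzchar(lnk)) {
    seg <- substr(reads$sequence, bc_len + 1L, strip_len)
    lnk_chars <- strsplit(lnk, "")[[1]]
    dl <- vapply(seg, function(p) {
      pc <- strsplit(p, "")[[1]]
      sum(pc != lnk_chars[seq_along(pc)]) + (nchar(lnk) - length(pc))
    }, numeric(1), USE.NAMES = FALSE)
    D <- D + dl
  }
  best <- apply(D, 1L, min)
  n_best <- rowSums(D == best)
  hit <- best <= max_mismatch & n_best == 1L
  ambiguous <- best <= max_mismatch & n_best > 1L
  label <- rep(NA_character_, n)
  label[hit] <- names(barcodes)[apply(D[hit, , drop = FALSE], 1L, which.min)]

  strip <- function(df) {
    df$sequence <- substr(df$sequence, strip_len + 1L, nchar(df$sequence))
    if ("quality" %in% names(df)) {
      df$quality <- substr(df$quality, strip_len + 1L, nchar(df$quality))
    }
    df
  }
  assigned <- lapply(stats::setNames(names(barcodes), names(barcodes)),
                     function(tr) strip(reads[which(label == tr), , drop = FALSE]))
  unassigned <- reads[!hit, , drop = FALSE]
  unassigned$ambiguous <- ambiguous[!hit]
  counts <- c(vapply(assigned, nrow, integer(1)), unassigned = nrow(unassigned))
  stopifnot(sum(counts) == n)
  list(assigned = assigned, unassigned = unassigned, counts = counts)
}
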