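#' Read and write reads as FASTQ (Phred+33)
#'
#' Thin wrappers around Biostrings FASTQ IO using the package's read
#' representation: a data frame with columns `id`, `sequence` and `quality`
#' (Phred+33 strings).
#'
#' @param reads Data frame with `id`, `sequence`, `quality`.
#' @param path File path.
#' @return `read_fastq` returns a reads data frame; `write_fastq` returns
#'   `path` invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "sequence", "quality") %in% names(reads)))
  handle <- file(path, "w")
  on.exit(close(handle))
  writeLines(paste0("@", reads$id, "\n", reads$sequence, "\n+\n",
                    reads$quality), handle)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  # Biostrings warns about dropped metadata columns on plain FASTQ; benign
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(id = sub(" .*", "", names(x)),
             sequence = as.character(x),
             quality = as.character(Biostrings::quality(x)))
}

#' Write / read a simulator truth table as TSV
#'
#' Coordinates are exported 1-based inclusive (`start1`, `end1`); internal
#' representation is 0-based half-open.
#'
#' @param truth Truth data frame from [sample_reads()].
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  out <- truth
  out$start1 <- out$start + 1L
  out$end1 <- out$end
  out$start <- out$end <- NULL
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$start <- df$start1 - 1L
  df$end <- df$end1
  df$start1 <- df$end1 <- NULL
  df
}

#' Write or read a genome as FASTA
#'
#' `read_genome_fasta` rebuilds a `genome_model` (without segment
#' annotation) from the first record of a FASTA file, including the
#' cumulative-GC index used by the window and fragment GC computations.
#'
#' @param genome A `genome_model`.
#' @param path File path.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome$sequence)
  names(x) <- genome$id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  seq <- as.character(x[[1]])
  is_gc <- strsplit(seq, "")[[1]] %in% c("G", "C")
  structure(list(id = sub(" .*", "", names(x)[1]), sequence = seq,
                 segments = NULL, length = nchar(seq),
                 gc_cum = c(0L, cumsum(as.integer(is_gc)))),
            class = "genome_model")
}

#' Decode Phred+33 quality strings to per-read mean quality
#' @param quality Character vector of Phred+33 strings.
#' @return Numeric vector of per-read arithmetic mean Phred scores.
#' @export
mean_quality <- function(quality) {
  vapply(quality, function(q) mean(utf8ToInt(q) - 33L), numeric(1),
         USE.NAMES = FALSE)
}
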