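#' Construct a linker specification
#'
#' A hemi-phosphorylated linker is an annealed pair of oligos: a
#' 5'-phosphorylated forward strand and a shorter, unphosphorylated reverse
#' strand whose reverse complement matches one end of the forward strand,
#' leaving a single-stranded overhang that promotes unidirectional ligation.
#' The reverse strand doubles as the amplification primer.
#'
#' @param forward Forward (phosphorylated) strand, 5'->3'.
#' @param reverse Reverse strand, 5'->3'.
#' @param amplification_primer Amplification primer; defaults to `reverse`.
#' @return List of class `linker_spec`.
#' @export
linker_spec <- function(forward, reverse, amplification_primer = reverse) {
  for (s in c(forward, reverse, amplification_primer)) {
    stopifnot(is.character(s), length(s) == 1L, nzchar(s),
              grepl("^[ACGT]+$", s))
  }
  structure(list(forward = forward, reverse = reverse,
                 amplification_primer = amplification_primer),
            class = "linker_spec")
}

#' The default linker used for 454 linker-amplification libraries
#' @return A `linker_spec`.
#' @export
default_linker <- function() {
  linker_spec(forward = "GTATGCTTCGTGATCTGTGTGGGTGT",
              reverse = "CCACACAGATCACGAAGCATAC")
}

#' Reverse complement of a nucleotide string
#' @param s Character string over ACGTN.
#' @return Character string.
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Validate a linker specification
#'
#' Checks the annealing geometry of a hemi-ligated linker: the reverse
#' strand must be the reverse complement of a terminal segment of the
#' forward strand (either end), the amplification primer must equal the
#' reverse strand, and the barcode-compatibility context is recorded:
#' whether the linker starts with a 5' C (which forbids barcodes ending in
#' C) — the emulsion-PCR primers' 3' G independently forbids barcodes
#' starting with G.
#'
#' @param spec A `linker_spec`.
#' @return List of class `linker_report` with `pass`, `violations`,
#'   `matched_length`, `matched_end` ("5prime"/"3prime"/NA), `mismatch_at`
#'   (first mismatching forward-strand position against the best terminal
#'   alignment, NA when matched) and `linker_5prime_C` (logical).
#' @export
validate_linker <- function(spec) {
  stopifnot(inherits(spec, "linker_spec"))
  violations <- character(0)
  rc <- revcomp(spec$reverse)
  n <- nchar(rc)
  L <- nchar(spec$forward)
  matched_end <- NA_character_
  matched_length <- 0L
  mismatch_at <- NA_integer_
  if (n > L) {
    violations <- c(violations, "reverse_longer_than_forward")
  } else {
    pre <- substr(spec$forward, 1L, n)
    suf <- substr(spec$forward, L - n + 1L, L)
    if (pre == rc) {
      matched_end <- "5prime"
      matched_length <- n
    } else if (suf == rc) {
      matched_end <- "3prime"
      matched_length <- n
    } else {
      violations <- c(violations, "reverse_not_revcomp_of_forward_end")
      # report first mismatch against the 5' terminal alignment
      a <- strsplit(pre, "")[[1]]
      b <- strsplit(rc, "")[[1]]
      mismatch_at <- which(a != b)[1]
    }
  }
  if (spec$amplification_primer != spec$reverse) {
    violations <- c(violations, "primer_not_equal_reverse")
  }
  structure(list(pass = length(violations) == 0L,
                 violations = violations,
                 matched_end = matched_end,
                 matched_length = matched_length,
                 mismatch_at = mismatch_at,
                 linker_5prime_C = substr(spec$reverse, 1L, 1L) == "C"),
            class = "linker_report")
}

#' @export
print.linker_report <- function(x, ...) {
  cat(if (x$pass) "linker OK" else paste("linker FAIL:", paste(x$violations, collapse = ", ")),
      sprintf(" (matched %d nt at %s end)\n", x$matched_length,
              ifelse(is.na(x$matched_end), "no", x$matched_end)))
  invisible(x)
}
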