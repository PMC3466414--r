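#' Validate a 5-bp sample barcode
#'
#' Checks a candidate barcode against the four design rules used for
#' linker-amplification libraries: (i) no consecutive duplicate nucleotides,
#' (ii) Hamming distance of at least `min_hamming` to every barcode already
#' in the set, (iii) no C at the 3' end (the linker starts with a 5' C), and
#' (iv) no G at the 5' end (the emulsion-PCR primers end in a 3' G).
#' Barcodes must be exactly 5 bp of uppercase ACGT.
#'
#' @param b Candidate barcode (single character string).
#' @param set_context Character vector of barcodes already accepted, or
#'   `NULL` for a free-standing check.
#' @param min_hamming Minimum pairwise Hamming distance required against
#'   `set_context` (default 2).
#' @return A list of class `barcode_report` with elements `barcode`, `pass`
#'   (logical) and `violations` (character vector naming each violated rule,
#'   empty when valid).
#' @examples
#' validate_barcode("CGACA")          # passes
#' validate_barcode("GACAC")          # starts with G, ends with C
#' @export
validate_barcode <- function(b, set_context = NULL, min_hamming = 2L) {
  stopifnot(is.character(b), length(b) == 1L, nzchar(b))
  chars <- strsplit(b, "")[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T"))
  if (length(bad) > 0L) {
    stop("non-ACGT character '", chars[bad[1]], "' at position ", bad[1],
         " in barcode '", b, "'")
  }
  violations <- character(0)
  if (nchar(b) != 5L) {
    violations <- c(violations, "length_not_5")
  }
  if (length(chars) > 1L && any(chars[-1] == chars[-length(chars)])) {
    violations <- c(violations, "consecutive_duplicate")
  }
  if (length(set_context) > 0L) {
    same_len <- nchar(set_context) == nchar(b)
    d <- vapply(set_context[same_len], hamming_distance, integer(1), b = b)
    if (any(!same_len) || (length(d) > 0L && min(d) < min_hamming)) {
      violations <- c(violations, "hamming_below_min")
    }
  }
  if (substr(b, nchar(b), nchar(b)) == "C") {
    violations <- c(violations, "c_at_3prime")
  }
  if (substr(b, 1L, 1L) == "G") {
    violations <- c(violations, "g_at_5prime")
  }
  structure(list(barcode = b, pass = length(violations) == 0L,
                 violations = violations),
            class = "barcode_report")
}

#' @export
print.barcode_report <- function(x, ...) {
  status <- if (x$pass) "PASS" else paste("FAIL:", paste(x$violations, collapse = ", "))
  cat(sprintf("barcode %s  %s\n", x$barcode, status))
  invisible(x)
}

hamming_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("unequal lengths: '", a, "' vs '", b, "'")
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Minimum pairwise Hamming distance of a barcode set
#'
#' @param set Character vector of at least two equal-length sequences.
#' @return Integer: the exact minimum Hamming distance over all unordered
#'   pairs.
#' @export
min_pairwise_hamming <- function(set) {
  stopifnot(is.character(set), length(set) >= 2L)
  if (length(unique(nchar(set))) != 1L) stop("barcodes have unequal lengths")
  m <- do.call(rbind, strsplit(set, ""))
  dmin <- nchar(set[1])
  for (i in seq_len(nrow(m) - 1L)) {
    for (j in seq(i + 1L, nrow(m))) {
      dmin <- min(dmin, sum(m[i, ] != m[j, ]))
    }
  }
  as.integer(dmin)
}

#' Design a set of valid 5-bp barcodes
#'
#' Enumerates every 5-mer satisfying rules (i), (iii) and (iv), shuffles the
#' enumeration with `seed`, and greedily accepts candidates that keep the
#' growing set at pairwise Hamming distance >= `min_hamming`. Deterministic
#' for a given seed.
#'
#' @param n Number of barcodes requested.
#' @param seed Integer seed controlling the shuffle order.
#' @param min_hamming Pairwise Hamming floor (default 2).
#' @return Character vector of `n` barcodes with attribute `min_hamming`.
#' @export
design_barcodes <- function(n, seed = 1L, min_hamming = 2L) {
  stopifnot(n >= 1L)
  pool <- enumerate_valid_barcodes()
  pool <- withr_seed(seed, sample(pool))
  accepted <- character(0)
  for (cand in pool) {
    rep <- validate_barcode(cand, set_context = accepted, min_hamming = min_hamming)
    if (rep$pass) accepted <- c(accepted, cand)
    if (length(accepted) == n) break
  }
  if (length(accepted) < n) {
    stop("cannot design ", n, " barcodes at Hamming >= ", min_hamming,
         "; maximum achievable for this seed's ordering is ", length(accepted))
  }
  structure(accepted, min_hamming = min_hamming)
}

# all 5-mers over ACGT passing rules (i), (iii), (iv)
enumerate_valid_barcodes <- function() {
  nt <- c("A", "C", "G", "T")
  grid <- expand.grid(nt, nt, nt, nt, nt, stringsAsFactors = FALSE)
  seqs <- apply(as.matrix(grid), 1, paste, collapse = "")
  keep <- substr(seqs, 1, 1) != "G" & substr(seqs, 5, 5) != "C"
  seqs <- seqs[keep]
  m <- do.call(rbind, strsplit(seqs, ""))
  no_dup <- rowSums(m[, -1] == m[, -5]) == 0
  sort(seqs[no_dup])
}

# evaluate expr under a local RNG seed without disturbing the caller's RNG
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Read or write a barcode set as two-column TSV (label, sequence)
#'
#' @param path File path.
#' @param barcodes Named character vector (names are treatment labels).
#' @return `read_barcodes` returns a named character vector.
#' @export
read_barcodes <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stats::setNames(df$sequence, df$label)
}

#' @rdname read_barcodes
#' @export
write_barcodes <- function(barcodes, path) {
  df <- data.frame(label = names(barcodes), sequence = as.character(barcodes))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
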