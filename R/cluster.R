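#' Pairwise sequence identity (cd-hit convention)
#'
#' Global (Needleman-Wunsch) alignment identity defined as the number of
#' identical aligned positions divided by the length of the shorter
#' sequence. For nucleotide sequences with `both_strands = TRUE`, the
#' reverse complement of the second sequence is also tried and the larger
#' identity returned.
#'
#' @param a,b Character sequences.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @param both_strands Consider the reverse complement of `b` (nucleotide
#'   only).
#' @return Identity fraction in `[0, 1]`.
#' @export
seq_identity <- function(a, b, alphabet = c("nucleotide", "protein"),
                         both_strands = FALSE) {
  alphabet <- match.arg(alphabet)
  id1 <- alignment_identity(a, b, alphabet)
  if (both_strands && alphabet == "nucleotide") {
    max(id1, alignment_identity(a, revcomp(b), alphabet))
  } else {
    id1
  }
}

alignment_identity <- function(a, b, alphabet) {
  cls <- if (alphabet == "nucleotide") Biostrings::DNAString
         else Biostrings::AAString
  aln <- Biostrings::pairwiseAlignment(
    cls(a), cls(b), type = "global",
    substitutionMatrix = NULL, gapOpening = 5, gapExtension = 2,
    fuzzyMatrix = NULL)
  Biostrings::nmatch(aln) / min(nchar(a), nchar(b))
}

# identities of one query against many references in a single alignment
# call; returns a numeric vector aligned with refs
alignment_identity_many <- function(refs, query, alphabet) {
  set_cls <- if (alphabet == "nucleotide") Biostrings::DNAStringSet
             else Biostrings::AAStringSet
  aln <- Biostrings::pairwiseAlignment(
    set_cls(refs), set_cls(query)[[1]], type = "global",
    substitutionMatrix = NULL, gapOpening = 5, gapExtension = 2,
    fuzzyMatrix = NULL)
  Biostrings::nmatch(aln) / pmin(nchar(refs), nchar(query))
}

# k-mer prefilter vocabulary of one sequence
seq_words <- function(s, word_size) {
  if (nchar(s) < word_size) return(character(0))
  unique(substring(s, seq_len(nchar(s) - word_size + 1L),
                   word_size:nchar(s)))
}

#' Greedy incremental identity clustering
#'
#' cd-hit-style clustering: sequences are sorted by decreasing length (ties
#' broken lexicographically by id) and processed in order; each sequence is
#' compared against existing cluster representatives (after a shared-k-mer
#' prefilter of `word_size`) and joins the first representative whose
#' identity (see [seq_identity()]) meets `threshold`, otherwise it founds a
#' new cluster. The representative is therefore always the longest member.
#' Deterministic.
#'
#' @param seqs Named character vector of sequences (names are ids).
#' @param threshold Identity threshold in `(0, 1]`.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @param both_strands Also compare reverse complements (nucleotide only).
#' @param word_size k-mer prefilter word length (default 8 for nucleotide
#'   work at 90% identity; use 4 for proteins at 60%).
#' @return List of class `cluster_set`: `membership` (data frame `id`,
#'   `cluster`, `is_representative`), `threshold`, `alphabet`,
#'   `both_strands`, `sizes` (integer vector per cluster).
#' @export
greedy_cluster <- function(seqs, threshold, alphabet = c("nucleotide", "protein"),
                           both_strands = FALSE, word_size = 8L) {
  alphabet <- match.arg(alphabet)
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  stopifnot(length(seqs) > 0L)
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%05d", seq_along(seqs))
  ord <- order(-nchar(seqs), names(seqs))
  rep_words <- list()
  rep_seq <- character(0)
  rep_id <- character(0)
  cluster <- integer(length(seqs))
  try_rc <- both_strands && alphabet == "nucleotide"
  for (i in ord) {
    s <- seqs[[i]]
    s_rc <- if (try_rc) revcomp(s) else NULL
    words <- seq_words(s, word_size)
    if (try_rc) words <- unique(c(words, seq_words(s_rc, word_size)))
    hit <- 0L
    cand <- which(vapply(rep_words, function(w) {
      length(w) == 0L || length(words) == 0L || any(words %in% w)
    }, logical(1)))
    if (length(cand) > 0L) {
      id <- alignment_identity_many(rep_seq[cand], s, alphabet)
      if (try_rc) {
        id <- pmax(id, alignment_identity_many(rep_seq[cand], s_rc, alphabet))
      }
      pass <- which(id >= threshold)
      if (length(pass) > 0L) hit <- cand[pass[1]]
    }
    if (hit == 0L) {
      g <- length(rep_seq) + 1L
      rep_seq[g] <- s
      rep_id[g] <- names(seqs)[i]
      rep_words[[g]] <- seq_words(s, word_size)
      cluster[i] <- g
    } else {
      cluster[i] <- hit
    }
  }
  membership <- data.frame(id = names(seqs), cluster = cluster,
                           is_representative = names(seqs) %in% rep_id)
  structure(list(membership = membership, threshold = threshold,
                 alphabet = alphabet, both_strands = both_strands,
                 sizes = tabulate(cluster)),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d sequences in %d clusters (threshold %.0f%%%s)\n",
              nrow(x$membership), length(x$sizes), 100 * x$threshold,
              if (x$both_strands) ", both strands" else ""))
  invisible(x)
}

#' Rarefaction of sequence clusters
#'
#' Subsamples reads without replacement at increasing effort and counts the
#' distinct *eligible* clusters represented, where eligibility is decided
#' on the full data set (cluster size >= `min_cluster_size`, the
#' "more than 20 members" convention with the default of 21). Reports mean
#' and SD over replicates at each effort.
#'
#' @param membership Data frame with columns `id` and `cluster` covering
#'   every read (e.g. from [greedy_cluster()]), or a `cluster_set`.
#' @param step Effort step in reads (default 5000); efforts are
#'   `step, 2*step, ...` capped at the total read count, which is always
#'   included.
#' @param efforts Explicit effort grid (overrides `step`). Efforts above
#'   the total are capped with a warning.
#' @param n_replicates Subsampling replicates per effort (default 100).
#' @param min_cluster_size Minimum full-data cluster size to count
#'   (default 21).
#' @param seed Integer seed.
#' @return Data frame of class `rarefaction_curve`: `effort`,
#'   `mean_clusters`, `sd_clusters`, `n_replicates`.
#' @export
rarefy <- function(membership, step = 5000L, efforts = NULL,
                   n_replicates = 100L, min_cluster_size = 21L, seed = 1L) {
  if (inherits(membership, "cluster_set")) membership <- membership$membership
  stopifnot(all(c("id", "cluster") %in% names(membership)))
  N <- nrow(membership)
  if (is.null(efforts)) {
    efforts <- unique(c(seq.int(step, N, by = step), N))
  }
  if (any(efforts > N)) {
    warning("efforts above total read count capped at ", N)
    efforts <- unique(pmin(efforts, N))
  }
  sizes <- table(membership$cluster)
  eligible <- as.integer(names(sizes)[sizes >= min_cluster_size])
  cl <- membership$cluster
  cl[!cl %in% eligible] <- NA_integer_
  res <- withr_seed(seed, {
    vapply(efforts, function(m) {
      counts <- vapply(seq_len(n_replicates), function(r) {
        drawn <- cl[sample.int(N, m)]
        length(unique(drawn[!is.na(drawn)]))
      }, numeric(1))
      c(mean(counts), stats::sd(counts))
    }, numeric(2))
  })
  structure(data.frame(effort = efforts, mean_clusters = res[1, ],
                       sd_clusters = res[2, ], n_replicates = n_replicates),
            min_cluster_size = min_cluster_size,
            class = c("rarefaction_curve", "data.frame"))
}

#' Closed-form expected rarefaction curve
#'
#' Analytic expectation of the number of eligible clusters represented in a
#' without-replacement sample of `m` reads out of `N`:
#' `sum_c [1 - choose(N - n_c, m) / choose(N, m)]` over eligible clusters
#' `c` with `n_c` members (hypergeometric inclusion probability). Computed
#' on log scale for numerical stability.
#'
#' @inheritParams rarefy
#' @return Data frame: `effort`, `expected_clusters`.
#' @export
rarefaction_expected <- function(membership, efforts, min_cluster_size = 21L) {
  if (inherits(membership, "cluster_set")) membership <- membership$membership
  N <- nrow(membership)
  sizes <- as.integer(table(membership$cluster))
  sizes <- sizes[sizes >= min_cluster_size]
  expected <- vapply(efforts, function(m) {
    miss <- ifelse(N - sizes >= m,
                   exp(lchoose(N - sizes, m) - lchoose(N, m)), 0)
    sum(1 - miss)
  }, numeric(1))
  data.frame(effort = efforts, expected_clusters = expected)
}

#' Singleton fraction of a read set
#'
#' Clusters reads at 90% nucleotide identity considering both strands and
#' reports the fraction of reads that sit in single-member clusters — a
#' proxy for the rare fraction of the community.
#'
#' @param seqs Named character vector of read sequences.
#' @param threshold Identity threshold (default 0.9).
#' @param word_size k-mer prefilter word size (default 8).
#' @return List: `fraction`, `n_singletons`, `n_reads`, `n_clusters`,
#'   `clusters` (the `cluster_set`).
#' @export
singleton_fraction <- function(seqs, threshold = 0.9, word_size = 8L) {
  cs <- greedy_cluster(seqs, threshold = threshold, alphabet = "nucleotide",
                       both_strands = TRUE, word_size = word_size)
  singles <- which(cs$sizes == 1L)
  n_single <- sum(cs$membership$cluster %in% singles)
  list(fraction = n_single / length(seqs), n_singletons = n_single,
       n_reads = length(seqs), n_clusters = length(cs$sizes), clusters = cs)
}

#' Translate reads to their longest open reading frame
#'
#' Desk-scale stand-in for the assembly + gene-prediction path: each read
#' is scanned in all three forward frames (and the reverse complement when
#' `both_strands`) for the longest stretch of codons without a stop, and
#' that stretch is translated. Reads whose longest ORF is shorter than
#' `min_aa` are dropped.
#'
#' @param seqs Named character vector of nucleotide reads (Ns tolerated;
#'   fuzzy codons translate to X).
#' @param min_aa Minimum ORF length in amino acids (default 20).
#' @param both_strands Also scan the reverse complement (default TRUE).
#' @return Named character vector of protein sequences.
#' @export
translate_longest_orf <- function(seqs, min_aa = 20L, both_strands = TRUE) {
  orf_of <- function(nt) {
    best <- ""
    strands <- if (both_strands) c(nt, revcomp(gsub("[^ACGTN]", "N", nt)))
               else nt
    for (s in strands) {
      for (off in 0:2) {
        sub <- substr(s, off + 1L, off + 3L * ((nchar(s) - off) %/% 3L))
        if (nchar(sub) < 3L) next
        aa <- suppressWarnings(as.character(Biostrings::translate(
          Biostrings::DNAString(sub), if.fuzzy.codon = "X")))
        for (piece in strsplit(aa, "\\*")[[1]]) {
          if (nchar(piece) > nchar(best)) best <- piece
        }
      }
    }
    best
  }
  out <- vapply(seqs, orf_of, character(1))
  out[nchar(out) >= min_aa]
}
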