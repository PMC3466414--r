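# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles deliberately re-derive results from definitions rather
# than calling the implementation paths they check.

random_dna <- function(n, len, seed) {
  withr::with_seed(seed, vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1)))
}

small_genome <- function(seed = 101, n_segments = 10L, segment_length = 1000L) {
  generate_genome(gc_gradient(n_segments, segment_length), seed = seed)
}

mutate_seq <- function(s, n_mut, seed) {
  withr::with_seed(seed, {
    chars <- strsplit(s, "")[[1]]
    pos <- sample.int(length(chars), n_mut)
    for (p in pos) {
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
    }
    paste(chars, collapse = "")
  })
}

# paired t from first principles: t = mean(d) / (sd(d)/sqrt(n)), two-tailed p
oracle_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1))
}

# naive per-window mean depth and GC by explicit loops
oracle_windows <- function(scaled, genome, window_size, step) {
  starts <- seq.int(0L, genome$length - window_size, by = step)
  chars <- strsplit(genome$sequence, "")[[1]]
  t(vapply(starts, function(s) {
    win <- (s + 1L):(s + window_size)
    c(mean_depth = mean(scaled[win]),
      gc = mean(chars[win] %in% c("G", "C")))
  }, numeric(2)))
}

# naive per-base depth by explicit loop over placements
oracle_depth <- function(placements, L) {
  d <- integer(L)
  for (i in seq_len(nrow(placements))) {
    idx <- (placements$start[i] + 1L):placements$end[i]
    d[idx] <- d[idx] + 1L
  }
  d
}

# exhaustive duplicate grouping under the same rule and greedy order:
# sort by (-length, id); each read joins the first group whose kept
# (longest) representative shares the 20-base prefix and has length within
# the tolerance, else founds a group
oracle_duplicates <- function(reads, prefix_len = 20L, len_tol = 0.02) {
  n <- nrow(reads)
  len <- nchar(reads$sequence)
  ord <- order(-len, reads$id)
  group <- integer(n)
  reps <- integer(0)
  for (i in ord) {
    hit <- 0L
    if (len[i] >= prefix_len) {
      for (g in seq_along(reps)) {
        r <- reps[g]
        if (len[r] >= prefix_len &&
            substr(reads$sequence[i], 1, prefix_len) ==
              substr(reads$sequence[r], 1, prefix_len) &&
            abs(len[i] - len[r]) / max(len[i], len[r]) <= len_tol) {
          hit <- g
          break
        }
      }
    }
    if (hit == 0L) {
      reps <- c(reps, i)
      group[i] <- length(reps)
    } else {
      group[i] <- hit
    }
  }
  keep <- logical(n)
  keep[reps] <- TRUE
  data.frame(id = reads$id, group = group, keep = keep)
}

# identity by direct global alignment, same definition as the package
oracle_identity <- function(a, b, both_strands = FALSE) {
  align_id <- function(x, y) {
    aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(x),
                                         Biostrings::DNAString(y),
                                         type = "global", gapOpening = 5,
                                         gapExtension = 2)
    Biostrings::nmatch(aln) / min(nchar(x), nchar(y))
  }
  id <- align_id(a, b)
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(b)))
    id <- max(id, align_id(a, rc))
  }
  id
}

# exhaustive greedy clustering from an all-pairs identity matrix, no
# k-mer prefilter
oracle_greedy_cluster <- function(seqs, threshold, both_strands = FALSE) {
  ord <- order(-nchar(seqs), names(seqs))
  reps <- integer(0)
  cluster <- integer(length(seqs))
  for (i in ord) {
    hit <- 0L
    for (g in seq_along(reps)) {
      if (oracle_identity(seqs[[reps[g]]], seqs[[i]], both_strands) >= threshold) {
        hit <- g
        break
      }
    }
    if (hit == 0L) {
      reps <- c(reps, i)
      cluster[i] <- length(reps)
    } else {
      cluster[i] <- hit
    }
  }
  cluster
}

# iterative per-cycle amplification oracle: multiply copies cycle by cycle
oracle_amplify_loop <- function(pool, model, cycles) {
  copies <- pool$copies
  e <- efficiency(model, pool$gc)
  for (i in seq_len(cycles)) copies <- copies * (1 + e)
  copies
}
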