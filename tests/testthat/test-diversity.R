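test_that("greedy clustering handles identity extremes and partitions the input", {
  s <- random_dna(1, 100, seed = 81)
  same <- stats::setNames(rep(s, 5), paste0("s", 1:5))
  cs <- greedy_cluster(same, 0.9, "nucleotide")
  expect_equal(length(cs$sizes), 1L)
  expect_equal(cs$sizes, 5L)

  far <- stats::setNames(random_dna(2, 100, seed = 82), c("a", "b"))
  cs2 <- greedy_cluster(far, 0.9, "nucleotide")
  expect_equal(length(cs2$sizes), 2L)

  expect_error(greedy_cluster(same, 1.5), "threshold")

  # partition property on a mixed input
  seqs <- stats::setNames(
    c(s, mutate_seq(s, 3, 1), mutate_seq(s, 40, 2), random_dna(5, 100, 83)),
    sprintf("m%02d", 1:8))
  cs3 <- greedy_cluster(seqs, 0.9, "nucleotide")
  expect_equal(sum(cs3$sizes), length(seqs))
  expect_equal(sort(unique(cs3$membership$cluster)), seq_along(cs3$sizes))
})

test_that("both-strand clustering joins reverse-complement reads", {
  s <- random_dna(1, 120, seed = 84)
  seqs <- stats::setNames(c(s, revcomp(s)), c("fwd", "rev"))
  expect_equal(length(greedy_cluster(seqs, 0.9, "nucleotide",
                                     both_strands = TRUE)$sizes), 1L)
  expect_equal(length(greedy_cluster(seqs, 0.9, "nucleotide",
                                     both_strands = FALSE)$sizes), 2L)
})

test_that("greedy clustering matches the exhaustive all-pairs oracle", {
  s1 <- random_dna(1, 90, seed = 85)
  s2 <- random_dna(1, 90, seed = 86)
  seqs <- c(s1, mutate_seq(s1, 2, 11), mutate_seq(s1, 5, 12),
            substr(s1, 1, 86),
            s2, mutate_seq(s2, 3, 13), revcomp(mutate_seq(s2, 4, 14)),
            random_dna(8, 90, seed = 87))
  names(seqs) <- sprintf("q%02d", seq_along(seqs))
  for (thr in c(0.85, 0.95)) {
    got <- greedy_cluster(seqs, thr, "nucleotide", both_strands = TRUE,
                          word_size = 8)$membership
    want <- oracle_greedy_cluster(seqs, thr, both_strands = TRUE)
    got_part <- got$cluster[match(names(seqs), got$id)]
    expect_equal(as.integer(factor(got_part, unique(got_part))),
                 as.integer(factor(want, unique(want))))
  }
})

test_that("raising the identity threshold never decreases cluster count", {
  s <- random_dna(1, 100, seed = 88)
  seqs <- stats::setNames(
    c(s, vapply(1:9, function(i) mutate_seq(s, i * 4, 100 + i), character(1))),
    sprintf("t%02d", 1:10))
  counts <- vapply(c(0.6, 0.75, 0.9, 0.99), function(thr) {
    length(greedy_cluster(seqs, thr, "nucleotide")$sizes)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("protein clustering groups translated variants", {
  g <- small_genome(seed = 89)
  pool <- shear(g, 50, seed = 90)
  rd <- sample_reads(pool, g, 40, seed = 91, error_rate = 0, ambig_rate = 0,
                     dup_rate = 0)
  prots <- translate_longest_orf(stats::setNames(rd$reads$sequence,
                                                 rd$reads$id))
  expect_gt(length(prots), 0L)
  cs <- greedy_cluster(prots, 0.6, "protein", word_size = 4L)
  expect_equal(sum(cs$sizes), length(prots))
})

test_that("rarefaction counts eligible clusters with hypergeometric means", {
  # planted community: 20 clusters of varying size + small ineligible ones
  withr::with_seed(92, {
    sizes <- sample(21:80, 20, replace = TRUE)
  })
  cl <- c(rep(seq_along(sizes), times = sizes),
          rep(21:40, times = 3))  # 20 ineligible clusters of 3
  membership <- data.frame(id = sprintf("r%05d", seq_along(cl)), cluster = cl)
  N <- nrow(membership)
  efforts <- unique(c(round(N * c(0.02, 0.05, 0.1, 0.3)), N))
  rc <- rarefy(membership, efforts = efforts, n_replicates = 100,
               min_cluster_size = 21, seed = 93)
  want <- rarefaction_expected(membership, efforts, min_cluster_size = 21)
  se <- rc$sd_clusters / sqrt(rc$n_replicates)
  # rule of three: with zero observed spread over n replicates, deviations
  # up to 3/n are consistent with sampling
  expect_true(all(abs(rc$mean_clusters - want$expected_clusters) <=
                    pmax(3 * se, 3 / rc$n_replicates)))
  # full effort touches every eligible cluster, in every replicate
  expect_equal(rc$mean_clusters[length(efforts)], 20)
  expect_equal(rc$sd_clusters[length(efforts)], 0)
  # monotone in effort
  expect_true(all(diff(rc$mean_clusters) >= 0))
})

test_that("rarefaction caps excess efforts and handles one cluster", {
  membership <- data.frame(id = paste0("r", 1:50), cluster = 1L)
  expect_warning(rc <- rarefy(membership, efforts = c(10, 100),
                              n_replicates = 10, min_cluster_size = 21,
                              seed = 1), "capped")
  expect_true(all(rc$mean_clusters == 1))
})

test_that("singleton fractions hit both extremes and simulator truth", {
  s <- random_dna(1, 100, seed = 94)
  all_same <- stats::setNames(rep(s, 10), paste0("a", 1:10))
  expect_equal(singleton_fraction(all_same)$fraction, 0)

  all_diff <- stats::setNames(random_dna(8, 100, seed = 95), paste0("d", 1:8))
  expect_equal(singleton_fraction(all_diff)$fraction, 1)

  # simulator with planted duplicate structure: at zero sequencing error,
  # two reads are >= 90% identical iff their genome placements overlap by
  # at least 90% of the shorter read (same fragment is the 100% case), so
  # the truth table predicts the singleton set directly
  g <- generate_genome(gc_gradient(25, 2000), seed = 96)
  pool <- shear(g, 150, size_low = 150L, size_high = 250L, seed = 97)
  rd <- sample_reads(pool, g, 120, seed = 98, error_rate = 0,
                     ambig_rate = 0, dup_rate = 0.05)
  res <- singleton_fraction(stats::setNames(rd$reads$sequence,
                                            rd$reads$id))
  tt <- rd$truth
  n <- nrow(tt)
  linked <- logical(n)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      ov <- min(tt$end[i], tt$end[j]) - max(tt$start[i], tt$start[j])
      shorter <- min(tt$end[i] - tt$start[i], tt$end[j] - tt$start[j])
      if (ov >= 0.9 * shorter) linked[c(i, j)] <- TRUE
    }
  }
  truth_fraction <- mean(!linked)
  expect_lt(abs(res$fraction - truth_fraction), 0.02)
})
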