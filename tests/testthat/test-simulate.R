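test_that("generated genomes hit their GC targets deterministically", {
  g <- generate_genome(data.frame(length = 50000, gc = 0.5), seed = 5)
  expect_lt(abs(g$segments$gc_realized - 0.5), 0.03)
  expect_equal(g$length, 50000L)

  g2 <- generate_genome(data.frame(length = 50000, gc = 0.5), seed = 5)
  expect_identical(g2$sequence, g$sequence)

  # two-level landscape spans the isolate-like GC range in windows
  g3 <- generate_genome(data.frame(length = c(5000, 5000), gc = c(0.30, 0.55)),
                        seed = 2)
  tr <- window_stats(rep(1, g3$length), g3, 500, 250)
  expect_lt(min(tr$gc), 0.33)
  expect_gt(max(tr$gc), 0.52)

  expect_error(generate_genome(data.frame(length = 20, gc = 0.5)), "30 bp")
})

test_that("shearing respects the size range and uniform-length moments", {
  g <- small_genome()
  pool <- shear(g, 500, seed = 3)
  len <- pool$end - pool$start
  expect_true(all(len >= 400 & len <= 800))
  expect_true(all(pool$start >= 0 & pool$end <= g$length))

  fixed <- shear(g, 100, size_low = 500, size_high = 500, seed = 1)
  expect_true(all(fixed$end - fixed$start == 500))

  big <- shear(g, 10000, seed = 8)
  lens <- big$end - big$start
  se <- stats::sd(400:800) / sqrt(10000)
  expect_lt(abs(mean(lens) - 600), 3 * se)

  # fragment GC column matches direct recomputation from sequence
  sub <- substring(g$sequence, pool$start[1:20] + 1, pool$end[1:20])
  gc_direct <- vapply(strsplit(sub, ""), function(x) {
    mean(x %in% c("G", "C"))
  }, numeric(1))
  expect_equal(pool$gc[1:20], gc_direct)
})

test_that("amplification follows (1+e)^C and matches a per-cycle loop oracle", {
  g <- small_genome()
  pool <- shear(g, 200, seed = 4)

  none <- amplify(pool, amplification_model("flat", e_max = 0),
                  protocol_config(cycles = 30))
  expect_equal(none$copies, pool$copies)

  zero_cyc <- amplify(pool, amplification_model("bell"),
                      protocol_config(cycles = 0))
  expect_equal(zero_cyc$copies, pool$copies)

  doubling <- amplify(pool, amplification_model("flat", e_max = 1),
                      protocol_config(cycles = 3))
  expect_equal(doubling$copies, pool$copies * 8)

  bell <- amplification_model("bell", e_max = 0.9, g_opt = 0.47, sigma = 0.45)
  amp <- amplify(pool, bell, protocol_config(cycles = 25))
  expect_equal(amp$copies, oracle_amplify_loop(pool, bell, 25),
               tolerance = 1e-12)
})

test_that("reconditioning applies exactly the extra cycles and bounded bias shift", {
  prot_r <- protocol_config(cycles = 20, reconditioned = TRUE)
  prot_n <- protocol_config(cycles = 20, reconditioned = FALSE)
  expect_equal(effective_cycles(prot_r) - effective_cycles(prot_n), 3L)

  g <- small_genome()
  pool <- shear(g, 300, seed = 6)
  bell <- amplification_model("bell")
  bins <- seq(0.25, 0.65, by = 0.02)
  fb_r <- expected_fold_bias(bell, prot_r, pool, bins)
  fb_n <- expected_fold_bias(bell, prot_n, pool, bins)
  ratio <- fb_r$fold / fb_n$fold
  ratio <- ratio[!is.na(ratio)]
  expect_true(all(ratio <= (1 + bell$e_max)^3 + 1e-9))
  expect_true(all(ratio >= (1 + bell$e_max)^-3 - 1e-9))
})

test_that("expected fold bias is exact on constructed pools", {
  g <- small_genome()
  pool <- shear(g, 300, seed = 7)
  flat <- expected_fold_bias(amplification_model("flat", e_max = 0.8),
                             protocol_config(cycles = 25), pool,
                             bins = seq(0.2, 0.7, by = 0.05))
  expect_true(all(abs(flat$fold[!flat$undefined] - 1) < 1e-12))

  # two equal classes with growth factors 2 and 1 -> folds 4/3 and 2/3
  toy <- structure(data.frame(start = c(0L, 0L), end = c(100L, 100L),
                              gc = c(0.25, 0.75), copies = c(1, 1)),
                   genome_id = "toy", class = c("fragment_pool", "data.frame"))
  lin <- amplification_model("linear", e_max = 2/3)  # e = 2/3*g
  # pick cycles = 1: growth 1 + 2/3*gc -> 7/6 and 3/2; ratios differ, use
  # explicit two-bin expectation instead
  fb <- expected_fold_bias(lin, protocol_config(cycles = 1), toy,
                           bins = c(0, 0.5, 1))
  w <- 1 + 2/3 * c(0.25, 0.75)
  expect_equal(fb$fold, w / mean(w))

  expect_true(expected_fold_bias(lin, protocol_config(cycles = 1), toy,
                                 bins = c(0, 0.1, 0.5, 1))$undefined[1])
})

test_that("bell-model fold bias ratio grows weakly with cycle number", {
  g <- small_genome()
  pool <- shear(g, 400, seed = 9)
  bell <- amplification_model("bell")
  bins <- seq(0.25, 0.65, by = 0.02)
  ratios <- vapply(c(15, 18, 20, 25, 30), function(C) {
    fb <- expected_fold_bias(bell, protocol_config(cycles = C), pool, bins)
    max(fb$fold, na.rm = TRUE) / min(fb$fold, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(ratios) >= 0))
})

test_that("read sampling conserves counts, placements and abundances", {
  g <- small_genome()
  pool <- shear(g, 50, seed = 10)
  rd <- sample_reads(pool, g, 500, treatment = "t", seed = 1,
                     error_rate = 0, ambig_rate = 0, dup_rate = 0)
  expect_equal(nrow(rd$truth), 500L)
  expect_equal(nrow(rd$reads), 500L)
  expect_false(any(rd$truth$is_duplicate))
  # exact substrings of the genome at the truth placement
  plus <- which(rd$truth$strand == "+")[1:20]
  expect_equal(rd$reads$sequence[plus],
               substring(g$sequence, rd$truth$start[plus] + 1,
                         rd$truth$end[plus]))
  minus <- which(rd$truth$strand == "-")[1:20]
  expect_equal(rd$reads$sequence[minus],
               vapply(substring(g$sequence, rd$truth$start[minus] + 1,
                                rd$truth$end[minus]), revcomp, character(1),
                      USE.NAMES = FALSE))
  expect_equal(nchar(rd$reads$quality), nchar(rd$reads$sequence))

  # 9:1 copy ratio recovered within 3 SE
  toy <- structure(data.frame(start = c(0L, 1000L), end = c(500L, 1500L),
                              gc = c(0.4, 0.5), copies = c(9, 1)),
                   genome_id = g$id, class = c("fragment_pool", "data.frame"))
  big <- sample_reads(toy, g, 1e5, seed = 2, dup_rate = 0,
                      emit_sequences = FALSE)
  p_hat <- mean(big$truth$fragment == 1L)
  se <- sqrt(0.9 * 0.1 / 1e5)
  expect_lt(abs(p_hat - 0.9), 3 * se)

  # duplicate emission rate and truth completeness
  dup <- sample_reads(pool, g, 1e4, seed = 3, dup_rate = 0.1,
                      emit_sequences = FALSE)
  frac <- sum(dup$truth$is_duplicate) / 1e4
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / 1e4))
  expect_equal(anyDuplicated(dup$truth$read_id), 0L)

  expect_error(sample_reads(structure(transform(pool, copies = 0),
                                      class = class(pool),
                                      genome_id = "x"),
                            g, 10), "zero total copies")
})

test_that("unamplified control and flat amplification give matching read GC", {
  g <- small_genome()
  rejections <- 0L
  for (s in 1:20) {
    pool <- shear(g, 1000, seed = s)
    flat <- amplify(pool, amplification_model("flat", e_max = 0.9),
                    protocol_config(cycles = 20))
    a <- sample_reads(pool, g, 800, seed = s + 100, dup_rate = 0,
                      emit_sequences = FALSE)
    b <- sample_reads(flat, g, 800, seed = s + 200, dup_rate = 0,
                      emit_sequences = FALSE)
    gc_a <- (g$gc_cum[a$truth$end + 1] - g$gc_cum[a$truth$start + 1]) /
      (a$truth$end - a$truth$start)
    gc_b <- (g$gc_cum[b$truth$end + 1] - g$gc_cum[b$truth$start + 1]) /
      (b$truth$end - b$truth$start)
    if (stats::t.test(gc_a, gc_b)$p.value < 0.05) rejections <- rejections + 1L
  }
  # two-sample test should reject at about the nominal 5% rate
  expect_lte(rejections, 4L)
})
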