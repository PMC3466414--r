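test_that("trapezoid areas are exact for constant and linear differences", {
  x <- c(0, 0.5, 1)
  same <- data.frame(x = x, y = c(2, 3, 4))
  expect_equal(trapezoid_area(same, same)$area, 0)

  offset <- data.frame(x = x, y = same$y + 1)
  expect_equal(trapezoid_area(offset, same)$area, 1)

  lin <- data.frame(x = x, y = same$y + x)
  expect_equal(trapezoid_area(lin, same)$area, 0.5)

  expect_error(trapezoid_area(data.frame(x = 0, y = 1),
                              data.frame(x = 0, y = 2)), "shared")
})

test_that("trapezoid area matches pracma::trapz and converges at O(h^2)", {
  skip_if_not_installed("pracma")
  f <- function(x) x^2
  area_at <- function(n) {
    x <- seq(0, 1, length.out = n)
    trapezoid_area(data.frame(x = x, y = f(x)),
                   data.frame(x = x, y = 0))$area
  }
  x <- seq(0, 1, length.out = 11)
  expect_equal(area_at(11), pracma::trapz(x, f(x)))
  # halving h quarters the error against the closed-form 1/3
  e1 <- abs(area_at(11) - 1 / 3)
  e2 <- abs(area_at(21) - 1 / 3)
  expect_equal(e1 / e2, 4, tolerance = 0.05)

  # undefined points are excluded before intersecting grids
  a <- data.frame(x = c(0, 0.25, 0.5, 1), y = c(1, NA, 1, 1))
  b <- data.frame(x = c(0, 0.5, 0.75, 1), y = c(0, 0, 0, 0))
  ar <- trapezoid_area(a, b)
  expect_equal(ar$area, 1)
  expect_equal(ar$n_points, 3L)
  expect_gt(ar$masked_fraction, 0)
})

test_that("paired t matches the definitional formulas to 1e-9", {
  res <- paired_t(c(1, 2, 3), c(0, 0, 0))
  expect_equal(res$t_statistic, 3.4641, tolerance = 1e-4)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, 0.0742, tolerance = 1e-3)

  for (s in 1:5) {
    a <- withr::with_seed(s, stats::rnorm(20))
    b <- withr::with_seed(s + 50, stats::rnorm(20))
    want <- oracle_paired_t(a, b)
    got <- paired_t(a, b)
    expect_equal(got$t_statistic, want$t, tolerance = 1e-9)
    expect_equal(got$p_value, want$p, tolerance = 1e-9)
  }

  # explicit pairing map
  a <- c(1, 2, 3, 4)
  b <- c(4, 3, 2, 1)
  expect_equal(paired_t(a, b, pairing = c(4, 3, 2, 1))$p_value, 1)
})

test_that("degenerate paired tests are flagged with limiting p-values", {
  same <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_true(same$degenerate)
  expect_equal(same$p_value, 1)

  shift <- paired_t(c(2, 3, 4), c(1, 2, 3))
  expect_true(shift$degenerate)
  expect_equal(shift$p_value, 0)

  expect_error(paired_t(1, 1), "at least 2")
})

test_that("paired t is calibrated under a plain Gaussian null", {
  rej <- withr::with_seed(77, {
    sum(vapply(1:1000, function(i) {
      a <- stats::rnorm(15)
      b <- stats::rnorm(15)
      paired_t(a, b)$p_value < 0.05
    }, logical(1)))
  })
  expect_gte(rej / 1000, 0.03)
  expect_lte(rej / 1000, 0.07)
})

test_that("comparison plans reproduce the reference design's pair counts", {
  md <- la_treatments()
  iso <- md[md$sample_set == "isolate", ]

  p1 <- enumerate_pairs(iso, "recon_vs_nonrecon_all")
  expect_equal(nrow(p1$pairs), 14L)
  expect_true(all(c("cyc20B", "cyc20rB") %in% p1$exclusions$treatment))

  p2 <- enumerate_pairs(iso, "recon_vs_nonrecon_per_cycle", cycles = 15)
  expect_equal(nrow(p2$pairs), 3L)

  p3 <- enumerate_pairs(iso, "cycle_vs_cycle")
  expect_equal(nrow(p3$pairs), 6L)  # cycle-20 group dropped
  expect_false(any(grepl("cyc20$", c(p3$pairs$a, p3$pairs$b))))

  p4 <- enumerate_pairs(iso, "cycle_vs_cycle_split")
  expect_equal(nrow(p4$pairs), 12L)

  # all read counts below the floor -> empty plan, full exclusion list
  starved <- transform(iso, reads = 5)
  p5 <- enumerate_pairs(starved, "recon_vs_nonrecon_all")
  expect_equal(nrow(p5$pairs), 0L)
  expect_setequal(p5$exclusions$treatment, iso$treatment)

  expect_error(enumerate_pairs(iso, "bogus"), "unknown scheme")
})

test_that("plans never self-pair and are invariant to metadata row order", {
  md <- la_treatments()
  iso <- md[md$sample_set == "isolate", ]
  shuffled <- withr::with_seed(5, iso[sample.int(nrow(iso)), ])
  for (scheme in c("recon_vs_nonrecon_all", "cycle_vs_cycle",
                   "cycle_vs_cycle_split")) {
    a <- enumerate_pairs(iso, scheme)
    b <- enumerate_pairs(shuffled, scheme)
    expect_false(any(a$pairs$a == a$pairs$b))
    key <- function(p) sort(paste(pmin(p$pairs$a, p$pairs$b),
                                  pmax(p$pairs$a, p$pairs$b)))
    expect_equal(key(a), key(b))
  }
})

test_that("bias_test_suite: identical treatments give zero area, degenerate p = 1", {
  md <- la_treatments()
  iso <- md[md$sample_set == "isolate", ]
  plan <- enumerate_pairs(iso, "recon_vs_nonrecon_all")
  x <- seq(0, 1, by = 0.1)
  flatline <- data.frame(x = x, y = rep(0.3, length(x)))
  curves <- stats::setNames(
    rep(list(flatline), length(plan$members)), names(plan$members))
  res <- bias_test_suite(curves, plan)
  expect_equal(nrow(res), 14L)
  expect_true(all(res$area == 0))
  expect_true(all(res$degenerate))
  expect_true(all(res$p_value == 1))

  expect_error(bias_test_suite(curves[-1], plan), "missing curve")
})

test_that("flat-model reconditioning contrasts reject at no more than the nominal rate", {
  g <- small_genome()
  flat <- amplification_model("flat", e_max = 0.9)
  rejections <- 0L
  for (s in 1:20) {
    pool <- shear(g, 1500, seed = 600 + s)
    non <- amplify(pool, flat, protocol_config(cycles = 25))
    rec <- amplify(pool, flat, protocol_config(cycles = 25,
                                               reconditioned = TRUE))
    un_rd <- sample_reads(pool, g, 3000, seed = 700 + s, dup_rate = 0,
                          emit_sequences = FALSE)
    du <- compute_depth(un_rd$truth, g$length)
    dev_of <- function(p, seed) {
      rd <- sample_reads(p, g, 3000, seed = seed, dup_rate = 0,
                         emit_sequences = FALSE)
      d <- compute_depth(rd$truth, g$length)
      sf <- mean(c(sum(d), sum(du)))
      trk <- window_stats(scale_depth(d, sum(d), sf), g, 500, 500)
      tru <- window_stats(scale_depth(du, sum(du), sf), g, 500, 500)
      data.frame(x = trk$center, y = trk$mean_depth - tru$mean_depth)
    }
    a <- dev_of(rec, 800 + s)
    b <- dev_of(non, 900 + s)
    if (paired_t(a$y, b$y)$p_value < 0.05) rejections <- rejections + 1L
  }
  # flat efficiency: reconditioning's +3 cycles change nothing; the dense
  # windowing makes this contrast conservative, so nominal is an upper bound
  expect_lte(rejections, 3L)
})

test_that("group-scheme sides average member curves before testing", {
  md <- la_treatments()
  iso <- md[md$sample_set == "isolate", ]
  plan <- enumerate_pairs(iso, "cycle_vs_cycle")
  x <- seq(0, 1, by = 0.25)
  curves <- list()
  for (lab in names(plan$members)) {
    for (tr in plan$members[[lab]]) {
      # members of the same group straddle a common mean
      delta <- if (grepl("r", tr)) 0.1 else -0.1
      base <- as.numeric(sub("cyc", "", lab)) / 10
      curves[[tr]] <- data.frame(x = x, y = base + delta)
    }
  }
  res <- bias_test_suite(curves, plan)
  # averaged group curves are constants -> area equals |difference in base|
  want <- apply(plan$pairs, 1, function(p) {
    abs(as.numeric(sub("cyc", "", p["a"])) -
          as.numeric(sub("cyc", "", p["b"]))) / 10
  })
  expect_equal(res$area, unname(want), tolerance = 1e-12)
})
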