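#' Trapezoid area between two curves
#'
#' Intersects the defined x grids of two curves and integrates the absolute
#' difference `|y_a - y_b|` by the trapezoid rule over the shared grid.
#' Used to quantify the magnitude of read-depth and GC bias between an
#' amplified treatment and its reference.
#'
#' @param curve_a,curve_b Data frames with columns `x` and `y`; rows with
#'   `NA` y are treated as undefined and dropped before intersecting.
#' @return List of class `bias_area`: `area` (>= 0), `domain` (range of the
#'   shared grid), `n_points`, `masked_fraction` (fraction of the union of
#'   x values excluded from the shared grid).
#' @export
trapezoid_area <- function(curve_a, curve_b) {
  stopifnot(all(c("x", "y") %in% names(curve_a)),
            all(c("x", "y") %in% names(curve_b)))
  a <- curve_a[!is.na(curve_a$y), ]
  b <- curve_b[!is.na(curve_b$y), ]
  shared <- intersect(a$x, b$x)
  if (length(shared) < 2L) stop("fewer than 2 shared defined x points")
  shared <- sort(shared)
  ya <- a$y[match(shared, a$x)]
  yb <- b$y[match(shared, b$x)]
  d <- abs(ya - yb)
  h <- diff(shared)
  area <- sum(h * (d[-length(d)] + d[-1]) / 2)
  union_x <- union(a$x, b$x)
  structure(list(area = area, domain = range(shared),
                 n_points = length(shared),
                 masked_fraction = 1 - length(shared) / length(union_x)),
            class = "bias_area")
}

#' Paired two-tailed Student's t-test
#'
#' Standard paired t on the differences, two-tailed p from the t
#' distribution with n-1 degrees of freedom (delegated to
#' [stats::t.test()]). Zero-variance differences are degenerate for the t
#' statistic: the test is flagged and p reported as 1 when all differences
#' are exactly zero (indistinguishable samples) and as the limit 0
#' otherwise (constant nonzero shift).
#'
#' @param values_a,values_b Numeric vectors of equal length >= 2.
#' @param pairing Optional integer index map: element `i` of `values_a` is
#'   paired with `values_b[pairing[i]]`. Default identity.
#' @return List of class `paired_test`: `n_pairs`, `t_statistic`, `df`,
#'   `p_value`, `mean_difference`, `degenerate`.
#' @export
paired_t <- function(values_a, values_b, pairing = seq_along(values_a)) {
  stopifnot(length(values_a) == length(pairing),
            all(pairing %in% seq_along(values_b)))
  b <- values_b[pairing]
  n <- length(values_a)
  if (n < 2L) stop("need at least 2 pairs")
  d <- values_a - b
  if (stats::sd(d) == 0) {
    return(structure(list(n_pairs = n, t_statistic = NA_real_, df = n - 1L,
                          p_value = if (all(d == 0)) 1 else 0,
                          mean_difference = mean(d), degenerate = TRUE),
                     class = "paired_test"))
  }
  tt <- stats::t.test(values_a, b, paired = TRUE, alternative = "two.sided")
  structure(list(n_pairs = n, t_statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value,
                 mean_difference = unname(tt$estimate), degenerate = FALSE),
            class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf("paired t: n=%d t=%.4f df=%s p=%.4g%s\n", x$n_pairs,
              ifelse(is.na(x$t_statistic), NaN, x$t_statistic),
              format(x$df), x$p_value,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Enumerate treatment pairs for a comparison scheme
#'
#' Builds the pairwise comparison plan over a treatment metadata table
#' (columns `treatment`, `cycles`, `reconditioned`, `replicate`, `reads`).
#' Unamplified controls (`cycles` 0 or NA) are the bias reference and never
#' enter pairs; treatments with fewer than `min_reads` post-QC reads are
#' excluded (failed libraries), and any pair or cycle group touching an
#' excluded treatment is dropped.
#'
#' Schemes:
#' * `recon_vs_nonrecon_all` — every replicate-wise (same cycles, same
#'   replicate letter) reconditioned / non-reconditioned pair, across all
#'   cycle numbers;
#' * `recon_vs_nonrecon_per_cycle` — the replicate-wise pairs within one
#'   cycle number (argument `cycles`);
#' * `cycle_vs_cycle` — all pairs of cycle-number groups, reconditioned and
#'   non-reconditioned members combined;
#' * `cycle_vs_cycle_split` — as above but groups split by reconditioning
#'   status, pairing groups of like status only.
#'
#' @param metadata Treatment metadata data frame (see [la_treatments()]).
#' @param scheme Scheme name (above).
#' @param min_reads Post-QC read-count floor (default 100).
#' @param cycles Cycle number for `recon_vs_nonrecon_per_cycle`.
#' @return List of class `comparison_plan`: `scheme`, `pairs` (data frame
#'   `a`, `b`), `members` (named list: pair-side label -> treatment
#'   labels), `exclusions` (data frame `treatment`, `reason`).
#' @export
enumerate_pairs <- function(metadata, scheme, min_reads = 100L, cycles = NULL) {
  stopifnot(all(c("treatment", "cycles", "reconditioned", "replicate",
                  "reads") %in% names(metadata)))
  known <- c("recon_vs_nonrecon_all", "recon_vs_nonrecon_per_cycle",
             "cycle_vs_cycle", "cycle_vs_cycle_split")
  if (!scheme %in% known) stop("unknown scheme '", scheme, "'")
  md <- metadata
  amp <- !is.na(md$cycles) & md$cycles > 0
  low <- amp & md$reads < min_reads
  excl <- data.frame(treatment = character(0), reason = character(0))
  if (any(!amp)) {
    excl <- rbind(excl, data.frame(treatment = md$treatment[!amp],
                                   reason = "unamplified_reference"))
  }
  if (any(low)) {
    excl <- rbind(excl, data.frame(treatment = md$treatment[low],
                                   reason = sprintf("reads_below_%d", min_reads)))
  }
  md <- md[amp & !low, , drop = FALSE]
  md <- md[order(md$cycles, md$replicate, md$reconditioned), , drop = FALSE]

  members <- list()
  pairs <- data.frame(a = character(0), b = character(0))
  if (scheme %in% c("recon_vs_nonrecon_all", "recon_vs_nonrecon_per_cycle")) {
    if (scheme == "recon_vs_nonrecon_per_cycle") {
      if (is.null(cycles)) stop("scheme requires a 'cycles' argument")
      md <- md[md$cycles == cycles, , drop = FALSE]
    }
    key <- paste(md$cycles, md$replicate)
    for (k in unique(key)) {
      grp <- md[key == k, ]
      nr <- grp$treatment[!grp$reconditioned]
      rc <- grp$treatment[grp$reconditioned]
      if (length(nr) == 1L && length(rc) == 1L) {
        pairs <- rbind(pairs, data.frame(a = rc, b = nr))
        members[[rc]] <- rc
        members[[nr]] <- nr
      }
    }
  } else {
    # cycle groups; drop any cycle whose full design had a low-read library
    bad_cycles <- unique(metadata$cycles[low])
    md <- md[!md$cycles %in% bad_cycles, , drop = FALSE]
    split_by <- if (scheme == "cycle_vs_cycle") list(all = c(FALSE, TRUE))
                else list(nonrecon = FALSE, recon = TRUE)
    for (status in names(split_by)) {
      sub <- md[md$reconditioned %in% split_by[[status]], , drop = FALSE]
      cyc <- sort(unique(sub$cycles))
      labels <- if (scheme == "cycle_vs_cycle") paste0("cyc", cyc)
                else paste0("cyc", cyc, "_", status)
      for (i in seq_along(cyc)) {
        members[[labels[i]]] <- sub$treatment[sub$cycles == cyc[i]]
      }
      if (length(cyc) >= 2L) {
        cmb <- utils::combn(labels, 2L)
        pairs <- rbind(pairs, data.frame(a = cmb[1, ], b = cmb[2, ]))
      }
    }
  }
  rownames(pairs) <- NULL
  stopifnot(!any(pairs$a == pairs$b))
  structure(list(scheme = scheme, pairs = pairs, members = members,
                 exclusions = excl),
            class = "comparison_plan")
}

#' @export
print.comparison_plan <- function(x, ...) {
  cat(sprintf("comparison plan '%s': %d pairs (%d exclusions)\n",
              x$scheme, nrow(x$pairs), nrow(x$exclusions)))
  invisible(x)
}

#' Run paired tests and bias areas over a comparison plan
#'
#' For each planned pair, pairs the two sides' deviation-from-unamplified
#' curves point-wise on their shared defined grid, then computes a paired
#' two-tailed t-test across the grid points and the trapezoid area between
#' the curves. Group-level pair sides (cycle-group schemes) average their
#' member treatments' curves point-wise first.
#'
#' @param curves Named list: treatment label -> data frame with columns `x`
#'   (window center or GC bin midpoint) and `y` (deviation from the
#'   unamplified reference: signed depth difference or fold deviation).
#' @param plan A `comparison_plan` from [enumerate_pairs()].
#' @return Data frame, one row per pair: `scheme`, `a`, `b`, `n_points`,
#'   `area`, `t_statistic`, `p_value`, `degenerate`, plus Bonferroni-
#'   adjusted p (`p_bonferroni`).
#' @export
bias_test_suite <- function(curves, plan) {
  stopifnot(inherits(plan, "comparison_plan"))
  need <- unique(unlist(plan$members))
  miss <- setdiff(need, names(curves))
  if (length(miss) > 0L) {
    stop("missing curve(s) for treatment(s): ", paste(miss, collapse = ", "))
  }
  side_curve <- function(label) {
    mem <- plan$members[[label]]
    cs <- curves[mem]
    xs <- Reduce(intersect, lapply(cs, function(c) c$x[!is.na(c$y)]))
    ys <- rowMeans(matrix(vapply(cs, function(c) c$y[match(xs, c$x)],
                                 numeric(length(xs))),
                          nrow = length(xs)))
    data.frame(x = xs, y = ys)
  }
  rows <- lapply(seq_len(nrow(plan$pairs)), function(i) {
    a <- side_curve(plan$pairs$a[i])
    b <- side_curve(plan$pairs$b[i])
    shared <- sort(intersect(a$x, b$x))
    if (length(shared) < 2L) {
      stop("pair ", plan$pairs$a[i], " vs ", plan$pairs$b[i],
           ": fewer than 2 shared points")
    }
    ya <- a$y[match(shared, a$x)]
    yb <- b$y[match(shared, b$x)]
    ar <- trapezoid_area(a, b)
    tt <- paired_t(ya, yb)
    data.frame(scheme = plan$scheme, a = plan$pairs$a[i], b = plan$pairs$b[i],
               n_points = length(shared), area = ar$area,
               t_statistic = tt$t_statistic, p_value = tt$p_value,
               degenerate = tt$degenerate)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_value * nrow(out))
  out
}
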