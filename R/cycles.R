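#' Default input-mass to PCR-cycle lookup table
#'
#' The cycle-number ranges used for small-scale PCR titration of
#' linker-ligated DNA: more cycles are needed as input mass drops,
#' following the log-linear relationship between input DNA and the cycle
#' number required for amplification. Intervals are half-open downward so
#' that a boundary mass falls in the higher-mass (fewer-cycle) interval:
#' the titration aims for the lowest cycle number giving high molecular
#' weight product.
#'
#' @return Data frame with columns `mass_low`, `mass_high` (ng), `cycle_min`,
#'   `cycle_max`, ordered by decreasing mass.
#' @export
cycle_lookup <- function() {
  data.frame(
    mass_low  = c(1,    0.1,  0.01, 0),
    mass_high = c(10,   1,    0.1,  0.01),
    cycle_min = c(15L, 18L, 22L, 25L),
    cycle_max = c(20L, 25L, 30L, 35L)
  )
}

#' Recommend PCR cycle numbers for a given input DNA mass
#'
#' Looks up the cycle range for the interval containing `mass` and proposes
#' three candidate cycle numbers spanning it (the titration convention of
#' testing three cycle numbers): the range minimum, the rounded midpoint,
#' and the maximum.
#'
#' @param mass Input DNA mass in nanograms (> 0).
#' @param table Lookup table as returned by [cycle_lookup()].
#' @return List with `cycle_min`, `cycle_max`, `candidate_cycles` (integer
#'   vector of 3) and `above_range` (TRUE when `mass` exceeds the table's top
#'   interval, in which case the lowest-cycle range is returned with this
#'   warning flag set).
#' @examples
#' recommend_cycles(5)       # 15-20 cycles
#' recommend_cycles(0.005)   # 5 pg: 25-35 cycles
#' @export
recommend_cycles <- function(mass, table = cycle_lookup()) {
  stopifnot(is.numeric(mass), length(mass) == 1L, mass > 0)
  above <- mass > max(table$mass_high)
  if (above) {
    row <- table[which.max(table$mass_high), ]
  } else {
    # half-open downward: [low, high) except the top interval, closed above
    hit <- which(mass >= table$mass_low &
                   (mass < table$mass_high | mass == max(table$mass_high)))
    row <- table[hit[1], ]
  }
  lo <- row$cycle_min
  hi <- row$cycle_max
  list(cycle_min = as.integer(lo),
       cycle_max = as.integer(hi),
       candidate_cycles = as.integer(c(lo, round((lo + hi) / 2), hi)),
       above_range = above)
}
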