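#' Hill-type fractional drug effect
#'
#' `E(d) = emax * d^h / (d^h + ic50^h)`: the fraction of the net growth rate
#' suppressed at dose `d`. `E(0) = 0`, `E(ic50) = emax / 2`.
#'
#' @param dose drug concentration (nM), vectorized, `>= 0`.
#' @param ic50 half-maximal concentration (nM).
#' @param hill Hill slope.
#' @param emax maximal fractional effect in `[0, 1]`.
#' @return numeric vector of effects in `[0, emax]`.
#' @examples
#' hillEffect(c(0, 50, 1e6), ic50 = 50, hill = 1)
#' @export
hillEffect <- function(dose, ic50, hill = 1, emax = 1) {
  stopifnot(all(dose >= 0), ic50 > 0, hill > 0, emax >= 0, emax <= 1)
  ifelse(dose == 0, 0, emax / (1 + (ic50 / dose)^hill))
}

## Expected count of one population at time t under dose d.
## Net rate model: log2 n(t)/n0 = (t/Td) * g * (1 - E) - deathRate * E * t / log(2)
## Feeders (Td = Inf) stay at n0; drug-insensitive populations have E = 0.
expectedPopulationCount <- function(pop, dose, time, media = NULL) {
  g <- 1
  shift <- 1
  if (!is.null(media)) {
    gm <- media@growthMultiplier
    if (!is.null(names(gm)) && pop@name %in% names(gm)) g <- gm[[pop@name]]
    else if (is.null(names(gm)) && length(gm) == 1L) g <- gm
    shift <- media@ic50Shift
  }
  E <- if (pop@drugSensitive)
    hillEffect(dose, pop@ic50 * shift, pop@hill, pop@emax) else 0
  growthExponent <- if (is.finite(pop@doublingTime))
    (time / pop@doublingTime) * g * (1 - E) else 0
  deathExponent <- pop@deathRate * E * time / log(2)
  pop@n0 * 2^(growthExponent - deathExponent)
}

#' Simulate per-population cell counts of one well
#'
#' Deterministic expectation under a net-exponential growth model with
#' multiplicative Hill inhibition of the growth rate, plus Poisson sampling
#' noise. Drug acts only on `drugSensitive` populations; irradiated feeders
#' (infinite doubling time) stay at their plated count in expectation.
#'
#' @param pops list of [PopulationParams-class] objects.
#' @param dose drug concentration, nM (`>= 0`).
#' @param time hours since treatment initiation (`>= 0`).
#' @param media optional [MediaScenario-class]; multiplies growth rates and
#'   shifts the operative IC50.
#' @param seed optional integer seed for the Poisson draw.
#' @return `data.frame` with columns `population`, `marker_positive`,
#'   `expected` (deterministic) and `sampled` (Poisson around expectation).
#' @examples
#' pops <- list(cancerPopulation(ic50 = 50), feederPopulation())
#' simulateWellCounts(pops, dose = 50, time = 96, seed = 1)
#' @export
simulateWellCounts <- function(pops, dose = 0, time = 0, media = NULL,
                               seed = NULL) {
  if (dose < 0) stop("'dose' must be >= 0")
  if (time < 0) stop("'time' must be >= 0")
  if (is(pops, "PopulationParams")) pops <- list(pops)
  expected <- vapply(pops, expectedPopulationCount, numeric(1),
                     dose = dose, time = time, media = media)
  draw <- function() stats::rpois(length(expected), expected)
  sampled <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  data.frame(
    population = vapply(pops, function(p) p@name, character(1)),
    marker_positive = vapply(pops, function(p) p@markerPositive, logical(1)),
    expected = expected,
    sampled = sampled,
    stringsAsFactors = FALSE
  )
}

#' Standard 12-point dilution series
#'
#' Three-fold serial dilution from a 3333.3 nM top dose, the layout used for
#' the drug plates the simulator emulates.
#'
#' @param top top dose, nM.
#' @param dilution fold-dilution between consecutive doses.
#' @param n number of doses.
#' @return numeric vector of doses, decreasing.
#' @examples
#' doseSeries()   # 3333.3, 1111.1, 370.4, ... nM
#' @export
doseSeries <- function(top = 3333.3, dilution = 3, n = 12) {
  stopifnot(top > 0, dilution > 1, n >= 1)
  top / dilution^(seq_len(n) - 1)
}
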