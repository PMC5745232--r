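## Sequential random placement with a minimum center-to-center separation,
## using a uniform grid for neighbour lookup. If a candidate cannot be placed
## after maxTry attempts the last candidate is accepted anyway (the requested
## number of cells is a hard contract; crowding is reported via an attribute).
placePoints <- function(n, lo, hi, minsep, centers = NULL, clusterSd = NULL,
                        maxTry = 60L, prior = NULL) {
  xs <- numeric(n)
  ys <- numeric(n)
  if (n == 0L) {
    out <- cbind(x = xs, y = ys)
    attr(out, "crowded") <- 0L
    return(out)
  }
  cs <- max(minsep, 1)
  ng <- ceiling((hi - lo) / cs) + 2L
  grid <- vector("list", ng * ng)
  crowded <- 0L
  nPrior <- 0L
  if (!is.null(prior) && nrow(prior)) {
    nPrior <- nrow(prior)
    xs <- c(prior[, 1], xs)
    ys <- c(prior[, 2], ys)
  }
  cellOf <- function(x, y) {
    cx <- min(max(floor((x - lo) / cs) + 1L, 1L), ng)
    cy <- min(max(floor((y - lo) / cs) + 1L, 1L), ng)
    c(cx, cy)
  }
  register <- function(i) {
    cc <- cellOf(xs[i], ys[i])
    key <- cc[1] + (cc[2] - 1L) * ng
    grid[[key]] <<- c(grid[[key]], i)
  }
  for (i in seq_len(nPrior)) register(i)
  for (i in seq_len(n) + nPrior) {
    ok <- FALSE
    for (k in seq_len(maxTry)) {
      if (is.null(centers)) {
        x <- stats::runif(1, lo, hi); y <- stats::runif(1, lo, hi)
      } else {
        j <- sample.int(nrow(centers), 1L)
        x <- min(max(stats::rnorm(1, centers[j, 1], clusterSd), lo), hi)
        y <- min(max(stats::rnorm(1, centers[j, 2], clusterSd), lo), hi)
      }
      cc <- cellOf(x, y)
      ok <- TRUE
      for (ix in max(1L, cc[1] - 1L):min(ng, cc[1] + 1L)) {
        for (iy in max(1L, cc[2] - 1L):min(ng, cc[2] + 1L)) {
          pts <- grid[[ix + (iy - 1L) * ng]]
          if (length(pts) &&
              any((xs[pts] - x)^2 + (ys[pts] - y)^2 < minsep^2)) {
            ok <- FALSE
            break
          }
        }
        if (!ok) break
      }
      if (ok) break
    }
    if (!ok) crowded <- crowded + 1L
    xs[i] <- x
    ys[i] <- y
    register(i)
  }
  out <- cbind(x = xs[seq_len(n) + nPrior], y = ys[seq_len(n) + nPrior])
  attr(out, "crowded") <- crowded
  out
}

#' Place cells of each population into the imaged area
#'
#' Draws cell positions, per-cell nucleus diameters, elongations and
#' orientations for every population of a well. Positions keep a minimum
#' center separation where geometrically feasible and stay inside an interior
#' margin so that whole cells lie in frame (one site covers the whole imaged
#' well area). Epithelial colonies can be emulated by Neyman-Scott clustering.
#' A drug-effect level can scale cell size upward, mimicking the enlarged
#' morphology of drug-treated cancer cells.
#'
#' @param counts named integer vector: cells to place per population; names
#'   must match `pops`.
#' @param pops list of [PopulationParams-class] objects (named or carrying
#'   matching `name` slots).
#' @param optics [OpticsParams-class]; defines the field geometry.
#' @param effect named numeric vector of drug-effect levels `E` in `[0, 1]`
#'   per population; diameters are scaled by `1 + sizeEffect * E`.
#' @param sizeEffect slope of the effect-to-diameter scaling (default 0.3).
#' @param clusterSd if non-`NULL`, epithelial (marker-positive) populations
#'   are placed in clusters with this Gaussian scatter (px).
#' @param minSeparation minimum center-to-center distance, px.
#' @param margin interior margin, px.
#' @param maxPacking error if total nominal nucleus area exceeds this
#'   fraction of the placeable area.
#' @param seed optional integer seed.
#' @return `data.frame` with columns `population`, `marker_positive`, `x`,
#'   `y` (pixel coordinates, 0-based, origin top-left), `diameter_px`,
#'   `elongation`, `angle`. Attribute `crowded` counts placements that gave
#'   up on the separation constraint.
#' @examples
#' pl <- placeCells(c(cancer = 10), list(cancerPopulation()), seed = 1)
#' nrow(pl)
#' @export
placeCells <- function(counts, pops, optics = OpticsParams(),
                       effect = NULL, sizeEffect = 0.3, clusterSd = NULL,
                       minSeparation = 9, margin = 16, maxPacking = 0.75,
                       seed = NULL) {
  if (any(counts < 0)) stop("'counts' must be >= 0")
  popNames <- vapply(pops, function(p) p@name, character(1))
  names(pops) <- popNames
  unknown <- setdiff(names(counts), popNames)
  if (length(unknown))
    stop("counts given for unknown population(s): ",
         paste(unknown, collapse = ", "))
  sz <- optics@imageSize
  lo <- margin + 1
  hi <- sz - margin
  area <- (hi - lo)^2
  nomArea <- sum(vapply(names(counts), function(nm) {
    counts[[nm]] * pi * (pops[[nm]]@morphology$nucleusDiameterMean / 2)^2
  }, numeric(1)))
  if (nomArea / area > maxPacking)
    stop(sprintf(
      "requested density %.2f exceeds the packing limit %.2f of the imaged area",
      nomArea / area, maxPacking))

  build <- function() {
    rows <- vector("list", length(counts))
    crowded <- 0L
    placed <- NULL  # occupied positions across populations
    for (k in seq_along(counts)) {
      nm <- names(counts)[k]
      n <- as.integer(counts[[nm]])
      if (n == 0L) next
      pop <- pops[[nm]]
      centers <- NULL
      if (!is.null(clusterSd) && pop@markerPositive && n >= 10L) {
        nc <- max(1L, round(n / 10))
        centers <- cbind(stats::runif(nc, lo, hi), stats::runif(nc, lo, hi))
      }
      pts <- placePoints(n, lo, hi, minSeparation, centers, clusterSd,
                         prior = placed)
      crowded <- crowded + attr(pts, "crowded")
      placed <- rbind(placed, pts)
      E <- if (!is.null(effect) && nm %in% names(effect)) effect[[nm]] else 0
      dia <- pmax(pop@morphology$nucleusDiameterMean / 2,
                  stats::rnorm(n, pop@morphology$nucleusDiameterMean,
                               pop@morphology$nucleusDiameterSd)) *
        (1 + sizeEffect * E)
      elong <- min(1.15, max(1, sqrt(pop@morphology$elongation)))
      rows[[k]] <- data.frame(
        population = nm, marker_positive = pop@markerPositive,
        x = pts[, 1] - 1, y = pts[, 2] - 1,  # 0-based pixel coordinates
        diameter_px = dia,
        elongation = rep(elong, n),
        angle = stats::runif(n, 0, pi),
        stringsAsFactors = FALSE)
    }
    rows <- Filter(Negate(is.null), rows)
    out <- if (length(rows))
      do.call(rbind, c(rows, list(make.row.names = FALSE)))
    else
      data.frame(population = character(), marker_positive = logical(),
                 x = numeric(), y = numeric(), diameter_px = numeric(),
                 elongation = numeric(), angle = numeric())
    attr(out, "crowded") <- crowded
    out
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}
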