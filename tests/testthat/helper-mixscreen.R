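## Greedy nearest-neighbour matching of detections to ground-truth positions.
## A truth cell is matched when an unclaimed detection lies within `radius`
## px (0.7x a nucleus diameter: centroids of partially merged pairs shift).
matchCells <- function(truthXY, detXY, radius = 7) {
  hit <- rep(NA_integer_, nrow(truthXY))
  if (!nrow(detXY)) return(hit)
  used <- rep(FALSE, nrow(detXY))
  r2 <- radius^2
  for (i in seq_len(nrow(truthXY))) {
    dd <- (detXY[, 1] - truthXY[i, 1])^2 + (detXY[, 2] - truthXY[i, 2])^2
    dd[used] <- Inf
    j <- which.min(dd)
    if (length(j) && dd[j] < r2) {
      hit[i] <- j
      used[j] <- TRUE
    }
  }
  hit
}

## Counts-level plate: simulate sampled well counts for a drug-plate layout
## (no images), honouring the quadrupling endpoint for the assay duration.
simCountPlate <- function(pops, seed, doses = doseSeries(), replicates = 4,
                          hours = 96, media = NULL) {
  map <- plateLayout("drug", doses = doses, replicates = replicates)
  wt <- do.call(rbind, lapply(seq_len(nrow(map)), function(i) {
    tw <- if (map$plate_role[i] == "day0") 0 else hours
    cnt <- simulateWellCounts(pops, dose = map$dose_nM[i], time = tw,
                              media = media,
                              seed = (seed * 1000L + i) %% 2147483600L)
    data.frame(well = map$well[i],
               n_positive = sum(cnt$sampled[cnt$marker_positive]),
               n_negative = sum(cnt$sampled[!cnt$marker_positive]),
               n_total = sum(cnt$sampled),
               stringsAsFactors = FALSE)
  }))
  list(map = map, wells = wt)
}

## Brute-force two-sided Fisher p by explicit enumeration of all tables with
## the observed margins, probabilities from multinomial coefficients
## (independent of the package's dhyper-based path).
bruteFisherP <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b
  c1 <- a + c
  logp <- function(x) {
    lchoose(r1, x) + lchoose(n - r1, c1 - x) - lchoose(n, c1)
  }
  support <- max(0, r1 + c1 - n):min(r1, c1)
  lp <- vapply(support, logp, numeric(1))
  pObs <- exp(logp(a))
  sum(exp(lp)[exp(lp) <= pObs * (1 + 1e-7)])
}
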