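#' Day-0 baseline counts
#'
#' Mean and dispersion of the positive and negative populations across the
#' day-0 replicate wells of a plate.
#'
#' @param wellTable per-well count table (from [quantifyPlate()]).
#' @param plateMap plate map with a `plate_role` column.
#' @return `data.frame` with one row per population (`positive`,
#'   `negative`): `mean`, `sd`, `n`. With a single day-0 well the `sd` is
#'   `NA` and attribute `singleWell` is `TRUE`.
#' @examples
#' wt <- data.frame(well = c("A1", "A2"), n_total = c(300, 310),
#'                  n_positive = c(250, 254), n_negative = c(50, 56))
#' pm <- data.frame(well = c("A1", "A2"), plate_role = "day0")
#' baselineCounts(wt, pm)
#' @export
baselineCounts <- function(wellTable, plateMap) {
  d0 <- plateMap$well[plateMap$plate_role == "day0"]
  w <- wellTable[wellTable$well %in% d0, , drop = FALSE]
  if (!nrow(w)) stop("no day-0 wells found on this plate")
  out <- data.frame(
    population = c("positive", "negative"),
    mean = c(mean(w$n_positive), mean(w$n_negative)),
    sd = if (nrow(w) > 1) c(stats::sd(w$n_positive), stats::sd(w$n_negative))
         else c(NA_real_, NA_real_),
    n = nrow(w),
    stringsAsFactors = FALSE
  )
  attr(out, "singleWell") <- nrow(w) == 1L
  out
}

#' Endpoint decision: has the cancer population quadrupled?
#'
#' Growth plates are monitored until the marker-positive (cancer) population
#' of untreated wells reaches `foldThreshold` times the day-0 baseline --
#' approximately two doublings -- at which point the drug plate is fixed.
#'
#' @param times timepoints in hours, strictly increasing.
#' @param counts untreated-well positive counts at those timepoints (condition
#'   means).
#' @param baseline day-0 positive count (> 0).
#' @param foldThreshold required fold change (default 4).
#' @return list with `reached` (logical), `time` (first qualifying timepoint,
#'   `NA` if not reached) and `index`.
#' @examples
#' checkEndpoint(c(24, 48, 72), c(400, 700, 1010), baseline = 250)
#' @export
checkEndpoint <- function(times, counts, baseline, foldThreshold = 4) {
  if (!(baseline > 0)) stop("baseline must be > 0")
  if (length(times) != length(counts))
    stop("'times' and 'counts' lengths differ")
  if (is.unsorted(times, strictly = TRUE))
    stop("'times' must be strictly increasing")
  hit <- which(counts >= foldThreshold * baseline)
  if (!length(hit))
    return(list(reached = FALSE, time = NA_real_, index = NA_integer_))
  list(reached = TRUE, time = times[hit[1]], index = hit[1])
}

#' Normalize per-well counts into dose series
#'
#' Aggregates replicate wells into condition means (mean +/- SD, n) per
#' (drug, dose, population) and normalizes: `percent_highest` divides each
#' condition mean by the largest condition mean of the same drug and
#' population (x100); `fold_of_day0` divides by the day-0 baseline of the
#' population. Vehicle wells are included as the dose-0 condition of every
#' drug.
#'
#' @param wellTable per-well count table.
#' @param plateMap plate map.
#' @param mode `"percent_highest"` or `"fold_of_day0"`.
#' @param baseline day-0 baselines (from [baselineCounts()]); required for
#'   `fold_of_day0`.
#' @return `data.frame`: `drug`, `dose_nM`, `population`, `mean`, `sd`, `n`,
#'   `value` (the normalized response).
#' @export
normalizeResponse <- function(wellTable, plateMap,
                              mode = c("percent_highest", "fold_of_day0"),
                              baseline = NULL) {
  mode <- match.arg(mode)
  m <- merge(wellTable, plateMap, by = "well")
  drugs <- unique(m$drug[m$plate_role == "drug"])
  out <- list()
  for (dr in drugs) {
    sub <- m[(m$plate_role == "drug" & m$drug == dr) |
               m$plate_role == "vehicle", , drop = FALSE]
    for (popCol in c("n_positive", "n_negative")) {
      pop <- sub("n_", "", popCol)
      agg <- stats::aggregate(sub[[popCol]], by = list(dose_nM = sub$dose_nM),
                              FUN = function(v) c(mean = mean(v),
                                                  sd = stats::sd(v),
                                                  n = length(v)))
      cond <- data.frame(drug = dr, dose_nM = agg$dose_nM, population = pop,
                         mean = agg$x[, "mean"], sd = agg$x[, "sd"],
                         n = agg$x[, "n"], stringsAsFactors = FALSE)
      if (mode == "percent_highest") {
        ref <- max(cond$mean)
        if (ref <= 0)
          stop("all-zero counts: percent_highest normalization undefined")
        cond$value <- 100 * cond$mean / ref
      } else {
        if (is.null(baseline)) stop("fold_of_day0 requires 'baseline'")
        b <- baseline$mean[baseline$population == pop]
        if (!length(b) || !(b > 0))
          stop("no positive day-0 baseline for population ", pop)
        cond$value <- cond$mean / b
      }
      out[[length(out) + 1L]] <- cond
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
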