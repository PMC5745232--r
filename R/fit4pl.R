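#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' `f(d) = bottom + (top - bottom) / (1 + (d / ic50)^hill)`
#' to a dose series. Replicate observations are aggregated to condition
#' means and fitted unweighted by default: with quadruplicate wells the
#' replicate SDs are so noisy (chi distribution, 3 df) that inverse-variance
#' weights destabilize partial curves; `weighted = TRUE` enables `1/SD^2`
#' condition weights when every condition has a usable SD. The IC50 is fitted on the log scale
#' with initialization top = max mean, bottom = min mean, hill = 1 and the
#' IC50 started at the interpolated half-response dose, and is bounded within
#' `[min dose / 10, max dose * 10]`. Dose-0 controls enter the residuals as
#' the top-anchoring condition (`f(0) = top` exactly). A failed or
#' degenerate optimization returns `converged = FALSE`, never an error.
#'
#' @param dose doses in nM (>= 0; at least 4 distinct positive doses).
#' @param response responses (counts or normalized), same length.
#' @param drug,population labels stored in the result.
#' @param weighted use inverse-variance condition weights when available?
#' @param bottomAnchor optional known bottom asymptote (response units). In a
#'   growth assay with a day-0 plate, a fully growth-arrested population sits
#'   at the day-0 count, so the bottom of a cytostatic response is known in
#'   advance. The anchor is engaged only for partial curves -- series that
#'   traverse less than 80% of the span between the top response and the
#'   anchor, so that their own lower shoulder is not identified by the data;
#'   a free four-parameter fit of such curves wanders along the
#'   shallow-slope/deep-bottom ridge. Complete curves (including cytotoxic
#'   ones dropping below the anchor) keep the free bottom (see
#'   [fitReport()]).
#' @return a [DRFit-class].
#' @examples
#' d <- rep(doseSeries(), each = 4)
#' r <- 1000 / (1 + d / 50) + rnorm(length(d), 0, 10)
#' fit4PL(d, r)
#' @export
fit4PL <- function(dose, response, drug = "drug", population = "positive",
                   weighted = FALSE, bottomAnchor = NULL) {
  stopifnot(length(dose) == length(response))
  if (any(dose < 0)) stop("doses must be >= 0")
  if (any(response < 0)) stop("responses must be >= 0")
  fail <- function(msg) new("DRFit", drug = drug, population = population,
                            bottom = NA_real_, top = NA_real_,
                            hill = NA_real_, ic50 = NA_real_,
                            ic50CI = c(NA_real_, NA_real_), converged = FALSE,
                            message = msg, residualSE = NA_real_, n = 0L)
  if (length(unique(dose[dose > 0])) < 4)
    return(fail("need at least 4 distinct positive doses"))
  agg <- stats::aggregate(response, by = list(dose = dose),
                          FUN = function(v) c(mean = mean(v),
                                              sd = stats::sd(v),
                                              n = length(v)))
  d <- agg$dose
  y <- agg$x[, "mean"]
  sdv <- agg$x[, "sd"]
  if (diff(range(y)) <= .Machine$double.eps * max(abs(y), 1))
    return(fail("no dose effect"))
  w <- rep(1, length(y))
  if (weighted && all(is.finite(sdv)) && all(sdv > 0)) w <- 1 / sdv^2
  pos <- d[d > 0]
  ## initialize the IC50 at the dose where the condition means cross the
  ## half-response level (log-interpolated); a fixed mid-range start misleads
  ## the optimizer when the transition sits near an end of the dose range
  startLic50 <- function(bottomRef) {
    ymid <- (max(y) + bottomRef) / 2
    dp <- d[d > 0]
    yp <- y[d > 0]
    o <- order(dp)
    dp <- dp[o]
    yp <- yp[o]
    j <- which(yp <= ymid)[1]
    if (is.na(j)) return(log(max(dp) * 2))   # partial curve: beyond range
    if (j == 1) return(log(dp[1]))
    frac <- (yp[j - 1] - ymid) / (yp[j - 1] - yp[j])
    log(dp[j - 1]) + frac * (log(dp[j]) - log(dp[j - 1]))
  }
  start <- list(bottom = min(y), top = max(y), hill = 1,
                lic50 = startLic50(min(y)))
  lower <- c(bottom = 0, top = .Machine$double.eps, hill = 0.1,
             lic50 = log(min(pos) / 10))
  upper <- c(bottom = Inf, top = Inf, hill = 10, lic50 = log(max(pos) * 10))
  ## note: for d = 0, log(d) = -Inf and exp(hill*(-Inf - lic50)) = 0, so the
  ## dose-0 condition anchors the top asymptote exactly, as intended.
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + exp(hill * (log(d) - lic50))),
      start = start, lower = lower, upper = upper, weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  ## With a known physical bottom (day-0 anchor), partial curves -- those
  ## traversing less than 80% of the physically available span, so their
  ## lower shoulder lies beyond the tested doses -- are refitted with the
  ## bottom fixed at the anchor: a free 4-parameter fit of a partial curve
  ## wanders along the shallow-hill/deep-bottom ridge. Complete curves keep
  ## the free bottom, which tracks genuine floors (including net death).
  anchored <- FALSE
  if (!is.null(bottomAnchor) && max(y) > bottomAnchor &&
      (max(y) - min(y)) < 0.8 * (max(y) - bottomAnchor)) {
    bottom <- bottomAnchor
    startA <- list(top = max(y), hill = 1, lic50 = startLic50(bottomAnchor))
    fitA <- tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + exp(hill * (log(d) - lic50))),
        start = startA,
        lower = lower[c("top", "hill", "lic50")],
        upper = upper[c("top", "hill", "lic50")], weights = w,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fitA)) {
      fit <- fitA
      anchored <- TRUE
    }
  }
  if (is.null(fit)) return(fail("optimizer failed"))
  cf <- stats::coef(fit)
  if (!"bottom" %in% names(cf)) cf <- c(cf, bottom = bottomAnchor)
  if (cf[["top"]] < cf[["bottom"]]) return(fail("inverted asymptotes"))
  se <- tryCatch(sqrt(diag(stats::vcov(fit)))[["lic50"]],
                 error = function(e) NA_real_)
  ic <- exp(cf[["lic50"]])
  ci <- if (is.finite(se)) exp(cf[["lic50"]] + c(-1.96, 1.96) * se)
        else c(NA_real_, NA_real_)
  new("DRFit", drug = drug, population = population,
      bottom = cf[["bottom"]], top = cf[["top"]], hill = cf[["hill"]],
      ic50 = ic, ic50CI = ci, converged = TRUE, message = "",
      residualSE = sqrt(sum(stats::resid(fit)^2 * w) /
                          max(1, length(y) - 4)),
      n = length(y))
}

#' Predict from a 4PL fit
#'
#' @param object a converged [DRFit-class].
#' @param dose doses (nM) at which to evaluate the fitted curve.
#' @return numeric vector of fitted responses.
#' @export
predict4PL <- function(object, dose) {
  stopifnot(is(object, "DRFit"))
  if (!object@converged) stop("cannot predict from an unconverged fit")
  object@bottom + (object@top - object@bottom) /
    (1 + (dose / object@ic50)^object@hill)
}

#' IC50 fold ratio between two fits
#'
#' @param fitA,fitB converged [DRFit-class] objects.
#' @return `ic50(fitA) / ic50(fitB)` (dimensionless).
#' @examples
#' \dontrun{ic50FoldRatio(crizotinibFit, ceritinibFit)  # e.g. ~14}
#' @export
ic50FoldRatio <- function(fitA, fitB) {
  if (!fitA@converged || !fitB@converged)
    stop("fold ratio requires two converged fits")
  fitA@ic50 / fitB@ic50
}

#' Bulk-viability surrogate signal
#'
#' Models a bulk ATP-luminescence readout as a weighted sum over all cells of
#' the well regardless of marker status: `signal = sum_k count_k * weight_k`.
#' Used to demonstrate why mixed cultures need per-population readouts: an
#' insensitive proliferating population compresses the dynamic range of the
#' bulk curve but leaves the marker-positive count curve untouched.
#'
#' @param wellTable per-well count table.
#' @param weights named numeric per-cell signal weights for `positive` and
#'   `negative` cells (> 0).
#' @return `data.frame` `well`, `signal`, labeled population `"bulk"`.
#' @export
bulkSurrogate <- function(wellTable, weights = c(positive = 1, negative = 1)) {
  if (!all(c("positive", "negative") %in% names(weights)))
    stop("weights must name 'positive' and 'negative'")
  if (any(weights <= 0)) stop("weights must be > 0")
  data.frame(well = wellTable$well,
             signal = wellTable$n_positive * weights[["positive"]] +
               wellTable$n_negative * weights[["negative"]],
             population = "bulk",
             stringsAsFactors = FALSE)
}

#' Slope test for flatness of a dose series
#'
#' Linear regression of the response on log10 dose; the series is called
#' flat when the 95% confidence interval of the slope covers zero. Used on
#' the marker-negative population, which should not respond to a
#' cancer-targeted drug.
#'
#' @param dose positive doses, nM.
#' @param response responses, same length.
#' @return list with `slope`, `ci` (length 2) and `flat` (logical).
#' @export
doseSlopeTest <- function(dose, response) {
  keep <- dose > 0
  fit <- stats::lm(response[keep] ~ log10(dose[keep]))
  ci <- stats::confint(fit)[2, ]
  list(slope = unname(stats::coef(fit)[2]), ci = unname(ci),
       flat = ci[1] <= 0 && ci[2] >= 0)
}
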