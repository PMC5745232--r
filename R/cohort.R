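## round half away from zero, the convention of the printed success-rate table
roundHalfUp <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Culture-establishment success rate
#'
#' @param finished number of finished cultures (`0 <= finished <= total`).
#' @param total number processed (> 0).
#' @param rounded round half-away-from-zero to integer percent, as printed
#'   in cohort summary tables?
#' @return percent successful (vectorized).
#' @examples
#' successRate(109, 373)        # 29.22252
#' successRate(109, 373, TRUE)  # 29
#' @export
successRate <- function(finished, total, rounded = FALSE) {
  if (any(total <= 0)) stop("'total' must be > 0")
  if (any(finished < 0) || any(finished > total))
    stop("need 0 <= finished <= total")
  p <- 100 * finished / total
  if (rounded) roundHalfUp(p) else p
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact test by full hypergeometric enumeration: with margins fixed, the
#' two-sided p-value is the sum of the probabilities of all tables whose
#' probability does not exceed that of the observed table (probability-mass
#' method, the convention of mainstream statistics tools). The odds ratio is
#' the sample odds ratio `(a*d)/(b*c)`; tables with zero cells are flagged
#' via `zeroCells` rather than silently continuity-corrected.
#'
#' @param a,b,c,d cell counts of the table `rbind(c(a, b), c(c, d))`
#'   (non-negative integers; at least one positive margin).
#' @return list with `p.value`, `odds.ratio`, `zeroCells` and `table`.
#' @examples
#' fisherExact2x2(3, 1, 1, 3)$p.value  # 34/70
#' fisherExact2x2(109, 264, 16, 88)$p.value  # < 0.01
#' @export
fisherExact2x2 <- function(a, b, c, d) {
  cnt <- c(a, b, c, d)
  if (any(cnt < 0)) stop("counts must be non-negative")
  if (any(cnt != round(cnt))) stop("counts must be integers")
  n <- sum(cnt)
  if (n == 0) stop("at least one margin must be positive")
  r1 <- a + b
  c1 <- a + c
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  pObs <- stats::dhyper(a, c1, n - c1, r1)
  ## relative tolerance guards against ties broken by floating-point error
  p <- sum(probs[probs <= pObs * (1 + 1e-7)])
  p <- min(p, 1)
  zero <- any(cnt == 0)
  orv <- (a * d) / (b * c)  # may be Inf or NaN when zeroCells
  list(p.value = p, odds.ratio = orv, zeroCells = zero,
       table = matrix(c(a, b, c, d), 2, byrow = TRUE))
}

#' Read and validate a cohort count table
#'
#' @param path CSV with columns `group`, `finished`, `failed`.
#' @return validated `data.frame` with added `total` and `percent`
#'   (raw) and `percent_rounded` columns.
#' @seealso [exampleCohortFile()] for the packaged tumor-type table.
#' @export
readCohortTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "finished", "failed")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("cohort table missing column(s): ", paste(miss, collapse = ", "))
  if (any(tab$finished < 0) || any(tab$failed < 0))
    stop("cohort counts must be non-negative")
  tab$total <- tab$finished + tab$failed
  tab$percent <- successRate(tab$finished, tab$total)
  tab$percent_rounded <- successRate(tab$finished, tab$total, rounded = TRUE)
  tab
}

#' Path to the packaged tumor-type cohort table
#'
#' Finished/failed culture counts per tumor type for a 568-specimen cohort,
#' as published for the assay this package reimplements.
#'
#' @return file path of the CSV.
#' @examples
#' readCohortTable(exampleCohortFile())
#' @export
exampleCohortFile <- function() {
  system.file("extdata", "cohort_success_rates.csv", package = "mixscreen",
              mustWork = TRUE)
}

#' Compare the success rates of two cohort groups
#'
#' Builds the finished/failed 2x2 table of the two groups and applies
#' [fisherExact2x2()].
#'
#' @param table cohort `data.frame` (see [readCohortTable()]).
#' @param groupA,groupB group labels present in `table$group`.
#' @return list with `groups`, `table` (2x2), `odds.ratio`, `p.value`,
#'   `zeroCells`.
#' @examples
#' tab <- readCohortTable(exampleCohortFile())
#' compareGroups(tab, "Lung", "Breast")$p.value  # < 0.01
#' @export
compareGroups <- function(table, groupA, groupB) {
  pick <- function(g) {
    i <- which(table$group == g)
    if (!length(i)) stop("unknown group label: ", g)
    table[i[1], ]
  }
  ra <- pick(groupA)
  rb <- pick(groupB)
  ft <- fisherExact2x2(ra$finished, ra$failed, rb$finished, rb$failed)
  list(groups = c(groupA, groupB), table = ft$table,
       odds.ratio = ft$odds.ratio, p.value = ft$p.value,
       zeroCells = ft$zeroCells)
}

#' Full cohort analysis: rates plus pairwise comparisons
#'
#' @param table cohort `data.frame` or CSV path.
#' @param comparisons list of 2-vectors of group labels; default compares
#'   every pair.
#' @return list with `rates` (the augmented table) and `comparisons`
#'   (`data.frame` of pairwise results).
#' @export
cohortAnalysis <- function(table, comparisons = NULL) {
  if (is.character(table)) table <- readCohortTable(table)
  if (!"total" %in% names(table)) {
    table$total <- table$finished + table$failed
    table$percent <- successRate(table$finished, table$total)
    table$percent_rounded <- successRate(table$finished, table$total, TRUE)
  }
  groups <- table$group
  if (is.null(comparisons)) {
    comparisons <- list()
    if (length(groups) > 1)
      for (i in seq_len(length(groups) - 1))
        for (j in seq(i + 1, length(groups)))
          comparisons[[length(comparisons) + 1L]] <- c(groups[i], groups[j])
  }
  comp <- do.call(rbind, lapply(comparisons, function(pr) {
    r <- compareGroups(table, pr[1], pr[2])
    data.frame(group_a = pr[1], group_b = pr[2],
               odds_ratio = r$odds.ratio, p_value = r$p.value,
               zero_cells = r$zeroCells, stringsAsFactors = FALSE)
  }))
  list(rates = table, comparisons = comp)
}
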