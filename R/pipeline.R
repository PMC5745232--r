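#' Fit every drug and population of a quantified plate
#'
#' For each drug on the plate, fits the 4PL curve to the marker-positive
#' condition means (vehicle wells as the dose-0 anchor), fits the
#' marker-negative series, tests the negative series for flatness, and
#' computes pairwise IC50 fold ratios between the converged positive-
#' population fits.
#'
#' @param wellTable per-well count table (from [quantifyPlate()] or
#'   simulated counts).
#' @param plateMap plate map.
#' @param normalization response scale handed to the fitter. The default
#'   `"log2"` fits `log2(count + 1)`: for a culture in exponential growth the
#'   drug acts on the growth rate, so the log2 count is exactly logistic in
#'   dose and the fitted midpoint estimates the IC50 without the downward
#'   bias a linear-count fit incurs over ~two doublings.
#'   `"percent_highest"` and `"none"` fit the linear scale.
#' @param day0Anchor when fitting on the log2 scale and the plate has day-0
#'   wells, pass the day-0 baseline to [fit4PL()] as the physical bottom
#'   asymptote of partial curves.
#' @return list per drug with elements `positive` and `negative`
#'   ([DRFit-class]), `negative_flat` (from [doseSlopeTest()]); plus
#'   `fold_ratios`, a `data.frame` of pairwise positive-fit IC50 ratios.
#' @export
fitReport <- function(wellTable, plateMap,
                      normalization = c("log2", "percent_highest", "none"),
                      day0Anchor = TRUE) {
  normalization <- match.arg(normalization)
  m <- merge(wellTable, plateMap, by = "well")
  drugs <- unique(m$drug[m$plate_role == "drug"])
  ## the day-0 plate pins down where a fully growth-arrested population sits;
  ## used as an upper bound on the bottom asymptote reference of log2-scale fits, which
  ## identifies curves whose lower shoulder lies above the top tested dose
  baseline <- NULL
  if (day0Anchor && normalization == "log2" &&
      any(plateMap$plate_role == "day0") &&
      any(wellTable$well %in% plateMap$well[plateMap$plate_role == "day0"]))
    baseline <- baselineCounts(wellTable, plateMap)
  out <- list(drugs = list())
  for (dr in drugs) {
    sub <- m[(m$plate_role == "drug" & m$drug == dr) |
               m$plate_role == "vehicle", , drop = FALSE]
    entry <- list()
    for (pop in c("positive", "negative")) {
      resp <- sub[[paste0("n_", pop)]]
      anchor <- NULL
      if (normalization == "log2") {
        resp <- log2(resp + 1)
        if (!is.null(baseline)) {
          b <- baseline$mean[baseline$population == pop]
          if (length(b) && b > 0) anchor <- log2(b + 1)
        }
      } else if (normalization == "percent_highest" && max(resp) > 0)
        resp <- 100 * resp / max(resp)
      entry[[pop]] <- fit4PL(sub$dose_nM, resp, drug = dr, population = pop,
                             bottomAnchor = anchor)
    }
    entry$negative_flat <- doseSlopeTest(sub$dose_nM, sub$n_negative)
    out$drugs[[dr]] <- entry
  }
  conv <- names(out$drugs)[vapply(out$drugs,
                                  function(e) e$positive@converged, logical(1))]
  fr <- list()
  if (length(conv) > 1)
    for (i in seq_len(length(conv) - 1))
      for (j in seq(i + 1, length(conv))) {
        fa <- out$drugs[[conv[i]]]$positive
        fb <- out$drugs[[conv[j]]]$positive
        fr[[length(fr) + 1L]] <- data.frame(
          drug_a = conv[i], drug_b = conv[j],
          fold = ic50FoldRatio(fa, fb), stringsAsFactors = FALSE)
      }
  out$fold_ratios <- if (length(fr))
    do.call(rbind, fr) else data.frame(drug_a = character(),
                                       drug_b = character(), fold = numeric())
  out
}

drFitToList <- function(f) {
  list(drug = f@drug, population = f@population, converged = f@converged,
       message = f@message, bottom = f@bottom, top = f@top, hill = f@hill,
       ic50_nM = f@ic50, ic50_ci = f@ic50CI, residual_se = f@residualSE,
       n_conditions = f@n)
}

#' Write a fit report to JSON
#'
#' @param report list from [fitReport()].
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
writeResults <- function(report, path) {
  ser <- list(
    drugs = lapply(report$drugs, function(e) list(
      positive = drFitToList(e$positive),
      negative = drFitToList(e$negative),
      negative_flat = e$negative_flat)),
    fold_ratios = report$fold_ratios)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

knownConfigKeys <- c("out_dir", "scenario", "doses", "replicates", "media",
                     "seed", "image_size", "noise_sd", "write_images",
                     "segmentation", "fold_threshold", "normalization")

#' Read and validate a run configuration
#'
#' A single YAML file drives an end-to-end run; unknown keys are rejected so
#' typos cannot silently change a run.
#'
#' @param path YAML file.
#' @return validated named list, with defaults filled in.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), knownConfigKeys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$seed)) stop("config must set a 'seed'")
  defaults <- list(scenario = "MGH051-1", doses = doseSeries(),
                   replicates = 4, media = "TCM_minus_E_I",
                   image_size = 512, noise_sd = 20, write_images = TRUE,
                   fold_threshold = 4, normalization = "log2")
  cfg <- utils::modifyList(defaults, cfg)
  cfg$doses <- as.numeric(unlist(cfg$doses))  # YAML sequences parse as lists
  cfg
}

#' Run the whole pipeline: simulate, quantify, fit, write
#'
#' Generates a synthetic plate for a named scenario, quantifies every well
#' from its images, fits all dose-response curves and writes `wells.csv`,
#' `cells.csv` and `results.json` next to the plate images. Intended as the
#' single-call interface for an end-to-end, seed-reproducible run.
#'
#' @param config list (see [readRunConfig()]) or path to a YAML config.
#' @param outDir output directory; overrides `config$out_dir`.
#' @return invisibly, the [fitReport()] list, with the quantified tables
#'   attached as attributes `wells` and `cells`.
#' @export
runScreen <- function(config, outDir = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  if (is.null(outDir)) outDir <- config$out_dir
  if (is.null(outDir)) stop("an output directory is required")
  optics <- OpticsParams(imageSize = config$image_size,
                         noiseSd = config$noise_sd)
  scen <- nsclcScenario(config$scenario)
  generatePlate(outDir, scen, doses = config$doses,
                replicates = config$replicates, media = config$media,
                optics = optics, seed = config$seed,
                writeImages = isTRUE(config$write_images))
  q <- quantifyPlate(outDir)
  utils::write.csv(q$wells, file.path(outDir, "wells.csv"), row.names = FALSE)
  utils::write.csv(q$cells, file.path(outDir, "cells.csv"), row.names = FALSE)
  map <- readPlateMap(outDir)
  rep <- fitReport(q$wells, map, normalization = config$normalization)
  writeResults(rep, file.path(outDir, "results.json"))
  attr(rep, "wells") <- q$wells
  attr(rep, "cells") <- q$cells
  invisible(rep)
}
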