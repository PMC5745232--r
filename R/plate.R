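## 384-well identifiers, row-major: A1..A24, B1..P24.
wellNames <- function(n) {
  stopifnot(n <= 384)
  rows <- rep(LETTERS[1:16], each = 24)
  cols <- rep(1:24, times = 16)
  paste0(rows, cols)[seq_len(n)]
}

#' Build a drug-plate layout
#'
#' One plate per assay: optional day-0 wells (fixed at treatment
#' initiation), vehicle control wells (dose 0 at assay end), and for every
#' drug a dose series in `replicates`-fold replication.
#'
#' @param drugs character vector of drug names.
#' @param doses numeric vector of doses (nM), e.g. [doseSeries()].
#' @param replicates wells per (drug, dose) condition.
#' @param nDay0,nVehicle numbers of day-0 and vehicle wells.
#' @param media media scenario label recorded per well.
#' @return `data.frame` with columns `well`, `plate_role`
#'   (`day0`/`vehicle`/`drug`), `drug`, `dose_nM`, `replicate`, `media`,
#'   `time_role` (`day0` wells are fixed at t = 0, all others at assay end).
#' @examples
#' nrow(subset(plateLayout("ceritinib"), plate_role == "drug"))  # 48
#' @export
plateLayout <- function(drugs, doses = doseSeries(), replicates = 4,
                        nDay0 = 4, nVehicle = 4, media = "TCM_minus_E_I") {
  if (!length(drugs)) stop("need at least one drug")
  if (!length(doses) || any(doses <= 0))
    stop("drug-plate doses must be a non-empty set of values > 0")
  rows <- list()
  if (nDay0 > 0)
    rows[[length(rows) + 1L]] <- data.frame(
      plate_role = "day0", drug = "none", dose_nM = 0,
      replicate = seq_len(nDay0), stringsAsFactors = FALSE)
  if (nVehicle > 0)
    rows[[length(rows) + 1L]] <- data.frame(
      plate_role = "vehicle", drug = "vehicle", dose_nM = 0,
      replicate = seq_len(nVehicle), stringsAsFactors = FALSE)
  for (dr in drugs)
    rows[[length(rows) + 1L]] <- data.frame(
      plate_role = "drug", drug = dr,
      dose_nM = rep(sort(doses, decreasing = TRUE), each = replicates),
      replicate = rep(seq_len(replicates), times = length(doses)),
      stringsAsFactors = FALSE)
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (nrow(out) > 384)
    stop("layout exceeds 384 wells; reduce drugs, doses or replicates")
  out$well <- wellNames(nrow(out))
  out$media <- media
  out[, c("well", "plate_role", "drug", "dose_nM", "replicate", "media")]
}

#' Published NSCLC biopsy-culture scenarios
#'
#' Ground-truth configurations for three ALK-translocated biopsy-culture
#' screens, with the reported per-drug IC50s (nM) as the simulator's truth:
#' MGH021-2 (ceritinib 90, crizotinib 1300), MGH051-1 (ceritinib 53,
#' crizotinib 60) and MGH092-1 (lorlatinib 2, crizotinib 166, ceritinib
#' 268). Each culture is plated at 250 cancer cells on ~500 irradiated
#' feeder fibroblasts per well.
#'
#' @param name scenario name.
#' @return list with elements `name`, `drugs` (named list of
#'   `list(ic50, hill, emax)`), `populations` (list of
#'   [PopulationParams-class]) and `assayHours`.
#' @examples
#' nsclcScenario("MGH051-1")$drugs$ceritinib$ic50  # 53
#' @export
nsclcScenario <- function(name = c("MGH021-2", "MGH051-1", "MGH092-1")) {
  name <- match.arg(name)
  truths <- list(
    "MGH021-2" = list(ceritinib = 90, crizotinib = 1300),
    "MGH051-1" = list(ceritinib = 53, crizotinib = 60),
    "MGH092-1" = list(lorlatinib = 2, crizotinib = 166, ceritinib = 268)
  )
  drugs <- lapply(truths[[name]], function(ic) list(ic50 = ic, hill = 1, emax = 1))
  list(name = name,
       drugs = drugs,
       populations = list(cancerPopulation(n0 = 250), feederPopulation(n0 = 500)),
       assayHours = NULL)  # fix at the >= 4x endpoint (two doublings)
}

## Per-well reproducible sub-seed derived from the master seed.
wellSeed <- function(seed, index) {
  (as.integer(seed) %% 100000L) * 10000L + index * 13L %% 10000L
}

#' Generate a complete synthetic plate on disk
#'
#' Simulates per-well population counts at the configured assay time (day-0
#' wells at t = 0), places and renders the cells, and writes per-well
#' single-channel grayscale TIFFs (`{well}_{site}_{channel}.tif`, channels
#' `nuclear` and `marker`), a plate map CSV, ground-truth CSVs (per-well
#' counts and per-cell records) and a manifest with the seed and a config
#' hash. Identical configurations and seeds reproduce identical outputs.
#'
#' @param dir output directory (created if missing).
#' @param scenario list as returned by [nsclcScenario()], or a custom list
#'   with the same elements.
#' @param doses dose series, nM.
#' @param replicates replicates per condition.
#' @param media a [MediaScenario-class] or scenario name.
#' @param optics [OpticsParams-class].
#' @param params placement options passed to [placeCells()] as needed.
#' @param seed master integer seed (required for reproducibility).
#' @param writeImages set `FALSE` to emit only the count-level ground truth
#'   and plate map (fast, for count-level studies).
#' @param sizeEffect drug-effect to cell-size coupling (see [placeCells()]).
#' @return invisibly, the plate map with a `ground_truth` attribute.
#' @export
generatePlate <- function(dir, scenario = nsclcScenario("MGH051-1"),
                          doses = doseSeries(), replicates = 4,
                          media = "TCM_minus_E_I", optics = OpticsParams(),
                          seed, writeImages = TRUE, sizeEffect = 0.3,
                          params = list()) {
  if (missing(seed)) stop("a master 'seed' is required")
  if (is.character(media)) media <- MediaScenario(media)
  if (is.null(scenario$drugs) || !length(scenario$drugs))
    stop("scenario must define at least one drug with an 'ic50'")
  for (d in scenario$drugs)
    if (is.null(d$ic50)) stop("every drug needs an 'ic50' entry")
  layout <- plateLayout(names(scenario$drugs), doses, replicates,
                        media = media@name)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pops <- scenario$populations
  tHours <- scenario$assayHours
  if (is.null(tHours)) {
    ## endpoint rule: fix the drug plate when the untreated cancer population
    ## has quadrupled (~two doublings), whatever its media-adjusted rate
    cancer <- Filter(function(p) p@markerPositive && is.finite(p@doublingTime),
                     pops)
    if (!length(cancer)) stop("no growing marker-positive population")
    g <- 1
    gm <- media@growthMultiplier
    if (!is.null(names(gm)) && cancer[[1]]@name %in% names(gm))
      g <- gm[[cancer[[1]]@name]]
    tHours <- 2 * cancer[[1]]@doublingTime / g
  }
  popNames <- vapply(pops, function(p) p@name, character(1))

  gtWell <- vector("list", nrow(layout))
  gtCells <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    rowi <- layout[i, ]
    tw <- if (rowi$plate_role == "day0") 0 else tHours
    ## instantiate drug-specific truth for sensitive populations
    popsi <- lapply(pops, function(p) {
      if (p@drugSensitive && rowi$plate_role == "drug") {
        d <- scenario$drugs[[rowi$drug]]
        p@ic50 <- d$ic50
        if (!is.null(d$hill)) p@hill <- d$hill
        if (!is.null(d$emax)) p@emax <- d$emax
      }
      p
    })
    sw <- wellSeed(seed, i)
    cnt <- simulateWellCounts(popsi, dose = rowi$dose_nM, time = tw,
                              media = media, seed = sw)
    cnt$well <- rowi$well
    cnt$time_h <- tw
    gtWell[[i]] <- cnt
    if (writeImages) {
      counts <- stats::setNames(cnt$sampled, cnt$population)
      eff <- vapply(popsi, function(p) {
        if (p@drugSensitive)
          hillEffect(rowi$dose_nM, p@ic50 * media@ic50Shift, p@hill, p@emax)
        else 0
      }, numeric(1))
      names(eff) <- popNames
      pl <- do.call(placeCells, c(
        list(counts = counts, pops = popsi, optics = optics, effect = eff,
             sizeEffect = sizeEffect, seed = sw + 1L), params))
      fi <- renderField(pl, optics, pops = popsi, well = rowi$well,
                        site = 1L, seed = sw + 2L)
      writeFieldImage(fi, dir)
      pl$well <- rowi$well
      pl$site <- 1L
      gtCells[[i]] <- pl[, c("well", "site", "population", "marker_positive",
                             "x", "y", "diameter_px")]
    }
  }
  gt <- do.call(rbind, c(gtWell, list(make.row.names = FALSE)))
  gt <- gt[, c("well", "time_h", "population", "marker_positive",
               "expected", "sampled")]
  utils::write.csv(layout, file.path(dir, "plate_map.csv"), row.names = FALSE)
  utils::write.csv(gt, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  if (writeImages) {
    cells <- do.call(rbind, c(gtCells, list(make.row.names = FALSE)))
    utils::write.csv(cells, file.path(dir, "ground_truth_cells.csv"),
                     row.names = FALSE)
  }
  manifest <- list(
    seed = as.integer(seed),
    scenario = scenario$name,
    drugs = lapply(scenario$drugs, function(d) d["ic50"]),
    doses = doses, replicates = replicates, media = media@name,
    assay_hours = tHours, image_size = optics@imageSize,
    images = writeImages)
  manifestJson <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA)
  writeLines(manifestJson, file.path(dir, "manifest.json"))
  hash <- tools::md5sum(file.path(dir, "manifest.json"))
  writeLines(unname(hash), file.path(dir, "manifest.md5"))
  attr(layout, "ground_truth") <- gt
  invisible(layout)
}

#' Write / read single-channel field TIFFs
#'
#' Images are stored one channel per file as `{well}_{site}_{channel}.tif`
#' (channels `nuclear`, `marker`), grayscale, at the bit depth of the field.
#'
#' @param fi a [FieldImage-class].
#' @param dir plate directory.
#' @return `writeFieldImage`: invisibly, the file paths;
#'   `readFieldImage`: a [FieldImage-class].
#' @rdname fieldImageIO
#' @export
writeFieldImage <- function(fi, dir) {
  maxv <- 2^fi@bitDepth - 1
  paths <- character(2)
  for (ch in c("nuclear", "marker")) {
    img <- slot(fi, ch)
    p <- file.path(dir, sprintf("%s_%d_%s.tif", fi@well, fi@site, ch))
    tiff::writeTIFF(img / maxv, p, bits.per.sample = fi@bitDepth)
    paths[if (ch == "nuclear") 1 else 2] <- p
  }
  invisible(paths)
}

#' @param well,site well id and site index to read.
#' @rdname fieldImageIO
#' @export
readFieldImage <- function(dir, well, site = 1L, bitDepth = 16L) {
  maxv <- 2^bitDepth - 1
  get <- function(ch) {
    p <- file.path(dir, sprintf("%s_%d_%s.tif", well, site, ch))
    if (!file.exists(p))
      stop(sprintf("missing %s channel for well %s site %d: %s",
                   ch, well, site, p))
    tiff::readTIFF(p) * maxv
  }
  FieldImage(nuclear = get("nuclear"), marker = get("marker"),
             well = well, site = site, bitDepth = bitDepth)
}

#' @param bitDepth stored bit depth.
#' @rdname fieldImageIO
#' @export
readPlateMap <- function(dir) {
  p <- file.path(dir, "plate_map.csv")
  if (!file.exists(p)) stop("no plate_map.csv in ", dir)
  map <- utils::read.csv(p, stringsAsFactors = FALSE)
  need <- c("well", "plate_role", "drug", "dose_nM", "replicate")
  miss <- setdiff(need, names(map))
  if (length(miss))
    stop("malformed plate map, missing column(s): ",
         paste(miss, collapse = ", "))
  map
}

#' Quantify every well of a plate directory
#'
#' Reads the plate map and per-well TIFFs and runs the full scoring pipeline.
#'
#' @param dir plate directory written by [generatePlate()] (or any directory
#'   following the same naming convention).
#' @param params [SegmentationParams-class].
#' @param sites sites per well.
#' @param wells optional subset of wells.
#' @return list with `wells` (per-well count table: `well`, `n_total`,
#'   `n_positive`, `n_negative`, `n_sites`) and `cells` (per-cell table).
#' @export
quantifyPlate <- function(dir, params = SegmentationParams(), sites = 1L,
                          wells = NULL) {
  map <- readPlateMap(dir)
  if (!is.null(wells)) map <- map[map$well %in% wells, , drop = FALSE]
  resW <- vector("list", nrow(map))
  resC <- vector("list", nrow(map))
  for (i in seq_len(nrow(map))) {
    fields <- lapply(seq_len(sites), function(s)
      readFieldImage(dir, map$well[i], s))
    q <- quantifyWell(fields, params)
    resW[[i]] <- q$wellCount
    resC[[i]] <- q$cells
  }
  list(wells = do.call(rbind, c(resW, list(make.row.names = FALSE))),
       cells = do.call(rbind, c(resC, list(make.row.names = FALSE))))
}
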