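#' @import methods
NULL

## Central parameter and result containers. Everything downstream (placement,
## rendering, segmentation, fitting) consumes these; validity methods enforce
## the biological/physical constraints once, at construction time.

#' Parameters of one cell population in a simulated well
#'
#' Describes a population of a mixed culture: its growth kinetics, its
#' response to drug, whether it expresses the epithelial CK8/18 marker, and
#' its morphology in rendered images. Irradiated feeder layers are encoded
#' with an infinite doubling time; stromal fibroblasts are marker-negative
#' and drug-insensitive.
#'
#' @slot name population label, e.g. `"cancer"`, `"feeder"`, `"fibroblast"`.
#' @slot n0 initial cells per well at plating.
#' @slot doublingTime population doubling time in hours; `Inf` for
#'   non-dividing (irradiated) cells.
#' @slot drugSensitive does drug act on this population?
#' @slot ic50 true half-maximal concentration of the drug effect, nM.
#' @slot hill true Hill slope (dimensionless, > 0).
#' @slot emax maximal fractional suppression of the growth rate in `[0, 1]`;
#'   1 means complete growth arrest at saturating dose.
#' @slot deathRate optional additional death rate (per hour) recruited in
#'   proportion to the drug effect, producing counts that fall below the
#'   day-0 baseline (cytotoxic rather than cytostatic curves).
#' @slot markerPositive does the population stain for CK8/18?
#' @slot morphology named list with elements `nucleusDiameterMean`,
#'   `nucleusDiameterSd` (pixels), `cytoplasmScale` (cytoplasm radius as a
#'   multiple of the nucleus radius) and `elongation` (nucleus axis ratio,
#'   1 = round).
#'
#' @seealso [PopulationParams()], [simulateWellCounts()]
#' @name PopulationParams-class
#' @rdname PopulationParams-class
#' @exportClass PopulationParams
setClass("PopulationParams",
  representation(
    name = "character",
    n0 = "numeric",
    doublingTime = "numeric",
    drugSensitive = "logical",
    ic50 = "numeric",
    hill = "numeric",
    emax = "numeric",
    deathRate = "numeric",
    markerPositive = "logical",
    morphology = "list"
  )
)

setValidity("PopulationParams", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (object@n0 < 0) msg <- c(msg, "'n0' must be >= 0")
  if (!(object@doublingTime > 0))
    msg <- c(msg, "'doublingTime' must be > 0 (may be Inf)")
  if (object@ic50 <= 0) msg <- c(msg, "'ic50' must be > 0")
  if (object@hill <= 0) msg <- c(msg, "'hill' must be > 0")
  if (object@emax < 0 || object@emax > 1)
    msg <- c(msg, "'emax' must lie in [0, 1]")
  if (object@deathRate < 0) msg <- c(msg, "'deathRate' must be >= 0")
  need <- c("nucleusDiameterMean", "nucleusDiameterSd", "cytoplasmScale",
            "elongation")
  if (!all(need %in% names(object@morphology)))
    msg <- c(msg, paste("morphology must contain:", paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct population parameters
#'
#' @param name population label.
#' @param n0 initial cells per well.
#' @param doublingTime doubling time in hours (`Inf` = non-dividing feeder).
#' @param drugSensitive logical; does the drug act on this population?
#' @param ic50,hill,emax true Hill dose-effect parameters (nM, unitless,
#'   fraction in `[0, 1]`). Ignored downstream when `drugSensitive = FALSE`
#'   but still validated.
#' @param deathRate effect-proportional death rate per hour (default 0,
#'   i.e. purely cytostatic drug action).
#' @param markerPositive logical; CK8/18 expression.
#' @param morphology named list; see [PopulationParams-class]. Missing
#'   entries are filled with defaults.
#'
#' @return a [PopulationParams-class] object.
#' @examples
#' cancerPopulation(ic50 = 53)
#' PopulationParams("feeder", n0 = 500, doublingTime = Inf,
#'                  drugSensitive = FALSE, markerPositive = FALSE)
#' @export
PopulationParams <- function(name, n0, doublingTime = 48,
                             drugSensitive = FALSE,
                             ic50 = 1, hill = 1, emax = 1, deathRate = 0,
                             markerPositive = FALSE,
                             morphology = list()) {
  defaults <- list(nucleusDiameterMean = 10, nucleusDiameterSd = 1,
                   cytoplasmScale = 1.5, elongation = 1)
  morphology <- utils::modifyList(defaults, morphology)
  new("PopulationParams", name = name, n0 = as.numeric(n0),
      doublingTime = as.numeric(doublingTime),
      drugSensitive = drugSensitive, ic50 = as.numeric(ic50),
      hill = as.numeric(hill), emax = as.numeric(emax),
      deathRate = as.numeric(deathRate),
      markerPositive = markerPositive, morphology = morphology)
}

#' Standard populations of the co-culture assay
#'
#' Convenience constructors with the defaults of the assay the simulator
#' emulates: 250-500 cancer cells plated on ~500 irradiated feeder
#' fibroblasts per 384-well.
#'
#' @param n0 initial cells per well.
#' @param ic50,hill,emax drug-effect ground truth for the cancer population.
#' @param deathRate see [PopulationParams()].
#' @param doublingTime hours; feeders are non-dividing (`Inf`) by default.
#' @param drugSensitive logical (fibroblasts default to insensitive).
#' @return a [PopulationParams-class] object.
#' @rdname standardPopulations
#' @export
cancerPopulation <- function(n0 = 250, ic50 = 50, hill = 1, emax = 1,
                             deathRate = 0, doublingTime = 48) {
  PopulationParams("cancer", n0 = n0, doublingTime = doublingTime,
                   drugSensitive = TRUE, ic50 = ic50, hill = hill,
                   emax = emax, deathRate = deathRate, markerPositive = TRUE,
                   morphology = list(nucleusDiameterMean = 10,
                                     nucleusDiameterSd = 1,
                                     cytoplasmScale = 1.5, elongation = 1))
}

#' @rdname standardPopulations
#' @export
feederPopulation <- function(n0 = 500) {
  PopulationParams("feeder", n0 = n0, doublingTime = Inf,
                   drugSensitive = FALSE, markerPositive = FALSE,
                   morphology = list(nucleusDiameterMean = 10.5,
                                     nucleusDiameterSd = 1,
                                     cytoplasmScale = 2.5, elongation = 3))
}

#' @rdname standardPopulations
#' @export
fibroblastPopulation <- function(n0 = 250, doublingTime = 72,
                                 drugSensitive = FALSE) {
  PopulationParams("fibroblast", n0 = n0, doublingTime = doublingTime,
                   drugSensitive = drugSensitive, markerPositive = FALSE,
                   morphology = list(nucleusDiameterMean = 10.5,
                                     nucleusDiameterSd = 1,
                                     cytoplasmScale = 2.5, elongation = 3))
}

#' Growth-media scenario
#'
#' Encodes how the growth medium modulates the assay: a per-population
#' growth-rate multiplier and a multiplicative shift of the drug IC50.
#' `"TCM"` (tumor culture media, containing EGF and insulin) shifts IC50s of
#' EGFR/ALK inhibitors to the right; removing EGF and insulin
#' (`"TCM_minus_E_I"`) restores the response observed in plain R10 media
#' while keeping the growth advantage.
#'
#' @slot name scenario label.
#' @slot growthMultiplier named numeric vector of per-population growth-rate
#'   multipliers; populations not named get 1.
#' @slot ic50Shift multiplicative factor applied to the true IC50 (> 0).
#' @name MediaScenario-class
#' @rdname MediaScenario-class
#' @exportClass MediaScenario
setClass("MediaScenario",
  representation(name = "character", growthMultiplier = "numeric",
                 ic50Shift = "numeric")
)

setValidity("MediaScenario", function(object) {
  msg <- character()
  if (any(object@growthMultiplier <= 0))
    msg <- c(msg, "growth multipliers must be > 0")
  if (object@ic50Shift <= 0) msg <- c(msg, "'ic50Shift' must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param name scenario label, or one of `"R10"`, `"TCM"`, `"TCM_minus_E_I"`
#'   to get the built-in scenario.
#' @param growthMultiplier named numeric vector (or scalar) of growth-rate
#'   multipliers.
#' @param ic50Shift multiplicative IC50 shift relative to R10.
#' @return a [MediaScenario-class] object.
#' @examples
#' MediaScenario("TCM")
#' MediaScenario("custom", growthMultiplier = c(cancer = 1.5), ic50Shift = 2)
#' @rdname MediaScenario-class
#' @export
MediaScenario <- function(name = "R10", growthMultiplier = NULL,
                          ic50Shift = NULL) {
  builtin <- list(
    R10 = list(g = c(cancer = 1), shift = 1),
    TCM = list(g = c(cancer = 1.25), shift = 4),
    TCM_minus_E_I = list(g = c(cancer = 1.25), shift = 1)
  )
  if (is.null(growthMultiplier) && is.null(ic50Shift) && name %in% names(builtin)) {
    b <- builtin[[name]]
    return(new("MediaScenario", name = name, growthMultiplier = b$g,
               ic50Shift = b$shift))
  }
  if (is.null(growthMultiplier)) growthMultiplier <- 1
  if (is.null(ic50Shift)) ic50Shift <- 1
  new("MediaScenario", name = name,
      growthMultiplier = growthMultiplier, ic50Shift = as.numeric(ic50Shift))
}

#' Optical/imaging parameters of the simulated high-content imager
#'
#' @slot imageSize side length of the square field in pixels.
#' @slot psfSigma point-spread softness in pixels; applied analytically as
#'   the shoulder width of the rendered blobs.
#' @slot backgroundLevel additive background intensity.
#' @slot noiseSd standard deviation of additive Gaussian read-out noise.
#' @slot nuclearIntensity peak intensity of a nucleus in the nuclear channel.
#' @slot markerIntensity peak intensity of marker-positive cytoplasm in the
#'   marker channel.
#' @slot bitDepth 8 or 16; rendered values are clipped to the bit range.
#' @name OpticsParams-class
#' @rdname OpticsParams-class
#' @exportClass OpticsParams
setClass("OpticsParams",
  representation(imageSize = "integer", psfSigma = "numeric",
                 backgroundLevel = "numeric", noiseSd = "numeric",
                 nuclearIntensity = "numeric", markerIntensity = "numeric",
                 bitDepth = "integer")
)

setValidity("OpticsParams", function(object) {
  msg <- character()
  if (object@imageSize < 32) msg <- c(msg, "'imageSize' must be >= 32")
  if (object@psfSigma <= 0) msg <- c(msg, "'psfSigma' must be > 0")
  if (any(c(object@backgroundLevel, object@noiseSd, object@nuclearIntensity,
            object@markerIntensity) < 0))
    msg <- c(msg, "intensities and noise must be >= 0")
  if (!object@bitDepth %in% c(8L, 16L))
    msg <- c(msg, "'bitDepth' must be 8 or 16")
  if (length(msg)) msg else TRUE
})

#' @param imageSize,psfSigma,backgroundLevel,noiseSd,nuclearIntensity,markerIntensity,bitDepth
#'   see [OpticsParams-class].
#' @return an [OpticsParams-class] object.
#' @examples
#' OpticsParams(noiseSd = 0)  # noiseless optics for oracle tests
#' @rdname OpticsParams-class
#' @export
OpticsParams <- function(imageSize = 512, psfSigma = 0.6,
                         backgroundLevel = 100, noiseSd = 20,
                         nuclearIntensity = 3000, markerIntensity = 2000,
                         bitDepth = 16) {
  new("OpticsParams", imageSize = as.integer(imageSize),
      psfSigma = psfSigma, backgroundLevel = backgroundLevel,
      noiseSd = noiseSd, nuclearIntensity = nuclearIntensity,
      markerIntensity = markerIntensity, bitDepth = as.integer(bitDepth))
}

#' One imaged site of a well: two co-registered grayscale channels
#'
#' @slot well well identifier (e.g. `"A1"`).
#' @slot site site index within the well (1-based).
#' @slot nuclear nuclear-stain (Hoechst) intensity matrix.
#' @slot marker marker-stain (CK8/18) intensity matrix, same shape.
#' @slot bitDepth bit depth of the source data.
#' @name FieldImage-class
#' @rdname FieldImage-class
#' @exportClass FieldImage
setClass("FieldImage",
  representation(well = "character", site = "integer",
                 nuclear = "matrix", marker = "matrix", bitDepth = "integer")
)

setValidity("FieldImage", function(object) {
  msg <- character()
  if (!identical(dim(object@nuclear), dim(object@marker)))
    msg <- c(msg, "nuclear and marker channels must have identical shape")
  if (min(object@nuclear) < 0 || min(object@marker) < 0)
    msg <- c(msg, "intensities must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param well,site,nuclear,marker,bitDepth see [FieldImage-class].
#' @return a [FieldImage-class] object.
#' @rdname FieldImage-class
#' @export
FieldImage <- function(nuclear, marker, well = "A1", site = 1L,
                       bitDepth = 16L) {
  new("FieldImage", well = well, site = as.integer(site),
      nuclear = nuclear, marker = marker, bitDepth = as.integer(bitDepth))
}

#' Segmentation and scoring parameters
#'
#' Mirrors the knobs of a multi-wavelength cell-scoring module: minimum and
#' maximum object widths and the per-channel signal intensity above local
#' background, plus the parameters of this package's own background
#' estimator, watershed splitting and positivity rule.
#'
#' @slot minWidth,maxWidth admissible nucleus equivalent-diameter range, px.
#' @slot intensityAboveBackground numeric of length 2, named `nuclear` and
#'   `marker`: detection thresholds above local background.
#' @slot backgroundWindow window (px) of the local background estimator.
#' @slot backgroundQuantile quantile of the window used as background; a low
#'   quantile keeps the estimate on off-cell pixels even in dense fields.
#' @slot splitTouching split touching nuclei by distance-transform watershed?
#' @slot watershedTolerance minimum distance-map peak prominence (px) for a
#'   separate object.
#' @slot cytoplasmRadius dilation radius (px) around each nucleus searched
#'   for marker signal ("entire cell" surrogate).
#' @slot positivityThreshold minimum fraction of the searched region covered
#'   by marker mask for a positive call.
#' @slot excludeBorder drop nuclei touching the image border?
#' @name SegmentationParams-class
#' @rdname SegmentationParams-class
#' @exportClass SegmentationParams
setClass("SegmentationParams",
  representation(minWidth = "numeric", maxWidth = "numeric",
                 intensityAboveBackground = "numeric",
                 backgroundWindow = "integer", backgroundQuantile = "numeric",
                 splitTouching = "logical", watershedTolerance = "numeric",
                 cytoplasmRadius = "numeric", positivityThreshold = "numeric",
                 excludeBorder = "logical")
)

setValidity("SegmentationParams", function(object) {
  msg <- character()
  if (!(object@minWidth > 0 && object@minWidth < object@maxWidth))
    msg <- c(msg, "need 0 < minWidth < maxWidth")
  if (any(object@intensityAboveBackground < 0))
    msg <- c(msg, "'intensityAboveBackground' must be >= 0")
  if (!all(c("nuclear", "marker") %in% names(object@intensityAboveBackground)))
    msg <- c(msg, "'intensityAboveBackground' needs elements 'nuclear' and 'marker'")
  if (object@backgroundQuantile <= 0 || object@backgroundQuantile >= 1)
    msg <- c(msg, "'backgroundQuantile' must be in (0, 1)")
  if (object@positivityThreshold < 0 || object@positivityThreshold > 1)
    msg <- c(msg, "'positivityThreshold' must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @param minWidth,maxWidth,intensityAboveBackground,backgroundWindow,backgroundQuantile,splitTouching,watershedTolerance,cytoplasmRadius,positivityThreshold,excludeBorder
#'   see [SegmentationParams-class].
#' @return a [SegmentationParams-class] object.
#' @examples
#' SegmentationParams(splitTouching = FALSE)
#' @rdname SegmentationParams-class
#' @export
SegmentationParams <- function(minWidth = 5, maxWidth = 22,
                               intensityAboveBackground = c(nuclear = 1000,
                                                            marker = 600),
                               backgroundWindow = 64,
                               backgroundQuantile = 0.12,
                               splitTouching = TRUE,
                               watershedTolerance = 0.2,
                               cytoplasmRadius = 3,
                               positivityThreshold = 0.5,
                               excludeBorder = TRUE) {
  new("SegmentationParams", minWidth = minWidth, maxWidth = maxWidth,
      intensityAboveBackground = intensityAboveBackground,
      backgroundWindow = as.integer(backgroundWindow),
      backgroundQuantile = backgroundQuantile,
      splitTouching = splitTouching, watershedTolerance = watershedTolerance,
      cytoplasmRadius = cytoplasmRadius,
      positivityThreshold = positivityThreshold,
      excludeBorder = excludeBorder)
}

#' Four-parameter logistic dose-response fit
#'
#' Result container of [fit4PL()]: the fitted curve
#' `f(d) = bottom + (top - bottom) / (1 + (d / ic50)^hill)`,
#' convergence status, residual summary and an approximate IC50 confidence
#' interval.
#'
#' @slot drug,population labels carried through from the input series.
#' @slot bottom,top fitted asymptotes, response units.
#' @slot hill fitted Hill slope (dimensionless).
#' @slot ic50 fitted inflection concentration (relative IC50), nM.
#' @slot ic50CI approximate 95% Wald interval of the IC50 (nM).
#' @slot converged did the fit converge to a usable curve?
#' @slot message reason when `converged` is `FALSE`.
#' @slot residualSE residual standard error of the weighted fit.
#' @slot n number of fitted condition means.
#' @name DRFit-class
#' @rdname DRFit-class
#' @exportClass DRFit
setClass("DRFit",
  representation(drug = "character", population = "character",
                 bottom = "numeric", top = "numeric", hill = "numeric",
                 ic50 = "numeric", ic50CI = "numeric", converged = "logical",
                 message = "character", residualSE = "numeric", n = "integer")
)

setValidity("DRFit", function(object) {
  if (object@converged && !(object@ic50 > 0))
    return("a converged fit must have ic50 > 0")
  if (object@converged && object@bottom > object@top)
    return("a converged fit must have bottom <= top")
  TRUE
})
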