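## Vectorised blob stamping. Each cell contributes a rotated anisotropic
## super-Gaussian amp * exp(-(r/R)^(2m)): flat core, shoulder of width ~ psf.
## All cells of a call share a patch half-width w; contributions are
## accumulated through a sparse matrix, which sums duplicate pixel entries.
stampBlobs <- function(sz, x, y, radius, amp, ratio, angle, psfSigma) {
  if (length(x) == 0L) return(matrix(0, sz, sz))
  w <- ceiling(max(radius * pmax(ratio, 1)) + 3 * psfSigma + 1)
  o <- seq(-w, w)
  K <- length(o)
  cx <- pmin(pmax(round(x), w + 1), sz - w)  # patch centers kept in frame
  cy <- pmin(pmax(round(y), w + 1), sz - w)
  dx <- outer(x - cx, rep(1, K)) - matrix(o, length(x), K, byrow = TRUE)
  dy <- outer(y - cy, rep(1, K)) - matrix(o, length(x), K, byrow = TRUE)
  dx <- -dx
  dy <- -dy
  idx1 <- rep(seq_len(K), each = K)   # x-offset index of flattened patch
  idx2 <- rep(seq_len(K), times = K)  # y-offset index
  if (all(ratio == 1)) {  # isotropic fast path: no rotation needed
    rr <- sqrt(dx[, idx1, drop = FALSE]^2 + dy[, idx2, drop = FALSE]^2) /
      radius
  } else {
    ca <- cos(angle); sa <- sin(angle)
    U <- dx[, idx1, drop = FALSE] * ca + dy[, idx2, drop = FALSE] * sa
    V <- -dx[, idx1, drop = FALSE] * sa + dy[, idx2, drop = FALSE] * ca
    rr <- sqrt((U / ratio)^2 + (V * ratio)^2) / radius
  }
  m <- pmax(2, round(radius / (2 * psfSigma)))
  val <- amp * exp(-rr^(2 * m))
  ii <- rep(cx, times = K * K) + rep(o[idx1], each = length(x))
  jj <- rep(cy, times = K * K) + rep(o[idx2], each = length(x))
  keep <- val > amp * 1e-4
  as.matrix(Matrix::sparseMatrix(i = ii[keep], j = jj[keep], x = val[keep],
                                 dims = c(sz, sz)))
}

#' Render a two-channel field image from cell placements
#'
#' Channel 1 (nuclear) receives one blurred nuclear blob per cell; channel 2
#' (marker) receives cytoplasmic signal only around marker-positive cells,
#' rendered as an annulus (dimmer over the nucleus). Both channels get the
#' configured additive background and Gaussian read-out noise and are clipped
#' to the bit range; channels are co-registered by construction.
#'
#' @param placements `data.frame` from [placeCells()].
#' @param optics [OpticsParams-class].
#' @param pops optional list of [PopulationParams-class] used to look up
#'   cytoplasm scale per population; defaults to 1.8x the nucleus radius.
#' @param well,site identifiers stored in the result.
#' @param noise render read-out noise? Set `FALSE` for noiseless oracle
#'   images.
#' @param seed optional integer seed for the noise draw.
#' @return a [FieldImage-class].
#' @examples
#' pl <- placeCells(c(cancer = 5), list(cancerPopulation()), seed = 1)
#' fi <- renderField(pl, OpticsParams(noiseSd = 0))
#' @export
renderField <- function(placements, optics = OpticsParams(), pops = NULL,
                        well = "A1", site = 1L, noise = TRUE, seed = NULL) {
  sz <- optics@imageSize
  if (nrow(placements) &&
      (any(placements$x < 0) || any(placements$x > sz - 1) ||
       any(placements$y < 0) || any(placements$y > sz - 1)))
    stop("placements outside the image bounds")
  cytScale <- function(popName) {
    if (!is.null(pops)) {
      nm <- vapply(pops, function(p) p@name, character(1))
      hit <- match(popName, nm)
      if (!is.na(hit)) return(pops[[hit]]@morphology$cytoplasmScale)
    }
    1.8
  }
  nuclear <- matrix(0, sz, sz)
  marker <- matrix(0, sz, sz)
  if (nrow(placements)) {
    x1 <- placements$x + 1  # to 1-based matrix coordinates
    y1 <- placements$y + 1
    nuclear <- stampBlobs(sz, x1, y1, placements$diameter_px / 2,
                          optics@nuclearIntensity, placements$elongation,
                          placements$angle, optics@psfSigma)
    posi <- placements$marker_positive
    if (any(posi)) {
      cs <- vapply(placements$population[posi], cytScale, numeric(1))
      rad <- placements$diameter_px[posi] / 2
      cyt <- stampBlobs(sz, x1[posi], y1[posi], rad * cs,
                        optics@markerIntensity, placements$elongation[posi],
                        placements$angle[posi], optics@psfSigma * 2)
      hole <- stampBlobs(sz, x1[posi], y1[posi], rad,
                         optics@markerIntensity * 0.35,
                         placements$elongation[posi],
                         placements$angle[posi], optics@psfSigma)
      marker <- pmax(cyt - hole, 0)
    }
  }
  addNoise <- function(img) {
    img <- img + optics@backgroundLevel
    if (noise && optics@noiseSd > 0)
      img <- img + matrix(stats::rnorm(sz * sz, 0, optics@noiseSd), sz, sz)
    pmin(pmax(img, 0), 2^optics@bitDepth - 1)
  }
  finish <- function() {
    FieldImage(nuclear = addNoise(nuclear), marker = addNoise(marker),
               well = well, site = site, bitDepth = optics@bitDepth)
  }
  if (is.null(seed)) finish() else withr::with_seed(seed, finish())
}
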