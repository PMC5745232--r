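#' Local background of a field image
#'
#' Background is estimated per `window`-sized block as a low quantile of the
#' block's intensities and interpolated bilinearly back to full resolution.
#' A low quantile (default 0.12) keeps the estimate anchored on off-cell
#' pixels even when cells cover half the field, where a median would be
#' pulled onto the cells.
#'
#' @param img intensity matrix.
#' @param window block size, px.
#' @param quantile block quantile taken as background.
#' @return matrix of the same shape as `img`.
#' @export
localBackground <- function(img, window = 64, quantile = 0.12) {
  sz <- dim(img)
  nbx <- max(1L, ceiling(sz[1] / window))
  nby <- max(1L, ceiling(sz[2] / window))
  bx <- rep(seq_len(nbx), each = window, length.out = sz[1])
  by <- rep(seq_len(nby), each = window, length.out = sz[2])
  m <- matrix(0, nbx, nby)
  for (a in seq_len(nbx))
    for (b in seq_len(nby))
      m[a, b] <- stats::quantile(img[bx == a, by == b], quantile, names = FALSE)
  if (nbx == 1L && nby == 1L) return(matrix(m[1, 1], sz[1], sz[2]))
  as.matrix(EBImage::resize(EBImage::Image(m), w = sz[1], h = sz[2]))
}

## Fill background holes smaller than minArea pixels (dim nucleus centers),
## without bridging the open background between cell clusters the way a
## convex-hull fill would.
fillSmallHoles <- function(mask, minArea) {
  inv <- EBImage::bwlabel(!mask)
  ar <- tabulate(as.integer(inv)[as.integer(inv) > 0])
  small <- which(ar < minArea)
  if (length(small)) mask[as.integer(inv) %in% small] <- TRUE
  mask
}

#' Segment nuclei in the nuclear (Hoechst) channel
#'
#' Pixels exceeding the local background by the configured intensity are
#' thresholded, small holes are filled, touching nuclei are split by a
#' distance-transform watershed (when `splitTouching` is on), and regions
#' are kept only if their equivalent diameter lies within
#' `[minWidth, maxWidth]`. Nuclei touching the image border are excluded when
#' `excludeBorder` is set, so per-field counts are unbiased across
#' conditions.
#'
#' @param img nuclear-channel intensity matrix (or a [FieldImage-class],
#'   whose nuclear channel is used).
#' @param params [SegmentationParams-class].
#' @return integer label matrix (0 = background; labels are consecutive from
#'   1). Attribute `qcWarning` carries a string when the field looks blank or
#'   saturated (the matrix is then all zero rather than an error).
#' @examples
#' pl <- placeCells(c(cancer = 12), list(cancerPopulation()), seed = 2)
#' fi <- renderField(pl, seed = 3)
#' labs <- segmentNuclei(fi, SegmentationParams())
#' max(labs)  # 12
#' @export
segmentNuclei <- function(img, params = SegmentationParams()) {
  if (is(img, "FieldImage")) img <- img@nuclear
  if (!length(img)) stop("empty image")
  thr <- params@intensityAboveBackground[["nuclear"]]
  bg <- localBackground(img, params@backgroundWindow,
                        params@backgroundQuantile)
  mask <- img > bg + thr
  frac <- mean(mask)
  qc <- NULL
  if (frac == 0) qc <- "blank field: no pixels above background + threshold"
  if (frac > 0.9) {
    qc <- "saturated field: >90% of pixels above threshold"
    mask[] <- FALSE
  }
  if (!is.null(qc)) {
    out <- matrix(0L, nrow(img), ncol(img))
    attr(out, "qcWarning") <- qc
    return(out)
  }
  mask <- fillSmallHoles(mask, pi * (params@minWidth / 2)^2)
  if (params@splitTouching) {
    lab <- EBImage::watershed(EBImage::distmap(mask),
                              tolerance = params@watershedTolerance, ext = 1)
  } else {
    lab <- EBImage::bwlabel(mask)
  }
  lab <- as.matrix(lab)
  storage.mode(lab) <- "integer"
  area <- tabulate(lab[lab > 0L])
  eqd <- sqrt(4 * area / pi)
  drop <- which(eqd < params@minWidth | eqd > params@maxWidth)
  if (params@excludeBorder) {
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    drop <- union(drop, border[border > 0L])
  }
  if (length(drop)) lab[lab %in% drop] <- 0L
  ## relabel consecutively
  kept <- sort(unique(lab[lab > 0L]))
  if (length(kept)) {
    remap <- integer(max(kept))
    remap[kept] <- seq_along(kept)
    pos <- lab > 0L
    lab[pos] <- remap[lab[pos]]
  }
  attr(lab, "qcWarning") <- NULL
  lab
}

#' Segment the marker (CK8/18) channel into a positivity mask
#'
#' Binary mask of pixels exceeding the local background by the marker
#' channel's intensity threshold, cleaned by a morphological opening.
#'
#' @param img marker-channel intensity matrix (or a [FieldImage-class]).
#' @param params [SegmentationParams-class].
#' @return logical matrix; attribute `qcWarning` as in [segmentNuclei()].
#' @export
segmentMarker <- function(img, params = SegmentationParams()) {
  if (is(img, "FieldImage")) img <- img@marker
  if (!length(img)) stop("empty image")
  thr <- params@intensityAboveBackground[["marker"]]
  bg <- localBackground(img, params@backgroundWindow,
                        params@backgroundQuantile)
  mask <- img > bg + thr
  qc <- NULL
  if (mean(mask) > 0.95) {
    qc <- "saturated marker channel"
    mask[] <- FALSE
  }
  mask <- EBImage::opening(mask, EBImage::makeBrush(3, "diamond"))
  mask <- as.matrix(mask) > 0
  attr(mask, "qcWarning") <- qc
  mask
}

#' Score segmented nuclei as marker-positive or -negative
#'
#' Each nucleus is dilated by `cytoplasmRadius` (a surrogate for the cell
#' body); contested pixels go to the nearest nucleus. A cell is called
#' marker-positive when at least `positivityThreshold` of its searched
#' region falls inside the marker mask.
#'
#' @param labels integer label matrix from [segmentNuclei()].
#' @param markerMask logical matrix from [segmentMarker()].
#' @param nuclear,marker intensity matrices used for per-cell mean
#'   intensities.
#' @param params [SegmentationParams-class].
#' @param well,site identifiers copied into the output.
#' @return `data.frame`, one row per nucleus: `well`, `site`, `x`, `y`
#'   (centroid, 0-based), `nucleus_area_px2`, `nuclear_mean`, `marker_mean`,
#'   `marker_positive`.
#' @export
scoreCells <- function(labels, markerMask, nuclear, marker,
                       params = SegmentationParams(),
                       well = "A1", site = 1L) {
  if (!identical(dim(labels), dim(markerMask)))
    stop("label matrix and marker mask must share the image frame")
  nlab <- max(labels)
  empty <- data.frame(well = character(), site = integer(), x = numeric(),
                      y = numeric(), nucleus_area_px2 = numeric(),
                      nuclear_mean = numeric(), marker_mean = numeric(),
                      marker_positive = logical())
  if (nlab == 0L) return(empty)
  px <- which(labels > 0L)
  l <- labels[px]
  area <- tabulate(l, nbins = nlab)
  cx <- (px - 1L) %% nrow(labels) + 1L
  cy <- (px - 1L) %/% nrow(labels) + 1L
  sx <- rowsum(as.numeric(cx), l)
  sy <- rowsum(as.numeric(cy), l)
  nucMean <- rowsum(as.numeric(nuclear[px]), l) / area
  ## grow each nucleus into its search zone; nearest-nucleus assignment
  r <- ceiling(params@cytoplasmRadius)
  zone <- EBImage::dilate(labels > 0L, EBImage::makeBrush(2L * r + 1L, "disc"))
  grown <- EBImage::propagate(EBImage::Image(matrix(0, nrow(labels), ncol(labels))),
                              seeds = labels, mask = zone, lambda = 1e8)
  grown <- as.matrix(grown)
  storage.mode(grown) <- "integer"
  gpx <- which(grown > 0L)
  gl <- grown[gpx]
  zoneArea <- tabulate(gl, nbins = nlab)
  overlap <- rowsum(as.numeric(markerMask[gpx]), gl)
  markMean <- rowsum(as.numeric(marker[gpx]), gl) / pmax(zoneArea, 1L)
  frac <- as.numeric(overlap) / pmax(zoneArea, 1L)
  data.frame(
    well = well, site = as.integer(site),
    x = as.numeric(sx) / area - 1,  # 0-based centroids
    y = as.numeric(sy) / area - 1,
    nucleus_area_px2 = as.numeric(area),
    nuclear_mean = as.numeric(nucMean),
    marker_mean = as.numeric(markMean),
    marker_positive = frac >= params@positivityThreshold,
    stringsAsFactors = FALSE
  )
}

#' Quantify one well from its field images
#'
#' Runs nuclear segmentation, marker segmentation and cell scoring on every
#' imaged site of a well and sums the calls into a per-well count record.
#'
#' @param fields a [FieldImage-class] or list of them (>= 1 site).
#' @param params [SegmentationParams-class].
#' @return list with elements `wellCount` (one-row `data.frame`: `well`,
#'   `n_total`, `n_positive`, `n_negative`, `n_sites`) and `cells` (the
#'   per-cell table across sites).
#' @examples
#' pl <- placeCells(c(cancer = 8, feeder = 5),
#'                  list(cancerPopulation(), feederPopulation()), seed = 4)
#' fi <- renderField(pl, seed = 5)
#' quantifyWell(fi)$wellCount
#' @export
quantifyWell <- function(fields, params = SegmentationParams()) {
  if (is(fields, "FieldImage")) fields <- list(fields)
  if (!length(fields)) stop("need at least one imaged site per well")
  cells <- lapply(fields, function(fi) {
    labs <- segmentNuclei(fi@nuclear, params)
    mask <- segmentMarker(fi@marker, params)
    scoreCells(labs, mask, fi@nuclear, fi@marker, params,
               well = fi@well, site = fi@site)
  })
  cells <- do.call(rbind, c(cells, list(make.row.names = FALSE)))
  wellCount <- data.frame(
    well = fields[[1]]@well,
    n_total = nrow(cells),
    n_positive = sum(cells$marker_positive),
    n_negative = sum(!cells$marker_positive),
    n_sites = length(fields),
    stringsAsFactors = FALSE
  )
  list(wellCount = wellCount, cells = cells)
}
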