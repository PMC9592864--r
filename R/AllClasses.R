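#' @import methods
#' @importFrom stats dnorm quantile rnorm runif sd fft setNames
#' @importFrom utils read.csv write.csv head
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' StainedSlide: an RGB raster with region of interest and derived masks
#'
#' The central container of the package: an 8-bit RGB image (stored as an
#' \code{H x W x 3} numeric array with values in \code{[0, 255]}) together
#' with its physical pixel size, the region of interest in which all
#' processing takes place, and the stain and epithelium masks derived by the
#' detection stages.
#'
#' @slot pixels numeric \code{H x W x 3} array, each channel in \code{[0,255]}.
#' @slot pixelSizeUm physical edge length of one pixel in micrometres
#'   (default 0.5, a 20x scan).
#' @slot roi logical \code{H x W} matrix or \code{NULL}; \code{NULL} means
#'   the whole frame.
#' @slot stain logical \code{H x W} matrix or \code{NULL}; DAB-positive
#'   pixels.
#' @slot epithelium logical \code{H x W} matrix or \code{NULL}; epithelial
#'   territories.
#' @export
setClass("StainedSlide",
  representation(
    pixels = "array",
    pixelSizeUm = "numeric",
    roi = "matrixOrNULL",
    stain = "matrixOrNULL",
    epithelium = "matrixOrNULL"
  ),
  prototype(pixelSizeUm = 0.5, roi = NULL, stain = NULL, epithelium = NULL)
)

setValidity("StainedSlide", function(object) {
  p <- object@pixels
  if (length(dim(p)) != 3L || dim(p)[3] != 3L)
    return("pixels must be an H x W x 3 array")
  if (dim(p)[1] < 1L || dim(p)[2] < 1L)
    return("image must be at least 1 x 1")
  if (min(p) < 0 || max(p) > 255)
    return("channel values must lie in [0, 255]")
  if (length(object@pixelSizeUm) != 1L || object@pixelSizeUm <= 0)
    return("pixelSizeUm must be a single positive number")
  for (nm in c("roi", "stain", "epithelium")) {
    m <- slot(object, nm)
    if (!is.null(m)) {
      if (!is.logical(m)) return(sprintf("%s mask must be logical", nm))
      if (!identical(dim(m), dim(p)[1:2]))
        return(sprintf("%s mask shape must match the image", nm))
    }
  }
  TRUE
})

#' OhtaImage: the three Ohta color features of an RGB image
#'
#' Linear color transform with layers \code{I1 = (R+G+B)/3},
#' \code{I2 = (R-B)/2} and \code{I3 = (2G-R-B)/4}. The second layer
#' separates the brown DAB chromogen (positive) from the blue hematoxylin
#' counterstain (negative) and drives stain classification.
#'
#' @slot i1,i2,i3 numeric \code{H x W} matrices; \code{i1} in
#'   \code{[0,255]}, \code{i2} and \code{i3} in \code{[-127.5, 127.5]}.
#' @export
setClass("OhtaImage",
  representation(i1 = "matrix", i2 = "matrix", i3 = "matrix"))

setValidity("OhtaImage", function(object) {
  d <- dim(object@i1)
  if (!identical(d, dim(object@i2)) || !identical(d, dim(object@i3)))
    return("the three layers must share a shape")
  if (min(object@i1) < -1e-9 || max(object@i1) > 255 + 1e-9)
    return("I1 must lie in [0, 255]")
  if (max(abs(object@i2)) > 127.5 + 1e-9 || max(abs(object@i3)) > 127.5 + 1e-9)
    return("I2 and I3 must lie in [-127.5, 127.5]")
  TRUE
})

#' StainModel: two-component mixture model of the I2 histogram
#'
#' A one-dimensional two-component Gaussian mixture fitted to the second
#' Ohta layer inside the ROI, plus the decision threshold (the curve
#' intersection between the component means) and an additive calibration
#' shift tuned by the stereology loop. A pixel is called stained when
#' \code{I2 >= decisionThreshold + calibrationShift}.
#'
#' @slot weights,means,sds numeric vectors of length 2 (means increasing).
#' @slot decisionThreshold numeric; intersection of the two component
#'   curves between their means.
#' @slot calibrationShift numeric; additive threshold adjustment
#'   (default 0).
#' @export
setClass("StainModel",
  representation(
    weights = "numeric", means = "numeric", sds = "numeric",
    decisionThreshold = "numeric", calibrationShift = "numeric"
  ),
  prototype(calibrationShift = 0)
)

setValidity("StainModel", function(object) {
  if (length(object@weights) != 2L || length(object@means) != 2L ||
      length(object@sds) != 2L)
    return("a StainModel has exactly two components")
  if (abs(sum(object@weights) - 1) > 1e-6) return("weights must sum to 1")
  if (any(object@sds <= 0)) return("sds must be positive")
  if (diff(object@means) <= 0) return("means must be increasing")
  TRUE
})

#' CrossGrid: a randomly offset regular point grid inside an ROI
#'
#' Stereology test grid of crosses: lattice nodes at a uniform random
#' offset plus integer multiples of \code{spacing}, retained only where
#' they fall inside the ROI. The random offset makes the point-count area
#' fraction an unbiased estimator.
#'
#' @slot spacing lattice period in pixels.
#' @slot offset length-2 numeric (dy, dx) in \code{[0, spacing)}.
#' @slot positions integer \code{n x 2} matrix of (row, col) nodes,
#'   1-based.
#' @slot dim image dimensions the grid was built for.
#' @slot seed integer seed the offset was drawn from.
#' @export
setClass("CrossGrid",
  representation(spacing = "numeric", offset = "numeric",
                 positions = "matrix", dim = "integer", seed = "integer"))

#' MarkSet: labels attached to the nodes of a CrossGrid
#'
#' Each cross carries one mark: \code{"labeled"} (positive),
#' \code{"unlabeled"} (negative) or \code{"excluded"} (dropped from every
#' ratio, e.g. where two experts disagree).
#'
#' @slot grid the \linkS4class{CrossGrid} the marks live on.
#' @slot labels character vector, one of labeled/unlabeled/excluded per
#'   node.
#' @export
setClass("MarkSet",
  representation(grid = "CrossGrid", labels = "character"))

setValidity("MarkSet", function(object) {
  if (length(object@labels) != nrow(object@grid@positions))
    return("one label per grid node required")
  if (!all(object@labels %in% c("labeled", "unlabeled", "excluded")))
    return("labels must be labeled/unlabeled/excluded")
  TRUE
})

#' HexTiling: pointy-top hexagonal partition of an image frame
#'
#' Every pixel is assigned to the hexagon whose center is nearest
#' (axial-coordinate rounding), so hexagons tile the frame without gaps or
#' overlaps. Only hexagons that intersect the ROI receive an index.
#'
#' @slot circumradius hexagon circumradius in pixels.
#' @slot assignment integer \code{H x W} matrix; hexagon index per pixel
#'   (NA outside the ROI).
#' @slot centers numeric \code{n x 2} matrix of hexagon centers (row, col).
#' @slot nHex number of hexagons intersecting the ROI.
#' @export
setClass("HexTiling",
  representation(circumradius = "numeric", assignment = "matrix",
                 centers = "matrix", nHex = "integer"))

#' Gmm1D: a one-dimensional Gaussian mixture fitted by deterministic EM
#'
#' Components are sorted by mean; the fit is bit-reproducible because the
#' EM is initialised from quantiles, never from random draws.
#'
#' @slot k component count.
#' @slot weights,means,sds numeric vectors of length \code{k}.
#' @slot logLik final log-likelihood.
#' @slot nIter EM iterations used.
#' @export
setClass("Gmm1D",
  representation(k = "integer", weights = "numeric", means = "numeric",
                 sds = "numeric", logLik = "numeric", nIter = "integer"))

setValidity("Gmm1D", function(object) {
  if (length(object@weights) != object@k ||
      length(object@means) != object@k || length(object@sds) != object@k)
    return("weights, means, sds must have length k")
  if (abs(sum(object@weights) - 1) > 1e-9) return("weights must sum to 1")
  if (any(object@sds <= 0)) return("sds must be positive")
  if (is.unsorted(object@means, strictly = TRUE))
    return("means must be strictly increasing")
  TRUE
})

#' ThresholdPair: the two curve-intersection thresholds of a 3-GMM
#'
#' Cuts the transmittance axis into the low / medium / high hexagon
#' classes. Both thresholds lie strictly between the adjacent component
#' means.
#'
#' @slot t1,t2 numeric thresholds, \code{t1 < t2}.
#' @export
setClass("ThresholdPair", representation(t1 = "numeric", t2 = "numeric"))

setValidity("ThresholdPair", function(object) {
  if (object@t1 >= object@t2) return("t1 must be < t2")
  TRUE
})

#' MomentPca: standardized PCA of the per-case moment table
#'
#' Stores the column standardization (mean and sample SD of each of the
#' three transmittance moments) and the unit-norm leading eigenvector of
#' the correlation matrix, oriented so the coefficient on the mean
#' transmittance is non-negative.
#'
#' @slot center,scale numeric length-3; column means and sample SDs.
#' @slot loading numeric length-3 unit vector.
#' @slot explainedVar fraction of variance carried by component 1.
#' @export
setClass("MomentPca",
  representation(center = "numeric", scale = "numeric",
                 loading = "numeric", explainedVar = "numeric"))

setValidity("MomentPca", function(object) {
  if (abs(sqrt(sum(object@loading^2)) - 1) > 1e-9)
    return("loading must have unit norm")
  if (object@loading[1] < 0)
    return("loading must be oriented with non-negative mean coefficient")
  TRUE
})
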