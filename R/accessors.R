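#' @describeIn StainedSlide image height and width
#' @param x,object a \code{StainedSlide}
#' @export
setMethod("dim", "StainedSlide", function(x) dim(x@pixels)[1:2])

#' Accessors for StainedSlide components
#'
#' @param x a \linkS4class{StainedSlide}
#' @return \code{slidePixels} the raw array; \code{pixelSizeUm} the pixel
#'   size; \code{roiMask}, \code{stainMask}, \code{epitheliumMask} the
#'   logical masks (or \code{NULL} when not yet computed). \code{roiMask}
#'   returns an all-\code{TRUE} matrix when no ROI was set.
#' @export
slidePixels <- function(x) x@pixels

#' @rdname slidePixels
#' @export
pixelSizeUm <- function(x) x@pixelSizeUm

#' @rdname slidePixels
#' @export
roiMask <- function(x) {
  if (is.null(x@roi)) matrix(TRUE, dim(x)[1], dim(x)[2]) else x@roi
}

#' @rdname slidePixels
#' @export
stainMask <- function(x) x@stain

#' @rdname slidePixels
#' @export
epitheliumMask <- function(x) x@epithelium

setMethod("show", "StainedSlide", function(object) {
  d <- dim(object)
  cat(sprintf("StainedSlide %d x %d px (%.2f um/px)\n",
              d[1], d[2], object@pixelSizeUm))
  cat(sprintf("  ROI: %s  stain: %s  epithelium: %s\n",
              if (is.null(object@roi)) "full frame" else
                sprintf("%d px", sum(object@roi)),
              if (is.null(object@stain)) "<not computed>" else
                sprintf("%d px", sum(object@stain)),
              if (is.null(object@epithelium)) "<not computed>" else
                sprintf("%d px", sum(object@epithelium))))
})

setMethod("show", "StainModel", function(object) {
  cat("StainModel (2-component mixture on Ohta I2)\n")
  cat(sprintf("  weights: %.3f / %.3f  means: %.2f / %.2f  sds: %.2f / %.2f\n",
              object@weights[1], object@weights[2], object@means[1],
              object@means[2], object@sds[1], object@sds[2]))
  cat(sprintf("  decision threshold: %.3f  calibration shift: %+.3f\n",
              object@decisionThreshold, object@calibrationShift))
})

setMethod("show", "Gmm1D", function(object) {
  cat(sprintf("Gmm1D with %d components (logLik %.3f, %d iterations)\n",
              object@k, object@logLik, object@nIter))
  print(data.frame(weight = round(object@weights, 4),
                   mean = round(object@means, 4),
                   sd = round(object@sds, 4)))
})

setMethod("show", "HexTiling", function(object) {
  cat(sprintf("HexTiling: %d hexagons, circumradius %g px, frame %d x %d\n",
              object@nHex, object@circumradius,
              nrow(object@assignment), ncol(object@assignment)))
})

setMethod("show", "CrossGrid", function(object) {
  cat(sprintf("CrossGrid: %d nodes, spacing %g px, offset (%.1f, %.1f)\n",
              nrow(object@positions), object@spacing,
              object@offset[1], object@offset[2]))
})

setMethod("show", "MarkSet", function(object) {
  tb <- table(factor(object@labels,
                     c("labeled", "unlabeled", "excluded")))
  cat(sprintf("MarkSet: %d labeled, %d unlabeled, %d excluded\n",
              tb[1], tb[2], tb[3]))
})

setMethod("show", "MomentPca", function(object) {
  cat("MomentPca (standardized PCA of per-case transmittance moments)\n")
  cat(sprintf("  loading: (%.4f, %.4f, %.4f)  explained variance: %.1f%%\n",
              object@loading[1], object@loading[2], object@loading[3],
              100 * object@explainedVar))
})

#' Number of hexagons in a tiling
#' @param tiling a \linkS4class{HexTiling}
#' @export
nHexagons <- function(tiling) tiling@nHex

#' Hexagon centers of a tiling
#' @param tiling a \linkS4class{HexTiling}
#' @return numeric matrix of (row, col) centers, one row per hexagon
#' @export
hexCenters <- function(tiling) tiling@centers

#' Mark labels of a MarkSet
#' @param marks a \linkS4class{MarkSet}
#' @export
markLabels <- function(marks) marks@labels

#' Grid node positions
#' @param x a \linkS4class{CrossGrid} or \linkS4class{MarkSet}
#' @return integer matrix of (row, col) node positions
#' @export
gridPositions <- function(x) {
  if (is(x, "MarkSet")) x@grid@positions else x@positions
}
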