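## DAB stain detection: Ohta color transform, 2-component mixture on the
## second layer, threshold classification with a calibration shift.

#' Ohta color transform
#'
#' Computes the three Ohta features of an RGB image in real arithmetic:
#' \code{I1 = (R+G+B)/3} (intensity), \code{I2 = (R-B)/2} (red-blue
#' opponent, positive for brown DAB, negative for blue hematoxylin) and
#' \code{I3 = (2G-R-B)/4}.
#'
#' @param slide a \linkS4class{StainedSlide} or an \code{H x W x 3} array.
#' @return an \linkS4class{OhtaImage}.
#' @export
ohtaTransform <- function(slide) {
  px <- if (is(slide, "StainedSlide")) slide@pixels else slide
  d <- dim(px)[1:2]
  r <- matrix(px[, , 1], d[1], d[2])
  g <- matrix(px[, , 2], d[1], d[2])
  b <- matrix(px[, , 3], d[1], d[2])
  new("OhtaImage",
      i1 = (r + g + b) / 3,
      i2 = (r - b) / 2,
      i3 = (2 * g - r - b) / 4)
}

#' Fit the stain model on the I2 histogram inside the ROI
#'
#' Fits a 2-component Gaussian mixture to the second Ohta layer by the
#' deterministic EM of \code{\link{fitGmm}}; the higher-mean component is
#' the DAB class, and the decision threshold is the intersection of the
#' two weighted component curves between their means. Large ROIs are
#' subsampled (seeded, reproducible) before fitting.
#'
#' @param i2 numeric vector of I2 values, or an \linkS4class{OhtaImage}.
#' @param roi optional logical mask selecting pixels when \code{i2} is an
#'   image.
#' @param subsampleCap fit at most this many pixels (default 200000).
#' @param seed seed for the subsample draw.
#' @return a \linkS4class{StainModel}.
#' @export
fitStainModel <- function(i2, roi = NULL, subsampleCap = 2e5, seed = 1L) {
  v <- if (is(i2, "OhtaImage")) {
    if (is.null(roi)) as.numeric(i2@i2) else i2@i2[roi]
  } else as.numeric(i2)
  v <- v[is.finite(v)]
  if (length(v) < 100L) stop("too few pixels to fit a stain model")
  if (length(v) > subsampleCap)
    v <- withSeed(seed, sample(v, subsampleCap))
  fit <- fitGmm(v, k = 2)
  thr <- .gaussIntersection(fit@weights[1], fit@means[1], fit@sds[1],
                            fit@weights[2], fit@means[2], fit@sds[2])
  new("StainModel", weights = fit@weights, means = fit@means,
      sds = fit@sds, decisionThreshold = thr, calibrationShift = 0)
}

#' Effective stain threshold of a model
#'
#' @param model a \linkS4class{StainModel}.
#' @return \code{decisionThreshold + calibrationShift}.
#' @export
effectiveThreshold <- function(model) {
  model@decisionThreshold + model@calibrationShift
}

#' Set the calibration shift of a stain model
#'
#' @param model a \linkS4class{StainModel}.
#' @param shift new additive shift.
#' @return the updated model.
#' @export
setCalibrationShift <- function(model, shift) {
  model@calibrationShift <- shift
  model
}

#' Classify stained pixels
#'
#' A pixel is called stained iff it lies inside the ROI and its I2 value
#' reaches the model's effective threshold. Raising the calibration shift
#' can only remove stained pixels.
#'
#' @param ohta an \linkS4class{OhtaImage}.
#' @param model a \linkS4class{StainModel}.
#' @param roi logical mask (default: whole frame).
#' @return logical stain mask.
#' @export
classifyStain <- function(ohta, model, roi = NULL) {
  stopifnot(is(ohta, "OhtaImage"), is(model, "StainModel"))
  m <- ohta@i2 >= effectiveThreshold(model)
  if (!is.null(roi)) {
    stopifnot(identical(dim(roi), dim(ohta@i2)))
    m <- m & roi
  }
  m
}

#' Brown intensity image of the stained pixels
#'
#' Carries the intensity (I1) of stained pixels and 255 elsewhere, so
#' unstained pixels behave as fully transmitting in the transmittance sum.
#'
#' @param slide a \linkS4class{StainedSlide} or RGB array.
#' @param stain logical stain mask.
#' @return numeric \code{H x W} matrix in \code{[0, 255]}.
#' @export
brownIntensity <- function(slide, stain) {
  i1 <- ohtaTransform(slide)@i1
  stopifnot(identical(dim(stain), dim(i1)))
  out <- matrix(255, nrow(i1), ncol(i1))
  out[stain] <- i1[stain]
  out
}

#' Serialize / restore a stain model as JSON
#'
#' @param model a \linkS4class{StainModel}.
#' @param path JSON file path.
#' @export
writeStainModel <- function(model, path) {
  jsonlite::write_json(list(
    weights = model@weights, means = model@means, sds = model@sds,
    decision_threshold = model@decisionThreshold,
    calibration_shift = model@calibrationShift
  ), path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname writeStainModel
#' @export
readStainModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("StainModel", weights = x$weights, means = x$means, sds = x$sds,
      decisionThreshold = x$decision_threshold,
      calibrationShift = x$calibration_shift)
}
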