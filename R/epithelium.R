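## Epithelium segmentation: Gaussian-windowed Fourier low-pass filtering
## (overlap-add), moment-preserving bilevel threshold, morphological
## opening, ROI restriction.

#' Parameters of the windowed-Fourier epithelium segmenter
#'
#' @param tile analysis window side in pixels (power of two).
#' @param windowSigma Gaussian apodization SD in pixels.
#' @param cutoff low-pass corner in cycles per window: the radial filter
#'   is 1 below \code{cutoff/2}, rolls off as a raised cosine, and is 0 at
#'   \code{cutoff}.
#' @param openingRadius disk radius (pixels) of the binary opening that
#'   removes residual noise and small objects; about 4 um at 0.5 um/px
#'   with the default.
#' @param darkIsForeground keep the darker side of the threshold as
#'   epithelium (nuclei-dense tissue under hematoxylin); set \code{FALSE}
#'   for tissues where the foreground is brighter.
#' @return a named list of validated parameters.
#' @export
gaborParams <- function(tile = 128, windowSigma = 32, cutoff = 8,
                        openingRadius = 8, darkIsForeground = TRUE) {
  stopifnot(tile >= 4 * windowSigma - 1e-9, cutoff > 0, cutoff <= tile / 2,
            openingRadius >= 0)
  list(tile = as.integer(tile), windowSigma = windowSigma,
       cutoff = cutoff, openingRadius = openingRadius,
       darkIsForeground = isTRUE(darkIsForeground))
}

## Radial raised-cosine low-pass transfer function on an n x n FFT grid,
## in cycles/window.
.lowpassFilter <- function(n, cutoff) {
  k <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  if (length(k) != n) k <- c(0:(ceiling(n / 2) - 1), -(n %/% 2):-1)
  r <- sqrt(outer(k^2, k^2, "+"))
  h <- ifelse(r < cutoff / 2, 1,
              ifelse(r < cutoff,
                     0.5 * (1 + cos(pi * (r - cutoff / 2) / (cutoff / 2))),
                     0))
  h
}

#' Gaussian-windowed Fourier low-pass filter
#'
#' Overlap-add windowed Fourier analysis: each tile is multiplied by a
#' Gaussian window, Fourier transformed, its spectrum multiplied by a
#' radial raised-cosine low-pass, inverse transformed and recombined with
#' the same window at half-tile stride. The recombination is normalized
#' by the window times its own filtered version, which makes the filter
#' exactly preserve constants; the whole operation is linear.
#'
#' @param image numeric matrix (intensity image).
#' @param params a \code{\link{gaborParams}} list.
#' @return filtered real matrix of the same shape.
#' @export
gaborLowpass <- function(image, params = gaborParams()) {
  h <- nrow(image); w <- ncol(image)
  n <- params$tile
  if (n > h || n > w)
    stop("tile (", n, ") larger than the image (", h, " x ", w, ")")
  stride <- n %/% 2L
  pad <- stride
  # reflect-pad so every output pixel is covered by interior tiles
  padTo <- function(len) {
    total <- len + 2L * pad
    extra <- (stride - (total - n) %% stride) %% stride
    total + extra
  }
  hp <- padTo(h); wp <- padTo(w)
  reflect <- function(i, len) {
    i <- (i - 1L) %% (2L * len)
    ifelse(i < len, i + 1L, 2L * len - i)
  }
  ri <- reflect(seq_len(hp) - pad, h)
  ci <- reflect(seq_len(wp) - pad, w)
  x <- image[ri, ci, drop = FALSE]

  g <- exp(-0.5 * ((seq_len(n) - (n + 1) / 2) / params$windowSigma)^2)
  win <- outer(g, g)
  lp <- .lowpassFilter(n, params$cutoff)
  # filtered window: normalizing by win * filt(win) passes constants
  # exactly (numerator and denominator coincide for a constant input)
  filtWin <- Re(fft(fft(win) * lp, inverse = TRUE)) / (n * n)

  num <- matrix(0, hp, wp)
  den <- matrix(0, hp, wp)
  for (r0 in seq(1L, hp - n + 1L, by = stride)) {
    for (c0 in seq(1L, wp - n + 1L, by = stride)) {
      rr <- r0:(r0 + n - 1L); cc <- c0:(c0 + n - 1L)
      patch <- win * x[rr, cc]
      filt <- Re(fft(fft(patch) * lp, inverse = TRUE)) / (n * n)
      num[rr, cc] <- num[rr, cc] + win * filt
      den[rr, cc] <- den[rr, cc] + win * filtWin
    }
  }
  out <- num / den
  out[(pad + 1L):(pad + h), (pad + 1L):(pad + w)]
}

#' Moment-preserving bilevel threshold
#'
#' Tsai's moment-preserving thresholding: chooses the cut so that a
#' two-level image with levels and mixing fraction preserving the first
#' three sample moments of the input results. The returned value is the
#' gray level at which the cumulative histogram first reaches the
#' preserved low-class fraction; pixels at or below it form the dark
#' class.
#'
#' @param image numeric matrix or vector of gray values.
#' @return the threshold value.
#' @export
momentThreshold <- function(image) {
  v <- as.numeric(image)
  v <- v[is.finite(v)]
  if (length(unique(v)) < 2L)
    stop("degenerate histogram: image has fewer than 2 distinct values")
  m1 <- mean(v); m2 <- mean(v^2); m3 <- mean(v^3)
  cd <- m2 - m1^2
  if (!is.finite(cd) || cd <= 1e-9 * (1 + m1^2))
    stop("degenerate histogram: image is (numerically) constant")
  c0 <- (m1 * m3 - m2^2) / cd
  c1 <- (m1 * m2 - m3) / cd
  disc <- c1^2 - 4 * c0
  if (disc < 0) disc <- 0
  z0 <- 0.5 * (-c1 - sqrt(disc))
  z1 <- 0.5 * (-c1 + sqrt(disc))
  p0 <- (z1 - m1) / (z1 - z0)
  p0 <- min(max(p0, 0), 1)
  sv <- sort(v)
  idx <- max(1L, min(length(sv), ceiling(p0 * length(sv))))
  sv[idx]
}

#' Segment epithelial territories
#'
#' Pipeline: intensity (Ohta I1) -> windowed-Fourier low-pass ->
#' moment-preserving threshold -> keep the darker (nuclei-dense) side ->
#' binary opening with a disk -> intersect with the ROI.
#'
#' @param slide a \linkS4class{StainedSlide} or RGB array.
#' @param roi logical mask (default whole frame).
#' @param params a \code{\link{gaborParams}} list.
#' @return logical epithelium mask.
#' @export
segmentEpithelium <- function(slide, roi = NULL, params = gaborParams()) {
  i1 <- ohtaTransform(slide)@i1
  sm <- gaborLowpass(i1, params)
  thr <- momentThreshold(sm)
  fg <- if (params$darkIsForeground) sm <= thr else sm > thr
  if (params$openingRadius > 0) {
    brush <- EBImage::makeBrush(2L * round(params$openingRadius) + 1L,
                                shape = "disc")
    fg <- EBImage::opening(fg * 1, brush) > 0.5
  }
  if (!is.null(roi)) {
    stopifnot(identical(dim(roi), dim(fg)))
    fg <- fg & roi
  }
  fg
}
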