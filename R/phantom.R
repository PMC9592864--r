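## Synthetic slide phantoms with known epithelium/stain ground truth.
##
## Rendering model: every pixel starts near-white and is darkened by two
## linear "dyes" -- a hematoxylin vector h (strongest blue retention, so
## nuclei-dense epithelium reads blue) and a DAB vector s (strongest blue
## removal, so staining reads brown). The red-blue separation (Ohta I2)
## is monotone in the stain amount s by construction, which makes the
## I2-based detector well-posed on phantoms.

#' Specification of a synthetic slide phantom
#'
#' @param seed integer; drives all randomness of the bundle.
#' @param height,width frame size in pixels.
#' @param epitheliumFraction target area fraction of epithelium in (0,1).
#' @param blobScale Gaussian smoothing scale (pixels) of the noise fields
#'   that shape epithelium regions and stain foci.
#' @param nucleiTextureAmplitude SD of the high-frequency hematoxylin
#'   texture added inside tissue (in dye units; epithelium density is
#'   about 0.55).
#' @param stainLevelProps length-3 proportions of epithelium assigned to
#'   low/medium/high stain foci (sum to 1).
#' @param stainIntensityMeans length-3 strictly decreasing brown-channel
#'   intensities (0-255) of the three levels; near 255 means essentially
#'   unstained.
#' @param stainNoiseSd per-channel Gaussian pixel noise SD.
#' @param markErrorRate flip probability used by
#'   \code{\link{simulateExpertMarks}} defaults.
#' @return a validated spec list.
#' @export
phantomSpec <- function(seed = 1L, height = 512L, width = 512L,
                        epitheliumFraction = 0.5, blobScale = 96,
                        nucleiTextureAmplitude = 0.12,
                        stainLevelProps = c(0.2, 0.5, 0.3),
                        stainIntensityMeans = c(235, 160, 60),
                        stainNoiseSd = 6, markErrorRate = 0) {
  stopifnot(height >= 32, width >= 32,
            epitheliumFraction > 0, epitheliumFraction < 1,
            blobScale > 0, nucleiTextureAmplitude >= 0,
            length(stainLevelProps) == 3L,
            abs(sum(stainLevelProps) - 1) <= 1e-9,
            length(stainIntensityMeans) == 3L,
            all(diff(stainIntensityMeans) < 0),
            all(stainIntensityMeans >= 0 & stainIntensityMeans <= 255),
            stainNoiseSd >= 0, markErrorRate >= 0, markErrorRate < 1)
  list(seed = as.integer(seed), height = as.integer(height),
       width = as.integer(width),
       epitheliumFraction = epitheliumFraction, blobScale = blobScale,
       nucleiTextureAmplitude = nucleiTextureAmplitude,
       stainLevelProps = stainLevelProps,
       stainIntensityMeans = stainIntensityMeans,
       stainNoiseSd = stainNoiseSd, markErrorRate = markErrorRate)
}

## Smooth unit-variance random field: white noise convolved with a
## Gaussian in the Fourier domain (periodic boundary), re-standardized.
## Exact for any smoothing scale, independent of kernel truncation.
.smoothField <- function(h, w, sigma) {
  z <- matrix(rnorm(h * w), h, w)
  fy <- c(0:(h %/% 2), -((h - h %/% 2 - 1):1)) / h
  fx <- c(0:(w %/% 2), -((w - w %/% 2 - 1):1)) / w
  att <- exp(-2 * pi^2 * sigma^2 * outer(fy^2, fx^2, "+"))
  f <- Re(fft(fft(z) * att, inverse = TRUE)) / (h * w)
  (f - mean(f)) / sd(f)
}

#' Generate a slide phantom with known ground truth
#'
#' Epithelium is a thresholded smooth noise field (threshold at the
#' quantile matching the target fraction) with added high-frequency
#' nuclei texture; stain foci are a second, independent smooth field cut
#' into low/medium/high regions at the requested proportions inside
#' epithelium. Staining darkens and browns pixels (raising red-blue
#' contrast); the background stroma carries a weak hematoxylin tint.
#' Deterministic for a fixed seed.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @return list with \code{slide} (a \linkS4class{StainedSlide}),
#'   \code{trueEpithelium}, \code{trueStain} (logical masks),
#'   \code{levelMap} (integer 0 outside epithelium, 1/2/3 = low/med/high
#'   focus), \code{stainAmount} (the per-pixel DAB dye amount in [0,1])
#'   and \code{trueStainFraction} (share of frame pixels truly stained).
#' @export
generatePhantom <- function(spec = phantomSpec()) {
  h <- spec$height; w <- spec$width
  withSeed(spec$seed, {
    epiField <- .smoothField(h, w, spec$blobScale)
    stainField <- .smoothField(h, w, spec$blobScale)
    jitterField <- .smoothField(h, w, spec$blobScale)
    texture <- matrix(rnorm(h * w, sd = spec$nucleiTextureAmplitude), h, w)
    noise <- array(rnorm(h * w * 3, sd = spec$stainNoiseSd), c(h, w, 3))
  })
  cut <- quantile(epiField, 1 - spec$epitheliumFraction, names = FALSE)
  epi <- epiField >= cut
  achieved <- mean(epi)
  if (abs(achieved - spec$epitheliumFraction) > 0.05)
    warning(sprintf(
      "epithelium fraction target %.3f not reached (achieved %.3f)",
      spec$epitheliumFraction, achieved))

  # stain level per epithelium pixel from the focus field quantiles
  levelMap <- matrix(0L, h, w)
  p <- spec$stainLevelProps
  sf <- stainField[epi]
  cuts <- quantile(sf, cumsum(p)[1:2], names = FALSE)
  levelMap[epi] <- 1L + findInterval(sf, cuts, left.open = TRUE)

  sAmount <- matrix(0, h, w)
  for (lv in 1:3)
    sAmount[levelMap == lv] <- (255 - spec$stainIntensityMeans[lv]) / 255
  # smooth within-level intensity variation (relative SD 15%), as real
  # chromogen deposition varies from region to region within one grade
  sAmount <- pmax(sAmount * (1 + 0.15 * jitterField), 0)
  trueStain <- sAmount >= 0.2

  hema <- matrix(0.03, h, w)          # faint background
  hema[epi] <- 0.55                    # nuclei-dense epithelium
  hema[!epi] <- 0.15                   # stroma
  hema <- pmax(hema + texture * (hema > 0.1), 0)

  # DAB hue saturates with dye amount while darkness keeps increasing,
  # as for a thickening chromogen layer; red-blue separation stays
  # monotone in the stain amount
  hue <- pmin(sAmount / 0.35, 1)
  px <- array(0, c(h, w, 3))
  px[, , 1] <- 245 - 155 * hema - 65 * sAmount + 45 * hue + noise[, , 1]
  px[, , 2] <- 245 - 140 * hema - 50 * sAmount + noise[, , 2]
  px[, , 3] <- 245 - 120 * hema - 65 * sAmount - 45 * hue + noise[, , 3]
  px <- round(pmin(pmax(px, 0), 255))

  slide <- new("StainedSlide", pixels = px, pixelSizeUm = 0.5)
  list(slide = slide, trueEpithelium = epi, trueStain = trueStain,
       levelMap = levelMap, stainAmount = sAmount,
       trueStainFraction = mean(trueStain),
       achievedEpitheliumFraction = achieved, spec = spec)
}

#' Majority ground-truth stain level per hexagon
#'
#' For each hexagon of a tiling, the most frequent ground-truth focus
#' level among its epithelium pixels (1 = low, 2 = medium, 3 = high; ties
#' to the lower level). Hexagons with no epithelium pixel get \code{NA}.
#'
#' @param bundle a \code{\link{generatePhantom}} result.
#' @param tiling a \linkS4class{HexTiling} over the same frame.
#' @return integer vector of length \code{nHexagons(tiling)}.
#' @export
trueHexLevels <- function(bundle, tiling) {
  idx <- tiling@assignment
  sel <- !is.na(idx) & bundle$trueEpithelium
  out <- rep(NA_integer_, tiling@nHex)
  if (!any(sel)) return(out)
  tab <- table(hex = idx[sel], level = bundle$levelMap[sel])
  maj <- apply(tab, 1, which.max)
  out[as.integer(rownames(tab))] <- as.integer(colnames(tab))[maj]
  out
}

#' Simulate expert marks from ground truth
#'
#' Labels each grid cross by the truth mask at its node, then flips each
#' label independently with probability \code{errorRate} (reader error).
#'
#' @param grid a \linkS4class{CrossGrid}.
#' @param truth logical ground-truth mask.
#' @param errorRate flip probability in \code{[0, 1)}.
#' @param seed integer seed for the flips.
#' @return a \linkS4class{MarkSet}.
#' @export
simulateExpertMarks <- function(grid, truth, errorRate = 0, seed = 1L) {
  stopifnot(errorRate >= 0, errorRate < 1)
  marks <- sampleMaskAt(grid, truth)
  if (errorRate > 0) {
    flip <- withSeed(seed, runif(length(marks@labels)) < errorRate)
    lab <- marks@labels
    lab[flip] <- ifelse(lab[flip] == "labeled", "unlabeled", "labeled")
    marks@labels <- lab
  }
  marks
}
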