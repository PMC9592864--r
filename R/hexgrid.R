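## Hexagonal tiling of the ROI and per-hexagon transmittance of DAB
## staining restricted to epithelium.

## Axial-coordinate rounding: map continuous (x, y) to the containing
## pointy-top hexagon of circumradius R. Returns integer axial (q, r).
.hexRound <- function(x, y, R) {
  qf <- (sqrt(3) / 3 * x - y / 3) / R
  rf <- (2 / 3 * y) / R
  xf <- qf; zf <- rf; yf <- -xf - zf
  rx <- round(xf); ry <- round(yf); rz <- round(zf)
  dx <- abs(rx - xf); dy <- abs(ry - yf); dz <- abs(rz - zf)
  fixX <- dx > dy & dx > dz
  fixY <- !fixX & dy > dz
  rx[fixX] <- -ry[fixX] - rz[fixX]
  rz[!fixX & !fixY] <- -rx[!fixX & !fixY] - ry[!fixX & !fixY]
  cbind(q = rx, r = rz)
}

#' Tile an image frame with pointy-top hexagons
#'
#' Assigns every pixel (via its center) to the hexagon whose center is
#' nearest, using exact axial-coordinate rounding, so the hexagons
#' partition the frame with no gaps or overlaps. Hexagons are indexed
#' only where they intersect the ROI; pixels outside the ROI get
#' \code{NA}.
#'
#' @param roi logical mask (the frame to tile).
#' @param circumradius hexagon circumradius in pixels (>= 2); the default
#'   100 px is about 50 um at 0.5 um/px.
#' @param origin length-2 numeric (row, col) offset of the lattice origin
#'   in pixels.
#' @return a \linkS4class{HexTiling}.
#' @export
tileHexagons <- function(roi, circumradius = 100, origin = c(0, 0)) {
  stopifnot(is.logical(roi), is.matrix(roi), circumradius >= 2)
  h <- nrow(roi); w <- ncol(roi)
  if (circumradius > max(h, w))
    warning("circumradius exceeds the frame extent: single-hexagon tiling")
  # pixel centers in continuous coordinates, relative to the lattice origin
  x <- rep(seq_len(w) - 0.5 - origin[2], each = h)
  y <- rep(seq_len(h) - 0.5 - origin[1], times = w)
  ax <- .hexRound(x, y, circumradius)
  key <- paste(ax[, 1], ax[, 2])
  inRoi <- as.vector(roi)
  keys <- unique(key[inRoi])
  idx <- match(key, keys)
  idx[!inRoi] <- NA_integer_
  assignment <- matrix(idx, h, w)
  qr <- do.call(rbind, strsplit(keys, " ", fixed = TRUE))
  q <- as.numeric(qr[, 1]); r <- as.numeric(qr[, 2])
  centers <- cbind(row = 1.5 * circumradius * r + origin[1],
                   col = sqrt(3) * circumradius * (q + r / 2) + origin[2])
  new("HexTiling", circumradius = circumradius, assignment = assignment,
      centers = centers, nHex = length(keys))
}

#' Per-hexagon transmittance of staining within epithelium
#'
#' For each hexagon, \code{T = sum over epithelium pixels of
#' (255 - brown) / (epithelium pixel count x 255)}, a value in
#' \code{[0, 1]}: 0 with no staining, 1 when every epithelium pixel is
#' stained fully dark. Unstained pixels carry brown = 255 and contribute
#' zero, so the sum effectively runs over the stained epithelial pixels
#' only. Hexagons with fewer than \code{minEpiPixels} epithelium pixels
#' are undefined (\code{NA}).
#'
#' @param tiling a \linkS4class{HexTiling}.
#' @param brown brown-intensity matrix from \code{\link{brownIntensity}}.
#' @param epithelium logical epithelium mask.
#' @param minEpiPixels minimum epithelium pixels for a defined value.
#' @return data.frame with \code{hex_index}, \code{center_row},
#'   \code{center_col}, \code{n_epi} and \code{transmittance}.
#' @export
hexTransmittance <- function(tiling, brown, epithelium, minEpiPixels = 50) {
  stopifnot(identical(dim(brown), dim(tiling@assignment)),
            identical(dim(epithelium), dim(tiling@assignment)))
  idx <- tiling@assignment
  sel <- !is.na(idx) & epithelium
  nEpi <- tabulate(idx[sel], nbins = tiling@nHex)
  absorb <- numeric(tiling@nHex)
  if (any(sel)) {
    rs <- rowsum(255 - brown[sel], group = idx[sel])
    absorb[as.integer(rownames(rs))] <- rs[, 1]
  }
  tr <- ifelse(nEpi >= minEpiPixels, absorb / (nEpi * 255), NA_real_)
  data.frame(hex_index = seq_len(tiling@nHex),
             center_row = tiling@centers[, 1],
             center_col = tiling@centers[, 2],
             n_epi = nEpi,
             transmittance = tr)
}

#' Per-case hexagon transmittance table
#'
#' Wraps \code{\link{hexTransmittance}} with the case and marker
#' identifiers, the tabular form every downstream stage consumes.
#'
#' @param case,marker identifiers.
#' @inheritParams hexTransmittance
#' @return data.frame with \code{case} and \code{marker} prepended.
#' @export
hexTable <- function(case, marker, tiling, brown, epithelium,
                     minEpiPixels = 50) {
  cbind(case = case, marker = marker,
        hexTransmittance(tiling, brown, epithelium, minEpiPixels))
}

#' Pool defined transmittance values across cases
#'
#' Concatenates all defined (non-\code{NA}) transmittances from a list of
#' per-case tables, the input of the marker-level 3-component mixture
#' fit.
#'
#' @param tables list of \code{\link{hexTable}} data.frames (one marker).
#' @return numeric vector.
#' @export
poolTransmittance <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  v <- unlist(lapply(tables, function(t) t$transmittance), use.names = FALSE)
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("empty pool: no defined hexagon values")
  v
}
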