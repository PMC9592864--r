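## Raster and table I/O: 8-bit RGB TIFF/PNG in, 0/255 mask TIFF out,
## GeoJSON-style polygon ROIs, CSV label tables.

#' Read an RGB slide image
#'
#' Reads an 8-bit RGB TIFF or PNG into a \linkS4class{StainedSlide}. For a
#' multi-page (pyramidal) TIFF the highest-resolution page is used. The
#' pixel size defaults to 0.5 um (a 20x scan) when the file carries no
#' resolution metadata.
#'
#' @param path path to a TIFF or PNG file.
#' @param pixelSizeUm pixel size override in micrometres.
#' @return a \linkS4class{StainedSlide}.
#' @export
readSlideImage <- function(path, pixelSizeUm = 0.5) {
  if (!file.exists(path)) stop("cannot read image: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = ,
    tiff = {
      pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
      npx <- vapply(pages, function(p) prod(dim(p)[1:2]), numeric(1))
      pages[[which.max(npx)]]
    },
    png = png::readPNG(path),
    stop("unsupported image format: .", ext)
  )
  if (length(dim(img)) != 3L || dim(img)[3] < 3L)
    stop("unsupported image: expected an 8-bit RGB raster, got ",
         paste(dim(img), collapse = "x"))
  px <- round(img[, , 1:3] * 255)
  new("StainedSlide", pixels = px, pixelSizeUm = pixelSizeUm)
}

#' Write / read a binary mask as single-channel 0/255 TIFF
#'
#' @param mask logical matrix.
#' @param path output path (.tif).
#' @return \code{readMask} returns the logical matrix; round-trips are
#'   lossless.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  tiff::writeTIFF(ifelse(mask, 1, 0), path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  if (!file.exists(path)) stop("cannot read mask: file not found: ", path)
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m > 0.5
}

## Point-in-polygon by even-odd ray casting; points exactly on an edge
## count as inside. poly is an n x 2 matrix of (x, y) vertices.
.pointsInPolygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  onedge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    # edge hit: collinear and within the segment's bounding box
    cross <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    hit <- abs(cross) < 1e-9 &
      px >= pmin(xi, xj) - 1e-9 & px <= pmax(xi, xj) + 1e-9 &
      py >= pmin(yi, yj) - 1e-9 & py <= pmax(yi, yj) + 1e-9
    onedge <- onedge | hit
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | onedge
}

#' Rasterize a polygon ROI onto a pixel grid
#'
#' A pixel belongs to the ROI iff its center lies inside (or exactly on
#' the boundary of) one of the polygons. Coordinates are 0-based pixel
#' units with columns (x, y) = (col, row), so the center of the top-left
#' pixel is (0.5, 0.5).
#'
#' @param polygons a list of \code{n x 2} numeric matrices (x, y vertex
#'   coordinates), or a single matrix.
#' @param dim integer (H, W) of the target frame.
#' @return logical \code{H x W} matrix.
#' @export
rasterizeRoi <- function(polygons, dim) {
  if (is.matrix(polygons)) polygons <- list(polygons)
  h <- as.integer(dim[1]); w <- as.integer(dim[2])
  mask <- matrix(FALSE, h, w)
  if (length(polygons) == 0L) {
    warning("empty polygon list: returning an empty ROI")
    return(mask)
  }
  px <- rep(seq_len(w) - 0.5, each = h)
  py <- rep(seq_len(h) - 0.5, times = w)
  for (poly in polygons) {
    poly <- as.matrix(poly)
    if (nrow(poly) < 3L)
      stop("degenerate polygon: fewer than 3 vertices")
    if (min(poly[, 1]) < 0 || max(poly[, 1]) > w ||
        min(poly[, 2]) < 0 || max(poly[, 2]) > h)
      stop("polygon coordinates fall outside the [0,W] x [0,H] frame")
    mask <- mask | matrix(.pointsInPolygon(px, py, poly), h, w)
  }
  mask
}

#' Read / write ROI polygons as JSON
#'
#' GeoJSON-style interchange: a JSON array of polygons, each an array of
#' \code{[x, y]} vertex pairs in 0-based pixel units.
#'
#' @param polygons list of \code{n x 2} matrices.
#' @param path JSON file path.
#' @export
writeRoiJson <- function(polygons, path) {
  if (is.matrix(polygons)) polygons <- list(polygons)
  jsonlite::write_json(lapply(polygons, function(p) unname(as.matrix(p))),
                       path, digits = NA)
  invisible(path)
}

#' @rdname writeRoiJson
#' @export
readRoiJson <- function(path) {
  x <- jsonlite::read_json(path)
  lapply(x, function(p)
    do.call(rbind, lapply(p, function(v) as.numeric(unlist(v)))))
}

#' Read / write a label table as CSV
#'
#' Plain CSV with a header row; \code{schema} (a character vector of
#' required column names) is checked on read, and any missing cell in the
#' declared schema is an error.
#'
#' @param table a data.frame.
#' @param path CSV file path.
#' @param schema character vector of required column names.
#' @return \code{readLabelTable} returns the data.frame.
#' @export
writeLabelTable <- function(table, path) {
  write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeLabelTable
#' @export
readLabelTable <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("cannot read table: file not found: ", path)
  df <- read.csv(path, check.names = FALSE)
  if (!is.null(schema)) {
    missing <- setdiff(schema, names(df))
    if (length(missing))
      stop("schema error: missing column(s): ",
           paste(missing, collapse = ", "))
    if (nrow(df) && anyNA(df[schema]))
      stop("schema error: missing cells in declared columns")
  }
  df
}
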