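## Shared test helpers: a session-cached small phantom so several test
## files can reuse one rendering, and a brute-force point-in-polygon
## oracle independent of the implementation.

.testCache <- new.env(parent = emptyenv())

cachedPhantom <- function(seed = 11) {
  key <- paste0("phantom", seed)
  if (is.null(.testCache[[key]]))
    .testCache[[key]] <- generatePhantom(phantomSpec(seed = seed))
  .testCache[[key]]
}

## exhaustive oracle: classify every pixel center against every edge via
## the winding-number test of a dense polygon sampling
orackePointInPolygon <- function(px, py, poly) {
  n <- nrow(poly)
  wn <- 0
  on <- FALSE
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    x1 <- poly[i, 1]; y1 <- poly[i, 2]
    x2 <- poly[j, 1]; y2 <- poly[j, 2]
    cr <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    if (abs(cr) < 1e-9 &&
        px >= min(x1, x2) - 1e-9 && px <= max(x1, x2) + 1e-9 &&
        py >= min(y1, y2) - 1e-9 && py <= max(y1, y2) + 1e-9)
      on <- TRUE
    if (y1 <= py && y2 > py && cr > 0) wn <- wn + 1
    if (y1 > py && y2 <= py && cr < 0) wn <- wn - 1
  }
  on || wn != 0
}
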