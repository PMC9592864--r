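test_that("hexagons partition the frame without gaps or overlaps", {
  roi <- matrix(TRUE, 120, 140)
  til <- tileHexagons(roi, 12)
  a <- til@assignment
  expect_false(anyNA(a))                       # every pixel assigned once
  expect_equal(sort(unique(c(a))), seq_len(nHexagons(til)))
  # ROI-restricted tiling leaves non-ROI pixels unassigned
  roi2 <- roi; roi2[1:60, ] <- FALSE
  til2 <- tileHexagons(roi2, 12)
  expect_true(all(is.na(til2@assignment[1:60, ])))
  expect_false(anyNA(til2@assignment[61:120, ]))
})

test_that("interior hexagon pixel counts match the area formula", {
  roi <- matrix(TRUE, 300, 300)
  r <- 20
  til <- tileHexagons(roi, r)
  counts <- table(til@assignment)
  centers <- hexCenters(til)
  interior <- centers[, 1] > 2 * r & centers[, 1] < 300 - 2 * r &
              centers[, 2] > 2 * r & centers[, 2] < 300 - 2 * r
  area <- 3 * sqrt(3) / 2 * r^2
  cnt <- as.numeric(counts[as.character(which(interior))])
  expect_true(all(abs(cnt - area) / area < 0.05))
})

test_that("tiling is consistent under a lattice-vector translation", {
  roi <- matrix(TRUE, 90, 90)
  r <- 10
  til1 <- tileHexagons(roi, r)
  # shift the origin by one lattice vector: same partition geometry
  til2 <- tileHexagons(roi, r, origin = c(3 * r, sqrt(3) * r))
  interiorCounts <- function(til) {
    cnt <- table(til@assignment)
    ctr <- hexCenters(til)
    keep <- ctr[, 1] > 2 * r & ctr[, 1] < 90 - 2 * r &
            ctr[, 2] > 2 * r & ctr[, 2] < 90 - 2 * r
    sort(as.numeric(cnt[as.character(which(keep))]))
  }
  expect_equal(interiorCounts(til1), interiorCounts(til2))
})

test_that("transmittance matches its defining arithmetic", {
  roi <- matrix(TRUE, 60, 60)
  til <- tileHexagons(roi, 30)    # single dominant hexagon scale
  epi <- matrix(TRUE, 60, 60)
  # no staining -> 0
  tab <- hexTransmittance(til, matrix(255, 60, 60), epi, minEpiPixels = 1)
  expect_true(all(tab$transmittance == 0))
  # fully stained black -> 1
  tab <- hexTransmittance(til, matrix(0, 60, 60), epi, minEpiPixels = 1)
  expect_true(all(tab$transmittance == 1))
  # half black half unstained -> 0.5
  brown <- matrix(255, 60, 60); brown[, 1:30] <- 0
  tab <- hexTransmittance(til, brown, epi, minEpiPixels = 1)
  pooled <- sum(tab$n_epi * tab$transmittance) / sum(tab$n_epi)
  expect_equal(pooled, 0.5, tolerance = 1e-12)
})

test_that("transmittance is bounded, monotone, and respects the n_epi floor", {
  set.seed(21)
  roi <- matrix(TRUE, 80, 80)
  til <- tileHexagons(roi, 14)
  epi <- matrix(runif(80 * 80) > 0.4, 80, 80)
  brown <- matrix(sample(0:255, 80 * 80, TRUE), 80, 80)
  tab <- hexTransmittance(til, brown, epi, minEpiPixels = 30)
  ok <- !is.na(tab$transmittance)
  expect_true(all(tab$transmittance[ok] >= 0 & tab$transmittance[ok] <= 1))
  expect_true(all(tab$n_epi[!ok] < 30) && all(tab$n_epi[ok] >= 30))
  # darkening any stained pixel never decreases T
  brown2 <- pmax(brown - 40, 0)
  tab2 <- hexTransmittance(til, brown2, epi, minEpiPixels = 30)
  expect_true(all(tab2$transmittance[ok] >= tab$transmittance[ok]))
})

test_that("pooling concatenates defined values across cases", {
  mk <- function(n, nNA) data.frame(transmittance = c(runif(n),
                                                      rep(NA, nNA)))
  set.seed(2)
  pooled <- poolTransmittance(list(mk(10, 2), mk(20, 0), mk(30, 5)))
  expect_length(pooled, 60)
  expect_error(poolTransmittance(list(mk(0, 4))), "empty pool")
})
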