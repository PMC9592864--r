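test_that("Ohta transform matches its closed forms", {
  px <- array(0, c(1, 3, 3))
  px[1, 1, ] <- c(128, 128, 128)   # gray
  px[1, 2, ] <- c(255, 0, 0)       # pure red
  px[1, 3, ] <- c(0, 0, 255)       # pure blue
  o <- ohtaTransform(px)
  expect_equal(c(o@i1), c(128, 85, 85))
  expect_equal(c(o@i2), c(0, 127.5, -127.5))
  expect_equal(c(o@i3), c(0, -63.75, -63.75))
})

test_that("Ohta transform is linear and invertible", {
  set.seed(8)
  px <- array(sample(0:255, 4 * 4 * 3, TRUE), c(4, 4, 3))
  o <- ohtaTransform(px)
  # invert: R = I1 + I2 - I3*2/3 ... check via explicit solve
  r <- o@i1 + o@i2 - (2 / 3) * o@i3
  g <- o@i1 + (4 / 3) * o@i3
  b <- o@i1 - o@i2 - (2 / 3) * o@i3
  expect_equal(r, px[, , 1], tolerance = 1e-9)
  expect_equal(g, px[, , 2], tolerance = 1e-9)
  expect_equal(b, px[, , 3], tolerance = 1e-9)
})

test_that("stain model threshold lies at the two-Gaussian intersection", {
  set.seed(13)
  x <- c(rnorm(5000, -30, 5), rnorm(5000, 60, 8))
  m <- fitStainModel(x)
  expect_gt(m@decisionThreshold, -30)
  expect_lt(m@decisionThreshold, 60)
  # analytic intersection of the generating components
  f <- function(t) 0.5 * dnorm(t, -30, 5) - 0.5 * dnorm(t, 60, 8)
  ref <- uniroot(f, c(-30, 60))$root
  expect_equal(m@decisionThreshold, ref, tolerance = 3,
               ignore_attr = TRUE)
  expect_error(fitStainModel(rep(3, 5000)), "identical|degenerate")
})

test_that("stain classification is monotone in the calibration shift", {
  b <- cachedPhantom()
  ohta <- ohtaTransform(b$slide)
  roi <- matrix(TRUE, nrow(ohta@i2), ncol(ohta@i2))
  m <- fitStainModel(ohta, roi)
  masks <- lapply(c(-5, 0, 5), function(s)
    classifyStain(ohta, setCalibrationShift(m, s), roi))
  expect_true(all(masks[[2]] | !masks[[3]]))  # raising shift removes pixels
  expect_true(all(masks[[1]] | !masks[[2]]))
  # extreme shifts hit the trivial masks
  lo <- classifyStain(ohta, setCalibrationShift(m, -1e6), roi)
  hi <- classifyStain(ohta, setCalibrationShift(m, 1e6), roi)
  expect_true(all(lo == roi))
  expect_false(any(hi))
})

test_that("stain detection on a phantom recovers the true stain", {
  b <- cachedPhantom()
  ohta <- ohtaTransform(b$slide)
  roi <- matrix(TRUE, nrow(ohta@i2), ncol(ohta@i2))
  st <- classifyStain(ohta, fitStainModel(ohta, roi), roi)
  ag <- maskAgreement(b$trueStain, st)
  expect_gte(ag[["sensitivity"]], 0.9)
  expect_gte(ag[["specificity"]], 0.9)
  expect_lt(abs(mean(st) - b$trueStainFraction), 0.05)
})

test_that("brown intensity carries I1 at stained pixels and 255 elsewhere", {
  px <- array(100, c(4, 4, 3))
  none <- matrix(FALSE, 4, 4)
  expect_true(all(brownIntensity(px, none) == 255))
  checker <- outer(1:4, 1:4, function(i, j) (i + j) %% 2 == 0)
  br <- brownIntensity(px, checker)
  expect_true(all(br[checker] == 100))
  expect_true(all(br[!checker] == 255))
  dark <- array(0, c(2, 2, 3))
  expect_true(all(brownIntensity(dark, matrix(TRUE, 2, 2)) == 0))
})

test_that("stain models survive a JSON round-trip", {
  d <- withr::local_tempdir()
  m <- new("StainModel", weights = c(0.6, 0.4), means = c(-10, 20),
           sds = c(4, 6), decisionThreshold = 3.7, calibrationShift = -1.2)
  writeStainModel(m, file.path(d, "m.json"))
  m2 <- readStainModel(file.path(d, "m.json"))
  expect_equal(effectiveThreshold(m2), effectiveThreshold(m))
  expect_equal(m2@means, m@means)
})
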