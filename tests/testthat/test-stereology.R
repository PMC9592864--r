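test_that("grid construction counts nodes and is seed-reproducible", {
  roi <- matrix(TRUE, 100, 100)
  g <- makeGrid(roi, 10, seed = 3)
  expect_equal(nrow(gridPositions(g)), 100)
  g2 <- makeGrid(roi, 10, seed = 3)
  expect_identical(gridPositions(g), gridPositions(g2))
  expect_false(identical(gridPositions(makeGrid(roi, 10, seed = 4)),
                         gridPositions(g)))
  expect_error(makeGrid(matrix(FALSE, 20, 20), 5), "empty grid")
})

test_that("point counting is an unbiased area-fraction estimator", {
  # disk mask; mean p_hat over many random offsets must approach the
  # true area fraction within Monte-Carlo error
  n <- 64
  d <- sqrt(outer((1:n - 32.5)^2, (1:n - 32.5)^2, "+"))
  mask <- d <= 20
  roi <- matrix(TRUE, n, n)
  truth <- mean(mask)
  ps <- vapply(1:500, function(s)
    estimateRatio(sampleMaskAt(makeGrid(roi, 8, seed = s), mask))$p_hat,
    numeric(1))
  se <- sd(ps) / sqrt(length(ps))
  expect_lt(abs(mean(ps) - truth), 3 * se)
})

test_that("ratio estimates follow the binomial formula", {
  grid <- makeGrid(matrix(TRUE, 50, 50), 5, seed = 1)
  n <- nrow(gridPositions(grid))
  labs <- rep(c("labeled", "unlabeled"), length.out = n)
  labs <- c(rep("labeled", 50), rep("unlabeled", 50),
            rep("excluded", n - 100))
  ms <- new("MarkSet", grid = grid, labels = labs)
  est <- estimateRatio(ms)
  expect_equal(est$p_hat, 0.5)
  expect_equal(est$n, 100)
  expect_equal(est$ci95, 0.5 + c(-1, 1) * 1.96 * sqrt(0.25 / 100),
               tolerance = 1e-9)
  # degenerate cases
  ms0 <- new("MarkSet", grid = grid,
             labels = c(rep("unlabeled", 10), rep("excluded", n - 10)))
  expect_equal(estimateRatio(ms0)$p_hat, 0)
  expect_equal(estimateRatio(ms0)$ci95[1], 0)
  msx <- new("MarkSet", grid = grid, labels = rep("excluded", n))
  expect_error(estimateRatio(msx), "non-excluded")
})

test_that("consensus keeps agreements and excludes disagreements", {
  grid <- makeGrid(matrix(TRUE, 40, 40), 4, seed = 2)
  n <- nrow(gridPositions(grid))
  l1 <- rep(c("labeled", "unlabeled"), length.out = n)
  m1 <- new("MarkSet", grid = grid, labels = l1)
  expect_identical(markLabels(consensusMarks(m1, m1)), l1)
  l2 <- ifelse(l1 == "labeled", "unlabeled", "labeled")
  expect_true(all(markLabels(consensusMarks(m1, new("MarkSet",
    grid = grid, labels = l2))) == "excluded"))
  # ~10% disagreement retains ~90%
  set.seed(6)
  flip <- runif(n) < 0.1
  l3 <- ifelse(flip, l2, l1)
  cons <- consensusMarks(m1, new("MarkSet", grid = grid, labels = l3))
  expect_equal(sum(markLabels(cons) != "excluded"), sum(!flip))
})

test_that("concordance percentages match the 2x2 table arithmetic", {
  grid <- makeGrid(matrix(TRUE, 100, 100), 10, seed = 1)  # 100 nodes
  l1 <- c(rep("labeled", 40), rep("unlabeled", 60))
  l2 <- c(rep("labeled", 30), rep("unlabeled", 10),
          rep("labeled", 10), rep("unlabeled", 50))
  m1 <- new("MarkSet", grid = grid, labels = l1)
  m2 <- new("MarkSet", grid = grid, labels = l2)
  cc <- concordancePercent(m1, m2)
  expect_equal(cc$labeled_agree_pct, 100 * 30 / 50)
  expect_equal(cc$unlabeled_agree_pct, 100 * 50 / 70, tolerance = 1e-9)
  expect_equal(cc$total, 100)
  ident <- concordancePercent(m1, m1)
  expect_equal(ident$labeled_agree_pct, 100)
  expect_equal(ident$unlabeled_agree_pct, 100)
})

test_that("sensitivity/specificity quality factor is their exact mean", {
  grid <- makeGrid(matrix(TRUE, 100, 100), 10, seed = 1)
  ref <- new("MarkSet", grid = grid,
             labels = c(rep("labeled", 40), rep("unlabeled", 60)))
  tst <- new("MarkSet", grid = grid,
             labels = c(rep("labeled", 28), rep("unlabeled", 12),
                        rep("labeled", 6), rep("unlabeled", 54)))
  qf <- qualityFactorSensSpec(ref, tst)
  expect_equal(qf$sensitivity, 28 / 40)
  expect_equal(qf$specificity, 54 / 60)
  expect_identical(qf$qf_sens_spec, (qf$sensitivity + qf$specificity) / 2)
  ident <- qualityFactorSensSpec(ref, ref)
  expect_equal(ident$qf_sens_spec, 1)
  oneClass <- new("MarkSet", grid = grid, labels = rep("labeled", 100))
  expect_error(qualityFactorSensSpec(oneClass, tst), "single class")
})

test_that("CI-overlap quality factor follows interval arithmetic", {
  e <- function(lo, hi) list(p_hat = (lo + hi) / 2, n = 1, ci95 = c(lo, hi))
  expect_equal(qualityFactorCI(e(0.4, 0.6), e(0.4, 0.6)), 1)
  expect_equal(qualityFactorCI(e(0.1, 0.2), e(0.5, 0.6)), 0)
  expect_equal(qualityFactorCI(e(0.40, 0.60), e(0.50, 0.70)), 1 / 3,
               tolerance = 1e-12)
})

test_that("calibration maximizes the quality factor with first-wins ties", {
  b <- cachedPhantom()
  roi <- matrix(TRUE, nrow(b$trueEpithelium), ncol(b$trueEpithelium))
  grid <- makeGrid(roi, 16, seed = 5)
  marks <- simulateExpertMarks(grid, b$trueStain, errorRate = 0)
  ohta <- ohtaTransform(b$slide)
  model <- fitStainModel(ohta, roi)
  shifts <- seq(-20, 20, by = 5)
  best <- calibrateDetector(function(s)
    classifyStain(ohta, setCalibrationShift(model, s), roi),
    as.list(shifts), marks)
  expect_gte(best$qf, 0.95)
  # single candidate returns itself; duplicated candidates return the first
  one <- calibrateDetector(function(s) b$trueStain, list(0), marks)
  expect_equal(one$index, 1)
  two <- calibrateDetector(function(s) b$trueStain, list(0, 0), marks)
  expect_equal(two$index, 1)
})
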