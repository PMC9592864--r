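test_that("deterministic EM recovers a well-separated 3-component mixture", {
  set.seed(42)
  x <- c(rnorm(1000, 0.2, 0.02), rnorm(1000, 0.5, 0.02),
         rnorm(1000, 0.8, 0.02))
  fit <- fitGmm(x, k = 3)
  expect_equal(fit@means, c(0.2, 0.5, 0.8), tolerance = 0.01)
  expect_true(all(abs(fit@weights - 1 / 3) < 0.03))
  expect_equal(sum(fit@weights), 1, tolerance = 1e-9)
  # identical input, identical fit (no random initialisation)
  fit2 <- fitGmm(x, k = 3)
  expect_identical(fit@means, fit2@means)
})

test_that("K = 1 reduces to the sample moments", {
  set.seed(1)
  x <- rnorm(200, 5, 2)
  fit <- fitGmm(x, k = 1)
  expect_equal(fit@means, mean(x), tolerance = 1e-6)
  expect_equal(fit@sds, sqrt(mean((x - mean(x))^2)), tolerance = 1e-6)
})

test_that("EM log-likelihood is monotone non-decreasing", {
  set.seed(3)
  x <- c(rnorm(300, 0, 1), rnorm(300, 4, 1))
  # trace by refitting with increasing iteration caps
  lls <- vapply(1:12, function(it)
    suppressWarnings(fitGmm(x, k = 2, maxIter = it)@logLik), numeric(1))
  expect_true(all(diff(lls) >= -1e-8))
})

test_that("EM agrees with an independent mixture fitter", {
  skip_if_not_installed("mclust")
  suppressMessages(withr::local_package("mclust"))
  set.seed(9)
  x <- c(rnorm(800, -2, 0.5), rnorm(1200, 1.5, 0.8))
  fit <- fitGmm(x, k = 2)
  ref <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(fit@means, as.numeric(ref$parameters$mean), tolerance = 0.05)
  expect_equal(fit@weights, as.numeric(ref$parameters$pro), tolerance = 0.02)
})

test_that("degenerate inputs are rejected", {
  expect_error(fitGmm(rep(1, 100), k = 2), "identical")
  expect_error(fitGmm(rnorm(10), k = 3), "too few")
})

test_that("adjacent-curve intersections match closed forms and a grid oracle", {
  # symmetry: equal weights and sds -> midpoint
  g <- new("Gmm1D", k = 3L, weights = rep(1, 3) / 3, means = c(0, 1, 2),
           sds = rep(0.1, 3), logLik = 0, nIter = 1L)
  thr <- intersectAdjacent(g)
  expect_equal(thr@t1, 0.5, tolerance = 1e-9)
  expect_equal(thr@t2, 1.5, tolerance = 1e-9)

  # closed-form equal-variance solution with unequal weights
  g2 <- new("Gmm1D", k = 3L, weights = c(0.7, 0.3, 0) + c(0, 0, 1e-12),
           means = c(0, 1, 2), sds = c(0.1, 0.1, 0.1), logLik = 0,
           nIter = 1L)
  g2@weights <- g2@weights / sum(g2@weights)
  thr2 <- intersectAdjacent(g2)
  expect_equal(thr2@t1, 0.5 + 0.1^2 * log(0.7 / 0.3), tolerance = 1e-6)

  # dense-grid crossing oracle on a general fitted model
  set.seed(5)
  x <- c(rnorm(500, 0.15, 0.04), rnorm(700, 0.45, 0.06),
         rnorm(400, 0.8, 0.05))
  fit <- fitGmm(x, k = 3)
  thr3 <- intersectAdjacent(fit)
  crossing <- function(i, j) {
    xs <- seq(fit@means[i], fit@means[j], length.out = 1e5)
    di <- fit@weights[i] * dnorm(xs, fit@means[i], fit@sds[i])
    dj <- fit@weights[j] * dnorm(xs, fit@means[j], fit@sds[j])
    xs[which(diff(sign(di - dj)) != 0)[1]]
  }
  expect_equal(thr3@t1, crossing(1, 2), tolerance = 1e-4)
  expect_equal(thr3@t2, crossing(2, 3), tolerance = 1e-4)
  # ordering invariant
  expect_true(fit@means[1] < thr3@t1 && thr3@t1 < fit@means[2] &&
              fit@means[2] < thr3@t2 && thr3@t2 < fit@means[3])
})

test_that("class assignment uses half-open intervals with upper boundaries", {
  thr <- new("ThresholdPair", t1 = 0.3, t2 = 0.6)
  expect_equal(assignClasses(c(0.1, 0.2), thr), c(n0 = 2, n1 = 0, n2 = 0))
  # boundary values belong to the upper class
  expect_equal(assignClasses(c(0.3, 0.6), thr), c(n0 = 0, n1 = 1, n2 = 1))
  # brute-force comparison on a uniform grid
  v <- seq(0, 1, length.out = 300)
  got <- assignClasses(v, thr)
  expect_equal(unname(got),
               c(sum(v < 0.3), sum(v >= 0.3 & v < 0.6), sum(v >= 0.6)))
})

test_that("case-calling rules reproduce published class-count rows", {
  # main-class rule
  expect_equal(callCaseMainClass(c(198, 770, 0)), "high")
  expect_equal(callCaseMainClass(c(1204, 162, 0)), "low")
  expect_equal(callCaseMainClass(c(711, 636, 4)), "low")
  expect_error(callCaseMainClass(c(0, 0, 0)), "empty")
  # high-class 50% rule
  r <- callCaseR50(c(201, 228, 2417))
  expect_equal(r$r_pct, 84.93, tolerance = 0.005)
  expect_equal(r$label, "high")
  r <- callCaseR50(c(278, 322, 438))
  expect_equal(r$r_pct, 42.20, tolerance = 0.005)
  expect_equal(r$label, "low")
  r <- callCaseR50(c(2, 74, 65))
  expect_equal(r$r_pct, 46.10, tolerance = 0.005)
  expect_equal(r$label, "low")
  # exact tie at 50% is called high
  expect_equal(callCaseR50(c(1, 1, 2))$label, "high")
})

test_that("discordance counting flags label mismatches and missing experts", {
  df <- data.frame(case = c("a", "b", "c"),
                   ip_label = c("low", "high", "high"),
                   expert_label = c("low", "low", "high"))
  d <- discordance(df)
  expect_equal(d$count, 1)
  expect_equal(d$table$case, "b")
  df$expert_label[2] <- NA
  expect_error(discordance(df), "b")
})
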