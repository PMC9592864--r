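## Deterministic 1-D Gaussian mixture EM, adjacent-curve intersection
## thresholds, hexagon classes and the first-approach case calls.

#' Fit a one-dimensional Gaussian mixture by deterministic EM
#'
#' Expectation-maximisation with a fully deterministic initialisation, so
#' the marker-level thresholds derived from the fit are bit-reproducible
#' run to run: component means start at the (2k-1)/(2K) sample quantiles,
#' weights at 1/K and standard deviations at the sample SD divided by K.
#' Standard deviations are floored at \code{1e-4} of the data range; a
#' component pinned at the floor for more than 10 consecutive iterations
#' is treated as collapsed. Components are sorted by mean on return.
#'
#' @param values numeric vector of observations.
#' @param k number of components.
#' @param tol EM stops when the log-likelihood gain drops below this.
#' @param maxIter iteration cap.
#' @return a \linkS4class{Gmm1D}.
#' @export
fitGmm <- function(values, k = 3, tol = 1e-8, maxIter = 500) {
  x <- as.numeric(values[is.finite(values)])
  n <- length(x)
  k <- as.integer(k)
  if (n < 10L * k)
    stop("too few values to fit ", k, " components (need >= ", 10 * k, ")")
  rng <- diff(range(x))
  if (rng == 0) stop("degenerate input: all values identical")
  sdFloor <- 1e-4 * rng

  mu <- as.numeric(quantile(x, (2 * seq_len(k) - 1) / (2 * k), names = FALSE))
  w <- rep(1 / k, k)
  sig <- rep(max(sd(x) / k, sdFloor), k)
  collapsed <- integer(k)
  ll <- -Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # E step in log space to survive narrow components
    lw <- matrix(0, n, k)
    for (j in seq_len(k))
      lw[, j] <- log(w[j]) + dnorm(x, mu[j], sig[j], log = TRUE)
    m <- apply(lw, 1, max)
    lse <- m + log(rowSums(exp(lw - m)))
    llNew <- sum(lse)
    resp <- exp(lw - lse)
    # M step
    nk <- colSums(resp)
    nk <- pmax(nk, 1e-300)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    for (j in seq_len(k)) {
      v <- sum(resp[, j] * (x - mu[j])^2) / nk[j]
      s <- sqrt(v)
      if (s < sdFloor) {
        sig[j] <- sdFloor
        collapsed[j] <- collapsed[j] + 1L
      } else {
        sig[j] <- s
        collapsed[j] <- 0L
      }
    }
    if (any(collapsed > 10L))
      stop("degenerate fit: component ", which.max(collapsed),
           " collapsed below the sd floor")
    if (is.finite(ll) && llNew - ll < tol) { ll <- llNew; break }
    ll <- llNew
    if (iter >= maxIter) break
  }
  ord <- order(mu)
  new("Gmm1D", k = k, weights = w[ord], means = mu[ord], sds = sig[ord],
      logLik = ll, nIter = iter)
}

#' Mixture density of a fitted Gmm1D
#'
#' @param model a \linkS4class{Gmm1D}.
#' @param x numeric vector of evaluation points.
#' @return mixture density values.
#' @export
gmmDensity <- function(model, x) {
  rowSums(vapply(seq_len(model@k), function(j)
    model@weights[j] * dnorm(x, model@means[j], model@sds[j]),
    numeric(length(x))))
}

## Intersection of two weighted Gaussian curves between their means.
## Solves the quadratic in x from w_i phi_i(x) = w_j phi_j(x); if no real
## root lies between the means, falls back to bisection on the
## log-density difference (which always changes sign between the means).
.gaussIntersection <- function(w1, m1, s1, w2, m2, s2) {
  stopifnot(m1 < m2)
  f <- function(x) log(w1) + dnorm(x, m1, s1, log = TRUE) -
    log(w2) - dnorm(x, m2, s2, log = TRUE)
  a <- 1 / s1^2 - 1 / s2^2
  b <- -2 * (m1 / s1^2 - m2 / s2^2)
  cc <- m1^2 / s1^2 - m2^2 / s2^2 - 2 * log(w1 / w2) - 2 * log(s2 / s1)
  roots <- if (abs(a) < 1e-14) {
    if (abs(b) < 1e-14) numeric(0) else -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) numeric(0) else (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  inb <- roots[roots > m1 & roots < m2]
  if (length(inb)) return(inb[1])
  # the dominant density flips between the means, so bisection succeeds
  lo <- m1 + 1e-12 * (m2 - m1); hi <- m2 - 1e-12 * (m2 - m1)
  if (f(lo) < 0 || f(hi) > 0) return((m1 + m2) / 2)
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Thresholds at the intersections of adjacent mixture components
#'
#' For a 3-component fit, returns the two cut points where adjacent
#' weighted component curves intersect between their means; these delimit
#' the low / medium / high classes.
#'
#' @param model a \linkS4class{Gmm1D} with \code{k = 3}.
#' @return a \linkS4class{ThresholdPair}.
#' @export
intersectAdjacent <- function(model) {
  stopifnot(is(model, "Gmm1D"))
  if (model@k != 3L) stop("intersectAdjacent expects a 3-component fit")
  w <- model@weights; m <- model@means; s <- model@sds
  t1 <- .gaussIntersection(w[1], m[1], s[1], w[2], m[2], s[2])
  t2 <- .gaussIntersection(w[2], m[2], s[2], w[3], m[3], s[3])
  new("ThresholdPair", t1 = t1, t2 = t2)
}

#' Assign transmittance values to the low / medium / high classes
#'
#' Class 0 (low) for \code{v < t1}, class 1 (medium) for
#' \code{t1 <= v < t2}, class 2 (high) for \code{v >= t2}: boundary
#' values belong to the upper class.
#'
#' @param values numeric vector (one case's defined hexagon
#'   transmittances).
#' @param thresholds a \linkS4class{ThresholdPair}.
#' @return named integer vector \code{c(n0, n1, n2)}.
#' @export
assignClasses <- function(values, thresholds) {
  v <- values[is.finite(values)]
  cls <- findInterval(v, c(thresholds@t1, thresholds@t2))
  c(n0 = sum(cls == 0L), n1 = sum(cls == 1L), n2 = sum(cls == 2L))
}

#' Case call by the main-class rule (Bim / Mcl-1)
#'
#' The main class is the one holding the most hexagons (ties resolved to
#' the lowest class index). The case is called \code{"low"} when the main
#' class is class 0 and \code{"high"} otherwise, i.e. the two upper
#' classes are grouped.
#'
#' @param counts numeric length-3 vector (n0, n1, n2).
#' @return \code{"low"} or \code{"high"}.
#' @export
callCaseMainClass <- function(counts) {
  counts <- as.numeric(counts)
  stopifnot(length(counts) == 3L)
  if (sum(counts) == 0) stop("empty case: no hexagons in any class")
  if (which.max(counts) == 1L) "low" else "high"
}

#' Case call by the high-class 50 percent rule (P-ERK)
#'
#' \code{r_pct} is the percentage of hexagons in the high class; the case
#' is \code{"high"} only when that share reaches 50 percent (the first two
#' classes are grouped as low).
#'
#' @param counts numeric length-3 vector (n0, n1, n2).
#' @return list with \code{r_pct} and \code{label}.
#' @export
callCaseR50 <- function(counts) {
  counts <- as.numeric(counts)
  stopifnot(length(counts) == 3L)
  tot <- sum(counts)
  if (tot == 0) stop("empty case: no hexagons in any class")
  r <- 100 * counts[3] / tot
  list(r_pct = r, label = if (r >= 50) "high" else "low")
}

#' Count discordant cases between automated and expert labels
#'
#' @param calls data.frame with columns \code{case}, \code{ip_label} and
#'   \code{expert_label}.
#' @return list with \code{count} and \code{table} (the discordant rows).
#' @export
discordance <- function(calls) {
  stopifnot(all(c("case", "ip_label", "expert_label") %in% names(calls)))
  bad <- is.na(calls$expert_label) | calls$expert_label == ""
  if (any(bad))
    stop("missing expert label for case(s): ",
         paste(calls$case[bad], collapse = ", "))
  disc <- calls$ip_label != calls$expert_label
  list(count = sum(disc), table = calls[disc, , drop = FALSE])
}
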