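## Composite heterogeneity score: per-case moments of the hexagon
## transmittance distribution, standardized PCA, percent normalization,
## mixture-derived zero origin, binary calls.

#' First three moments of a case's transmittance distribution
#'
#' Mean, population standard deviation (divide by n) and population
#' skewness \code{g1 = m3 / m2^(3/2)} of the defined hexagon
#' transmittances of one case. A zero-variance case gets skewness 0 with
#' a warning.
#'
#' @param values numeric vector (>= 3 defined values).
#' @return named numeric vector \code{c(i_moy, i_sig, i_skw)}.
#' @export
caseMoments <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 3L)
    stop("insufficient data: need at least 3 defined hexagon values")
  m <- mean(v)
  m2 <- mean((v - m)^2)
  if (m2 == 0) {
    warning("zero variance: skewness set to 0")
    return(c(i_moy = m, i_sig = 0, i_skw = 0))
  }
  m3 <- mean((v - m)^3)
  c(i_moy = m, i_sig = sqrt(m2), i_skw = m3 / m2^1.5)
}

#' Standardized PCA of the per-case moment table
#'
#' Each moment column is standardized by its mean and sample standard
#' deviation; the loading is the unit-norm leading eigenvector of the
#' correlation matrix, sign-oriented so the coefficient on the mean
#' transmittance (\code{i_moy}) is non-negative. With that orientation a
#' higher score always means a more strongly stained, right-shifted
#' transmittance distribution.
#'
#' @param moments data.frame or matrix with columns \code{i_moy},
#'   \code{i_sig}, \code{i_skw} (one row per case, >= 4 cases).
#' @return a \linkS4class{MomentPca}.
#' @export
fitMomentPca <- function(moments) {
  X <- as.matrix(moments[, c("i_moy", "i_sig", "i_skw")])
  if (nrow(X) < 4L) stop("need at least 4 cases to fit the PCA")
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop("degenerate column: ",
         paste(colnames(X)[sds == 0], collapse = ", "), " is constant")
  ev <- eigen(stats::cor(X), symmetric = TRUE)
  v <- ev$vectors[, 1]
  if (v[1] < 0) v <- -v
  new("MomentPca", center = colMeans(X), scale = sds, loading = v,
      explainedVar = ev$values[1] / sum(ev$values))
}

#' Project cases onto the first principal component
#'
#' \code{cp1 = loading . standardized moment row}; over the fitting table
#' the scores have zero mean.
#'
#' @param model a \linkS4class{MomentPca}.
#' @param moments table as in \code{\link{fitMomentPca}}.
#' @return numeric vector of scores.
#' @export
scoreCases <- function(model, moments) {
  X <- as.matrix(moments[, c("i_moy", "i_sig", "i_skw")])
  Z <- sweep(sweep(X, 2, model@center), 2, model@scale, "/")
  unname(drop(Z %*% model@loading))
}

#' Min-max normalization of scores to a 0-100 percent scale
#'
#' @param scores numeric vector with \code{max > min}.
#' @return \code{100 * (x - min) / (max - min)}.
#' @export
minmaxPercent <- function(scores) {
  rng <- range(scores)
  if (diff(rng) == 0) stop("cannot normalize: all scores equal")
  100 * (scores - rng[1]) / diff(rng)
}

#' Automatic zero-origin threshold on the percent scale
#'
#' Fits a 3-component deterministic Gaussian mixture to the percent
#' scores and returns the higher of the two adjacent-curve intersection
#' thresholds (the published procedure selects the highest threshold as
#' the 0-value). A manual \code{override} bypasses the fit, which is how
#' the published per-marker thresholds are reproduced.
#'
#' @param pct numeric percent scores (>= 10 cases unless \code{override}).
#' @param override optional fixed threshold in \code{[0, 100]}.
#' @return threshold in \code{[0, 100]}.
#' @export
autoThreshold <- function(pct, override = NULL) {
  if (!is.null(override)) {
    stopifnot(override >= 0, override <= 100)
    return(override)
  }
  if (length(pct) < 10L)
    stop("need at least 10 cases for an automatic threshold")
  fit <- fitGmm(pct, k = 3)
  intersectAdjacent(fit)@t2
}

#' Shift scores to the threshold origin and call cases
#'
#' \code{shifted = pct - threshold}; a case is \code{"high"} iff its
#' shifted score is non-negative. Discordance is counted against the
#' expert labels.
#'
#' @param pct numeric percent scores.
#' @param threshold zero-origin threshold in \code{[0, 100]}.
#' @param expert character vector of expert labels (low/high).
#' @param case optional case identifiers.
#' @return list with \code{records} (a data.frame) and
#'   \code{discordant} (count).
#' @export
shiftAndCall <- function(pct, threshold, expert, case = seq_along(pct)) {
  stopifnot(threshold >= 0, threshold <= 100,
            length(expert) == length(pct))
  if (anyNA(expert)) stop("missing expert label")
  shifted <- pct - threshold
  ip <- ifelse(shifted >= 0, "high", "low")
  rec <- data.frame(case = case, pct = pct, shifted = shifted,
                    ip_label = ip, expert_label = expert,
                    discordant = ip != expert)
  list(records = rec, discordant = sum(rec$discordant))
}
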