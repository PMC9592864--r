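## Stereology quality control: random-offset cross grids, expert marks,
## surface-ratio estimation with a binomial confidence interval, the two
## quality factors, reader concordance and detector calibration.

#' Build a randomly offset cross grid inside an ROI
#'
#' Nodes sit at a uniform random offset (drawn from \code{seed}) plus
#' integer multiples of \code{spacing}; only nodes whose pixel falls in
#' the ROI are kept. The random offset is what makes point counting an
#' unbiased estimator of area fraction.
#'
#' @param roi logical mask.
#' @param spacing lattice period in pixels (>= 2).
#' @param seed integer seed for the offset.
#' @return a \linkS4class{CrossGrid}.
#' @export
makeGrid <- function(roi, spacing, seed = 1L) {
  stopifnot(is.logical(roi), is.matrix(roi), spacing >= 2)
  off <- withSeed(seed, runif(2, 0, spacing))
  # nodes in continuous 0-based coordinates; a node belongs to the pixel
  # containing it
  if (off[1] >= nrow(roi) || off[2] >= ncol(roi))
    stop("empty grid: no node lands inside the ROI")
  rows <- seq(off[1], nrow(roi) - 1e-9, by = spacing)
  cols <- seq(off[2], ncol(roi) - 1e-9, by = spacing)
  pr <- as.integer(floor(rows)) + 1L
  pc <- as.integer(floor(cols)) + 1L
  pos <- cbind(row = rep(pr, times = length(pc)),
               col = rep(pc, each = length(pr)))
  keep <- roi[pos]
  pos <- pos[keep, , drop = FALSE]
  if (nrow(pos) == 0L) stop("empty grid: no node lands inside the ROI")
  new("CrossGrid", spacing = spacing, offset = off, positions = pos,
      dim = dim(roi), seed = as.integer(seed))
}

#' Sample a binary mask at the grid nodes
#'
#' Produces the "virtual marks" of an automated detector: each cross is
#' labeled iff the mask is true at its node pixel.
#'
#' @param grid a \linkS4class{CrossGrid}.
#' @param mask logical matrix with the grid's frame dimensions.
#' @return a \linkS4class{MarkSet}.
#' @export
sampleMaskAt <- function(grid, mask) {
  stopifnot(identical(dim(mask), grid@dim))
  lab <- ifelse(mask[grid@positions], "labeled", "unlabeled")
  new("MarkSet", grid = grid, labels = lab)
}

#' Surface-ratio estimate from a mark set
#'
#' Point-count estimate of the area fraction: \code{p_hat} is the share
#' of labeled marks among non-excluded marks, with a binomial (Wald) 95\%
#' confidence interval clipped to \code{[0, 1]}.
#'
#' @param marks a \linkS4class{MarkSet}.
#' @return list with \code{p_hat}, \code{n} and \code{ci95 = c(lo, hi)}.
#' @export
estimateRatio <- function(marks) {
  keep <- marks@labels != "excluded"
  n <- sum(keep)
  if (n == 0L) stop("no non-excluded marks to estimate from")
  p <- sum(marks@labels[keep] == "labeled") / n
  half <- 1.96 * sqrt(p * (1 - p) / n)
  list(p_hat = p, n = n,
       ci95 = c(max(0, p - half), min(1, p + half)))
}

#' Consensus of two readers' marks
#'
#' Positions where the two labels agree keep the label; disagreements are
#' marked \code{"excluded"} (retained in the grid bookkeeping but dropped
#' from every ratio), reproducing the keep-only-common-marks rule used
#' for calibration.
#'
#' @param m1,m2 \linkS4class{MarkSet}s on the same grid.
#' @return a \linkS4class{MarkSet}.
#' @export
consensusMarks <- function(m1, m2) {
  .checkSameGrid(m1, m2)
  lab <- ifelse(m1@labels == m2@labels, m1@labels, "excluded")
  new("MarkSet", grid = m1@grid, labels = lab)
}

.checkSameGrid <- function(m1, m2) {
  if (!identical(m1@grid@positions, m2@grid@positions) ||
      !identical(m1@grid@dim, m2@grid@dim))
    stop("mark sets live on different grids")
  invisible(TRUE)
}

#' Percent concordance between two readers
#'
#' Among non-excluded positions, the labeled agreement is the share of
#' both-labeled positions within the union of positions either reader
#' labels; analogously for unlabeled agreement.
#'
#' @param m1,m2 \linkS4class{MarkSet}s on the same grid.
#' @return list with \code{labeled_agree_pct}, \code{unlabeled_agree_pct}
#'   and \code{total} (non-excluded count).
#' @export
concordancePercent <- function(m1, m2) {
  .checkSameGrid(m1, m2)
  keep <- m1@labels != "excluded" & m2@labels != "excluded"
  a <- m1@labels[keep] == "labeled"
  b <- m2@labels[keep] == "labeled"
  lab <- if (any(a | b)) 100 * sum(a & b) / sum(a | b) else NA_real_
  unl <- if (any(!a | !b)) 100 * sum(!a & !b) / sum(!a | !b) else NA_real_
  list(labeled_agree_pct = lab, unlabeled_agree_pct = unl,
       total = sum(keep))
}

#' Sensitivity/specificity quality factor against a reference reader
#'
#' Counts true/false positives and negatives of the test marks against
#' the reference marks (excluded positions in either set are dropped) and
#' averages sensitivity and specificity into the second quality factor.
#'
#' @param reference,test \linkS4class{MarkSet}s on the same grid; the
#'   expert is always the reference.
#' @return list with \code{sensitivity}, \code{specificity} and
#'   \code{qf_sens_spec}, all in \code{[0, 1]}.
#' @export
qualityFactorSensSpec <- function(reference, test) {
  .checkSameGrid(reference, test)
  keep <- reference@labels != "excluded" & test@labels != "excluded"
  ref <- reference@labels[keep] == "labeled"
  tst <- test@labels[keep] == "labeled"
  if (!any(ref) || all(ref))
    stop("undefined metric: reference marks contain a single class")
  sens <- sum(ref & tst) / sum(ref)
  spec <- sum(!ref & !tst) / sum(!ref)
  list(sensitivity = sens, specificity = spec,
       qf_sens_spec = (sens + spec) / 2)
}

#' Confidence-interval overlap quality factor
#'
#' Overlap length of the two 95\% confidence intervals divided by the
#' length of their union; 1 when they coincide, 0 when disjoint.
#'
#' @param e1,e2 ratio estimates from \code{\link{estimateRatio}}.
#' @return a number in \code{[0, 1]}.
#' @export
qualityFactorCI <- function(e1, e2) {
  a <- e1$ci95; b <- e2$ci95
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  uni <- max(a[2], b[2]) - min(a[1], b[1])
  if (uni == 0) return(1)
  inter / uni
}

#' Calibrate a parameterized detector against consensus expert marks
#'
#' Exhaustive search over a finite parameter grid: for each candidate the
#' detector produces a mask, the mask is sampled at the expert grid nodes
#' and scored by the sensitivity/specificity quality factor against the
#' expert marks. The first candidate (grid order) achieving the maximum
#' is returned.
#'
#' @param detector function taking one element of \code{paramGrid} and
#'   returning a logical mask.
#' @param paramGrid list of candidate parameter values.
#' @param marks consensus expert \linkS4class{MarkSet}.
#' @return list with \code{params}, \code{index} and \code{qf}.
#' @export
calibrateDetector <- function(detector, paramGrid, marks) {
  stopifnot(length(paramGrid) >= 1L)
  best <- NULL
  for (i in seq_along(paramGrid)) {
    mask <- detector(paramGrid[[i]])
    qf <- tryCatch(
      qualityFactorSensSpec(marks, sampleMaskAt(marks@grid, mask))$qf_sens_spec,
      error = function(e) NA_real_)
    if (!is.na(qf) && (is.null(best) || qf > best$qf))
      best <- list(params = paramGrid[[i]], index = i, qf = qf)
  }
  if (is.null(best)) stop("calibration failure: all candidates degenerate")
  best
}
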