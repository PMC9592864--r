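## End-to-end orchestration: detect stain, segment epithelium, tile
## hexagons, pool transmittance per marker, threshold into classes
## (first approach) and score by PCA (second approach). Also the
## fixture-only paths that reproduce the published per-case tables
## without any raster input.

#' First-approach case calls from a class-count table
#'
#' Applies the per-marker grouping rule to a table of per-case hexagon
#' class counts: the main-class rule (\code{rule = "main_class"}, used
#' for Bim and Mcl-1) or the high-class 50 percent rule
#' (\code{rule = "r50"}, used for P-ERK).
#'
#' @param counts data.frame with columns \code{case}, \code{n0},
#'   \code{n1}, \code{n2} and optionally \code{expert_label}.
#' @param rule \code{"main_class"} or \code{"r50"}.
#' @return data.frame of calls with \code{r_pct} (r50 rule only) and,
#'   when expert labels are present, \code{discordant}.
#' @export
classifyCases <- function(counts, rule = c("main_class", "r50")) {
  rule <- match.arg(rule)
  stopifnot(all(c("case", "n0", "n1", "n2") %in% names(counts)))
  out <- data.frame(case = counts$case)
  if (rule == "main_class") {
    out$ip_label <- apply(counts[, c("n0", "n1", "n2")], 1,
                          callCaseMainClass)
    out$r_pct <- NA_real_
  } else {
    calls <- apply(counts[, c("n0", "n1", "n2")], 1, callCaseR50)
    out$ip_label <- vapply(calls, `[[`, character(1), "label")
    out$r_pct <- vapply(calls, `[[`, numeric(1), "r_pct")
  }
  if ("expert_label" %in% names(counts)) {
    out$expert_label <- counts$expert_label
    out$discordant <- out$ip_label != out$expert_label
  }
  out
}

.fixtureRule <- function(marker) {
  if (marker %in% c("Bim", "Mcl-1")) "main_class" else "r50"
}

#' Reproduce the published first-approach calls for one marker
#'
#' Runs \code{\link{classifyCases}} on the packaged class-count table
#' with the marker's published grouping rule.
#'
#' @param marker one of \code{"Bim"}, \code{"Mcl-1"}, \code{"P-ERK"}.
#' @return list with \code{calls} and \code{discordant}.
#' @export
classifyFixtureCases <- function(marker = c("Bim", "Mcl-1", "P-ERK")) {
  marker <- match.arg(marker)
  tab <- paperFixture("table4_counts")
  tab <- tab[tab$marker == marker, ]
  calls <- classifyCases(tab, .fixtureRule(marker))
  list(calls = calls, discordant = sum(calls$discordant))
}

#' Published second-approach zero-origin thresholds (percent)
#' @export
publishedScoreThresholds <- c(Bim = 45, "Mcl-1" = 25, "P-ERK" = 85)

#' Reproduce the published composite-score calls for one marker
#'
#' Fits the standardized PCA on the packaged per-case moment table,
#' normalizes the component-1 scores to percent, shifts by the marker's
#' published zero-origin threshold and counts discordance against the
#' packaged expert labels.
#'
#' @param marker one of \code{"Bim"}, \code{"Mcl-1"}, \code{"P-ERK"}.
#' @param threshold zero-origin override; defaults to the published
#'   per-marker value.
#' @return list with \code{pca} (the \linkS4class{MomentPca}),
#'   \code{cp1}, \code{records} and \code{discordant}.
#' @export
scoreFixtureCases <- function(marker = c("Bim", "Mcl-1", "P-ERK"),
                              threshold = NULL) {
  marker <- match.arg(marker)
  if (is.null(threshold)) threshold <- publishedScoreThresholds[[marker]]
  mom <- paperFixture("table5_moments")
  mom <- mom[mom$marker == marker, ]
  t4 <- paperFixture("table4_counts")
  t4 <- t4[t4$marker == marker, ]
  expert <- t4$expert_label[match(mom$case, t4$case)]
  pca <- fitMomentPca(mom)
  cp1 <- scoreCases(pca, mom)
  pct <- minmaxPercent(cp1)
  res <- shiftAndCall(pct, autoThreshold(pct, override = threshold),
                      expert, case = mom$case)
  list(pca = pca, cp1 = setNames(cp1, mom$case),
       records = res$records, discordant = res$discordant)
}

#' Analyze one slide: masks, hexagons, transmittance
#'
#' The per-case imaging pipeline: Ohta transform, stain-model fit inside
#' the ROI, stain classification, epithelium segmentation, hexagonal
#' tiling and per-hexagon transmittance.
#'
#' @param slide a \linkS4class{StainedSlide} (or path readable by
#'   \code{\link{readSlideImage}}).
#' @param roi logical ROI mask; default whole frame.
#' @param gabor \code{\link{gaborParams}} for the epithelium stage.
#' @param circumradius hexagon circumradius in pixels.
#' @param minEpiPixels minimum epithelium pixels per defined hexagon.
#' @param calibrationShift additive stain-threshold shift.
#' @param case,marker identifiers carried into the hexagon table.
#' @return list with the updated \code{slide} (stain and epithelium masks
#'   filled), \code{stainModel}, \code{tiling} and \code{hexTable}.
#' @export
analyzeSlide <- function(slide, roi = NULL, gabor = gaborParams(),
                         circumradius = 100, minEpiPixels = 50,
                         calibrationShift = 0, case = "case",
                         marker = "marker") {
  if (is.character(slide)) slide <- readSlideImage(slide)
  if (is.null(roi)) roi <- roiMask(slide)
  ohta <- ohtaTransform(slide)
  model <- setCalibrationShift(fitStainModel(ohta, roi), calibrationShift)
  stain <- classifyStain(ohta, model, roi)
  epi <- segmentEpithelium(slide, roi, gabor)
  brown <- brownIntensity(slide, stain)
  tiling <- tileHexagons(roi, circumradius)
  tab <- hexTable(case, marker, tiling, brown, epi, minEpiPixels)
  slide@roi <- roi; slide@stain <- stain; slide@epithelium <- epi
  list(slide = slide, stainModel = model, tiling = tiling, hexTable = tab)
}

#' Run the full pipeline over a cohort of slides
#'
#' For every configured case: stain detection, epithelium segmentation
#' and hexagon transmittance. Per marker: pool the defined hexagon
#' values, fit the 3-component mixture, cut at the adjacent-curve
#' intersections, count classes per case and call cases by the marker's
#' grouping rule (first approach); compute per-case moments, the
#' standardized PCA score, percent normalization and the zero-origin
#' call (second approach). Deterministic for fixed inputs and config.
#'
#' @param cases list of per-case lists with fields \code{case},
#'   \code{marker}, \code{slide} (object or path), optional \code{roi}
#'   (mask or polygon-JSON path) and optional \code{expert_label}.
#' @param gabor,circumradius,minEpiPixels,calibrationShift shared stage
#'   parameters (see \code{\link{analyzeSlide}}).
#' @param rules named character vector mapping marker to
#'   \code{"main_class"} or \code{"r50"}; unlisted markers default to
#'   \code{"main_class"}.
#' @param scoreThresholds named numeric vector of per-marker zero-origin
#'   overrides for the second approach; markers not listed use the
#'   automatic mixture threshold.
#' @return a run report: per-case class counts and calls, per-marker
#'   thresholds, score records and discordance summaries (lists of
#'   data.frames).
#' @export
runPipeline <- function(cases, gabor = gaborParams(), circumradius = 100,
                        minEpiPixels = 50, calibrationShift = 0,
                        rules = NULL, scoreThresholds = NULL) {
  stopifnot(length(cases) >= 1L)
  tabs <- vector("list", length(cases))
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    roi <- cs$roi
    if (is.character(roi))
      roi <- rasterizeRoi(readRoiJson(roi), dim(readSlideImage(cs$slide)))
    an <- analyzeSlide(cs$slide, roi, gabor, circumradius, minEpiPixels,
                       calibrationShift, cs$case, cs$marker)
    tabs[[i]] <- an$hexTable
  }
  allTab <- do.call(rbind, tabs)
  markers <- unique(allTab$marker)
  report <- list(hexTables = allTab, markers = list(),
                 parameters = list(gabor = gabor,
                                   circumradius = circumradius,
                                   minEpiPixels = minEpiPixels,
                                   calibrationShift = calibrationShift))
  for (mk in markers) {
    sub <- allTab[allTab$marker == mk, ]
    pooled <- poolTransmittance(sub)
    fit <- fitGmm(pooled, k = 3)
    thr <- intersectAdjacent(fit)
    caseIds <- unique(sub$case)
    counts <- t(vapply(caseIds, function(cid)
      assignClasses(sub$transmittance[sub$case == cid], thr),
      numeric(3)))
    countTab <- data.frame(case = caseIds, n0 = counts[, 1],
                           n1 = counts[, 2], n2 = counts[, 3])
    expert <- vapply(cases, function(cs)
      if (identical(cs$marker, mk) && !is.null(cs$expert_label))
        cs$expert_label else NA_character_, character(1))
    names(expert) <- vapply(cases, `[[`, character(1), "case")
    expert <- expert[!is.na(expert)]
    if (length(expert))
      countTab$expert_label <- unname(expert[match(countTab$case,
                                                   names(expert))])
    rule <- if (!is.null(rules) && mk %in% names(rules)) rules[[mk]]
            else "main_class"
    calls <- classifyCases(countTab, rule)
    mrep <- list(gmm = fit, thresholds = thr, classCounts = countTab,
                 calls = calls)
    if ("discordant" %in% names(calls))
      mrep$discordantFirst <- sum(calls$discordant)
    # second approach needs >= 4 cases with >= 3 defined hexagons each
    momOk <- vapply(caseIds, function(cid)
      sum(is.finite(sub$transmittance[sub$case == cid])) >= 3, logical(1))
    if (sum(momOk) >= 4L) {
      mom <- t(vapply(caseIds[momOk], function(cid)
        caseMoments(sub$transmittance[sub$case == cid]), numeric(3)))
      mom <- data.frame(case = caseIds[momOk], mom)
      pca <- fitMomentPca(mom)
      pct <- minmaxPercent(scoreCases(pca, mom))
      ov <- if (!is.null(scoreThresholds) && mk %in% names(scoreThresholds))
        scoreThresholds[[mk]] else NULL
      thr2 <- tryCatch(autoThreshold(pct, override = ov),
                       error = function(e) NA_real_)
      if (!is.na(thr2) && length(expert)) {
        exp2 <- unname(expert[match(mom$case, names(expert))])
        if (!anyNA(exp2)) {
          sc <- shiftAndCall(pct, thr2, exp2, case = mom$case)
          mrep$scoreRecords <- sc$records
          mrep$discordantSecond <- sc$discordant
        }
      }
      mrep$pca <- pca
      mrep$scoreThreshold <- thr2
    }
    report$markers[[mk]] <- mrep
  }
  report
}
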