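## Published reference tables shipped with the package: per-case hexagon
## class counts with expert labels, per-case transmittance moments with
## composite scores and loadings, and the stain-detection quality-factor
## cells. All values transcribed digit-for-digit from the study report.

.fixtureFiles <- c(
  table4_counts   = "table4_counts.csv",
  table4_expert   = "table4_counts.csv",
  table4_r50      = "table4_r50.csv",
  table5_moments  = "table5_moments.csv",
  table5_cp1      = "table5_cp1.csv",
  table5_loadings = "table5_loadings.csv",
  table2_sens_spec = "table2_sens_spec.csv"
)

#' Load a packaged reference table
#'
#' Returns one of the reference tables shipped with the package as a
#' data.frame:
#' \describe{
#'   \item{table4_counts}{25 cases x 3 markers; hexagon counts per class
#'     (n0, n1, n2) with the published automated and expert labels.}
#'   \item{table4_expert}{alias of \code{table4_counts} (the expert
#'     labels live in its \code{expert_label} column).}
#'   \item{table4_r50}{published high-class percentages for the P-ERK
#'     50\%-rule.}
#'   \item{table5_moments}{per-case mean, SD and skewness of hexagon
#'     transmittance, per marker.}
#'   \item{table5_cp1}{published first-principal-component scores.}
#'   \item{table5_loadings}{published component-1 loadings (percent).}
#'   \item{table2_sens_spec}{stain-detection sensitivity / specificity /
#'     quality-factor cells for the calibration cases.}
#' }
#'
#' @param name fixture name (see above).
#' @return a data.frame.
#' @export
paperFixture <- function(name) {
  if (!name %in% names(.fixtureFiles))
    stop("unknown fixture: ", name, " (known: ",
         paste(names(.fixtureFiles), collapse = ", "), ")")
  path <- system.file("extdata", .fixtureFiles[[name]], package = "hexIHC",
                      mustWork = TRUE)
  read.csv(path, check.names = FALSE)
}
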