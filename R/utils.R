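## Internal helpers.

## Run an expression under a temporary RNG state seeded from `seed`,
## restoring the caller's RNG afterwards. All randomness in the package
## flows through this, so no call perturbs global reproducibility.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Dice overlap of two logical masks.

#' Dice coefficient between two binary masks
#'
#' @param a,b logical matrices of equal shape.
#' @return \code{2|a & b| / (|a| + |b|)}; 1 when both are empty.
#' @export
diceCoefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}

#' Sensitivity and specificity of a mask against a reference mask
#'
#' @param reference,test logical matrices of equal shape.
#' @return named numeric vector with \code{sensitivity} and
#'   \code{specificity}.
#' @export
maskAgreement <- function(reference, test) {
  stopifnot(identical(dim(reference), dim(test)))
  c(sensitivity = sum(reference & test) / sum(reference),
    specificity = sum(!reference & !test) / sum(!reference))
}
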