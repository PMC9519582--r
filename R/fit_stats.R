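#' Goodness-of-fit statistics
#'
#' Standard agreement measures between model predictions and observations:
#' coefficient of determination `R^2 = 1 - SSres/SStot`, root-mean-square
#' error, and mean absolute error.
#'
#' @param predicted,observed equal-length numeric vectors (length >= 2).
#' @return list with `r_squared`, `rmse`, `mae`.
#' @export
goodness_of_fit <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed), length(observed) >= 2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0)
    stop("observed values have zero variance: R^2 undefined", call. = FALSE)
  res <- observed - predicted
  list(r_squared = 1 - sum(res^2) / ss_tot,
       rmse = sqrt(mean(res^2)),
       mae = mean(abs(res)))
}

#' Bland-Altman agreement analysis
#'
#' Bias (mean difference) and 95% limits of agreement
#' (`bias +/- 1.96 * sd(differences)`) between two measurement series of
#' the same quantity.
#'
#' @param a,b equal-length numeric vectors (length >= 2).
#' @return list with `bias`, `loa_low`, `loa_high`, and the per-pair `means`
#'   and `differences` used for plotting.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2)
    stop("bland_altman needs two equal-length vectors of length >= 2",
         call. = FALSE)
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       means = (a + b) / 2, differences = d)
}
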