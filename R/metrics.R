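#' Root mean squared error
#'
#' `sqrt(mean((pred - actual)^2))` over the pairwise non-missing entries.
#'
#' @param pred,actual numeric vectors of equal length.
#' @return non-negative scalar, in the units of the response.
#' @export
rmse <- function(pred, actual) {
  if (length(pred) != length(actual)) stop("pred and actual differ in length")
  ok <- !is.na(pred) & !is.na(actual)
  if (!any(ok)) stop("no pairwise non-missing observations")
  sqrt(mean((pred[ok] - actual[ok])^2))
}

#' Coefficient of determination
#'
#' `1 - sum((pred - actual)^2) / sum((actual - mean(actual))^2)` over the
#' pairwise non-missing entries; can be negative for a model worse than the
#' mean.
#'
#' @param pred,actual numeric vectors of equal length; `actual` must not be
#'   constant.
#' @return dimensionless scalar, at most 1.
#' @export
r_squared <- function(pred, actual) {
  if (length(pred) != length(actual)) stop("pred and actual differ in length")
  ok <- !is.na(pred) & !is.na(actual)
  if (sum(ok) < 2) stop("need at least 2 pairwise non-missing observations")
  tss <- sum((actual[ok] - mean(actual[ok]))^2)
  if (tss == 0) stop("actual values are constant; R-squared undefined")
  1 - sum((pred[ok] - actual[ok])^2) / tss
}
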