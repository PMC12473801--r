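# broom-style tidiers for the evaluation report.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-pair ratios behind an evaluation report
#'
#' @param x A `pk_evaluation` object.
#' @param ... Unused.
#' @return The underlying pair tibble with `ratio`, `fold_error` and `within`
#'   columns.
#' @exportS3Method generics::tidy
tidy.pk_evaluation <- function(x, ...) {
  attr(x, "pairs") |>
    fold_error_within() |>
    dplyr::mutate(ratio = .data$fold_error)
}

#' One-row pooled summary of an evaluation report
#'
#' @param x A `pk_evaluation` object.
#' @param ... Unused.
#' @return A one-row tibble: pooled `n`, `AFE`, `RMSE`, `MAE` over every pair
#'   and the fraction of fold errors inside the 0.5-2 band.
#' @exportS3Method generics::glance
glance.pk_evaluation <- function(x, ...) {
  pairs <- attr(x, "pairs")
  fe <- fold_error_within(pairs)
  tibble::tibble(
    n = nrow(pairs),
    AFE = afe(pairs$predicted, pairs$observed),
    RMSE = rmse(pairs$predicted, pairs$observed),
    MAE = mae(pairs$predicted, pairs$observed),
    prop_within_2fold = mean(fe$within)
  )
}
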