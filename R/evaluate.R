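# Model-qualification metrics on predicted/observed (PRE/OBS) parameter
# pairs: per-pair ratios, average fold error (AFE), RMSE, MAE, mean ratio
# with 95% CI, and the 0.5-2 fold-error acceptance band.

#' Load the packaged predicted/observed parameter pairs
#'
#' Reads the packaged PRE/OBS tables for the healthy (IV + oral) and the
#' renally impaired cohorts and pivots them into one tidy row per
#' study x parameter.
#'
#' @param which `"healthy"`, `"ri"`, or `"all"` (default).
#' @return A tibble: `study`, `cohort`, `route`, `dose_mg`, `parameter`
#'   (Cmax / AUC_0_t / CL), `predicted`, `observed`.
#' @export
load_pk_pairs <- function(which = c("all", "healthy", "ri")) {
  which <- match.arg(which)
  pivot <- function(df) {
    df |>
      tidyr::pivot_longer(
        cols = dplyr::matches("^(cmax|auc|cl)_(pre|obs)$"),
        names_to = c("parameter", "side"),
        names_pattern = "^(cmax|auc|cl)_(pre|obs)$",
        values_to = "value"
      ) |>
      dplyr::mutate(parameter = dplyr::recode(.data$parameter,
                                              cmax = "Cmax", auc = "AUC_0_t",
                                              cl = "CL")) |>
      tidyr::pivot_wider(names_from = "side", values_from = "value") |>
      dplyr::rename(predicted = "pre", observed = "obs")
  }
  healthy <- read_packaged_csv("table3_healthy_pairs.csv") |>
    dplyr::mutate(cohort = dplyr::if_else(.data$route == "iv_infusion",
                                          "healthy_iv", "healthy_po")) |>
    pivot()
  ri <- read_packaged_csv("table5_ri_pairs.csv") |>
    dplyr::mutate(cohort = paste0("ri_", .data$stage), route = "oral") |>
    dplyr::select(-"stage") |>
    pivot()
  out <- switch(which, healthy = healthy, ri = ri,
                all = dplyr::bind_rows(healthy, ri))
  dplyr::select(out, "study", "cohort", "route", "dose_mg", "parameter",
                "predicted", "observed")
}

check_positive_pairs <- function(predicted, observed) {
  if (length(predicted) == 0) abort("empty predicted/observed input")
  if (any(observed <= 0) || any(predicted <= 0)) {
    abort("all predicted and observed values must be positive")
  }
}

#' Predicted/observed ratio
#'
#' `R = predicted / observed`, elementwise.
#'
#' @param predicted,observed Positive numeric vectors.
#' @return Numeric vector of ratios.
#' @export
ratio_pre_obs <- function(predicted, observed) {
  if (any(observed <= 0)) abort("ratio_pre_obs: observed must be > 0")
  predicted / observed
}

#' Average fold error
#'
#' `AFE = 10 ^ mean(log10(predicted / observed))` — the geometric mean fold
#' error.
#'
#' @param predicted,observed Positive numeric vectors of equal length.
#' @return A single positive number.
#' @export
afe <- function(predicted, observed) {
  check_positive_pairs(predicted, observed)
  10^mean(log10(predicted / observed))
}

#' Root mean squared error
#' @param predicted,observed Numeric vectors of equal length.
#' @return `sqrt(mean((predicted - observed)^2))`.
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) == 0) abort("rmse: empty input")
  sqrt(mean((predicted - observed)^2))
}

#' Mean absolute error
#' @param predicted,observed Numeric vectors of equal length.
#' @return `mean(abs(predicted - observed))`.
#' @export
mae <- function(predicted, observed) {
  if (length(predicted) == 0) abort("mae: empty input")
  mean(abs(predicted - observed))
}

#' Mean predicted/observed ratio with 95% interval
#'
#' Arithmetic mean ratio; for `n >= 3` a t-distribution 95% confidence
#' interval, for `n < 3` the min-max range with `small_n = TRUE` (mirroring
#' the reporting convention for cohorts with very few profiles).
#'
#' @param ratios Numeric vector of ratios (n >= 1).
#' @return A one-row tibble: `mean_R`, `lo`, `hi`, `n`, `small_n`.
#' @export
ratio_summary <- function(ratios) {
  n <- length(ratios)
  if (n < 1) abort("ratio_summary: need at least one ratio")
  m <- mean(ratios)
  if (n >= 3) {
    half <- qt(0.975, df = n - 1) * sd(ratios) / sqrt(n)
    tibble::tibble(mean_R = m, lo = m - half, hi = m + half, n = n,
                   small_n = FALSE)
  } else {
    tibble::tibble(mean_R = m, lo = min(ratios), hi = max(ratios), n = n,
                   small_n = TRUE)
  }
}

#' Flag fold errors against an acceptance band
#'
#' Fold error is `predicted / observed`; the band is inclusive at both
#' bounds (the conventional 0.5-2 predictive band by default).
#'
#' @param data A tibble with `predicted` and `observed` columns.
#' @param lo,hi Band bounds.
#' @return `data` with `fold_error` and `within` columns added.
#' @export
fold_error_within <- function(data, lo = 0.5, hi = 2) {
  data |>
    dplyr::mutate(
      fold_error = ratio_pre_obs(.data$predicted, .data$observed),
      within = .data$fold_error >= lo & .data$fold_error <= hi
    )
}

#' Qualification report over predicted/observed pairs
#'
#' Groups the pairs (by default per cohort and PK parameter) and computes the
#' per-group AFE, RMSE, MAE, mean ratio with its 95% interval, and fold-error
#' band coverage.
#'
#' @param pairs A tidy pair tibble as from [load_pk_pairs()].
#' @param by Character vector of grouping columns.
#' @return A `pk_evaluation` tibble (one row per group) with columns `n`,
#'   `AFE`, `RMSE`, `MAE`, `mean_R`, `R_lo`, `R_hi`, `small_n`,
#'   `all_within_2fold`. [tidy()] recovers per-pair ratios, [glance()] the
#'   pooled metrics.
#' @export
evaluate_pairs <- function(pairs, by = c("cohort", "parameter")) {
  out <- pairs |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_modify(function(g, key) {
      rs <- ratio_summary(ratio_pre_obs(g$predicted, g$observed))
      fe <- fold_error_within(g)
      tibble::tibble(
        n = nrow(g),
        AFE = afe(g$predicted, g$observed),
        RMSE = rmse(g$predicted, g$observed),
        MAE = mae(g$predicted, g$observed),
        mean_R = rs$mean_R, R_lo = rs$lo, R_hi = rs$hi, small_n = rs$small_n,
        all_within_2fold = all(fe$within)
      )
    }) |>
    dplyr::ungroup()
  class(out) <- c("pk_evaluation", class(out))
  attr(out, "pairs") <- pairs
  out
}

#' @export
print.pk_evaluation <- function(x, ...) {
  cat("<pk_evaluation> model-qualification metrics\n")
  NextMethod()
  invisible(x)
}
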