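# Non-compartmental analysis: Cmax/Tmax by direct maximum, AUC_0-t by the
# linear trapezoid, terminal slope by log-linear regression over the best
# 3-6 terminal points, AUC_0-inf by Clast/lambda_z extrapolation.

trapezoid_auc <- function(time, conc) {
  sum(diff(time) * (head(conc, -1) + tail(conc, -1)) / 2)
}

# best-adjusted-R^2 log-linear terminal fit over the last 3-6 post-Tmax
# points; ties resolved toward more points
terminal_slope <- function(time, conc) {
  i_max <- which.max(conc)
  cand_idx <- seq_along(time)
  cand_idx <- cand_idx[cand_idx >= i_max & conc > 0]
  n_avail <- length(cand_idx)
  if (n_avail < 3) return(NULL)
  best <- NULL
  for (k in 3:min(6, n_avail)) {
    idx <- tail(cand_idx, k)
    fit <- lm(log(conc[idx]) ~ time[idx])
    slope <- coef(fit)[[2]]
    if (!is.finite(slope) || slope >= -1e-12) next  # needs a genuine decline
    lconc <- log(conc[idx])
    sse <- sum(fit$residuals^2)
    sst <- sum((lconc - mean(lconc))^2)
    r2 <- if (sst > 0) 1 - sse / sst else 0
    r2adj <- 1 - (1 - r2) * (k - 1) / (k - 2)
    if (is.null(best) || r2adj >= best$r2adj - 1e-9) {
      best <- list(lambda_z = -slope, r2adj = r2adj, n_points = k)
    }
  }
  best
}

#' Non-compartmental analysis of one profile
#'
#' @param profile A tibble with columns `time_h` and `conc_ug_ml` (at least 3
#'   points, non-negative, strictly increasing times).
#' @param dose_mg Administered dose in mg (total of a single administration;
#'   clearance is apparent, `dose / AUC`, without bioavailability correction
#'   for the oral route).
#' @param route `"iv_infusion"` or `"oral"` (annotation only).
#' @param auc_for_cl Whether CL uses `AUC_0-inf` (default) or `AUC_0-t`.
#' @return A one-row tibble: `Cmax`, `Tmax`, `AUC_0_t`, `AUC_0_inf`,
#'   `lambda_z`, `t_half`, `CL`, `lambda_points`, `lambda_estimable`. When the
#'   terminal slope is non-estimable (e.g. a non-decreasing tail) the
#'   extrapolated quantities are `NA` and `lambda_estimable` is `FALSE`;
#'   `AUC_0_t` is still returned.
#' @export
run_nca <- function(profile, dose_mg, route = c("iv_infusion", "oral"),
                    auc_for_cl = c("auc_inf", "auc_0_t")) {
  route <- match.arg(route)
  auc_for_cl <- match.arg(auc_for_cl)
  time <- profile$time_h
  conc <- profile$conc_ug_ml
  if (length(time) < 3) abort("run_nca: need at least 3 points")
  if (any(conc < 0)) abort("run_nca: negative concentrations")
  if (any(diff(time) <= 0)) abort("run_nca: times must be strictly increasing")

  cmax <- max(conc)
  tmax <- time[which.max(conc)]
  auc_t <- trapezoid_auc(time, conc)

  term <- terminal_slope(time, conc)
  if (is.null(term) || cmax == 0) {
    lambda_z <- NA_real_; t_half <- NA_real_; auc_inf <- NA_real_
    n_pts <- NA_integer_; estimable <- FALSE
  } else {
    lambda_z <- term$lambda_z
    t_half <- log(2) / lambda_z
    auc_inf <- auc_t + tail(conc[conc > 0], 1) / lambda_z
    n_pts <- term$n_points
    estimable <- TRUE
  }
  auc_cl <- if (auc_for_cl == "auc_inf") auc_inf else auc_t
  cl <- if (dose_mg > 0 && !is.na(auc_cl) && auc_cl > 0) {
    dose_mg / auc_cl
  } else {
    NA_real_
  }
  tibble::tibble(
    Cmax = cmax, Tmax = tmax, AUC_0_t = auc_t, AUC_0_inf = auc_inf,
    lambda_z = lambda_z, t_half = t_half, CL = cl,
    lambda_points = n_pts, lambda_estimable = estimable, route = route
  )
}

#' Non-compartmental analysis of an ensemble
#'
#' Runs [run_nca()] per subject of a population ensemble.
#'
#' @param profiles A tibble `time_h`, `conc_ug_ml`, `subject_id`.
#' @param dose_mg Dose per administration in mg.
#' @param route,auc_for_cl Passed to [run_nca()].
#' @return A tibble with one NCA row per subject.
#' @export
nca_population <- function(profiles, dose_mg, route = c("iv_infusion", "oral"),
                           auc_for_cl = c("auc_inf", "auc_0_t")) {
  route <- match.arg(route)
  auc_for_cl <- match.arg(auc_for_cl)
  profiles |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(~ run_nca(.x, dose_mg = dose_mg, route = route,
                                  auc_for_cl = auc_for_cl)) |>
    dplyr::ungroup()
}
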