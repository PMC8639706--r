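#' Oxygen consumption rate from endpoint DO readings
#'
#' Endpoint estimator used for every sealed bottle: the decrease in
#' dissolved O2 between the first and last reading divided by the elapsed
#' time, converted to per-day units.
#'
#' @param DO_start,DO_end dissolved O2, nM.
#' @param elapsed_hours time between readings, hours (> 0).
#' @return consumption rate, nmol O2 L^-1 day^-1 (positive = consumption).
#' @export
#' @examples
#' ocr_endpoint(500, 300, 24) # 200
ocr_endpoint <- function(DO_start, DO_end, elapsed_hours) {
  if (any(elapsed_hours <= 0)) abort("`elapsed_hours` must be > 0")
  (DO_start - DO_end) / elapsed_hours * 24
}

#' Oxygen consumption rate from a continuously monitored DO series
#'
#' Ordinary least-squares slope of dissolved O2 against time for a
#' continuously monitored bottle, negated and converted to per-day units.
#' Censored readings (below the sensor detection limit) are excluded from
#' the regression. With fewer than 3 uncensored points the estimator falls
#' back to [ocr_endpoint()] on the available endpoints (noted in the
#' `method` column); with more than half the readings censored the bottle
#' is reported rate-indeterminate (`NA` rate).
#'
#' When at least 8 readings are available the series is also screened for
#' linearity (see [linearity_classification()]); the screen uses the
#' reported DO values including censored readings held at the detection
#' limit, since the flattening of a trace at the limit is itself the
#' signature of a drawdown curve bending over.
#'
#' @param series a data frame with columns `t_hours`, `DO_nM` and optionally
#'   `censored` (logical).
#' @param r2_min,mic_gap linearity thresholds passed to
#'   [linearity_classification()].
#' @return a one-row tibble (class `ocr_estimate`): `rate`, `se`, `r2`,
#'   `mic`, `n_points`, `n_censored`, `method` (`"regression"` or
#'   `"endpoint"`), `linear` (logical, `NA` if unclassified),
#'   `classification`.
#' @export
ocr_regression <- function(series, r2_min = 0.6, mic_gap = 0.2) {
  .need_cols(series, c("t_hours", "DO_nM"), "ocr_regression")
  if (is.unsorted(series$t_hours, strictly = TRUE)) {
    abort("`t_hours` must be strictly increasing")
  }
  cens <- if ("censored" %in% names(series)) series$censored else
    rep(FALSE, nrow(series))
  keep <- !cens
  n_all <- nrow(series)
  cls <- linearity_classification(series, r2_min = r2_min, mic_gap = mic_gap)
  if (sum(cens) > n_all / 2) {
    inform("more than half the DO readings are censored; rate indeterminate")
    return(tibble(rate = NA_real_, se = NA_real_, r2 = cls$r2, mic = cls$mic,
                  n_points = sum(keep), n_censored = sum(cens),
                  method = "indeterminate", linear = NA,
                  classification = cls$classification))
  }
  if (sum(keep) < 3) {
    inform("fewer than 3 uncensored DO readings; falling back to endpoints")
    s <- series[keep, , drop = FALSE]
    if (nrow(s) < 2) s <- series
    rate <- ocr_endpoint(s$DO_nM[1], s$DO_nM[nrow(s)],
                         s$t_hours[nrow(s)] - s$t_hours[1])
    return(tibble(rate = rate, se = NA_real_, r2 = NA_real_, mic = cls$mic,
                  n_points = nrow(s), n_censored = sum(cens),
                  method = "endpoint", linear = NA,
                  classification = cls$classification))
  }
  s <- series[keep, , drop = FALSE]
  fit <- lm(DO_nM ~ t_hours, data = s)
  sm <- summary(fit)
  slope <- coef(fit)[["t_hours"]]
  slope_se <- sm$coefficients["t_hours", "Std. Error"]
  r2 <- if (sd(s$DO_nM) == 0) 0 else sm$r.squared
  out <- tibble(rate = -slope * 24, se = slope_se * 24, r2 = r2,
                mic = cls$mic, n_points = nrow(s), n_censored = sum(cens),
                method = "regression",
                linear = if (cls$classification == "unclassified") NA else
                  cls$classification == "linear",
                classification = cls$classification)
  class(out) <- c("ocr_estimate", class(out))
  out
}

#' Aggregate replicate oxygen consumption rates
#'
#' Arithmetic mean and sample standard deviation across replicate bottles at
#' one depth (the shipboard design uses five replicates per depth).
#'
#' @param data a data frame of per-bottle estimates.
#' @param rate_col name of the rate column.
#' @return a one-row tibble: `mean_rate`, `sd_rate`, `n`, and `n_lt_5`
#'   flagging aggregates built from fewer than five replicates.
#' @export
#' @examples
#' replicate_ocr(data.frame(rate = c(100, 200, 300, 400, 500)))
replicate_ocr <- function(data, rate_col = "rate") {
  .need_cols(data, rate_col, "replicate_ocr")
  r <- data[[rate_col]]
  r <- r[is.finite(r)]
  if (length(r) < 2) abort("replicate_ocr() needs at least 2 finite rates")
  tibble(mean_rate = mean(r), sd_rate = sd(r), n = length(r),
         n_lt_5 = length(r) < 5)
}

#' Classify a DO drawdown curve as linear or nonlinear
#'
#' Implements the MIC + r^2 screen: a drawdown curve is linear iff the
#' regression r^2 exceeds `r2_min` (default 0.6) and the gap between the
#' maximal information coefficient and r^2 is below `mic_gap` (default 0.2).
#' MIC is near 1 for any noiseless functional relationship, so a large
#' MIC - r^2 gap indicates a strong but nonlinear dependence, i.e. a
#' consumption rate that changes as O2 is drawn down. Series with fewer than
#' 8 readings are unclassified.
#'
#' The screen is applied to the reported DO values (censored readings held
#' at the detection limit are retained): the flat tail of a trace pinned at
#' the limit is exactly the nonlinearity the screen is meant to catch.
#'
#' @param series a data frame with columns `t_hours`, `DO_nM`.
#' @param r2_min minimum r^2 for a linear call.
#' @param mic_gap maximum MIC - r^2 for a linear call.
#' @return a one-row tibble: `classification` (`"linear"`, `"nonlinear"` or
#'   `"unclassified"`), `r2`, `mic`, `n`.
#' @export
linearity_classification <- function(series, r2_min = 0.6, mic_gap = 0.2) {
  .need_cols(series, c("t_hours", "DO_nM"), "linearity_classification")
  n <- nrow(series)
  if (n < 8) {
    return(tibble(classification = "unclassified", r2 = NA_real_,
                  mic = NA_real_, n = n))
  }
  if (sd(series$DO_nM) == 0) {
    return(tibble(classification = "nonlinear", r2 = 0, mic = 0, n = n))
  }
  r2 <- summary(lm(DO_nM ~ t_hours, data = series))$r.squared
  m <- mic(series$t_hours, series$DO_nM)
  linear <- r2 > r2_min && (m - r2) < mic_gap
  tibble(classification = if (linear) "linear" else "nonlinear",
         r2 = r2, mic = m, n = n)
}
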