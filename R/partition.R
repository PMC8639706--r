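#' Oxygen demand of nitrogen oxidation
#'
#' Converts nitrogen oxidation rates into oxygen consumption: nitrite
#' oxidation appends one O atom per N, consuming 0.5 mol O2 per mol N
#' (`O2_PER_NO2_OXIDATION`); ammonia oxidation to nitrite consumes 1.5 mol
#' O2 per mol N (`O2_PER_NH4_OXIDATION`, canonical nitrification
#' stoichiometry).
#'
#' @param rate nitrogen oxidation rate, nmol N L^-1 day^-1 (>= 0).
#' @param factor stoichiometric factor, mol O2 per mol N.
#' @return oxygen demand, nmol O2 L^-1 day^-1.
#' @export
#' @examples
#' o2_demand_nitrite(100) # 50
#' o2_demand_ammonia(100) # 150
o2_demand_nitrite <- function(rate, factor = O2_PER_NO2_OXIDATION) {
  if (any(rate < 0, na.rm = TRUE)) abort("`rate` must be >= 0")
  factor * rate
}

#' @rdname o2_demand_nitrite
#' @export
o2_demand_ammonia <- function(rate, factor = O2_PER_NH4_OXIDATION) {
  if (any(rate < 0, na.rm = TRUE)) abort("`rate` must be >= 0")
  factor * rate
}

#' Percentage of oxygen consumption attributable to nitrite oxidation
#'
#' 100 * 0.5 * R_NO2ox / OCR: the share of the overall oxygen consumption
#' rate explained by the measured nitrite oxidation rate, using the half-mole
#' O2 stoichiometry. Values above 100 are possible when the two rates come
#' from different bottles or methods and are returned unchanged (flag them
#' downstream rather than capping). Records with OCR <= 0 give `NA`.
#'
#' @param R_NO2ox nitrite oxidation rate, nmol N L^-1 day^-1.
#' @param OCR oxygen consumption rate, nmol O2 L^-1 day^-1.
#' @param factor stoichiometric factor, mol O2 per mol N.
#' @return percentage (>= 0, uncapped).
#' @export
#' @examples
#' percent_contribution(200, 1000) # 10
percent_contribution <- function(R_NO2ox, OCR,
                                 factor = O2_PER_NO2_OXIDATION) {
  bad <- !is.na(OCR) & OCR <= 0
  if (any(bad)) {
    inform(sprintf("%d record(s) with OCR <= 0: percentage undefined (NA)",
                   sum(bad)))
  }
  ifelse(OCR > 0, 100 * factor * R_NO2ox / OCR, NA_real_)
}

#' Build a partition table from paired rates
#'
#' Assembles per-record percentages of oxygen consumption attributable to
#' nitrite (and optionally ammonia) oxidation, applying the profile DO
#' ceiling (default 18 uM: records above it are excluded from the
#' DO-dependence analysis) and dropping records with non-positive OCR.
#'
#' @param data a data frame with a mean-DO column, an OCR column and a
#'   nitrite oxidation rate column (optionally an ammonia oxidation rate
#'   column).
#' @param do_col,ocr_col,no2ox_col,nh3ox_col column names; set `nh3ox_col =
#'   NULL` if no ammonia rates are present.
#' @param do_ceiling maximum mean DO (nM) retained, default 18000.
#' @return a tibble with `mean_DO_nM`, `OCR`, `R_NO2ox`, `pct_NO2ox` (and
#'   `R_NH3ox`, `pct_NH3ox`), plus `flag_over_100`.
#' @export
partition_table <- function(data, do_col = "mean_DO_nM", ocr_col = "OCR",
                            no2ox_col = "no2ox_rate", nh3ox_col = NULL,
                            do_ceiling = 18000) {
  .need_cols(data, c(do_col, ocr_col, no2ox_col), "partition_table")
  n_in <- nrow(data)
  keep <- is.finite(data[[do_col]]) & is.finite(data[[ocr_col]]) &
    is.finite(data[[no2ox_col]]) & data[[ocr_col]] > 0 &
    data[[do_col]] <= do_ceiling
  d <- data[keep, , drop = FALSE]
  inform(sprintf(
    "partition: %d records in, %d retained (%d dropped: OCR <= 0, non-finite, or DO > %g nM)",
    n_in, nrow(d), n_in - nrow(d), do_ceiling))
  out <- tibble(mean_DO_nM = d[[do_col]],
                OCR = d[[ocr_col]],
                R_NO2ox = d[[no2ox_col]],
                pct_NO2ox = 100 * O2_PER_NO2_OXIDATION * d[[no2ox_col]] /
                  d[[ocr_col]])
  if (!is.null(nh3ox_col) && nh3ox_col %in% names(d)) {
    out$R_NH3ox <- d[[nh3ox_col]]
    out$pct_NH3ox <- 100 * O2_PER_NH4_OXIDATION * d[[nh3ox_col]] / d[[ocr_col]]
  }
  out$flag_over_100 <- out$pct_NO2ox > 100
  out
}

#' Fit a power law to percentage-of-OCR versus dissolved O2
#'
#' Ordinary least squares of log10(pct) on log10(DO): pct = a * DO^b. Only
#' records with positive percentage and positive DO enter the fit
#' (multiplicative scatter is symmetric in log space). A negative exponent b
#' means nitrite oxidation claims a growing share of oxygen consumption as
#' DO falls.
#'
#' @param data a data frame of partition records.
#' @param pct_col,do_col column names of the percentage and DO (nM).
#' @return an object of class `power_law_fit`: `a` (prefactor), `b`
#'   (exponent), `r2`, `p` (regression slope p-value), `n`, `n_dropped`,
#'   and the log-log `lm` model. Methods: [tidy()], [glance()],
#'   [threshold_do()], [autoplot()].
#' @export
fit_power_law <- function(data, pct_col = "pct_NO2ox", do_col = "mean_DO_nM") {
  .need_cols(data, c(pct_col, do_col), "fit_power_law")
  pct <- data[[pct_col]]
  DO <- data[[do_col]]
  keep <- is.finite(pct) & is.finite(DO) & pct > 0 & DO > 0
  if (sum(keep) < 5) abort("need at least 5 records with pct > 0 and DO > 0")
  if (sum(!keep) > 0) {
    inform(sprintf("power law: dropped %d record(s) with pct <= 0 or DO <= 0",
                   sum(!keep)))
  }
  df <- data.frame(lp = log10(pct[keep]), ld = log10(DO[keep]))
  fit <- lm(lp ~ ld, data = df)
  sm <- summary(fit)
  structure(list(a = 10^coef(fit)[["(Intercept)"]],
                 b = coef(fit)[["ld"]],
                 r2 = sm$r.squared,
                 p = sm$coefficients["ld", "Pr(>|t|)"],
                 n = sum(keep),
                 n_dropped = sum(!keep),
                 model = fit),
            class = "power_law_fit")
}

#' Dissolved O2 at which nitrite oxidation reaches a target share of OCR
#'
#' Inverts a fitted power law pct = a * DO^b at a target percentage:
#' DO* = (target / a)^(1 / b). With the default target of 100% this is the
#' DO concentration below which nitrite oxidation alone can account for all
#' oxygen consumption. The inversion is meaningful as a threshold only for
#' b < 0 (share rising as DO falls); a warning is issued otherwise.
#'
#' @param fit a `power_law_fit`.
#' @param target_pct target percentage of OCR (default 100).
#' @return DO concentration, nM.
#' @export
threshold_do <- function(fit, target_pct = 100) {
  if (!inherits(fit, "power_law_fit")) abort("`fit` must be a power_law_fit")
  if (fit$a <= 0) abort("power-law prefactor must be > 0")
  if (fit$b == 0) abort("power-law exponent is 0; threshold undefined")
  if (fit$b > 0) {
    warn("exponent b > 0: share falls as DO falls; threshold is not a lower bound")
  }
  (target_pct / fit$a)^(1 / fit$b)
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power-law fit: pct = %.4g * DO^%.4g (n = %d)\n", x$a, x$b, x$n))
  cat(sprintf("  r2 = %.3f, p = %.3g\n", x$r2, x$p))
  invisible(x)
}

#' Tidy a power-law fit
#'
#' @param x a `power_law_fit`.
#' @param ... ignored.
#' @return `tidy()`: one row per parameter. `glance()`: one-row summary.
#' @export
tidy.power_law_fit <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tibble(term = c("a", "b"),
         estimate = c(x$a, x$b),
         std.error = c(log(10) * x$a * sm["(Intercept)", "Std. Error"],
                       sm["ld", "Std. Error"]),
         p.value = c(sm["(Intercept)", "Pr(>|t|)"], x$p))
}

#' @rdname tidy.power_law_fit
#' @export
glance.power_law_fit <- function(x, ...) {
  tibble(r.squared = x$r2, p.value = x$p, n = x$n, n_dropped = x$n_dropped)
}
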