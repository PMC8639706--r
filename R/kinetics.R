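#' Fit a Michaelis-Menten oxygen-affinity curve across bottles
#'
#' Least-squares fit of v = vmax * S / (Km + S) to (mean dissolved O2, rate)
#' pairs from an oxygen manipulation experiment: the "overall" affinity of
#' the assemblage, with dissolved O2 as the substrate axis. The fit is
#' multi-start (initial Km at 0.1x, 1x and 10x the median DO; initial vmax
#' at the maximum observed rate) because Michaelis-Menten fits on narrow DO
#' ranges are initialization-sensitive; the lowest-SSE converged start is
#' kept. A fit whose Km Wald p-value is >= `p_threshold` is reported but
#' flagged not significant (NS), mirroring standard reporting of these
#' parameters.
#'
#' @param data a data frame of per-bottle pairs.
#' @param do_col,rate_col column names of mean DO (nM) and rate
#'   (nmol L^-1 day^-1).
#' @param p_threshold Wald p-value on Km above which the fit is flagged NS.
#' @return an object of class `mm_fit`: fields `Km`, `Km_se`, `Km_p`,
#'   `vmax`, `vmax_se`, `r2`, `significant`, `converged`, `n`, `fit_kind`
#'   (`"overall"`), and the data used. Methods: [tidy()], [glance()],
#'   [predict_rate()], [autoplot()].
#' @export
#' @examples
#' S <- c(100, 300, 1000, 3000, 10000)
#' d <- data.frame(do_nM = S, rate = 2000 * S / (1000 + S))
#' fit <- fit_michaelis_menten(d)
#' glance(fit)
fit_michaelis_menten <- function(data, do_col = "do_nM", rate_col = "rate",
                                 p_threshold = 0.05) {
  .need_cols(data, c(do_col, rate_col), "fit_michaelis_menten")
  keep <- is.finite(data[[do_col]]) & is.finite(data[[rate_col]])
  S <- data[[do_col]][keep]
  v <- data[[rate_col]][keep]
  if (length(S) < 4) abort("need at least 4 (DO, rate) pairs")
  if (max(S) / max(min(S), 1e-12) < 10) {
    warn("DO values span less than one order of magnitude; Km is weakly constrained")
  }
  df <- data.frame(S = S, v = v)
  starts <- lapply(c(1, 0.1, 10), function(m) {
    list(vmax = max(v), Km = m * median(S))
  })
  fits <- lapply(starts, function(st) {
    tryCatch(
      minpack.lm::nlsLM(v ~ vmax * S / (Km + S), data = df, start = st,
                        lower = c(vmax = 0, Km = 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) {
    warn("Michaelis-Menten fit did not converge from any start; flagged NS")
    return(new_mm_fit(Km = NA_real_, Km_se = NA_real_, Km_p = NA_real_,
                      vmax = NA_real_, vmax_se = NA_real_, r2 = NA_real_,
                      significant = FALSE, converged = FALSE,
                      n = length(S), fit_kind = "overall",
                      data = tibble(do_nM = S, rate = v)))
  }
  fit <- fits[[which.min(vapply(fits, stats::deviance, numeric(1)))]]
  co <- summary(fit)$coefficients
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((v - mean(v))^2)
  new_mm_fit(Km = co["Km", "Estimate"], Km_se = co["Km", "Std. Error"],
             Km_p = co["Km", "Pr(>|t|)"],
             vmax = co["vmax", "Estimate"], vmax_se = co["vmax", "Std. Error"],
             r2 = r2,
             significant = co["Km", "Pr(>|t|)"] < p_threshold,
             converged = TRUE, n = length(S), fit_kind = "overall",
             data = tibble(do_nM = S, rate = v))
}

new_mm_fit <- function(...) {
  structure(list(...), class = "mm_fit")
}

#' Closed-form DO depletion under integrated Michaelis-Menten kinetics
#'
#' For a bottle consuming O2 at v = vmax * S / (Km + S), the progress curve
#' satisfies t(S) = (S0 - S) / vmax + (Km / vmax) * ln(S0 / S). This
#' function inverts that relation numerically (monotone interpolation on a
#' log-spaced S grid) to give DO as a function of time.
#'
#' @param t_days times since the first reading, days.
#' @param S0 initial dissolved O2, nM.
#' @param Km,vmax Michaelis-Menten parameters (nM, nmol L^-1 day^-1).
#' @return dissolved O2 at each time, nM.
#' @export
mm_depletion_do <- function(t_days, S0, Km, vmax) {
  if (S0 <= 0 || Km <= 0 || vmax <= 0) {
    abort("S0, Km and vmax must all be > 0")
  }
  Sg <- S0 * exp(seq(0, -18, length.out = 600))
  tg <- (S0 - Sg) / vmax + (Km / vmax) * log(S0 / Sg)
  approx(tg, Sg, xout = pmax(t_days, 0), rule = 2)$y
}

#' Fit the low-level oxygen affinity from a within-bottle DO decline
#'
#' Bottles incubated at low dissolved O2 (mean DO below ~235 nM) draw O2
#' down through the half-saturation range, so their consumption rate
#' declines over time and the full progress curve constrains Km directly.
#' This fits the integrated Michaelis-Menten depletion model (see
#' [mm_depletion_do()]) to the DO readings by nonlinear least squares on the
#' DO residuals, excluding censored readings. Km is the parameter of
#' interest; vmax is a nuisance parameter, and S0 is fixed to the first
#' uncensored reading by default (set `estimate_S0 = TRUE` to free it).
#'
#' @param series a data frame with columns `t_hours`, `DO_nM` and optionally
#'   `censored`.
#' @param low_do_cutoff advisory mean-DO cutoff (nM) for this estimator;
#'   a warning is issued above it.
#' @param min_do guard level (nM): readings below it are excluded along
#'   with censored ones. Near the detection limit only upward noise
#'   excursions survive censoring, which flattens the curve tail and
#'   inflates Km; excluding readings within ~3 sensor standard deviations
#'   of the limit (e.g. `min_do = limit + 3 * sensor_sd`) removes that
#'   one-sided truncation bias.
#' @param estimate_S0 estimate the initial DO instead of fixing it to the
#'   first uncensored reading.
#' @param p_threshold Wald p-value on Km above which the fit is flagged NS.
#' @return an `mm_fit` with `fit_kind = "low_level"` and an `S0` field.
#' @export
fit_low_level_km <- function(series, low_do_cutoff = 235, min_do = 0,
                             estimate_S0 = FALSE, p_threshold = 0.05) {
  .need_cols(series, c("t_hours", "DO_nM"), "fit_low_level_km")
  cens <- if ("censored" %in% names(series)) series$censored else
    rep(FALSE, nrow(series))
  s <- series[!cens & series$DO_nM >= min_do, , drop = FALSE]
  if (nrow(s) < 5) abort("need at least 5 uncensored DO readings")
  if (mean(series$DO_nM) > low_do_cutoff) {
    warn(sprintf("mean DO %.0f nM exceeds the %.0f nM low-level cutoff",
                 mean(series$DO_nM), low_do_cutoff))
  }
  t_days <- (s$t_hours - s$t_hours[1]) / 24
  DO <- s$DO_nM
  S0_fix <- DO[1]
  span_days <- max(t_days)
  if (span_days <= 0) abort("need a positive time span")
  # rough initial vmax from the gross depletion slope
  v0 <- max((max(DO) - min(DO)) / span_days, 1)
  resid_fn <- function(par) {
    Km <- par[["Km"]]; vmax <- par[["vmax"]]
    S0 <- if (estimate_S0) par[["S0"]] else S0_fix
    if (Km <= 0 || vmax <= 0 || S0 <= 0) return(rep(1e6, length(DO)))
    DO - mm_depletion_do(t_days, S0, Km, vmax)
  }
  starts <- list()
  for (kmul in c(0.05, 0.3, 1)) {
    for (vmul in c(1, 2.5)) {
      st <- c(Km = kmul * S0_fix, vmax = vmul * v0)
      if (estimate_S0) st <- c(st, S0 = S0_fix)
      starts <- c(starts, list(st))
    }
  }
  lower <- c(Km = 1e-3, vmax = 1e-3)
  if (estimate_S0) lower <- c(lower, S0 = 1e-3)
  fits <- lapply(starts, function(st) {
    tryCatch(minpack.lm::nls.lm(par = st, lower = lower, fn = resid_fn,
                                control = minpack.lm::nls.lm.control(maxiter = 300)),
             error = function(e) NULL)
  })
  fits <- Filter(function(f) !is.null(f) && all(is.finite(f$par)), fits)
  if (length(fits) == 0) {
    warn("low-level depletion fit did not converge; flagged NS")
    return(new_mm_fit(Km = NA_real_, Km_se = NA_real_, Km_p = NA_real_,
                      vmax = NA_real_, vmax_se = NA_real_, r2 = NA_real_,
                      significant = FALSE, converged = FALSE, n = nrow(s),
                      fit_kind = "low_level", S0 = S0_fix,
                      data = tibble(t_hours = s$t_hours, DO_nM = DO)))
  }
  dev <- vapply(fits, function(f) sum(resid_fn(f$par)^2), numeric(1))
  fit <- fits[[which.min(dev)]]
  co <- tryCatch(summary(fit)$coefficients, error = function(e) NULL)
  get <- function(term, col, fallback = NA_real_) {
    if (!is.null(co) && term %in% rownames(co)) co[term, col] else fallback
  }
  r2 <- 1 - min(dev) / sum((DO - mean(DO))^2)
  Km_p <- get("Km", "Pr(>|t|)")
  new_mm_fit(Km = fit$par[["Km"]], Km_se = get("Km", "Std. Error"),
             Km_p = Km_p,
             vmax = fit$par[["vmax"]], vmax_se = get("vmax", "Std. Error"),
             r2 = r2,
             significant = is.finite(Km_p) && Km_p < p_threshold,
             converged = TRUE, n = nrow(s), fit_kind = "low_level",
             S0 = if (estimate_S0) fit$par[["S0"]] else S0_fix,
             data = tibble(t_hours = s$t_hours, DO_nM = DO))
}

#' Predict a rate from a fitted Michaelis-Menten curve
#'
#' @param fit an `mm_fit`.
#' @param S dissolved O2, nM (>= 0).
#' @return predicted rate(s), nmol L^-1 day^-1.
#' @export
predict_rate <- function(fit, S) {
  if (!inherits(fit, "mm_fit")) abort("`fit` must be an mm_fit")
  if (any(S < 0)) abort("`S` must be >= 0")
  if (!is.finite(fit$Km) || !is.finite(fit$vmax)) {
    abort("fit has no finite parameters")
  }
  fit$vmax * S / (fit$Km + S)
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten %s fit (n = %d)\n", x$fit_kind, x$n))
  cat(sprintf("  Km   = %.4g +/- %.3g nM (p = %.3g)%s\n", x$Km, x$Km_se,
              x$Km_p, if (isTRUE(x$significant)) "" else "  [NS]"))
  cat(sprintf("  vmax = %.4g +/- %.3g nmol L^-1 day^-1\n", x$vmax, x$vmax_se))
  cat(sprintf("  r2   = %.3f\n", x$r2))
  invisible(x)
}

#' Tidy a Michaelis-Menten fit
#'
#' @param x an `mm_fit`.
#' @param ... ignored.
#' @return `tidy()`: one row per parameter with `term`, `estimate`,
#'   `std.error`, `p.value`. `glance()`: a one-row model summary.
#' @export
tidy.mm_fit <- function(x, ...) {
  tibble(term = c("Km", "vmax"),
         estimate = c(x$Km, x$vmax),
         std.error = c(x$Km_se, x$vmax_se),
         p.value = c(x$Km_p, NA_real_))
}

#' @rdname tidy.mm_fit
#' @export
glance.mm_fit <- function(x, ...) {
  tibble(r.squared = x$r2, n = x$n, significant = x$significant,
         converged = x$converged, fit_kind = x$fit_kind)
}
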