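#' Michaelis-Menten parameter-recovery study
#'
#' Repeated synthetic oxygen manipulation experiments for assessing how well
#' the across-bottle Michaelis-Menten fit recovers known oxygen-affinity
#' parameters. Each replicate simulates an 8-bottle experiment (one bottle
#' per DO level) with the forward model, measures each bottle the way the
#' field method does — endpoint oxygen consumption rate for `process =
#' "ocr"`, 15NO2- tracer inversion ([nitrite_oxidation_rate()]) for
#' `process = "no2ox"` — applies multiplicative Gaussian rate noise, and
#' refits the saturation curve against mean bottle DO.
#'
#' @param Km,vmax generating parameters (nM, nmol L^-1 day^-1).
#' @param process `"ocr"` (heterotrophic O2 drawdown measured by endpoint
#'   OCR) or `"no2ox"` (nitrite oxidation measured by tracer inversion).
#' @param DO_levels target initial DO per bottle, nM.
#' @param duration incubation length, hours.
#' @param noise_frac multiplicative rate noise (1 sd), default 10%.
#' @param n_seeds number of replicate experiments.
#' @param dt integration step, hours.
#' @param seed master seed.
#' @return a tibble with one row per replicate: `seed`, `Km_hat`,
#'   `vmax_hat`, `Km_se`, `vmax_se`, `converged`.
#' @export
mm_recovery_study <- function(Km, vmax,
                              process = c("ocr", "no2ox"),
                              DO_levels = NULL,
                              duration = 16,
                              noise_frac = 0.1,
                              n_seeds = 200,
                              dt = 0.05,
                              seed = 1L) {
  process <- match.arg(process)
  if (is.null(DO_levels)) {
    DO_levels <- if (process == "ocr") {
      c(50, 150, 400, 1000, 2500, 6000, 12000, 20000)
    } else {
      c(10, 25, 50, 100, 250, 500, 1000, 2000)
    }
  }
  base <- if (process == "ocr") {
    sim_config(vmax_het = vmax, Km_het = Km, duration = duration, dt = dt,
               sensor_sd = 0, atpct_sd = 0, sensor_detection_limit = 0)
  } else {
    sim_config(vmax_NO = vmax, Km_NO = Km, initial_NO2 = 2000,
               initial_NO3 = 20000, duration = duration, dt = dt,
               sensor_sd = 0, atpct_sd = 0, sensor_detection_limit = 0)
  }
  # the latent experiment is deterministic; noise enters at the rate level
  ex <- simulate_experiment(base, DO_levels = DO_levels,
                            treatments = if (process == "ocr") "unlabeled"
                            else "15NO2",
                            seed = seed)
  ex$mean_DO_nM <- (ex$DO_nM_initial + ex$DO_nM_final) / 2
  rate <- if (process == "ocr") {
    ocr_endpoint(ex$DO_nM_initial, ex$DO_nM_final, ex$t_hours)
  } else {
    nitrite_oxidation_rate(ex)$no2ox_rate
  }
  purrr::map(seq_len(n_seeds), function(s) {
    obs <- withr::with_seed(mix_seed(seed, s), {
      rate * (1 + noise_frac * rnorm(length(rate)))
    })
    fit <- fit_michaelis_menten(
      tibble(do_nM = ex$mean_DO_nM, rate = obs))
    tibble(seed = s, Km_hat = fit$Km, vmax_hat = fit$vmax,
           Km_se = fit$Km_se, vmax_se = fit$vmax_se,
           converged = fit$converged)
  }) |> dplyr::bind_rows()
}

#' Low-level Km parameter-recovery study
#'
#' Repeated within-bottle DO-decline experiments for assessing recovery of
#' the low-level oxygen affinity: one latent depletion trajectory (initial
#' DO below the half-saturation screening cutoff, drawn down through Km) is
#' observed `n_seeds` times with independent sensor noise and a detection
#' limit, and each noisy series is refit with the integrated
#' Michaelis-Menten model ([fit_low_level_km()]). Fits exclude readings
#' within 3 sensor standard deviations of the detection limit (the
#' truncation guard; see `min_do` in [fit_low_level_km()]).
#'
#' @param Km,vmax generating parameters (nM, nmol L^-1 day^-1).
#' @param S0 initial dissolved O2, nM.
#' @param duration monitoring length, hours.
#' @param n_obs number of DO readings.
#' @param sensor_sd sensor noise, nM.
#' @param detection_limit sensor detection limit, nM.
#' @param n_seeds number of replicate observations.
#' @param dt integration step, hours.
#' @param seed master seed.
#' @return a tibble with one row per replicate: `seed`, `Km_hat`, `Km_se`,
#'   `vmax_hat`, `converged`.
#' @export
low_level_km_study <- function(Km = 124, vmax = 1500, S0 = 235,
                               duration = 19, n_obs = 20,
                               sensor_sd = 5, detection_limit = 10,
                               n_seeds = 200, dt = 0.02, seed = 1L) {
  cfg <- sim_config(initial_O2 = S0, vmax_het = vmax, Km_het = Km,
                    duration = duration, dt = dt, sensor_sd = sensor_sd,
                    sensor_detection_limit = detection_limit)
  series <- simulate_bottle(cfg)
  obs_times <- seq(0, duration, length.out = n_obs)
  guard <- detection_limit + 3 * sensor_sd
  purrr::map(seq_len(n_seeds), function(s) {
    o <- observe_bottle(series, obs_times = obs_times,
                        seed = mix_seed(seed, s))
    fit <- tryCatch(
      suppressWarnings(fit_low_level_km(o$do_series[[1]], min_do = guard)),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(tibble(seed = s, Km_hat = NA_real_, Km_se = NA_real_,
                    vmax_hat = NA_real_, converged = FALSE))
    }
    tibble(seed = s, Km_hat = fit$Km, Km_se = fit$Km_se,
           vmax_hat = fit$vmax, converged = fit$converged)
  }) |> dplyr::bind_rows()
}

#' Linearity-screen accuracy study
#'
#' Classifies replicate simulated drawdown curves of two kinds — constant
#' rate far above the half-saturation concentration (truth: linear) and
#' Michaelis-Menten depletion from low DO through Km to the detection limit
#' (truth: nonlinear) — under independent sensor noise, and reports the
#' classification accuracy of the MIC + r^2 screen.
#'
#' @param n_seeds replicate bottles per kind.
#' @param sensor_sd sensor noise, nM.
#' @param n_obs readings per bottle.
#' @param dt integration step, hours.
#' @param seed master seed.
#' @return a tibble with one row per bottle: `kind`, `seed`,
#'   `classification`, `correct`.
#' @export
linearity_screen_study <- function(n_seeds = 50, sensor_sd = 2, n_obs = 13,
                                   dt = 0.05, seed = 1L) {
  lin_cfg <- sim_config(initial_O2 = 5000, vmax_het = 500, Km_het = 100,
                        duration = 24, dt = dt, sensor_sd = sensor_sd,
                        sensor_detection_limit = 10)
  non_cfg <- sim_config(initial_O2 = 235, vmax_het = 1500, Km_het = 100,
                        duration = 24, dt = dt, sensor_sd = sensor_sd,
                        sensor_detection_limit = 10)
  lin_series <- simulate_bottle(lin_cfg)
  non_series <- simulate_bottle(non_cfg)
  obs_times <- seq(0, 24, length.out = n_obs)
  one <- function(series, kind, truth, s) {
    o <- observe_bottle(series, obs_times = obs_times,
                        seed = mix_seed(seed, s))
    cls <- linearity_classification(o$do_series[[1]])
    tibble(kind = kind, seed = s, classification = cls$classification,
           correct = cls$classification == truth)
  }
  dplyr::bind_rows(
    purrr::map(seq_len(n_seeds),
               ~ one(lin_series, "constant_rate", "linear", .x)),
    purrr::map(seq_len(n_seeds),
               ~ one(non_series, "mm_depletion", "nonlinear",
                     .x + n_seeds)))
}
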