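#' Configure a simulated bottle incubation
#'
#' Builds the parameter set for a forward-simulated sealed-bottle incubation:
#' initial pool sizes, 15N atom fractions, process rates, integration controls
#' and observation-noise levels. The process model couples four pools (O2,
#' NH4+, NO2-, NO3-, all in nM) through ammonia oxidation, nitrite oxidation,
#' heterotrophic respiration and nitrate reduction (see
#' [simulate_bottle()]).
#'
#' @param initial_O2,initial_NH4,initial_NO2,initial_NO3 initial pool
#'   concentrations, nM.
#' @param f15_NH4,f15_NO2,f15_NO3 initial 15N atom fractions (0-1) of each
#'   nitrogen pool; default natural abundance.
#' @param R_AO ammonia oxidation rate, nmol N L^-1 day^-1 (zero order in NH4
#'   until the pool nears exhaustion).
#' @param vmax_NO,Km_NO Michaelis-Menten parameters of nitrite oxidation with
#'   dissolved O2 as substrate: maximal rate (nmol N L^-1 day^-1) and
#'   half-saturation (nM O2).
#' @param vmax_het,Km_het Michaelis-Menten parameters of heterotrophic O2
#'   respiration (nmol O2 L^-1 day^-1, nM O2).
#' @param R_NAR nitrate reduction (NO3- -> NO2-) rate, nmol N L^-1 day^-1.
#' @param O2_production photosynthetic O2 source, nM O2 day^-1 (about
#'   100 nM day^-1 in a secondary chlorophyll maximum; default 0, dark
#'   incubation).
#' @param duration incubation length, hours.
#' @param dt integration step, hours (fixed-step explicit midpoint).
#' @param seed integer seed used for observation noise in [observe_bottle()].
#' @param sensor_sd optode sensor noise on dissolved O2 readings, nM (1 sd).
#' @param sensor_detection_limit optode detection limit, nM: 10 for
#'   trace-level spots, 100 for wide-range spots. Readings below it are
#'   reported at the limit and flagged censored.
#' @param atpct_sd measurement noise on atom-percent values; default derived
#'   from the 0.3 permil delta-15N precision at natural abundance.
#' @param o2_per_no2,o2_per_nh4 O2 stoichiometry of nitrite oxidation (0.5)
#'   and ammonia oxidation (1.5), mol O2 per mol N.
#' @param ramp_width width (nM) of the smooth shutoff applied to each rate as
#'   its substrate pool approaches zero; avoids overshoot without event
#'   detection.
#' @return an object of class `sim_config` (a named list).
#' @seealso [simulate_bottle()], [observe_bottle()], [simulate_experiment()]
#' @export
#' @examples
#' cfg <- sim_config(vmax_NO = 100, Km_NO = 100, duration = 24)
#' str(cfg[c("vmax_NO", "Km_NO", "duration")])
sim_config <- function(initial_O2 = 500,
                       initial_NH4 = 100,
                       initial_NO2 = 2000,
                       initial_NO3 = 20000,
                       f15_NH4 = nat_abundance_frac(),
                       f15_NO2 = nat_abundance_frac(),
                       f15_NO3 = nat_abundance_frac(),
                       R_AO = 0,
                       vmax_NO = 0,
                       Km_NO = 1000,
                       vmax_het = 0,
                       Km_het = 1000,
                       R_NAR = 0,
                       O2_production = 0,
                       duration = 24,
                       dt = 0.01,
                       seed = 1L,
                       sensor_sd = 2,
                       sensor_detection_limit = 10,
                       atpct_sd = atpct_sd_from_permil(0.3),
                       o2_per_no2 = O2_PER_NO2_OXIDATION,
                       o2_per_nh4 = O2_PER_NH4_OXIDATION,
                       ramp_width = 1) {
  cfg <- as.list(environment())
  num <- unlist(cfg[setdiff(names(cfg), "seed")])
  if (any(!is.finite(num))) {
    abort("all sim_config parameters must be finite numbers")
  }
  conc <- c(initial_O2, initial_NH4, initial_NO2, initial_NO3)
  if (any(conc < 0)) abort("initial concentrations must be >= 0")
  fr <- c(f15_NH4, f15_NO2, f15_NO3)
  if (any(fr < 0 | fr > 1)) abort("atom fractions must lie in [0, 1]")
  if (dt <= 0) abort("dt must be > 0")
  if (duration <= 0) abort("duration must be > 0")
  if (Km_NO <= 0 || Km_het <= 0) abort("Km values must be > 0")
  if (any(c(R_AO, vmax_NO, vmax_het, R_NAR) < 0)) {
    abort("rate parameters must be >= 0")
  }
  if (sensor_sd < 0 || atpct_sd < 0) abort("noise sd must be >= 0")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

# cubic smoothstep from 0 (x <= 0) to 1 (x >= 1)
smoothstep <- function(x) {
  t <- pmin(1, pmax(0, x))
  t * t * (3 - 2 * t)
}

# state y = (O2, NH4, NO2, NO3, A_NH4, A_NO2, A_NO3); A_* are 15N atom
# concentrations (nM). All rates per day; the substrate shutoff ramps each
# rate to zero over the last `ramp_width` nM of its substrate(s).
bottle_fluxes <- function(y, cf) {
  O2 <- y[1]; NH4 <- y[2]; NO2 <- y[3]; NO3 <- y[4]
  f_NH4 <- if (NH4 > 1e-12) y[5] / NH4 else 0
  f_NO2 <- if (NO2 > 1e-12) y[6] / NO2 else 0
  f_NO3 <- if (NO3 > 1e-12) y[7] / NO3 else 0
  gO2 <- smoothstep(O2 / cf$ramp_width)
  R_AO <- cf$R_AO * smoothstep(NH4 / cf$ramp_width) * gO2
  R_NO <- cf$vmax_NO * O2 / (cf$Km_NO + O2) *
    smoothstep(NO2 / cf$ramp_width) * gO2
  R_het <- cf$vmax_het * O2 / (cf$Km_het + O2) * gO2
  R_NAR <- cf$R_NAR * smoothstep(NO3 / cf$ramp_width)
  dy <- c(cf$O2_production - cf$o2_per_no2 * R_NO - cf$o2_per_nh4 * R_AO - R_het,
          -R_AO,
          R_AO + R_NAR - R_NO,
          R_NO - R_NAR,
          -R_AO * f_NH4,
          R_AO * f_NH4 + R_NAR * f_NO3 - R_NO * f_NO2,
          R_NO * f_NO2 - R_NAR * f_NO3)
  list(dy = dy,
       rates = c(no2_oxidation = R_NO, nh3_oxidation = R_AO,
                 heterotrophy = R_het, nitrate_reduction = R_NAR,
                 o2_production = cf$O2_production))
}

#' Forward-simulate a bottle incubation
#'
#' Integrates the coupled O2 / NH4+ / NO2- / NO3- process model with a
#' fixed-step explicit midpoint scheme. Per day, the model is
#' d NO3/dt = R_NO - R_NAR, d NO2/dt = R_AO + R_NAR - R_NO,
#' d NH4/dt = -R_AO, and
#' d O2/dt = P - 0.5 R_NO - 1.5 R_AO - R_het, with R_NO and R_het
#' Michaelis-Menten in O2. 15N label is advected with the fluxes: ammonia
#' oxidation delivers NO2- at the NH4+ pool's atom fraction, nitrate
#' reduction delivers NO2- at the NO3- fraction, and nitrite oxidation
#' delivers NO3- at the NO2- fraction, so total N and total 15N atoms are
#' conserved identically. Every rate shuts off smoothly as its substrate
#' pool(s) approach zero; O2 is never driven negative.
#'
#' @param config a [sim_config()].
#' @return a tibble (class `bottle_series`) with columns `time_h`, `O2`,
#'   `NH4`, `NO2`, `NO3` (nM) and `f15_NH4`, `f15_NO2`, `f15_NO3` (atom
#'   fractions), with the config and the cumulative process budget attached
#'   as attributes (see [o2_budget()]).
#' @export
#' @examples
#' s <- simulate_bottle(sim_config(vmax_NO = 100, Km_NO = 1e-6, dt = 0.1))
#' tail(s, 2)
simulate_bottle <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be created by sim_config()")
  }
  n_steps <- max(1L, as.integer(ceiling(config$duration / config$dt)))
  dt_day <- (config$duration / n_steps) / 24
  y <- c(config$initial_O2, config$initial_NH4, config$initial_NO2,
         config$initial_NO3,
         config$f15_NH4 * config$initial_NH4,
         config$f15_NO2 * config$initial_NO2,
         config$f15_NO3 * config$initial_NO3)
  states <- matrix(0, n_steps + 1L, 7L)
  states[1L, ] <- y
  acc <- c(no2_oxidation = 0, nh3_oxidation = 0, heterotrophy = 0,
           nitrate_reduction = 0, o2_production = 0)
  for (i in seq_len(n_steps)) {
    d1 <- bottle_fluxes(y, config)
    ym <- pmax(y + 0.5 * dt_day * d1$dy, 0)
    d2 <- bottle_fluxes(ym, config)
    y <- y + dt_day * d2$dy
    # the midpoint shutoff keeps overshoot at rounding level; clip it
    y[y < 0] <- 0
    if (any(!is.finite(y))) {
      bad <- c("O2", "NH4", "NO2", "NO3", "A_NH4", "A_NO2", "A_NO3")[
        which(!is.finite(y))[1]]
      abort(sprintf(
        "non-finite state (%s) at integration step %d (t = %.3f h)",
        bad, i, i * config$duration / n_steps))
    }
    acc <- acc + dt_day * d2$rates
    states[i + 1L, ] <- y
  }
  frac <- function(a, pool) ifelse(pool > 1e-12, a / pool, 0)
  out <- tibble(
    time_h = seq(0, config$duration, length.out = n_steps + 1L),
    O2 = states[, 1], NH4 = states[, 2], NO2 = states[, 3], NO3 = states[, 4],
    f15_NH4 = frac(states[, 5], states[, 2]),
    f15_NO2 = frac(states[, 6], states[, 3]),
    f15_NO3 = frac(states[, 7], states[, 4]))
  attr(out, "config") <- config
  attr(out, "budget") <- acc
  class(out) <- c("bottle_series", class(out))
  out
}

#' Cumulative O2 budget of a simulated bottle
#'
#' Returns the time-integrated contribution of each process to the O2 balance
#' of a simulated bottle, accumulated alongside the state integration so that
#' closure against the net O2 change is exact up to rounding: net change =
#' production - 0.5 * nitrite oxidation - 1.5 * ammonia oxidation -
#' heterotrophy.
#'
#' @param series a `bottle_series` from [simulate_bottle()].
#' @return a tibble with one row per term: `term`, `nmol_per_l` (cumulative
#'   N or O2 transformed) and `o2_nmol_per_l` (signed O2 contribution).
#' @export
o2_budget <- function(series) {
  acc <- attr(series, "budget")
  cf <- attr(series, "config")
  if (is.null(acc) || is.null(cf)) {
    abort("`series` must come from simulate_bottle()")
  }
  sign_o2 <- c(no2_oxidation = -cf$o2_per_no2,
               nh3_oxidation = -cf$o2_per_nh4,
               heterotrophy = -1,
               nitrate_reduction = 0,
               o2_production = 1)
  tibble(term = names(acc),
         nmol_per_l = unname(acc),
         o2_nmol_per_l = unname(acc * sign_o2[names(acc)]))
}

# stable integer mixing so bottle k's noise does not depend on how many
# bottles are simulated before or after it
mix_seed <- function(seed, i) {
  s <- as.double(seed) %% 2147483647
  as.integer((s * 16807 + as.double(i) * 2654435 + 12345) %% 2147483647)
}

#' Observe a simulated bottle as endpoint measurements
#'
#' Converts a latent [simulate_bottle()] trajectory into what the instruments
#' report: dissolved O2 readings at the monitoring times with Gaussian sensor
#' noise and a detection-limit floor (readings below the limit are reported
#' at the limit and flagged censored), plus endpoint pool concentrations and
#' atom-percent values with atom-percent measurement noise. All noise is
#' drawn under a seed derived from the bottle config, so repeated calls give
#' identical tables.
#'
#' @param series a `bottle_series`.
#' @param obs_times times (hours) at which DO is read; default 13 evenly
#'   spaced readings across the incubation.
#' @param seed optional integer overriding the config seed.
#' @return a one-row tibble: `t_hours`, initial/final DO readings and censor
#'   flags, initial and final pool concentrations (nM), measured atom
#'   percents of NH4+, NO2-, NO3- and of the combined product (NO2- + NO3-)
#'   pool, the sensor detection limit, and a nested `do_series` tibble
#'   (`t_hours`, `DO_nM`, `censored`).
#' @export
observe_bottle <- function(series, obs_times = NULL, seed = NULL) {
  cf <- attr(series, "config")
  if (is.null(cf)) abort("`series` must come from simulate_bottle()")
  if (is.null(obs_times)) {
    obs_times <- seq(0, cf$duration, length.out = 13)
  }
  if (any(obs_times < 0 | obs_times > cf$duration)) {
    abort("obs_times must lie within the incubation duration")
  }
  seed <- as.integer(seed %||% cf$seed)
  withr::with_seed(seed, {
    do_latent <- approx(series$time_h, series$O2, xout = obs_times)$y
    do_obs <- do_latent + rnorm(length(do_latent), 0, cf$sensor_sd)
    cens <- do_obs < cf$sensor_detection_limit
    do_obs[cens] <- cf$sensor_detection_limit
    do_tbl <- tibble(t_hours = obs_times, DO_nM = do_obs, censored = cens)

    first <- series[1L, ]
    last <- series[nrow(series), ]
    at <- function(f) 100 * f + rnorm(length(f), 0, cf$atpct_sd)
    f_prod <- function(row) {
      pool <- row$NO2 + row$NO3
      if (pool > 1e-12) (row$f15_NO2 * row$NO2 + row$f15_NO3 * row$NO3) / pool else 0
    }
    tibble(
      t_hours = cf$duration,
      DO_nM_initial = do_tbl$DO_nM[1L],
      DO_nM_final = do_tbl$DO_nM[nrow(do_tbl)],
      censored_initial = do_tbl$censored[1L],
      censored_final = do_tbl$censored[nrow(do_tbl)],
      NH4_nM = first$NH4, NO2_nM = first$NO2, NO3_nM = first$NO3,
      NH4_nM_final = last$NH4, NO2_nM_final = last$NO2, NO3_nM_final = last$NO3,
      atpct_NH4_initial = at(first$f15_NH4),
      atpct_NO2_initial = at(first$f15_NO2),
      atpct_NO3_initial = at(first$f15_NO3),
      atpct_NO3_final = at(last$f15_NO3),
      atpct_prod_initial = at(f_prod(first)),
      atpct_prod_final = at(f_prod(last)),
      sensor_detection_limit = cf$sensor_detection_limit,
      do_series = list(do_tbl))
  })
}

#' Simulate a multi-bottle oxygen manipulation experiment
#'
#' Mirrors the shipboard design: one sealed bottle per combination of target
#' initial dissolved O2 level and label treatment (the standard design is 8
#' DO levels x 3 treatments = 24 bottles: eight 15NO2-, eight 15NH4-, eight
#' unlabeled). Tracer additions are applied at a fixed fraction of the
#' ambient pool at 98 at% 15N; each bottle's observation noise uses an
#' independent child seed derived by stable integer mixing from the master
#' seed, so adding bottles never changes earlier bottles' noise.
#'
#' @param base_config a [sim_config()] giving the shared water-mass
#'   properties; `initial_O2` is overridden per bottle.
#' @param DO_levels target initial DO concentrations, nM (typically spanning
#'   tens of nM to thousands of nM).
#' @param treatments character vector drawn from `"15NO2"`, `"15NH4"`,
#'   `"unlabeled"`; repeats allowed (replicates).
#' @param spike_fraction tracer addition as a fraction of the ambient pool
#'   (0.05-0.10 in practice; default 0.1).
#' @param spike_atpct atom percent 15N of the tracer stock (98).
#' @param seed master seed; default the base config seed.
#' @param obs_times passed to [observe_bottle()].
#' @return a tibble with one row per bottle: `bottle_id`, `treatment`,
#'   `do_target_nM`, spike description, ambient pools, all
#'   [observe_bottle()] columns, and a `config` list-column holding each
#'   bottle's realized [sim_config()].
#' @export
simulate_experiment <- function(base_config,
                                DO_levels,
                                treatments = c("15NO2", "15NH4", "unlabeled"),
                                spike_fraction = 0.1,
                                spike_atpct = 98,
                                seed = NULL,
                                obs_times = NULL) {
  if (!inherits(base_config, "sim_config")) {
    abort("`base_config` must be created by sim_config()")
  }
  if (length(DO_levels) == 0) abort("`DO_levels` must not be empty")
  treatments <- match.arg(treatments, c("15NO2", "15NH4", "unlabeled"),
                          several.ok = TRUE)
  seed <- as.integer(seed %||% base_config$seed)
  grid <- tidyr::expand_grid(do_target_nM = as.double(DO_levels),
                             treatment = treatments)
  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    cfg <- base_config
    cfg$initial_O2 <- grid$do_target_nM[i]
    cfg$seed <- mix_seed(seed, i)
    trt <- grid$treatment[i]
    spike_nM <- 0
    if (trt == "15NO2") {
      amb <- base_config$initial_NO2
      spike_nM <- spike_fraction * amb
      cfg$f15_NO2 <- spike_atom_percent(amb, 100 * base_config$f15_NO2,
                                        spike_nM, spike_atpct) / 100
      cfg$initial_NO2 <- amb + spike_nM
    } else if (trt == "15NH4") {
      amb <- base_config$initial_NH4
      spike_nM <- spike_fraction * amb
      cfg$f15_NH4 <- spike_atom_percent(amb, 100 * base_config$f15_NH4,
                                        spike_nM, spike_atpct) / 100
      cfg$initial_NH4 <- amb + spike_nM
    }
    cfg <- structure(cfg, class = "sim_config")
    rec <- observe_bottle(simulate_bottle(cfg), obs_times = obs_times)
    dplyr::bind_cols(
      tibble(bottle_id = sprintf("B%03d", i),
             treatment = trt,
             do_target_nM = grid$do_target_nM[i],
             spike_nM = spike_nM,
             spike_atpct = spike_atpct,
             no2_ambient_nM = base_config$initial_NO2,
             nh4_ambient_nM = base_config$initial_NH4),
      rec,
      tibble(config = list(cfg)))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "base_config") <- base_config
  out
}

#' Parametric depth-profile template for an OMZ/AMZ station
#'
#' Describes the vertical structure the simulator emulates: a sigmoid decline
#' of dissolved O2 through the oxycline, Gaussian chlorophyll peaks (surface
#' maximum plus a secondary chlorophyll maximum, SCM), nitrite accumulating
#' in a secondary nitrite maximum (SNM) below the oxycline, and depth-varying
#' process rates (nitrite oxidizers concentrated around the SCM/SNM,
#' heterotrophy decaying with depth, nitrate reduction confined to low-DO
#' water).
#'
#' @param station station label.
#' @param depths strictly increasing depth grid, m.
#' @param DO_surface,DO_deep surface and deep dissolved O2, nM.
#' @param oxycline_depth,oxycline_width centre and width of the sigmoid DO
#'   decline, m.
#' @param chl_max,chl_depth,chl_sd surface chlorophyll peak (mg m^-3, m, m).
#' @param scm_max,scm_depth,scm_sd secondary chlorophyll maximum.
#' @param snm_max,snm_depth,snm_sd secondary nitrite maximum (nM, m, m); set
#'   `snm_max = 0` for a station without an SNM.
#' @param no2_background background nitrite, nM.
#' @param no3_deep deep nitrate, nM.
#' @param nh4_background ammonium, nM.
#' @param vmax_NO_max,Km_NO,nob_depth,nob_sd nitrite-oxidizer Michaelis-Menten
#'   parameters and the Gaussian depth envelope of their maximal rate.
#' @param vmax_het_surface,Km_het,het_depth_scale heterotrophic respiration:
#'   surface maximal rate, half-saturation, and exponential depth scale (m).
#' @param R_AO_surface,ao_depth_scale ammonia oxidation surface rate and
#'   depth scale.
#' @param R_NAR_max nitrate reduction rate inside the low-DO core.
#' @param seed master seed for bottles generated from this profile.
#' @param dt integration step (hours) for bottles generated from this profile.
#' @param duration incubation length (hours) for generated bottles.
#' @return a list of class `profile_template`.
#' @export
profile_template <- function(station = "AMZ-1",
                             depths = seq(20, 300, by = 10),
                             DO_surface = 200000,
                             DO_deep = 5,
                             oxycline_depth = 60,
                             oxycline_width = 10,
                             chl_max = 3, chl_depth = 25, chl_sd = 10,
                             scm_max = 1.5, scm_depth = 120, scm_sd = 20,
                             snm_max = 2000, snm_depth = 170, snm_sd = 45,
                             no2_background = 50,
                             no3_deep = 25000,
                             nh4_background = 100,
                             vmax_NO_max = 150, Km_NO = 100,
                             nob_depth = 145, nob_sd = 45,
                             vmax_het_surface = 2500, Km_het = 1800,
                             het_depth_scale = 80,
                             R_AO_surface = 50, ao_depth_scale = 80,
                             R_NAR_max = 100,
                             seed = 1L,
                             dt = 0.05,
                             duration = 24) {
  if (length(depths) < 1) abort("`depths` must have at least one entry")
  if (is.unsorted(depths, strictly = TRUE)) {
    abort("`depths` must be strictly increasing")
  }
  structure(as.list(environment()), class = "profile_template")
}

#' Simulate a station depth profile
#'
#' Evaluates a [profile_template()] on its depth grid and attaches a
#' per-depth [sim_config()] so bottles can be generated at any depth with
#' the local dissolved O2, nitrite and process rates.
#'
#' @param template a [profile_template()].
#' @return a tibble with columns `station`, `depth_m`, `DO_nM`, `NO2_nM`,
#'   `chl_mg_m3` and a `config` list-column.
#' @export
simulate_profile <- function(template = profile_template()) {
  if (!inherits(template, "profile_template")) {
    abort("`template` must be created by profile_template()")
  }
  tp <- template
  z <- tp$depths
  DO <- tp$DO_deep + (tp$DO_surface - tp$DO_deep) *
    plogis((tp$oxycline_depth - z) / tp$oxycline_width)
  gauss <- function(z, mu, sd) exp(-(z - mu)^2 / (2 * sd^2))
  chl <- tp$chl_max * gauss(z, tp$chl_depth, tp$chl_sd) +
    tp$scm_max * gauss(z, tp$scm_depth, tp$scm_sd)
  below_oxycline <- plogis((z - tp$oxycline_depth) / 5)
  NO2 <- tp$no2_background + tp$snm_max * gauss(z, tp$snm_depth, tp$snm_sd) *
    below_oxycline
  vmax_NO <- tp$vmax_NO_max * (0.05 + 0.95 * gauss(z, tp$nob_depth, tp$nob_sd))
  vmax_het <- tp$vmax_het_surface * exp(-z / tp$het_depth_scale) + 100
  R_AO <- tp$R_AO_surface * exp(-z / tp$ao_depth_scale) + 1
  R_NAR <- tp$R_NAR_max * plogis((2000 - DO) / 500) * below_oxycline
  cfgs <- purrr::map(seq_along(z), function(i) {
    sim_config(initial_O2 = DO[i],
               initial_NH4 = tp$nh4_background,
               initial_NO2 = NO2[i],
               initial_NO3 = tp$no3_deep,
               vmax_NO = vmax_NO[i], Km_NO = tp$Km_NO,
               vmax_het = vmax_het[i], Km_het = tp$Km_het,
               R_AO = R_AO[i],
               R_NAR = R_NAR[i],
               duration = tp$duration,
               dt = tp$dt,
               seed = mix_seed(tp$seed, i))
  })
  tibble(station = tp$station, depth_m = z, DO_nM = DO, NO2_nM = NO2,
         chl_mg_m3 = chl, config = cfgs)
}

#' Simulate dual nitrate-isotope Rayleigh evolution with reoxidation
#'
#' Evolves the delta-15N and delta-18O of a nitrate pool undergoing
#' respiratory reduction (Rayleigh: delta = delta0 - eps * ln f in the
#' residual pool), optionally overprinted by nitrite reoxidation: a fraction
#' of the reduced nitrogen re-enters the nitrate pool carrying the
#' accumulated-product delta-15N (its N atoms are returned unmodified) while
#' its O isotopes are reset to a water-derived end-member, decoupling the two
#' systems. With equal isotope effects and no reoxidation the trajectory
#' stays exactly on the 1:1 line; reoxidation with a water end-member lighter
#' than the accumulating residual drives Delta(15,18) negative.
#'
#' @param f_remaining fraction of the initial nitrate remaining (0 < f <= 1);
#'   vectorized.
#' @param eps15,eps18 isotope effects of nitrate reduction, permil.
#' @param reox_fraction fraction of the reduced N returned by nitrite
#'   reoxidation (0 <= r < 1).
#' @param delta0_15N,delta0_18O source-water nitrate composition, permil.
#' @param delta18O_water delta-18O of nitrate newly formed by nitrite
#'   oxidation (water-derived end-member), permil; default the source value.
#' @return a tibble: `f_remaining`, `delta15N`, `delta18O`.
#' @seealso [delta_15_18()] for the deviation statistic.
#' @export
#' @examples
#' simulate_dual_isotopes(c(1, 0.5, 0.2), eps15 = 25, eps18 = 25)
simulate_dual_isotopes <- function(f_remaining,
                                   eps15 = 25,
                                   eps18 = 25,
                                   reox_fraction = 0,
                                   delta0_15N = 6,
                                   delta0_18O = 2,
                                   delta18O_water = delta0_18O) {
  if (any(f_remaining <= 0 | f_remaining > 1)) {
    abort("`f_remaining` must satisfy 0 < f <= 1")
  }
  if (reox_fraction < 0 || reox_fraction >= 1) {
    abort("`reox_fraction` must lie in [0, 1)")
  }
  f <- f_remaining
  r <- reox_fraction
  d15_res <- delta0_15N - eps15 * log(f)
  d18_res <- delta0_18O - eps18 * log(f)
  # accumulated-product composition; -> delta0 - eps as f -> 1
  d15_prod <- ifelse(f < 1, delta0_15N + eps15 * f * log(f) / (1 - f),
                     delta0_15N - eps15)
  w_res <- f
  w_reox <- r * (1 - f)
  d15 <- (w_res * d15_res + w_reox * d15_prod) / (w_res + w_reox)
  d18 <- (w_res * d18_res + w_reox * delta18O_water) / (w_res + w_reox)
  d15[f == 1] <- delta0_15N
  d18[f == 1] <- delta0_18O
  tibble(f_remaining = f, delta15N = d15, delta18O = d18)
}
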