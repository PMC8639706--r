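#' Convert between delta-15N and atom percent
#'
#' Standard conversion through the isotope ratio: R = R_air * (1 +
#' delta/1000) and at% = 100 * R / (1 + R), with R_air = `R15_AIR`. The two
#' functions are exact inverses.
#'
#' @param delta15N delta-15N vs air N2, permil (> -1000).
#' @param atpct atom percent 15N (0-100).
#' @return atom percent, or permil.
#' @export
#' @examples
#' delta_to_atom_percent(0) # natural abundance, 0.3663 at%
#' atom_percent_to_delta(delta_to_atom_percent(12.5))
delta_to_atom_percent <- function(delta15N) {
  if (any(delta15N <= -1000)) abort("delta values must exceed -1000 permil")
  R <- R15_AIR * (1 + delta15N / 1000)
  100 * R / (1 + R)
}

#' @rdname delta_to_atom_percent
#' @export
atom_percent_to_delta <- function(atpct) {
  if (any(atpct < 0 | atpct >= 100)) abort("atom percent must lie in [0, 100)")
  R <- atpct / (100 - atpct)
  (R / R15_AIR - 1) * 1000
}

#' Atom percent of a pool after a tracer spike
#'
#' Concentration-weighted mean atom percent of an ambient pool mixed with a
#' tracer addition: the initial labelling n0 of the spiked pool.
#'
#' @param pool_conc ambient pool concentration, nM.
#' @param pool_atpct ambient atom percent; default natural abundance
#'   (0.3663 at%).
#' @param spike_conc tracer addition, nM.
#' @param spike_atpct tracer stock atom percent (98 for a typical 15N spike).
#' @return atom percent of the mixed pool.
#' @export
#' @examples
#' spike_atom_percent(100, spike_conc = 10) # 9.24 at%
spike_atom_percent <- function(pool_conc,
                               pool_atpct = nat_abundance_atpct(),
                               spike_conc = 0,
                               spike_atpct = 98) {
  if (any(pool_conc < 0 | spike_conc < 0)) {
    abort("concentrations must be >= 0")
  }
  total <- pool_conc + spike_conc
  if (any(total <= 0)) {
    abort("pool_conc + spike_conc must be > 0")
  }
  (pool_conc * pool_atpct + spike_conc * spike_atpct) / total
}

#' Exponential-average atom percent of a diluting nitrite pool
#'
#' During an incubation the labelled NO2- pool is continuously diluted by
#' unlabeled NO2- produced from ammonia oxidation. With the pool size held
#' constant by balanced production and consumption, the atom percent decays
#' as n(tau) = n0 * exp(-k tau) with dilution constant k = R_AO / [NO2-]
#' (day^-1), and the time-mean labelling that weights the tracer transfer is
#' n-bar = n0 * (1 - exp(-k t)) / (k t). A series expansion is used below
#' k t = 1e-6, giving the continuous limit n-bar -> n0 as dilution vanishes.
#'
#' @param n0 initial atom percent of the spiked NO2- pool.
#' @param R_AO ammonia oxidation rate, nmol L^-1 day^-1 (>= 0).
#' @param NO2_conc NO2- pool concentration, nM (> 0).
#' @param t incubation length, days (> 0).
#' @return time-mean atom percent over the incubation.
#' @export
#' @examples
#' exponential_average_atom_percent(10, R_AO = 0, NO2_conc = 200, t = 1)
exponential_average_atom_percent <- function(n0, R_AO, NO2_conc, t) {
  if (any(NO2_conc <= 0)) abort("`NO2_conc` must be > 0")
  if (any(t <= 0)) abort("`t` must be > 0")
  if (any(R_AO < 0)) abort("`R_AO` must be >= 0")
  kt <- R_AO / NO2_conc * t
  ifelse(kt < 1e-6,
         n0 * (1 - kt / 2 + kt^2 / 6),
         n0 * (1 - exp(-kt)) / kt)
}

#' Correct measured nitrate atom percent for 15NO3- spike contamination
#'
#' 15NO2- tracer stocks can carry a small 15NO3- impurity which inflates the
#' measured atom percent of the nitrate pool. Given the fraction of the
#' spike's 15N atoms present as NO3-, the impurity's contribution is removed
#' by mass balance on the NO3- pool. The corrected value is floored at the
#' unlabeled-nitrate baseline: contamination in excess of the measured
#' enrichment yields a zero excess (and a non-detectable rate downstream),
#' not a negative one.
#'
#' @param n_t_raw measured atom percent of the NO3- pool at time t.
#' @param NO3_conc nitrate pool concentration, nM.
#' @param spike_conc tracer addition, nM.
#' @param spike_atpct tracer stock atom percent.
#' @param contam_fraction fraction of spike 15N atoms present as NO3-
#'   (0 to 0.05).
#' @param n_oNO3 atom percent of unlabeled NO3- (the floor); default natural
#'   abundance.
#' @return corrected atom percent.
#' @export
correct_tracer_contamination <- function(n_t_raw,
                                         NO3_conc,
                                         spike_conc,
                                         spike_atpct = 98,
                                         contam_fraction = 0,
                                         n_oNO3 = nat_abundance_atpct()) {
  if (any(contam_fraction < 0 | contam_fraction > 0.05)) {
    abort("`contam_fraction` must lie in [0, 0.05]")
  }
  if (any(NO3_conc <= 0)) abort("`NO3_conc` must be > 0")
  contam_nM <- contam_fraction * spike_conc
  # measured pool includes the impurity: n_raw (NO3 + c) = n_true NO3 + c a_s
  corrected <- (n_t_raw * (NO3_conc + contam_nM) - contam_nM * spike_atpct) /
    NO3_conc
  pmax(corrected, n_oNO3)
}

# pull a time-in-days column out of a bottle table
.t_days <- function(data) {
  if ("t_days" %in% names(data)) {
    data$t_days
  } else if ("t_hours" %in% names(data)) {
    data$t_hours / 24
  } else {
    abort("need a `t_days` or `t_hours` column")
  }
}

.need_cols <- function(data, cols, where) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf("%s: missing required column(s): %s", where,
                  paste(missing, collapse = ", ")))
  }
}

#' Nitrite oxidation rates from 15NO2- tracer endpoints
#'
#' Inverts endpoint isotope measurements of 15NO2--labelled bottles into
#' nitrite oxidation rates: rate = (n_t - n_oNO3) * \[NO3-\] / (n-bar * t),
#' where n_t is the measured at% 15N of nitrate at the end of the incubation
#' (corrected for 15NO3- contamination of the spike), n_oNO3 the unlabeled
#' nitrate baseline, and n-bar the exponential-average at% of the NO2- pool
#' over the incubation (initial spike labelling diluted by unlabeled NO2-
#' from ammonia oxidation; see [exponential_average_atom_percent()]).
#'
#' Measurement noise on the two at% values is propagated to a first-order
#' standard error, and a bottle is flagged non-detectable when the at%
#' excess falls below `detect_mult` times the propagated noise of the
#' difference. Negative excesses are reported as rate 0 (tracer accumulation
#' cannot be negative) and non-detectable.
#'
#' @param data a data frame with one row per bottle and columns
#'   `atpct_NO3_final`, `atpct_NO3_initial`, `NO3_nM`, `no2_ambient_nM`,
#'   `spike_nM`, `spike_atpct`, a time column (`t_days` or `t_hours`), and
#'   optionally `R_AO` (measured ammonia oxidation rate, nmol L^-1 day^-1;
#'   0 when absent), `atpct_NO2_ambient` (natural abundance when absent)
#'   and `contam_fraction` (0 when absent).
#' @param atpct_sd at% measurement noise (1 sd); default from the 0.3 permil
#'   delta-15N precision.
#' @param detect_mult detectability threshold as a multiple of the
#'   propagated at% noise (default 3).
#' @param use_dilution set `FALSE` to replace n-bar by the initial labelling
#'   n0 (no isotope-dilution correction); with ammonia oxidation active this
#'   biases rates low and exists for sensitivity analysis.
#' @return the input tibble with columns `no2ox_rate` (nmol L^-1 day^-1),
#'   `no2ox_se`, `no2ox_detectable`, `no2ox_nbar` (at%), `no2ox_method`.
#' @export
nitrite_oxidation_rate <- function(data,
                                   atpct_sd = atpct_sd_from_permil(0.3),
                                   detect_mult = 3,
                                   use_dilution = TRUE) {
  .need_cols(data, c("atpct_NO3_final", "atpct_NO3_initial", "NO3_nM",
                     "no2_ambient_nM", "spike_nM", "spike_atpct"),
             "nitrite_oxidation_rate")
  if (any(data$NO3_nM <= 0)) abort("`NO3_nM` must be > 0")
  t_days <- .t_days(data)
  if (any(t_days <= 0)) abort("incubation time must be > 0")
  R_AO <- if ("R_AO" %in% names(data)) data$R_AO else 0
  amb_at <- if ("atpct_NO2_ambient" %in% names(data)) {
    data$atpct_NO2_ambient
  } else {
    nat_abundance_atpct()
  }
  contam <- if ("contam_fraction" %in% names(data)) data$contam_fraction else 0
  no2_pool <- data$no2_ambient_nM + data$spike_nM
  spike_frac <- data$spike_nM / pmax(data$no2_ambient_nM, 1e-12)
  if (any(data$spike_nM > 0 & (spike_frac < 0.05 | spike_frac > 0.10))) {
    warn("some spikes fall outside the 5-10% of ambient NO2- band")
  }
  n0 <- spike_atom_percent(data$no2_ambient_nM, amb_at,
                           data$spike_nM, data$spike_atpct)
  nbar <- if (use_dilution) {
    exponential_average_atom_percent(n0, R_AO, no2_pool, t_days)
  } else {
    n0
  }
  n_t <- correct_tracer_contamination(data$atpct_NO3_final, data$NO3_nM,
                                      data$spike_nM, data$spike_atpct,
                                      contam, n_oNO3 = data$atpct_NO3_initial)
  excess <- n_t - data$atpct_NO3_initial
  scale <- data$NO3_nM / (nbar * t_days)
  noise <- sqrt(2) * atpct_sd
  dplyr::mutate(as_tibble(data),
                no2ox_rate = pmax(excess, 0) * scale,
                no2ox_se = noise * scale,
                no2ox_detectable = excess >= detect_mult * noise,
                no2ox_nbar = nbar,
                no2ox_method = "15NO2_tracer")
}

#' Ammonia oxidation rates from 15NH4+ tracer endpoints
#'
#' Rate = (at%_prod,t - at%_prod,0) * \[NO2- + NO3-\] / (at%_NH4 * t): the
#' accumulation of 15N label in the combined product (NO2- + NO3-) pool,
#' normalized by the labelling of the NH4+ source pool after the spike.
#' Detectability follows the same contract as [nitrite_oxidation_rate()].
#'
#' @param data a data frame with one row per bottle and columns
#'   `atpct_prod_final`, `atpct_prod_initial`, `atpct_NH4_initial`, final
#'   product-pool concentrations (`NO2_nM_final`, `NO3_nM_final`) and a time
#'   column (`t_days` or `t_hours`).
#' @inheritParams nitrite_oxidation_rate
#' @return the input tibble with columns `nh3ox_rate`, `nh3ox_se`,
#'   `nh3ox_detectable`, `nh3ox_method`.
#' @export
ammonia_oxidation_rate <- function(data,
                                   atpct_sd = atpct_sd_from_permil(0.3),
                                   detect_mult = 3) {
  .need_cols(data, c("atpct_prod_final", "atpct_prod_initial",
                     "atpct_NH4_initial", "NO2_nM_final", "NO3_nM_final"),
             "ammonia_oxidation_rate")
  t_days <- .t_days(data)
  if (any(t_days <= 0)) abort("incubation time must be > 0")
  prod_pool <- data$NO2_nM_final + data$NO3_nM_final
  if (any(prod_pool <= 0)) abort("product pool (NO2- + NO3-) must be > 0")
  excess <- data$atpct_prod_final - data$atpct_prod_initial
  scale <- prod_pool / (data$atpct_NH4_initial * t_days)
  noise <- sqrt(2) * atpct_sd
  dplyr::mutate(as_tibble(data),
                nh3ox_rate = pmax(excess, 0) * scale,
                nh3ox_se = noise * scale,
                nh3ox_detectable = excess >= detect_mult * noise,
                nh3ox_method = "15NH4_tracer")
}

#' Correct a measured delta value for carrier addition
#'
#' Low-concentration nitrate samples are analyzed after adding carrier NO3-
#' of known isotopic composition; the sample composition follows by
#' two-member mass balance: delta_sample = (delta_measured * (sample +
#' carrier) - delta_carrier * carrier) / sample.
#'
#' @param delta_measured measured delta of the sample + carrier mixture,
#'   permil.
#' @param sample_conc sample NO3- concentration, nM (> 0).
#' @param carrier_conc carrier NO3- concentration, nM.
#' @param delta_carrier carrier composition, permil.
#' @return carrier-corrected sample delta, permil.
#' @export
#' @examples
#' carrier_correction(5, 100, 100, 4) # 6 permil
carrier_correction <- function(delta_measured, sample_conc, carrier_conc,
                               delta_carrier) {
  if (any(sample_conc <= 0)) abort("`sample_conc` must be > 0")
  if (any(carrier_conc < 0)) abort("`carrier_conc` must be >= 0")
  (delta_measured * (sample_conc + carrier_conc) -
     delta_carrier * carrier_conc) / sample_conc
}
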