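test_that("spike atom percent is a concentration-weighted mean", {
  expect_equal(spike_atom_percent(100, spike_conc = 0), nat_abundance_atpct())
  expect_equal(spike_atom_percent(100, 0.3663, 10, 98),
               (0.3663 * 100 + 98 * 10) / 110)
  expect_equal(spike_atom_percent(100, 0.3663, 10, 98), 9.243,
               tolerance = 1e-4)
  expect_equal(spike_atom_percent(50, 4, 50, 10), 7) # symmetry
  expect_error(spike_atom_percent(0, 5, 0, 98), "> 0")
})

test_that("exponential-average atom percent matches a numeric time integral", {
  # independent oracle: mean of n0 * exp(-k tau) over [0, t] by quadrature
  oracle <- function(n0, k, t) {
    integrate(function(tau) n0 * exp(-k * tau), 0, t)$value / t
  }
  expect_equal(exponential_average_atom_percent(10, 0, 200, 1), 10)
  k <- log(2)
  expect_equal(exponential_average_atom_percent(10, k * 200, 200, 1),
               oracle(10, k, 1), tolerance = 1e-9)
  expect_equal(exponential_average_atom_percent(10, k * 200, 200, 1),
               7.213475, tolerance = 1e-6)
  # kt -> infinity: fully diluted
  expect_lt(exponential_average_atom_percent(10, 1e6, 10, 10), 1e-4)
  # continuity across the series-expansion switch at kt = 1e-6: the two
  # branches may only differ by the O(kt^3) truncation, not a jump
  lo <- exponential_average_atom_percent(10, 0.99e-6 * 200, 200, 1)
  hi <- exponential_average_atom_percent(10, 1.01e-6 * 200, 200, 1)
  expect_lt(abs(lo - hi), 10 * 0.02e-6) # bounded by n0 * d(kt) / 2
  expect_error(exponential_average_atom_percent(10, 5, 0, 1), "NO2_conc")
})

test_that("tracer contamination correction removes the impurity excess", {
  expect_equal(correct_tracer_contamination(0.5, 20000, 10, 98, 0), 0.5)
  # excess removed ~ 98 * 0.01 * 10 / 20010 in at% units
  raw <- 0.5
  corr <- correct_tracer_contamination(raw, 20000, 10, 98, 0.01)
  expect_equal(raw - corr, 98 * 0.01 * 10 / 20010, tolerance = 0.01)
  # contamination equal to the whole measured excess floors at the baseline
  n_o <- nat_abundance_atpct()
  excess <- 98 * 0.01 * 10 / 20010
  floored <- correct_tracer_contamination(n_o + excess / 2, 20000, 10, 98,
                                          0.01, n_oNO3 = n_o)
  expect_equal(floored, n_o)
  expect_error(correct_tracer_contamination(0.5, 20000, 10, 98, 0.2),
               "contam_fraction")
})

test_that("Eq-style rate inversion reproduces a hand-computed value", {
  row <- tibble::tibble(
    atpct_NO3_final = nat_abundance_atpct() + 0.1,
    atpct_NO3_initial = nat_abundance_atpct(),
    NO3_nM = 20000, no2_ambient_nM = 200, atpct_NO2_ambient = 10,
    spike_nM = 0, spike_atpct = 98, t_days = 1)
  est <- nitrite_oxidation_rate(row)
  expect_equal(est$no2ox_rate, 0.1 * 20000 / (10 * 1), tolerance = 1e-9)
  expect_true(est$no2ox_detectable)
  # no label transfer -> zero rate, not detectable
  row0 <- dplyr::mutate(row, atpct_NO3_final = atpct_NO3_initial)
  est0 <- nitrite_oxidation_rate(row0)
  expect_equal(est0$no2ox_rate, 0)
  expect_false(est0$no2ox_detectable)
  # negative excess is clamped to zero, never negative
  rneg <- dplyr::mutate(row, atpct_NO3_final = atpct_NO3_initial - 0.001)
  expect_equal(nitrite_oxidation_rate(rneg)$no2ox_rate, 0)
})

test_that("rate estimate is monotone in each Eq-1 term", {
  base <- tibble::tibble(
    atpct_NO3_final = 0.5, atpct_NO3_initial = nat_abundance_atpct(),
    NO3_nM = 20000, no2_ambient_nM = 2000, spike_nM = 180,
    spike_atpct = 98, t_days = 1, R_AO = 20)
  r <- function(d) suppressWarnings(nitrite_oxidation_rate(d))$no2ox_rate
  expect_gt(r(dplyr::mutate(base, atpct_NO3_final = 0.6)), r(base))
  expect_gt(r(dplyr::mutate(base, NO3_nM = 30000)), r(base))
  expect_lt(r(dplyr::mutate(base, t_days = 2)), r(base))
  # larger R_AO -> smaller n-bar -> larger inferred rate
  expect_gt(r(dplyr::mutate(base, R_AO = 200)), r(base))
})

test_that("tracer inversion recovers a simulated constant rate within 5%", {
  base <- quiet_config(initial_O2 = 5e4, initial_NO2 = 2000,
                       initial_NO3 = 20000, vmax_NO = 100, Km_NO = 1e-6,
                       duration = 24, dt = 0.01)
  ex <- simulate_experiment(base, DO_levels = 5e4, treatments = "15NO2")
  est <- nitrite_oxidation_rate(ex)
  expect_lt(abs(est$no2ox_rate / 100 - 1), 0.05)
})

test_that("disabling the dilution term biases the estimate low", {
  # all nitrite supplied by (unlabeled) ammonia oxidation: constant pool,
  # dilution constant k = R_AO / [NO2] exactly as modeled
  base <- quiet_config(initial_O2 = 5e4, initial_NH4 = 500,
                       initial_NO2 = 2000, initial_NO3 = 20000, f15_NH4 = 0,
                       R_AO = 100, vmax_NO = 100, Km_NO = 1e-6,
                       duration = 24, dt = 0.01)
  ex <- simulate_experiment(base, DO_levels = 5e4, treatments = "15NO2")
  ex$R_AO <- 100
  with_dilution <- nitrite_oxidation_rate(ex)$no2ox_rate
  without <- nitrite_oxidation_rate(ex, use_dilution = FALSE)$no2ox_rate
  expect_lt(abs(with_dilution / 100 - 1), 0.05)
  expect_lt(without, with_dilution)
  expect_lt(without, 100)
})

test_that("ammonia oxidation rate reproduces hand and simulated values", {
  row <- tibble::tibble(
    atpct_prod_final = 1.05, atpct_prod_initial = 1.00,
    atpct_NH4_initial = 20, NO2_nM_final = 4000, NO3_nM_final = 6000,
    t_days = 1)
  expect_equal(ammonia_oxidation_rate(row)$nh3ox_rate, 25)
  row0 <- dplyr::mutate(row, atpct_prod_final = atpct_prod_initial)
  expect_equal(ammonia_oxidation_rate(row0)$nh3ox_rate, 0)
  # simulator oracle: true R_AO = 50, no noise
  base <- quiet_config(initial_O2 = 5e4, initial_NH4 = 100, R_AO = 50,
                       duration = 24, dt = 0.01)
  ex <- simulate_experiment(base, DO_levels = 5e4, treatments = "15NH4")
  est <- ammonia_oxidation_rate(ex)
  expect_lt(abs(est$nh3ox_rate / 50 - 1), 0.05)
})

test_that("carrier correction inverts forward mixing", {
  expect_equal(carrier_correction(5, 100, 100, 4), 6)
  expect_equal(carrier_correction(5, 123, 0, 99), 5)
  expect_equal(carrier_correction(7, 50, 200, 7), 7) # degenerate mixing
  set.seed(9)
  for (i in 1:20) {
    ds <- runif(1, -5, 25); dc <- runif(1, -5, 25)
    cs <- runif(1, 10, 500); cc <- runif(1, 0, 500)
    mixed <- (ds * cs + dc * cc) / (cs + cc)
    expect_equal(carrier_correction(mixed, cs, cc, dc), ds,
                 tolerance = 1e-9)
  }
  expect_error(carrier_correction(5, 0, 10, 4), "sample_conc")
})

test_that("delta and atom percent convert exactly and round-trip", {
  expect_equal(delta_to_atom_percent(0), 0.36630, tolerance = 1e-5)
  # at% = 50 -> R = 1 -> delta = (1/R_air - 1) * 1000
  expect_equal(atom_percent_to_delta(50), (1 / R15_AIR - 1) * 1000)
  d <- c(-40, 0, 5, 300, 5000)
  expect_equal(atom_percent_to_delta(delta_to_atom_percent(d)), d,
               tolerance = 1e-10)
})
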