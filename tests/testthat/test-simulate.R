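test_that("null dynamics leave every state constant", {
  s <- simulate_bottle(quiet_config(dt = 0.5))
  for (col in c("O2", "NH4", "NO2", "NO3", "f15_NH4", "f15_NO2", "f15_NO3")) {
    expect_equal(s[[col]], rep(s[[col]][1], nrow(s)), tolerance = 1e-12)
  }
})

test_that("zero-order nitrite oxidation consumes half a mole of O2 per mole N", {
  s <- simulate_bottle(quiet_config(initial_O2 = 1000, vmax_NO = 100,
                                    Km_NO = 1e-6, duration = 24))
  expect_equal(tail(s$NO3, 1) - s$NO3[1], 100, tolerance = 1e-6)
  expect_equal(tail(s$NO2, 1) - s$NO2[1], -100, tolerance = 1e-6)
  expect_equal(tail(s$O2, 1) - s$O2[1], -50, tolerance = 1e-6)
})

test_that("label dilution by unlabeled nitrite production follows exp(-kt)", {
  # constant NO2 pool: production (R_AO, truly label-free NH4) balances
  # consumption (R_NO = R_AO); k = R_AO / [NO2] = ln 2 per day
  no2 <- 100 / log(2)
  cfg <- quiet_config(initial_O2 = 5e4, initial_NH4 = 1000,
                      initial_NO2 = no2, f15_NH4 = 0, f15_NO2 = 0.1,
                      f15_NO3 = 0, R_AO = 100, vmax_NO = 100, Km_NO = 1e-6,
                      duration = 24, dt = 0.005)
  s <- simulate_bottle(cfg)
  expect_equal(tail(s$NO2, 1), no2, tolerance = 1e-4)
  expect_equal(tail(s$f15_NO2, 1), 0.1 * exp(-log(2)), tolerance = 1e-4)
})

test_that("N mass, 15N atoms and the O2 budget close on random scenarios", {
  set.seed(42)
  for (i in 1:8) {
    cfg <- quiet_config(
      initial_O2 = runif(1, 200, 20000),
      initial_NH4 = runif(1, 50, 500),
      initial_NO2 = runif(1, 500, 3000),
      initial_NO3 = runif(1, 5000, 25000),
      f15_NH4 = runif(1, 0, 0.5), f15_NO2 = runif(1, 0, 0.5),
      f15_NO3 = runif(1, 0, 0.02),
      R_AO = runif(1, 0, 50), vmax_NO = runif(1, 0, 200),
      Km_NO = runif(1, 50, 2000), vmax_het = runif(1, 0, 2000),
      Km_het = runif(1, 200, 3000), R_NAR = runif(1, 0, 100),
      O2_production = runif(1, 0, 100),
      duration = 24, dt = 0.02)
    s <- simulate_bottle(cfg)
    tot <- series_totals(s)
    expect_lt(max(abs(tot$N / tot$N[1] - 1)), 1e-6)
    if (tot$N15[1] > 0) {
      expect_lt(max(abs(tot$N15 / tot$N15[1] - 1)), 1e-6)
    }
    # O2 closure: net change equals the signed budget terms
    bud <- o2_budget(s)
    net <- tail(s$O2, 1) - s$O2[1]
    scale <- max(1, sum(abs(bud$o2_nmol_per_l)))
    expect_lt(abs(net - sum(bud$o2_nmol_per_l)) / scale, 1e-6)
    expect_true(all(s$O2 >= 0))
  }
})

test_that("halving dt changes endpoint states by less than 0.1%", {
  base <- list(initial_O2 = 500, vmax_NO = 100, Km_NO = 100,
               vmax_het = 800, Km_het = 1800, R_AO = 20, R_NAR = 30,
               duration = 24)
  s1 <- simulate_bottle(do.call(quiet_config, c(base, dt = 0.01)))
  s2 <- simulate_bottle(do.call(quiet_config, c(base, dt = 0.005)))
  for (col in c("O2", "NH4", "NO2", "NO3")) {
    a <- tail(s1[[col]], 1); b <- tail(s2[[col]], 1)
    expect_lt(abs(a - b) / max(abs(b), 1), 1e-3)
  }
})

test_that("first-order regime matches the exponential closed form", {
  # Km_NO >> O2: R_NO ~ (vmax/Km) O2, so O2 decays exponentially with
  # k = 0.5 * vmax / Km (half a mole of O2 per mole N)
  cfg <- quiet_config(initial_O2 = 500, initial_NO2 = 1e5, vmax_NO = 2000,
                      Km_NO = 1e6, duration = 24, dt = 0.005)
  s <- simulate_bottle(cfg)
  k <- 0.5 * 2000 / 1e6
  expected <- 500 * exp(-k * s$time_h / 24)
  expect_lt(max(abs(s$O2 - expected) / expected), 0.005)
})

test_that("stepped integration agrees with an independent ODE solver", {
  skip_if_not_installed("deSolve")
  cfg <- quiet_config(initial_O2 = 800, initial_NH4 = 300, R_AO = 40,
                      vmax_NO = 120, Km_NO = 150, vmax_het = 900,
                      Km_het = 1500, R_NAR = 50, f15_NO2 = 0.08,
                      duration = 24, dt = 0.01)
  s <- simulate_bottle(cfg)
  rhs <- function(t, y, p) {
    list(nitroxr:::bottle_fluxes(y, cfg)$dy / 24) # per hour
  }
  y0 <- c(cfg$initial_O2, cfg$initial_NH4, cfg$initial_NO2, cfg$initial_NO3,
          cfg$f15_NH4 * cfg$initial_NH4, cfg$f15_NO2 * cfg$initial_NO2,
          cfg$f15_NO3 * cfg$initial_NO3)
  ref <- deSolve::lsoda(y0, c(0, 24), rhs, NULL, rtol = 1e-10, atol = 1e-10)
  end <- c(tail(s$O2, 1), tail(s$NH4, 1), tail(s$NO2, 1), tail(s$NO3, 1))
  expect_equal(end, unname(ref[2, 2:5]), tolerance = 1e-4)
})

test_that("observation is the identity when noise and the limit are off", {
  s <- simulate_bottle(quiet_config(initial_O2 = 700, vmax_het = 300,
                                    Km_het = 500, dt = 0.1))
  o <- observe_bottle(s)
  expect_equal(o$DO_nM_initial, s$O2[1])
  expect_equal(o$DO_nM_final, tail(s$O2, 1))
  expect_false(any(o$do_series[[1]]$censored))
  expect_equal(o$atpct_NO3_final, 100 * tail(s$f15_NO3, 1))
})

test_that("DO below the detection limit is censored at the limit", {
  s <- simulate_bottle(sim_config(initial_O2 = 4, sensor_sd = 0,
                                  sensor_detection_limit = 10, dt = 0.5))
  o <- observe_bottle(s)
  expect_true(all(o$do_series[[1]]$DO_nM == 10))
  expect_true(all(o$do_series[[1]]$censored))
})

test_that("observation is deterministic under a fixed seed", {
  s <- simulate_bottle(sim_config(initial_O2 = 500, vmax_het = 300,
                                  Km_het = 500, sensor_sd = 3, seed = 11,
                                  dt = 0.1))
  expect_identical(observe_bottle(s), observe_bottle(s))
})

test_that("experiment design yields one bottle per DO level and treatment", {
  base <- quiet_config(dt = 0.5, duration = 2)
  ex <- simulate_experiment(base, DO_levels = c(10, 50, 100, 250, 500, 1000,
                                                5000, 20000))
  expect_equal(nrow(ex), 24) # 8 levels x 3 treatments
  expect_equal(sum(ex$treatment == "15NO2"), 8)
  one <- simulate_experiment(base, DO_levels = 500, treatments = "unlabeled")
  expect_equal(nrow(one), 1)
  expect_error(simulate_experiment(base, DO_levels = numeric(0)), "empty")
  ex2 <- simulate_experiment(base, DO_levels = c(10, 50, 100, 250, 500, 1000,
                                                 5000, 20000))
  expect_identical(ex$DO_nM_final, ex2$DO_nM_final)
})

test_that("tracer spikes shift pool size and atom fraction consistently", {
  base <- quiet_config(initial_NO2 = 2000, dt = 0.5, duration = 2)
  ex <- simulate_experiment(base, DO_levels = 500, treatments = "15NO2",
                            spike_fraction = 0.1)
  cfg <- ex$config[[1]]
  expect_equal(cfg$initial_NO2, 2200)
  expect_equal(100 * cfg$f15_NO2,
               spike_atom_percent(2000, nat_abundance_atpct(), 200, 98),
               tolerance = 1e-10)
})

test_that("profile template shapes the expected AMZ structure", {
  prof <- simulate_profile(profile_template())
  expect_gt(max(prof$NO2_nM[prof$depth_m > 60]), 1000) # SNM criterion
  expect_lt(min(prof$DO_nM), 20000) # OMZ by definition
  no_snm <- simulate_profile(profile_template(snm_max = 0, no2_background = 0))
  expect_true(all(no_snm$NO2_nM == 0))
  single <- simulate_profile(profile_template(depths = 100))
  expect_equal(nrow(single), 1)
  expect_error(profile_template(depths = c(100, 50)), "increasing")
})

test_that("equal-effect Rayleigh evolution stays on the 1:1 line", {
  tr <- simulate_dual_isotopes(seq(1, 0.05, by = -0.05), eps15 = 25,
                               eps18 = 25, reox_fraction = 0)
  expect_lt(max(abs((tr$delta15N - 6) - (tr$delta18O - 2))), 1e-9)
  at1 <- simulate_dual_isotopes(1, eps15 = 25, eps18 = 25)
  expect_equal(c(at1$delta15N, at1$delta18O), c(6, 2))
  expect_error(simulate_dual_isotopes(0), "f_remaining")
})

test_that("reoxidation overprinting drives Delta(15,18) negative", {
  f <- seq(0.95, 0.3, by = -0.05)
  tr <- simulate_dual_isotopes(f, eps15 = 25, eps18 = 25,
                               reox_fraction = 0.3)
  delta <- (tr$delta15N - 6) - (tr$delta18O - 2)
  expect_true(all(delta < 0))
  # more reoxidation, larger departure
  tr2 <- simulate_dual_isotopes(f, eps15 = 25, eps18 = 25,
                                reox_fraction = 0.5)
  delta2 <- (tr2$delta15N - 6) - (tr2$delta18O - 2)
  expect_true(all(delta2 < delta))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(initial_O2 = -1), ">= 0")
  expect_error(sim_config(f15_NO2 = 1.5), "atom fractions")
  expect_error(sim_config(dt = 0), "dt")
  expect_error(sim_config(Km_NO = 0), "Km")
})
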