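test_that("stoichiometric O2 demand factors are applied", {
  expect_equal(o2_demand_nitrite(100), 50)
  expect_equal(o2_demand_nitrite(0), 0)
  expect_equal(o2_demand_nitrite(71.2), 35.6)
  expect_equal(o2_demand_ammonia(100), 150)
  expect_error(o2_demand_nitrite(-5), ">= 0")
})

test_that("percent contribution follows the half-mole conversion", {
  expect_equal(percent_contribution(200, 1000), 10)
  expect_equal(percent_contribution(2 * 1000, 1000), 100)
  expect_equal(percent_contribution(400, 1380), 14.49, tolerance = 1e-3)
  expect_message(p <- percent_contribution(100, 0), "OCR <= 0")
  expect_true(is.na(p))
  # invariant under joint unit rescaling
  expect_equal(percent_contribution(400 * 3, 1380 * 3),
               percent_contribution(400, 1380))
})

test_that("simulated O2 drawdown closes against the per-process demands", {
  cfg <- quiet_config(initial_O2 = 2000, initial_NH4 = 300, R_AO = 40,
                      vmax_NO = 120, Km_NO = 100, vmax_het = 600,
                      Km_het = 1500, duration = 24, dt = 0.01)
  s <- simulate_bottle(cfg)
  bud <- attr(s, "budget")
  drawdown <- s$O2[1] - tail(s$O2, 1)
  expect_equal(drawdown,
               o2_demand_nitrite(bud[["no2_oxidation"]]) +
                 o2_demand_ammonia(bud[["nh3_oxidation"]]) +
                 bud[["heterotrophy"]],
               tolerance = 1e-6)
})

test_that("partition table filters on OCR and the DO ceiling", {
  d <- tibble::tibble(mean_DO_nM = c(100, 500, 3000, 25000, 800),
                      OCR = c(400, 600, 900, 1200, -5),
                      no2ox_rate = c(100, 90, 60, 50, 40))
  suppressMessages(tbl <- partition_table(d))
  expect_equal(nrow(tbl), 3) # drops DO > 18000 and OCR <= 0
  expect_equal(tbl$pct_NO2ox[1], 100 * 0.5 * 100 / 400)
  suppressMessages(tbl2 <- partition_table(d, do_ceiling = 2000))
  expect_lt(nrow(tbl2), nrow(tbl))
})

test_that("noiseless power laws are recovered exactly", {
  DO <- c(100, 300, 900, 2700, 8100, 16000)
  d <- data.frame(mean_DO_nM = DO, pct_NO2ox = 50 * DO^(-0.5))
  fit <- suppressWarnings(fit_power_law(d))
  expect_equal(fit$a, 50, tolerance = 1e-9)
  expect_equal(fit$b, -0.5, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  # constant percentage: zero exponent, no significance
  dc <- data.frame(mean_DO_nM = DO, pct_NO2ox = rep(12, 6))
  fc <- suppressWarnings(fit_power_law(dc))
  expect_equal(fc$b, 0, tolerance = 1e-12)
  expect_false(isTRUE(fc$p < 0.05))
  expect_error(fit_power_law(d[1:3, ]), "at least 5")
})

test_that("log-normal scatter leaves the fitted law within 2 se", {
  DO <- c(100, 250, 600, 1500, 4000, 10000)
  b_true <- -0.7; a_true <- 100 / 393^b_true
  ests <- sapply(1:200, function(s) {
    set.seed(s)
    pct <- a_true * DO^b_true * 10^rnorm(6, 0, 0.2)
    fit <- fit_power_law(data.frame(mean_DO_nM = DO, pct_NO2ox = pct))
    c(fit$b, tidy(fit)$std.error[2])
  })
  expect_lt(abs(median(ests[1, ]) - b_true), 2 * median(ests[2, ]))
})

test_that("threshold DO inverts the power law", {
  DO <- c(100, 300, 900, 2700, 8100)
  f1 <- suppressWarnings(
    fit_power_law(data.frame(mean_DO_nM = DO, pct_NO2ox = 100 / DO)))
  expect_equal(f1$a, 100, tolerance = 1e-9)
  expect_equal(threshold_do(f1), 1, tolerance = 1e-9)
  expect_equal(threshold_do(f1, target_pct = 50), 2, tolerance = 1e-9)
  # constructed inverse problem: pct = 100 exactly at DO = 393 nM
  b <- -0.76; a <- 100 / 393^b
  d <- data.frame(mean_DO_nM = c(100, 250, 600, 1500, 4000, 10000))
  d$pct_NO2ox <- a * d$mean_DO_nM^b
  f2 <- suppressWarnings(fit_power_law(d))
  expect_equal(threshold_do(f2), 393, tolerance = 1e-6)
  # rising-share direction required for a threshold reading
  f_up <- suppressWarnings(
    fit_power_law(data.frame(mean_DO_nM = DO, pct_NO2ox = 0.01 * DO)))
  expect_warning(threshold_do(f_up), "b > 0")
})

test_that("nitrite oxidation's share grows as DO falls when its affinity is higher", {
  # Km_NO << Km_het: heterotrophy decays faster with DO
  DO <- 10^seq(1, 4.2, length.out = 25)
  R_NO <- 150 * DO / (100 + DO)
  R_het <- 2500 * DO / (1800 + DO)
  pct <- 100 * 0.5 * R_NO / (0.5 * R_NO + R_het)
  expect_true(all(diff(pct) < 0)) # non-increasing in DO
})
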