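test_that("endpoint OCR is the per-day DO decline", {
  expect_equal(ocr_endpoint(500, 300, 24), 200)
  expect_equal(ocr_endpoint(450, 450, 10), 0)
  expect_equal(ocr_endpoint(480, 230, 19), 250 / 19 * 24, tolerance = 1e-12)
  expect_equal(ocr_endpoint(480, 230, 19), 315.8, tolerance = 1e-3)
  expect_error(ocr_endpoint(500, 300, 0), "elapsed")
})

test_that("regression OCR equals endpoint OCR on exactly linear data", {
  t <- seq(0, 24, by = 2)
  s <- tibble::tibble(t_hours = t, DO_nM = 900 - 10 * t)
  est <- suppressWarnings(ocr_regression(s))
  expect_equal(est$rate, 240, tolerance = 1e-9)
  expect_equal(est$rate, ocr_endpoint(900, 900 - 240, 24),
               tolerance = 1e-9)
  expect_equal(est$r2, 1, tolerance = 1e-12)
  expect_equal(est$classification, "linear")
})

test_that("degenerate and sparse series are handled explicitly", {
  flat <- tibble::tibble(t_hours = 0:9, DO_nM = rep(400, 10))
  est <- suppressWarnings(ocr_regression(flat))
  expect_equal(est$rate, 0)
  expect_equal(est$r2, 0)
  sparse <- tibble::tibble(t_hours = c(0, 10, 20), DO_nM = c(500, 400, 310),
                           censored = c(FALSE, TRUE, FALSE))
  expect_message(est2 <- ocr_regression(sparse), "endpoint")
  expect_equal(est2$method, "endpoint")
  expect_equal(est2$rate, (500 - 310) / 20 * 24)
  mostly_censored <- tibble::tibble(t_hours = 0:9, DO_nM = c(30, 20, rep(10, 8)),
                                    censored = c(FALSE, FALSE, rep(TRUE, 8)))
  expect_message(est3 <- ocr_regression(mostly_censored), "indeterminate")
  expect_true(is.na(est3$rate))
})

test_that("regression slope sits within 2 se of the generating slope", {
  set.seed(31)
  hits <- 0
  for (i in 1:40) {
    t <- seq(0, 24, length.out = 13)
    s <- tibble::tibble(t_hours = t, DO_nM = 800 - 8 * t + rnorm(13, 0, 5))
    est <- ocr_regression(s)
    if (abs(est$rate - 192) <= 2 * est$se) hits <- hits + 1
  }
  expect_gte(hits / 40, 0.85) # ~95% nominal coverage
})

test_that("replicate aggregation gives the sample mean and SD", {
  agg <- replicate_ocr(data.frame(rate = c(100, 200, 300, 400, 500)))
  expect_equal(agg$mean_rate, 300)
  expect_equal(agg$sd_rate, sqrt(25000))
  expect_equal(agg$sd_rate, 158.11, tolerance = 1e-4)
  expect_false(agg$n_lt_5)
  same <- replicate_ocr(data.frame(rate = rep(250, 5)))
  expect_equal(same$sd_rate, 0)
  two <- replicate_ocr(data.frame(rate = c(100, 200)))
  expect_true(two$n_lt_5)
  expect_error(replicate_ocr(data.frame(rate = 100)), "at least 2")
})

test_that("MIC is 1 on noiseless functional data and 0 on constant data", {
  x <- seq(0, 1, length.out = 20)
  expect_equal(mic(x, 3 * x - 2), 1)
  expect_equal(mic(x, rep(1, 20)), 0)
  expect_equal(mic(rep(2, 20), x), 0)
  # noiseless parabola on a symmetric range: high MIC, negligible r2
  y <- (x - 0.5)^2
  expect_gte(mic(x, y), 0.9)
  expect_lte(summary(lm(y ~ x))$r.squared, 0.1)
  expect_error(mic(x[1:5], x[1:5]), "at least 8")
})

test_that("MIC equals the brute-force grid-search oracle", {
  set.seed(17)
  cases <- list(
    list(x = seq(0, 1, length.out = 12), y = rnorm(12)),
    list(x = rnorm(16), y = rnorm(16)),
    list(x = seq(0, 1, length.out = 20),
         y = sin(4 * seq(0, 1, length.out = 20)) + rnorm(20, 0, 0.1)),
    list(x = rnorm(14), y = NULL))
  cases[[4]]$y <- cases[[4]]$x^2 + rnorm(14, 0, 0.05)
  for (cs in cases) {
    expect_equal(mic(cs$x, cs$y), mic_oracle(cs$x, cs$y), tolerance = 1e-12)
  }
})

test_that("MIC is symmetric and invariant under monotone transforms", {
  set.seed(23)
  x <- runif(20, 1, 5)
  y <- 2 * x + rnorm(20, 0, 0.5)
  expect_equal(mic(x, y), mic(y, x), tolerance = 1e-12)
  expect_lt(abs(mic(x, y) - mic(exp(x), y)), 0.05)
  expect_lt(abs(mic(x, y) - mic(x, log(y - min(y) + 1))), 0.05)
})

test_that("linearity screen separates constant-rate and MM-depletion bottles", {
  # noiseless line
  t <- seq(0, 24, length.out = 13)
  lin <- tibble::tibble(t_hours = t, DO_nM = 5000 - 20 * t)
  expect_equal(
    suppressWarnings(linearity_classification(lin))$classification, "linear")
  # MM depletion from 235 nM through Km = 100 nM: OCR declines over time
  cfg <- quiet_config(initial_O2 = 235, vmax_het = 1500, Km_het = 100,
                      duration = 24, dt = 0.02)
  s <- simulate_bottle(cfg)
  curve <- tibble::tibble(t_hours = t,
                          DO_nM = approx(s$time_h, s$O2, t)$y)
  cls <- linearity_classification(curve)
  expect_equal(cls$classification, "nonlinear")
  expect_gt(cls$mic - cls$r2, 0.2)
  # pure noise never classifies linear
  set.seed(5)
  noise <- tibble::tibble(t_hours = t, DO_nM = rnorm(13, 500, 50))
  expect_true(linearity_classification(noise)$classification != "linear")
  # too few points
  short <- tibble::tibble(t_hours = 0:5, DO_nM = 100 - (0:5))
  expect_equal(linearity_classification(short)$classification, "unclassified")
})

test_that("screen is 100% correct on noisy simulator bottles across seeds", {
  study <- linearity_screen_study(n_seeds = 50, sensor_sd = 2)
  expect_equal(mean(study$correct), 1)
})
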