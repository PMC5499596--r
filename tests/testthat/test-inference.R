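# Rate-constant and half-life estimation, yield quantitation, rate ratios.

test_that("noiseless round trip recovers the generating rate constant exactly", {
  times <- seq(0, 120, 5)
  for (k in c(1e-4, 1e-3, 1e-2, 5.6e-2, 0.3, 1)) {
    tc <- gen_ligation_timecourse(k, 0, 1, times, noise_spec(sd = 0))
    fit <- suppressWarnings(fit_first_order(tc))
    expect_equal(fit$k_app, k, tolerance = 1e-10)
    expect_equal(fit$half_life * fit$k_app, log(2), tolerance = 1e-12)
  }
})

test_that("the default window is the initial-velocity regime and is harmless on true first-order data", {
  times <- seq(0, 120, 5)
  tc <- gen_ligation_timecourse(5.6e-2, 0, 1, times, noise_spec(sd = 0))
  fit_win <- suppressWarnings(fit_first_order(tc))
  fit_full <- suppressWarnings(fit_first_order(tc, window = c(0, 120)))
  # window excludes the late points (product > 0.5) ...
  expect_lt(fit_win$n_points_used, fit_full$n_points_used)
  expect_true(all(tc$frac_product[tc$time_min <= fit_win$window[2]] <= 0.5))
  # ... but on true first-order data the estimate is unchanged
  expect_equal(fit_win$k_app, fit_full$k_app, tolerance = 1e-9)
})

test_that("the initial-velocity window protects the estimate from a sub-unity plateau", {
  times <- seq(0, 120, 5)
  # plateau at 75%: full-course log-linear fit is biased low, windowed is not
  tc <- gen_ligation_timecourse(5.6e-2, 1.43e-3, 0.75, times, noise_spec(sd = 0))
  fit_win <- suppressWarnings(fit_first_order(tc))
  fit_full <- suppressWarnings(fit_first_order(tc, window = c(0, 120)))
  expect_lt(abs(fit_win$k_app - 5.6e-2) / 5.6e-2, abs(fit_full$k_app - 5.6e-2) / 5.6e-2)
})

test_that("degenerate courses are handled: constant, non-positive, too short", {
  flat <- timecourse(seq(0, 60, 10), frac_amino_remaining = rep(1, 7),
                     frac_product = rep(0, 7))
  fit <- fit_first_order(flat)
  expect_identical(fit$k_app, 0)
  expect_true(fit$zero_rate)
  expect_identical(fit$half_life, Inf)
  withzero <- data.frame(time_min = c(0, 10, 20, 30),
                         frac_amino_remaining = c(1, 0.5, 0.25, 0))
  expect_warning(f2 <- fit_first_order(withzero), "C/C0 <= 0")
  expect_equal(f2$n_points_used, 3)
  expect_error(suppressWarnings(fit_first_order(
    data.frame(time_min = c(0, 10), frac_amino_remaining = c(1, 0.5)))),
    "fewer than 3")
})

test_that("free-intercept variant is available and agrees on origin-true data", {
  tc <- gen_ligation_timecourse(2e-2, 0, 1, seq(0, 120, 10), noise_spec(sd = 0))
  f0 <- suppressWarnings(fit_first_order(tc))
  f1 <- suppressWarnings(fit_first_order(tc, free_intercept = TRUE))
  expect_equal(f0$k_app, f1$k_app, tolerance = 1e-9)
})

test_that("half-life estimation round-trips and flags non-decay", {
  # two ideal points determine the half-life exactly
  two <- timecourse(c(0, 486), frac_ept_active = c(1, 0.5))
  expect_equal(fit_half_life(two)$half_life, 486, tolerance = 1e-12)
  # noiseless generator round trip, in minutes and hours
  tc <- gen_decay_timecourse(486, seq(0, 1944, 162), noise_spec(sd = 0))
  fit <- suppressWarnings(fit_half_life(tc))
  expect_equal(fit$half_life, 486, tolerance = 1e-10)
  expect_equal(fit$half_life_h, 8.1, tolerance = 1e-10)
  # non-decaying input
  const <- timecourse(seq(0, 600, 100), frac_ept_active = rep(1, 7))
  expect_identical(fit_half_life(const)$half_life, Inf)
})

test_that("median rate recovery is within 5% at gel-level noise", {
  set.seed(2718)
  ks <- replicate(200, {
    tc <- gen_ligation_timecourse(1e-2, 0, 1, seq(0, 120, 20), noise_spec(sd = 0.02))
    suppressWarnings(fit_first_order(tc))$k_app
  })
  expect_lt(abs(median(ks) - 1e-2) / 1e-2, 0.05)
})

test_that("median bias is under 2% at small noise", {
  set.seed(314)
  ks <- replicate(200, {
    tc <- gen_ligation_timecourse(1e-2, 0, 1, seq(0, 120, 20), noise_spec(sd = 0.01))
    suppressWarnings(fit_first_order(tc))$k_app
  })
  expect_lt(abs(median(ks) - 1e-2) / 1e-2, 0.02)
})

test_that("yield quantitation follows the intensity ratio and its error model", {
  expect_equal(yield_from_intensities(0.25, 0.75), 0.75)
  expect_identical(yield_from_intensities(3.2, 0), 0)
  expect_error(yield_from_intensities(0, 0), "undefined")
  expect_error(yield_from_intensities(-1, 2), "non-negative")
  set.seed(53)
  tab <- gen_gel_table(rep(0.53, 100), 1000,
                       noise_spec("multiplicative_gaussian", sd = 0.02))
  y <- yield_from_intensities(tab$i_remaining, tab$i_product)
  expect_lt(abs(mean(y) - 0.53), 0.01)
})

test_that("rate ratios reproduce the printed 3.6 and are reciprocal-symmetric", {
  times <- seq(0, 120, 5)
  fits <- lapply(c(5.0e-2, 1.4e-2), function(k) {
    suppressWarnings(fit_first_order(
      gen_ligation_timecourse(k, 0, 1, times, noise_spec(sd = 0))))
  })
  tab <- compare_rates(fits, c("NH2_5p_RNA_pH8", "NH2_3p_RNA_pH8"))
  r <- tab$ratio[tab$numerator == "NH2_5p_RNA_pH8"]
  expect_equal(signif(r, 2), 3.6)
  expect_equal(tab$ratio[1] * tab$ratio[2], 1, tolerance = 1e-12)
  # identical fits give unity; zero-rate denominators are flagged
  same <- compare_rates(fits[c(1, 1)])
  expect_equal(same$ratio, c(1, 1))
  flat <- fit_first_order(timecourse(seq(0, 60, 10),
                                     frac_amino_remaining = rep(1, 7),
                                     frac_product = rep(0, 7)))
  mixed <- compare_rates(list(fits[[1]], flat), c("live", "flat"))
  expect_true(mixed$undefined[mixed$denominator == "flat"])
})

test_that("fit objects expose the standard modelling methods", {
  tc <- gen_ligation_timecourse(3e-2, 0, 1, seq(0, 120, 10), noise_spec(sd = 0))
  fit <- suppressWarnings(fit_first_order(tc))
  expect_named(coef(fit), "k_app")
  expect_equal(predict(fit, c(0, 10)), exp(-fit$k_app * c(0, 10)))
  expect_lt(max(abs(residuals(fit))), 1e-10)
  expect_output(print(fit), "k_app")
  s <- summary(fit)
  expect_equal(s$k_paper_units, 3.0)
  expect_output(print(s), "half-life")
  sims <- simulate(fit, nsim = 2, seed = 5, noise_sd = 0.02)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "timecourse")
})
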