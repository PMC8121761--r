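test_that("perturbation multiplies by uniform errors within the stated range", {
  expect_equal(perturb(10, c(1, 1), n = 5), rep(10, 5))
  expect_equal(perturb(0, c(0.75, 1.25), n = 10), rep(0, 10))
  set.seed(6)
  v <- perturb(10, c(0.75, 1.25), n = 500)
  expect_true(all(v >= 7.5 & v <= 12.5))
  expect_error(perturb(1, c(-0.1, 1)))
})

test_that("a noiseless linear series collapses the corridor onto the line", {
  series <- data.frame(timestep = 1:60, value = 2 + 0.5 * (1:60))
  cor <- fit_corridor(series, span = 0.5, degree = 1)
  expect_lt(max(cor$upper - cor$lower), 1e-6)
  expect_equal(cor$fit, series$value, tolerance = 1e-8)
  expect_true(all(cor$lower <= cor$upper))
  expect_error(fit_corridor(series[1:5, ]), "10 points")
})

test_that("iid noise around a constant yields a band near +/-1.96 sigma", {
  set.seed(11)
  sigma <- 3
  series <- data.frame(timestep = 1:350, value = 100 + rnorm(350, 0, sigma))
  cor <- fit_corridor(series, span = 0.75, degree = 0)
  halfwidth <- median((cor$upper - cor$lower) / 2)
  expect_equal(halfwidth, 1.96 * sigma, tolerance = 0.1)
  expect_equal(median(cor$fit), 100, tolerance = 0.01)
})

test_that("coverage counts aligned timesteps inside the band", {
  cor <- structure(data.frame(timestep = 1:20, fit = 0, lower = -1, upper = 1),
                   class = c("fvchain_corridor", "data.frame"))
  inside <- data.frame(timestep = 1:20, value = 0)
  expect_equal(coverage_fraction(inside, cor), 1)
  above <- data.frame(timestep = 1:20, value = 5)
  expect_equal(coverage_fraction(above, cor), 0)
  mixed <- data.frame(timestep = 1:20, value = c(rep(0, 19), 9))
  expect_equal(coverage_fraction(mixed, cor), 0.95)
  expect_error(coverage_fraction(data.frame(timestep = 21, value = 0), cor),
               "align")
})

test_that("triage applies the 95/90 thresholds", {
  expect_identical(triage(0.96), "insensitive")
  expect_identical(triage(0.95), "insensitive")
  expect_identical(triage(0.93), "yellow")
  expect_identical(triage(0.80), "red")
  expect_identical(triage(c(1, 0.9, 0.899)),
                   c("insensitive", "yellow", "red"))
})

test_that("KS screen matches the brute-force ECDF gap oracle exactly", {
  set.seed(12)
  for (i in 1:20) {
    x <- runif(sample(3:20, 1), 0.75, 1.25)
    y <- runif(sample(3:20, 1), 0.75, 1.25)
    got <- ks_screen(x, y)
    expect_equal(got$D, ks_D_oracle(x, y), tolerance = 1e-12)
  }
  # identical subsets and disjoint supports hit the extremes
  x <- c(0.8, 0.9, 1.0)
  expect_equal(ks_screen(x, x)$D, 0)
  expect_false(ks_screen(x, x)$influential)
  expect_equal(ks_screen(c(0.75, 0.8, 0.9), c(1.05, 1.1, 1.2))$D, 1)
  empty <- ks_screen(numeric(0), runif(5))
  expect_false(empty$screenable)
  expect_true(is.na(empty$D))
})

test_that("manifest paths resolve to config values and perturb cleanly", {
  cfg <- shared_config()
  man <- default_sensitivity_manifest(cfg)
  expect_true(all(c("variable", "V0", "group") %in% names(man)))
  for (i in seq_len(nrow(man))) {
    expect_equal(get_config_value(cfg, man$variable[i]), man$V0[i])
  }
  cfg2 <- set_config_value(cfg, "production.yields.Rabi", 0.99)
  expect_equal(get_config_value(cfg2, "production.yields.Rabi"), 0.99)
  expect_error(get_config_value(cfg, "no.such.path"), "unknown")
})
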