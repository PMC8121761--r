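test_that("reference prices are weekly, positive, seasonal and reproducible", {
  cfg <- shared_config()
  cal <- build_calendar("2017-10-01", "2021-09-30")
  p1 <- make_reference_price_series(cal, cfg, seed = 5)
  p2 <- make_reference_price_series(cal, cfg, seed = 5)
  expect_identical(p1, p2)
  expect_true(all(p1 > 0))
  # piecewise constant over each 14-half-day week
  first_fortnight <- p1[1:14]
  expect_equal(length(unique(first_fortnight)), 1L)
  expect_gt(length(unique(p1)), 40)
  # long-run mean near the configured level (lognormal noise is mean-one)
  expect_equal(mean(p1), cfg$fixtures$price_level, tolerance = 0.02)
  # noiseless series is exactly year-periodic (52-week template)
  cfg0 <- cfg
  cfg0$fixtures$price_noise_sd <- 0
  p0 <- make_reference_price_series(cal, cfg0, seed = 1)
  expect_equal(p0[1:728], p0[729:1456])
})

test_that("staple prices share the weekly structure", {
  cfg <- shared_config()
  cal <- build_calendar("2017-10-01", "2018-09-30")
  s <- make_staple_price_series(cal, cfg, seed = 2)
  expect_true(all(s > 0))
  expect_equal(mean(s), cfg$fixtures$staple_level, tolerance = 0.03)
})

test_that("cost draws are non-negative with the configured mean", {
  cfg <- shared_config()
  set.seed(10)
  draws <- make_cost_draws(10000, cfg)
  expect_true(all(draws >= 0))
  mu <- sum(vapply(cfg$fixtures$cost_components, `[[`, numeric(1), "mean")) / 2
  # truncation at zero lifts the mean slightly; CLT-scale agreement
  expect_equal(mean(draws), mu, tolerance = 0.05)
  cfg0 <- cfg
  cfg0$fixtures$cost_components <- lapply(cfg$fixtures$cost_components,
                                          function(cc) c(mean = cc[["mean"]],
                                                         sd = 0))
  expect_equal(unique(make_cost_draws(5, cfg0)), mu)
})

test_that("pseudo-observed series reproduce the baseline at zero noise", {
  base <- data.frame(timestep = 1:50, value = 100 + sin(1:50))
  same <- make_pseudo_observed_series(base, noise_sd = 0)
  expect_equal(same$value, base$value)
  noisy1 <- make_pseudo_observed_series(base, 0.05, seed = 7)
  noisy2 <- make_pseudo_observed_series(base, 0.05, seed = 7)
  expect_identical(noisy1, noisy2)
  win <- make_pseudo_observed_series(base, 0, window = c(10, 20))
  expect_equal(win$timestep, 10:20)
})

test_that("the fixture bundle resolves scenario and evaluation indices", {
  inputs <- shared_inputs()
  expect_identical(nrow(inputs$calendar), 2922L)
  expect_identical(inputs$t_scenario, 731L)
  expect_identical(inputs$t_subsidy_end, 730L)
  # evaluation window spans 178 days = 356 half-days
  expect_identical(diff(inputs$eval_days) + 1L, 178L)
  expect_identical(length(inputs$ref_price), 2922L)
})

test_that("fixture bundles round-trip through plain-text files", {
  cfg <- shared_config()
  dir <- withr::local_tempdir()
  write_fixture_bundle(shared_inputs(), cfg, dir)
  ref <- read.csv(file.path(dir, "reference_price.csv"))
  expect_identical(nrow(ref), 1461L)
  expect_true(all(ref$value > 0))
  cfg2 <- read_config(file.path(dir, "config.yaml"))
  expect_equal(cfg2$adoption$total_farmers, 12087)
  expect_equal(unname(unlist(cfg2$production$yields)),
               unname(unlist(cfg$production$yields)), tolerance = 1e-9)
})
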