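# Closed-loop properties of the full simulator. Short-horizon
# configurations keep these runs cheap; the full 2922-half-day invariants
# live in the acceptance suite.

short_config <- function(end = "2018-03-31") {
  cfg <- shared_config()
  cfg$horizon$end <- end
  if (as.Date(end) <= as.Date("2018-10-01")) {
    cfg$horizon$scenario_start <- "2018-03-01"
  }
  cfg
}

test_that("identical seeds give bit-identical runs", {
  cfg <- short_config()
  inp <- make_fixture_inputs(cfg, 2L)
  r1 <- run_simulation(cfg, NULL, run_seed = 17L, inputs = inp,
                       keep_series = TRUE)
  r2 <- run_simulation(cfg, NULL, run_seed = 17L, inputs = inp,
                       keep_series = TRUE)
  expect_identical(r1$outcomes, r2$outcomes)
  expect_identical(r1$series, r2$series)
  r3 <- run_simulation(cfg, NULL, run_seed = 18L, inputs = inp)
  expect_false(identical(r1$outcomes, r3$outcomes))
})

test_that("stocks stay within their physical bounds over a run", {
  run <- shared_baseline()
  s <- run$series
  M <- shared_config()$adoption$total_farmers
  expect_true(all(s$loop_farmers >= 0 & s$loop_farmers <= M))
  expect_true(all(s$trust >= 0 & s$trust <= 1))
  expect_true(all(s$pref_A >= 0 & s$pref_A <= 100))
  expect_true(all(s$participation[s$morning] >= 0.2 &
                    s$participation[s$morning] <= 1))
  expect_true(all(is.finite(s$price_A) & s$price_A > 0))
  expect_false(run$diagnostics$failed)
})

test_that("offered prices stay inside the clamp band around the reference", {
  run <- shared_baseline()
  inp <- shared_inputs()
  s <- run$series
  expect_true(all(s$price_A <= 1.5 * inp$ref_price + 1e-9))
  expect_true(all(s$price_A >= 0.5 * 0.8 * inp$ref_price - 1e-9))
  # lower bound includes the worst-case quality discount (h = 0.6)
})

test_that("yield multipliers respect the 1.5%/year investment cap", {
  run <- shared_baseline()
  years <- 4
  expect_true(all(run$final$yield_multiplier <= 1.015^years + 1e-9))
  expect_true(all(run$final$yield_multiplier >= 1))
})

test_that("a supply boost lowers retail prices and raises purchases (balancing loop)", {
  cfg <- short_config("2018-03-31")
  inp <- make_fixture_inputs(cfg, 3L)
  base <- run_simulation(cfg, NULL, run_seed = 5L, inputs = inp,
                         keep_series = TRUE)
  cfg_hi <- cfg
  cfg_hi$production$yields <- cfg$production$yields * 1.25
  boom <- run_simulation(cfg_hi, NULL, run_seed = 5L, inputs = inp,
                         keep_series = TRUE)
  expect_lt(mean(boom$series$price_B), mean(base$series$price_B))
  expect_gt(sum(boom$series$cons_B_per_cust),
            sum(base$series$cons_B_per_cust))
})

test_that("strong demand growth raises cumulative purchases per customer", {
  # growth also inflates wholesale competition for produce, so the
  # response is not locally monotone; the end-to-end direction holds
  cfg <- shared_config()
  inp <- make_fixture_inputs(cfg, 4L)
  grow <- function(g) {
    sc <- list(extension_rate = 0, subsidy_B = 0, cs_active_raw = 0,
               cs_level = 0, demand_growth = g)
    run_simulation(cfg, sc, run_seed = 9L, inputs = inp)$outcomes$cum_purchases_B
  }
  p <- vapply(c(0, 10), grow, numeric(1))
  expect_gt(p[2], p[1])
})

test_that("a persistent guaranteed-sales advantage drags preference to its clamp", {
  pref <- 80
  trace <- numeric(300)
  for (i in 1:300) {
    pref <- update_market_preference(pref, 5, 5, sales_A = 0.6, sales_B = 1)
    trace[i] <- pref
  }
  expect_true(all(diff(trace) <= 0))
  expect_equal(min(trace), 0)
})
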