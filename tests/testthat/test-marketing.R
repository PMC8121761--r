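test_that("participation share is neutral at parity and bounded", {
  neutral <- loop_participation_share(50, 50, 0.9, 0.9)
  expect_equal(neutral, 0.5 * (0.2 + 1))
  dominant <- loop_participation_share(1e5, 0, 1, 0,
                                       profit_scale = 60)
  expect_gt(dominant, 0.99)
  expect_lte(dominant, 1)
  worse <- loop_participation_share(90, 100, 0.9, 0.9)
  expect_lt(worse, neutral)
  # sign property against a direct logistic oracle
  x <- 0.4 * (90 - 100) / 60
  expect_equal(worse, 0.2 + 0.8 * plogis(3 * x))
})

test_that("market preference integrates weighted signals within [0, 100]", {
  expect_equal(update_market_preference(50, 5, 5, 0.9, 0.9), 50)
  expect_equal(update_market_preference(100, 10, 0, 1, 0.2), 100)
  moved <- update_market_preference(50, 5, 5, 0.9, 0.8,
                                    adjustment_rate = 5, w_sales = 0.7,
                                    w_profit = 0.3)
  expect_equal(moved, 50 + 5 * 0.7 * 0.1)
  # property: stays in bounds under arbitrary signal sequences
  set.seed(99)
  pref <- 50
  for (i in 1:500) {
    pref <- update_market_preference(pref, rnorm(1, 0, 20), rnorm(1, 0, 20),
                                     runif(1), runif(1),
                                     adjustment_rate = runif(1, 0, 50))
    expect_true(pref >= 0 && pref <= 100)
  }
})

test_that("independent farmers jitter around their constant split", {
  expect_equal(nonloop_market_split(0.8, 0.1, u = 0), 0.72)
  expect_equal(nonloop_market_split(0.8, 0.1, u = 1), 0.88)
  expect_equal(nonloop_market_split(0.8, 0, u = 0.37), 0.8)
  expect_equal(nonloop_market_split(0.95, 0.1, u = 1), 1) # clamp
  set.seed(3)
  draws <- replicate(200, nonloop_market_split(0.8, 0.1))
  expect_true(all(draws >= 0.72 & draws <= 0.88))
})

test_that("trader allocation conserves mass and respects presence", {
  one <- trader_allocation(100, c(0.9, 0.9, 0.9), c(10, 10, 10),
                           present = c(FALSE, TRUE, FALSE))
  expect_equal(one, c(0, 100, 0))
  sym <- trader_allocation(900, rep(0.8, 3), rep(11, 3), rep(TRUE, 3))
  expect_equal(sym, rep(300, 3))
  expect_equal(sum(trader_allocation(512, runif(3), runif(3, 5, 15),
                                     rep(TRUE, 3))), 512)
  none <- trader_allocation(100, c(0.9, 0.9), c(10, 10), c(FALSE, FALSE))
  expect_equal(none, c(0, 0))
  # better attributes draw a strictly larger share
  tilted <- trader_allocation(100, c(1, 0.5), c(15, 8), c(TRUE, TRUE))
  expect_gt(tilted[1], tilted[2])
})

test_that("transport tariffs sample the printed ranges and honour subsidies", {
  expect_equal(transport_cost(c(0.5, 0.85), subsidy = 0, u = 0), 0.5)
  expect_equal(transport_cost(c(0.5, 0.85), subsidy = 0, u = 1), 0.85)
  expect_equal(transport_cost(c(0.8, 1.1), subsidy = 0.5, u = 0.5), 0.95 / 2)
  set.seed(4)
  self_cost <- replicate(100, transport_cost(c(1.0, 1.5)))
  expect_true(all(self_cost >= 1.0 & self_cost <= 1.5))
  expect_error(transport_cost(c(1, 1.5), subsidy = 1.2))
})
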