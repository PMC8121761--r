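test_that("cold storage capacity follows the activation and level mapping", {
  expect_equal(cold_storage_capacity(1, 3, "A"), 75000)
  expect_equal(cold_storage_capacity(1, 3, "B"), 15000)
  expect_equal(cold_storage_capacity(0, 3, "A"), 0)
  expect_equal(cold_storage_capacity(1, 1, "A"), 25000)
  expect_equal(cold_storage_capacity(1, 1.5, "B"), 7500)
  expect_error(cold_storage_capacity(1, 3.5, "A"), "level")
})

test_that("quality adjustment averages full and half price", {
  expect_equal(quality_adjusted_price(10, 1), 10)
  expect_equal(quality_adjusted_price(10, 0), 5)
  expect_equal(quality_adjusted_price(10, 0.6), 8)
})

test_that("offered prices anchor on the reference within the clamp band", {
  expect_equal(offered_price(12, availability = 500, demand = 500), 12)
  expect_equal(offered_price(12, availability = 1e6, demand = 1), 6)
  expect_equal(offered_price(12, availability = 0, demand = 100), 18)
  expect_equal(offered_price(12, availability = 100, demand = 0), 6)
  expect_equal(offered_price(12, 123, 77, eta = 0), 12)
  # always within the band, any inputs
  set.seed(8)
  for (i in 1:200) {
    p <- offered_price(12, runif(1, 0, 1e4), runif(1, 0, 1e4),
                       eta = runif(1, 0, 1))
    expect_true(p >= 6 && p <= 18)
  }
})

test_that("trader profit is revenue minus purchase bill and costs", {
  expect_equal(trader_profit(0, 0, 8, 10, costs = 500), -500)
  expect_equal(trader_profit(1000, 1000, 8, 10, costs = 500), 1500)
  # storage rent: 2000 kg held one half-day at 0.15 Rs/kg
  rent <- 0.15 * 2000
  expect_equal(trader_profit(0, 0, 8, 10, costs = rent), -300)
})

test_that("entry scales with profit and exit floors at zero", {
  expect_equal(trader_entry_exit(10, 0), 10)
  base_entry <- trader_entry_exit(10, 1e6, entry_coeff = 1e-6) - 10
  expect_equal(trader_entry_exit(10, 2e6, entry_coeff = 1e-6) - 10,
               2 * base_entry)
  n <- 5
  for (i in 1:10000) n <- trader_entry_exit(n, -1, exit_coeff = 0.01)
  expect_gte(n, 0)
  expect_lt(n, 5)
})

test_that("inventory ages, spoils past shelf life and respects cold storage", {
  q <- numeric(42)
  q[4] <- 100 # two days old, at the ambient limit
  no_storage <- age_inventory(q, ambient_shelf = 4, cold_capacity = 0)
  expect_equal(no_storage$spoiled, 100) # aged to 5 half-days, expires
  expect_equal(sum(no_storage$queue), 0)
  with_storage <- age_inventory(q, ambient_shelf = 4, cold_capacity = 500)
  expect_equal(with_storage$spoiled, 0)
  expect_equal(sum(with_storage$queue), 100)
  # cold capacity binds: only the capacity share survives, oldest spoils
  q2 <- numeric(42)
  q2[c(10, 20)] <- c(60, 50)
  capped <- age_inventory(q2, 4, cold_capacity = 80)
  expect_equal(capped$spoiled, 30)
  expect_equal(sum(capped$queue), 80)
  expect_equal(capped$queue[11], 60) # newer cohort survives intact
  # produce older than the cold shelf life always spoils
  q3 <- numeric(42)
  q3[42] <- 7
  expect_equal(age_inventory(q3, 4, 1e9)$spoiled, 7)
})

test_that("spoilage wrapper reports carried and spoiled consistently", {
  z <- spoilage_update(unsold = 0)
  expect_equal(z$carried, 0)
  expect_equal(z$spoiled, 0)
  held <- spoilage_update(unsold = 250, cold_active = TRUE,
                          cold_capacity = 1e4)
  expect_equal(held$carried, 250)
  q <- numeric(42)
  q[5] <- 40 # would be 6 half-days old after ageing
  expired <- spoilage_update(queue = q, shelf_life = 4, cold_active = FALSE)
  expect_equal(expired$spoiled, 40)
  kept <- spoilage_update(queue = q, shelf_life = 4, cold_active = TRUE,
                          cold_capacity = 100)
  expect_equal(kept$carried, 40) # 6 < 42 half-days with storage
})

test_that("FIFO drain sells oldest stock first", {
  q <- numeric(6)
  q[c(2, 5)] <- c(30, 20)
  dr <- drain_inventory(q, 35)
  expect_equal(dr$sold, 35)
  expect_equal(dr$queue[5], 0) # oldest fully drained
  expect_equal(dr$queue[2], 15)
  all_gone <- drain_inventory(q, 1e6)
  expect_equal(all_gone$sold, 50)
  expect_equal(sum(all_gone$queue), 0)
})
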