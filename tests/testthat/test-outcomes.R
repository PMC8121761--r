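test_that("scheme ROI averages fee-to-compensation ratios over active half-days", {
  expect_equal(loop_roi(100, 1000), 1.0)
  expect_equal(loop_roi(300, 1000), 3.0)
  expect_equal(loop_roi(0, 1000), 0)
  # zero-sales half-days are skipped, not counted as zero
  expect_equal(loop_roi(c(100, 0, 300), c(1000, 0, 1000)), 2.0)
  expect_warning(r <- loop_roi(c(0, 0), c(0, 0)), "undefined")
  expect_true(is.na(r))
})

test_that("every sign octant maps to exactly one trade-off category", {
  octants <- expand.grid(a = c(TRUE, FALSE), p = c(TRUE, FALSE),
                         r = c(TRUE, FALSE))
  labels <- mapply(classify_signs, octants$a, octants$p, octants$r)
  expect_true(all(labels %in% tradeoff_categories))
  expect_identical(length(labels), 8L)
  # the six categories partition the eight octants
  expect_setequal(unique(labels), tradeoff_categories)
  expect_identical(classify_signs(TRUE, TRUE, TRUE), "win_win_win")
  expect_identical(classify_signs(TRUE, TRUE, FALSE), "access_profit_wins")
  expect_identical(classify_signs(TRUE, FALSE, TRUE), "access_wins")
  expect_identical(classify_signs(TRUE, FALSE, FALSE), "access_wins")
  expect_identical(classify_signs(FALSE, TRUE, TRUE), "profit_wins")
  expect_identical(classify_signs(FALSE, TRUE, FALSE), "profit_wins")
  expect_identical(classify_signs(FALSE, FALSE, TRUE), "others")
  expect_identical(classify_signs(FALSE, FALSE, FALSE), "lose_lose_lose")
})

test_that("ties count as losses and classify matches outcome lists", {
  base <- list(cum_purchases_B = 10, cum_profit_loop = 100, mean_roi = 1)
  expect_identical(classify_tradeoff(base, base), "lose_lose_lose")
  up <- list(cum_purchases_B = 11, cum_profit_loop = 101, mean_roi = 2)
  expect_identical(classify_tradeoff(up, base), "win_win_win")
  mixed <- list(cum_purchases_B = 11, cum_profit_loop = 99, mean_roi = 2)
  expect_identical(classify_tradeoff(mixed, base), "access_wins")
  roi_only <- list(cum_purchases_B = 9, cum_profit_loop = 99, mean_roi = 2)
  expect_identical(classify_tradeoff(roi_only, base), "others")
})

test_that("core subset agrees with a brute-force distance oracle", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 50
    deltas <- cbind(d_purchases = rnorm(n, 0, 5),
                    d_profit = rnorm(n, 0, 2000),
                    d_roi = rnorm(n, 0, 0.5))
    category <- sample(tradeoff_categories[1:3], n, replace = TRUE)
    got <- core_subset(deltas, category)
    # oracle: z-scale by column SD, euclidean distance, mean + sd per group
    sds <- apply(deltas, 2, sd)
    dist <- sqrt(rowSums(sweep(deltas, 2, sds, "/")^2))
    want <- logical(n)
    for (cat in unique(category)) {
      idx <- category == cat
      want[idx] <- dist[idx] > mean(dist[idx]) + sd(dist[idx])
    }
    expect_identical(got, want)
  }
})

test_that("core subset handles degenerate categories", {
  d <- cbind(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1))
  # all equidistant: sd = 0, nothing strictly exceeds mean + sd
  expect_identical(core_subset(d, rep("access_wins", 3)),
                   rep(FALSE, 3))
  expect_warning(
    single <- core_subset(cbind(1, 1, 1), "others"),
    "singleton"
  )
  expect_false(single)
  # one extreme outlier among near-baseline points is the only core member
  d2 <- rbind(matrix(rnorm(27, 0, 0.01), ncol = 3), c(50, 50, 50))
  flags <- core_subset(d2, rep("access_wins", 10), normalize = FALSE)
  expect_identical(which(flags), 10L)
})

test_that("conditional probability profiles count per equal-width bin", {
  vals <- c(0.1, 0.2, 0.3, 0.4, 0.6, 0.7, 0.8, 0.9)
  labs <- c(rep("access_wins", 3), "profit_wins", rep("profit_wins", 4))
  prof <- conditional_probability_profile(vals, labs, n_bins = 2,
                                          range = c(0, 1))
  expect_equal(prof$n, c(4L, 4L))
  expect_equal(prof$access_wins, c(0.75, 0))
  expect_equal(prof$profit_wins, c(0.25, 1))
  # proportions sum to one where defined
  sums <- rowSums(prof[, c("access_wins", "profit_wins")])
  expect_equal(sums, c(1, 1))
  # empty bins are missing, single category is certainty
  uni <- conditional_probability_profile(c(0.1, 0.15), rep("others", 2),
                                         n_bins = 4, range = c(0, 1))
  expect_equal(uni$others, c(1, NA, NA, NA))
})
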