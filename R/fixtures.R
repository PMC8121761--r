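#' Synthetic input fixtures
#'
#' The field deployment this model describes draws on proprietary sources
#' (an aggregation-scheme dashboard and regional wholesale price records)
#' with no public accession. This module generates synthetic stand-ins
#' with the statistical structure the model assumes - a weekly seasonal
#' wholesale reference price, a staple-price series, truncated-normal
#' household cost draws, and pseudo-observed calibration series - so every
#' other module is testable without any download. All fixtures are
#' deterministic given a configuration and seed.
#'
#' @name synthetic_fixtures
NULL

# Truncated-normal sampler (lower bound 0) via inverse-CDF; sd = 0
# degenerates to the mean.
rtrunc_norm0 <- function(n, mean, sd) {
  if (sd <= 0) return(rep(mean, n))
  p0 <- stats::pnorm(0, mean, sd)
  stats::qnorm(p0 + stats::runif(n) * (1 - p0), mean, sd)
}

#' Weekly wholesale reference-price series
#'
#' A 52-week seasonal template (sinusoid around the configured level with
#' multiplicative lognormal weekly noise) tiled over the horizon, so the
#' series is piecewise-constant over each week (14 half-days) and
#' year-periodic in expectation - emulating a weekly wholesale price
#' record repeated over the simulation.
#'
#' @param calendar calendar from [build_calendar()].
#' @param config full configuration (uses the `fixtures` section).
#' @param seed RNG seed.
#' @return Numeric vector: Rs/kg per half-day.
#' @export
make_reference_price_series <- function(calendar, config = default_config(),
                                        seed = 1L) {
  fx <- config$fixtures
  set.seed(seed)
  week_template <- seq_len(52)
  seasonal <- fx$price_level *
    (1 + fx$price_amplitude * cos(2 * pi * (week_template - fx$price_peak_week) / 52))
  noise <- exp(stats::rnorm(52, 0, fx$price_noise_sd) - fx$price_noise_sd^2 / 2)
  template <- seasonal * noise
  week_of_year <- pmin(((calendar$day - 1) %/% 7) %% 52, 51) + 1
  template[week_of_year]
}

#' Weekly staple-price series
#'
#' Same construction as the reference price but around the staple level
#' with its own (smaller) seasonal amplitude and noise; used only through
#' the F&V-to-staple price ratio steering land allocation.
#'
#' @inheritParams make_reference_price_series
#' @return Numeric vector: Rs/kg per half-day.
#' @export
make_staple_price_series <- function(calendar, config = default_config(),
                                     seed = 2L) {
  fx <- config$fixtures
  set.seed(seed)
  week_template <- seq_len(52)
  seasonal <- fx$staple_level *
    (1 + fx$staple_amplitude * cos(2 * pi * (week_template - 20) / 52))
  noise <- exp(stats::rnorm(52, 0, fx$staple_noise_sd) - fx$staple_noise_sd^2 / 2)
  template <- seasonal * noise
  week_of_year <- pmin(((calendar$day - 1) %/% 7) %% 52, 51) + 1
  template[week_of_year]
}

#' Per-farmer cost component draws
#'
#' Each on-farm cost component (production inputs, labour, miscellaneous)
#' samples a truncated-normal value per draw; components are summed and
#' halved to a per-half-day cost.
#'
#' @param n number of draws.
#' @param config full configuration.
#' @return Numeric vector of Rs/farmer/half-day costs, all non-negative.
#' @export
make_cost_draws <- function(n, config = default_config()) {
  comps <- config$fixtures$cost_components
  daily <- Reduce(`+`, lapply(comps, function(cc) {
    rtrunc_norm0(n, cc[["mean"]], cc[["sd"]])
  }))
  daily / 2
}

#' Pseudo-observed calibration series
#'
#' Multiplies a baseline model series by lognormal noise and restricts it
#' to the evaluation window, producing a synthetic stand-in for an
#' observed record against which constraint corridors are fitted.
#'
#' @param baseline_series data.frame with `timestep` and `value`.
#' @param noise_sd lognormal noise SD (0 reproduces the baseline).
#' @param window optional length-2 timestep range to keep.
#' @param seed RNG seed.
#' @return data.frame with `timestep` and `value`.
#' @export
make_pseudo_observed_series <- function(baseline_series, noise_sd = 0.05,
                                        window = NULL, seed = 3L) {
  set.seed(seed)
  out <- baseline_series
  out$value <- out$value *
    exp(stats::rnorm(nrow(out), 0, noise_sd) - noise_sd^2 / 2)
  if (!is.null(window)) {
    out <- out[out$timestep >= window[1] & out$timestep <= window[2], ,
               drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Assemble the full fixture input bundle for a simulation
#'
#' Builds the calendar and all exogenous series a run needs. The scenario
#' start index and evaluation window indices are resolved here from the
#' configured dates.
#'
#' @param config full configuration.
#' @param seed master fixture seed (price/staple seeds derive from it).
#' @return List: `calendar`, `ref_price`, `staple_price`, `t_scenario`,
#'   `t_subsidy_end`, `eval_days` (day-number range of the evaluation
#'   window).
#' @export
make_fixture_inputs <- function(config = default_config(), seed = 1L) {
  cal <- build_calendar(config$horizon$start, config$horizon$end)
  origin <- as.Date(config$horizon$start)
  win <- as.Date(config$fixtures$evaluation_window)
  list(
    calendar = cal,
    ref_price = make_reference_price_series(cal, config, seed = seed),
    staple_price = make_staple_price_series(cal, config, seed = seed + 1L),
    t_scenario = halfday_index(config$horizon$scenario_start, origin),
    t_subsidy_end = halfday_index(config$transport$baseline_subsidy_end,
                                  origin, "afternoon"),
    eval_days = as.integer(win - origin) + 1L
  )
}

#' Write the fixture bundle to a directory as plain text
#'
#' Emits `reference_price.csv` and `staple_price.csv` (`date,value`, one
#' row per half-day date/phase pair collapsed to dates with morning
#' values) plus the configuration as YAML, so a run is fully specified by
#' files on disk.
#'
#' @param inputs bundle from [make_fixture_inputs()].
#' @param config configuration used to build it.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_fixture_bundle <- function(inputs, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  morning <- inputs$calendar$morning
  ref <- data.frame(date = inputs$calendar$date[morning],
                    value = inputs$ref_price[morning])
  sta <- data.frame(date = inputs$calendar$date[morning],
                    value = inputs$staple_price[morning])
  utils::write.csv(ref, file.path(dir, "reference_price.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(sta, file.path(dir, "staple_price.csv"),
                   row.names = FALSE, quote = FALSE)
  write_config(config, file.path(dir, "config.yaml"))
  invisible(dir)
}
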