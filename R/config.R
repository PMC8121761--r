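#' Default model configuration
#'
#' Returns the full nested parameter list driving a simulation. Constants
#' printed in the source field study (farmer population 12,087; initial
#' scheme membership 90; transport cost ranges; land price 76,000 Rs/katha;
#' investment rules; trader capacities; storage rent 0.15 Rs/kg/half-day;
#' shelf lives of 4 vs 42 half-days) are locked here and exercised by the
#' test suite. Everything else is a calibration constant of this package:
#' chosen once to produce a plausible baseline (slow organic membership
#' growth from 90 farmers, peak-Rabi market capacities of roughly 100,000
#' and 20,000 kg/day, farm supply commensurate with market capacity) and
#' documented in the methods vignette.
#'
#' @return A nested named list of parameters.
#' @export
default_config <- function() {
  list(
    horizon = list(
      start = "2017-10-01",
      end = "2021-09-30",
      scenario_start = "2018-10-01"
    ),
    adoption = list(
      total_farmers = 12087,
      initial_loop = 90,
      extension_rate = 0, # farmers per 1000 non-members per half-day (baseline: none)
      imitation_coeff = 0.0015, # word-of-mouth coefficient per half-day
      trust_init = 0.6,
      trust_gain = 0.004,
      trust_decay = 0.004,
      trend_window = 60, # half-days used for monthly trust trends
      trend_deadband = 1e-8,
      disadoption_rate = 0.001,
      w_profit = 0.4,
      w_sales = 0.6,
      disadoption_mode = "trust" # or "utility"
    ),
    production = list(
      land_loop = 2000, # m2 cultivable per member farmer
      land_nonloop = 2000,
      # monthly land-fraction cycle (Jan..Dec): Rabi peak ~0.8, Kharif trough ~0.5
      fv_month_frac = c(0.80, 0.78, 0.72, 0.65, 0.58, 0.52,
                        0.50, 0.50, 0.52, 0.78, 0.80, 0.80),
      price_ratio_ref = 0.6, # reference F&V/staple price ratio (neutral land response)
      yields = c(Rabi = 0.050, Zaid = 0.031, Kharif = 0.022), # kg/m2 per marketing half-day
      own_consumption_rate = 0.10,
      giveaway_rate = 0.03,
      pre_farmgate_loss_rate = 0.08,
      female_fraction_loop = 0.25,
      female_fraction_nonloop = 0.25,
      female_consumption_boost = 0.10,
      quality_range = c(0.6, 1.0), # high-grade fraction drawn uniformly per half-day
      land_price_per_katha = 76000, # Rs
      m2_per_katha = 400, # one-tenth katha ~ 40 m2
      land_invest_rate = 0.20,
      land_invest_threshold = 7600, # Rs: cost of one-tenth katha
      yield_invest_rate = 0.10,
      yield_gain_per_rs = 0.01 / 20000, # 1% per Rs 20,000
      yield_annual_cap = 0.015 # max 1.5%/year
    ),
    marketing = list(
      w_sales = 0.6, # guaranteed sales weighted above profit
      w_profit = 0.4,
      participation_kappa = 3,
      participation_share_min = 0.2,
      pref_A_init = 80, # percentage of aggregated supply headed to Market A
      pref_adjustment_rate = 4, # percentage points per marketing morning at unit signal
      nonloop_base_A = 0.80, # constant share of independent supply to Market A
      nonloop_noise = 0.10,
      alloc_kappa = 2, # softmax steepness of trader choice
      profit_scale = 60 # Rs/farmer normalising weekly profit differences
    ),
    transport = list(
      loop_A = c(0.50, 0.85), # Rs/kg, aggregated route to Market A
      loop_B = c(0.80, 1.10),
      self_A = c(1.00, 1.50), # self-supply, either market
      self_B = c(1.00, 1.50),
      baseline_subsidy = 0.5, # up to 50% over the first year
      baseline_subsidy_end = "2018-09-30",
      commission_A = 0.14, # urban mandi commission, fraction of sale value
      commission_B = 0.04 # small local markets charge far less
    ),
    traders = list(
      capacity_distance = 2000, # kg/trader/half-day, morning only
      capacity_wholesale = 600, # kg/trader/half-day, all day
      counts = c(A_distance = 15, A_wholesale = 50, A_retail = 120,
                 B_wholesale = 6, B_retail = 400),
      margins = c(A_distance = 0.15, A_wholesale = 0.20, A_retail = 0.30,
                  B_wholesale = 0.20, B_retail = 0.30),
      misc_cost = c(A_distance = 220, A_wholesale = 380, A_retail = 25,
                    B_wholesale = 380, B_retail = 25), # Rs/trader/half-day
      outbound_transport = c(A_distance = 0.4, A_wholesale = 0, A_retail = 0,
                             B_wholesale = 0, B_retail = 0), # Rs/kg sold onward
      entry_coeff = 5e-9, # traders per Rs of trailing 30-day cohort profit
      exit_coeff = 5e-4, # per half-day while trailing profit is negative
      profit_window = 60, # half-days (one month)
      price_elasticity = 0.4, # exponent of demand/availability in price anchoring
      price_clamp = c(0.5, 1.5),
      shelf_life = 4, # half-days (two days) without cold storage
      shelf_life_cold = 42, # half-days (21 days) with cold storage
      storage_rent = 0.15 # Rs/kg-stored/half-day
    ),
    demand = list(
      elasticity_urban = -0.6, # Market A expenditure elasticity
      elasticity_rural = -0.9, # Market B
      reference_demand_A = 0.10, # kg/customer/half-day at reference price
      reference_demand_B = 0.10,
      customers_A = 30000, # fixed retail customer population, Market A
      customers_B = 64000, # catchment of the small retail-oriented market

      reference_retail_price_A = 12, # Rs/kg
      reference_retail_price_B = 9, # rural purchasing power is weaker
      smoothing_halfdays = 14 # consumers adjust roughly once per week
    ),
    roi = list(
      compensation_rate = 0.1 # Rs paid to aggregators per kg sold
    ),
    fixtures = list(
      price_level = 12, # Rs/kg mean wholesale reference price
      price_amplitude = 0.25, # seasonal sinusoid amplitude (relative)
      price_peak_week = 38, # week of year (from Oct 1) when prices peak
      price_noise_sd = 0.08, # lognormal weekly noise
      staple_level = 18, # Rs/kg staple price
      staple_amplitude = 0.05,
      staple_noise_sd = 0.02,
      cost_components = list( # Rs/farmer/day, truncated-normal
        production = c(mean = 10, sd = 4),
        labour = c(mean = 8, sd = 4),
        misc = c(mean = 4, sd = 2)
      ),
      pseudo_observed_noise_sd = 0.05,
      evaluation_window = c("2018-03-01", "2018-08-25")
    ),
    scenario = list(
      ranges_phase1 = list(
        extension_rate = c(0, 0.274),
        subsidy_B = c(0, 100),
        cs_active_raw = c(0, 1),
        cs_level = c(0, 3),
        demand_growth = c(0, 10)
      ),
      ranges_phase2 = list(
        extension_rate = c(0.035, 0.086),
        subsidy_B = c(0, 50),
        cs_active_raw = c(0, 1),
        cs_level = c(0, 0.62),
        demand_growth = c(7.5, 10)
      ),
      cs_activation_threshold = 0.5,
      cs_capacity_A = 25000, # kg/half-day per unit investment level
      cs_capacity_B = 5000
    )
  )
}

#' Read / write a configuration as YAML
#'
#' Thin wrappers over [yaml::read_yaml()] and [yaml::write_yaml()] so a full
#' parameterisation can be stored alongside run outputs.
#'
#' @param path file path.
#' @param config configuration list.
#' @return `read_config()` returns the configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Validate structural invariants of a configuration
#'
#' Checks the handful of invariants the model relies on: utility and
#' marketing weights summing to one, non-marketing outflow rates summing
#' below one, positive yields and a sane horizon ordering.
#'
#' @param config configuration list.
#' @return The configuration, invisibly; errors describe the first violated
#'   invariant.
#' @export
validate_config <- function(config) {
  a <- config$adoption
  if (abs(a$w_profit + a$w_sales - 1) > 1e-8) {
    stop("adoption utility weights must sum to 1", call. = FALSE)
  }
  p <- config$production
  out_sum <- p$own_consumption_rate * (1 + p$female_consumption_boost) +
    p$giveaway_rate + p$pre_farmgate_loss_rate
  if (out_sum >= 1) {
    stop("non-marketing outflow rates must sum to less than 1", call. = FALSE)
  }
  if (any(unlist(p$yields) <= 0)) {
    stop("yield baselines must be positive", call. = FALSE)
  }
  h <- config$horizon
  if (as.Date(h$end) < as.Date(h$start)) {
    stop("horizon end precedes start", call. = FALSE)
  }
  if (as.Date(h$scenario_start) < as.Date(h$start) ||
      as.Date(h$scenario_start) > as.Date(h$end)) {
    stop("scenario start outside horizon", call. = FALSE)
  }
  invisible(config)
}

#' Get or set a configuration entry by dotted path
#'
#' Sensitivity analysis perturbs parameters addressed as e.g.
#' `"production.yields.Rabi"` or `"marketing.nonloop_base_A"`.
#'
#' @param config configuration list.
#' @param path dotted path string.
#' @param value replacement value (for `set_config_value`).
#' @return The entry, or the modified configuration.
#' @export
get_config_value <- function(config, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- config
  for (k in keys) {
    if (is.null(node[[k]])) stop("unknown config path: ", path, call. = FALSE)
    node <- node[[k]]
  }
  node
}

#' @rdname get_config_value
#' @export
set_config_value <- function(config, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  expr <- Reduce(function(acc, k) call("[[", acc, k), keys, quote(config))
  eval(call("<-", expr, value))
  config
}
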