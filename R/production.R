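#' Production, land allocation and on-farm investment
#'
#' Marketable production is the product of the farmers marketing on a given
#' half-day, their cultivable land, the fraction of it under F&V, and the
#' seasonal baseline yield scaled by an investment-driven multiplier. Land
#' allocation cycles seasonally (peaking around 80% in Rabi, bottoming near
#' 50% in Kharif) and responds secondarily to the F&V-to-staple price
#' ratio. Cumulative profits are reinvested in land and yield enhancement
#' at the start of every season.
#'
#' @name production
NULL

#' Marketable F&V production for one half-day
#'
#' @param n_farmers farmers in the population.
#' @param marketing_fraction fraction of them marketing this half-day.
#' @param land_area m2 of cultivable land per farmer.
#' @param fv_land_fraction fraction of land under F&V.
#' @param baseline_yield kg/m2 per marketing half-day for the season.
#' @param yield_multiplier dimensionless (>= 1), grown by investment.
#' @return kg of F&V brought forward this half-day.
#' @export
marketable_production <- function(n_farmers, marketing_fraction, land_area,
                                  fv_land_fraction, baseline_yield,
                                  yield_multiplier = 1) {
  n_farmers * marketing_fraction * land_area * fv_land_fraction *
    baseline_yield * yield_multiplier
}

#' Seasonal F&V land fraction with price response
#'
#' The monthly base cycle (configured, ~0.8 in peak Rabi down to ~0.5 in
#' Kharif) is multiplied by a saturating adjustment in `(0.8, 1.2)` that
#' increases with the F&V-to-staple price ratio and is neutral (exactly 1)
#' when the ratio equals its reference value; the result is clamped to
#' `[0, 1]`.
#'
#' @param month calendar month (1-12).
#' @param fv_price,staple_price current price indices, Rs/kg.
#' @param month_frac length-12 base fractions (Jan..Dec).
#' @param price_ratio_ref reference F&V/staple ratio.
#' @return Fraction of land under F&V.
#' @export
fv_land_fraction <- function(month, fv_price, staple_price,
                             month_frac = default_config()$production$fv_month_frac,
                             price_ratio_ref = 0.6) {
  if (fv_price <= 0 || staple_price <= 0) {
    stop("prices must be positive", call. = FALSE)
  }
  ratio <- fv_price / staple_price
  adj <- 0.8 + 0.4 * ratio / (ratio + price_ratio_ref)
  min(max(month_frac[month] * adj, 0), 1)
}

#' Non-marketing outflows before the farmgate
#'
#' Splits production into own household consumption (scaled up by 10% per
#' unit female-headed-household fraction), quantities given away, and
#' pre-farmgate losses. All three are subtracted before marketing.
#'
#' @param production kg produced this half-day.
#' @param female_fraction fraction of female-headed households.
#' @param own_rate,give_rate,loss_rate baseline outflow fractions; their
#'   effective sum (including the female consumption boost) must stay
#'   below 1.
#' @param female_boost relative increase in own consumption for
#'   female-headed households.
#' @return Named list: `own_consumption`, `given_away`, `pre_farmgate_loss`
#'   (kg each).
#' @export
non_marketing_outflows <- function(production, female_fraction,
                                   own_rate = 0.10, give_rate = 0.03,
                                   loss_rate = 0.08, female_boost = 0.10) {
  eff_own <- own_rate * (1 + female_boost * female_fraction)
  if (eff_own + give_rate + loss_rate >= 1) {
    stop("outflow rates sum to >= 1", call. = FALSE)
  }
  list(
    own_consumption = eff_own * production,
    given_away = give_rate * production,
    pre_farmgate_loss = loss_rate * production
  )
}

#' Season-start land purchase rule
#'
#' Farmers invest in land only when 20% of their cumulative profit exceeds
#' the cost of one-tenth of a katha (Rs 7,600 at 76,000 Rs/katha); if so
#' they spend exactly that 20%, converted to area at the configured katha
#' size (~40 m2 per tenth katha).
#'
#' @param cumulative_profit Rs per farmer.
#' @param land_price Rs per katha.
#' @param rate fraction of cumulative profit spent.
#' @param threshold Rs that the prospective spend must strictly exceed.
#' @param m2_per_katha land-unit conversion.
#' @return Named list: `area_bought` (m2) and `spend` (Rs).
#' @export
invest_in_land <- function(cumulative_profit, land_price = 76000,
                           rate = 0.20, threshold = 7600,
                           m2_per_katha = 400) {
  if (cumulative_profit <= 0) return(list(area_bought = 0, spend = 0))
  spend <- rate * cumulative_profit
  if (spend <= threshold) return(list(area_bought = 0, spend = 0))
  list(area_bought = spend / land_price * m2_per_katha, spend = spend)
}

#' Season-start yield-enhancement rule
#'
#' Farmers spend 10% of cumulative profits on enhanced yields, with every
#' Rs 20,000 buying a 1% yield increase, capped at 1.5% per model year.
#' Only the spend actually converted (after the cap) is deducted.
#'
#' @param cumulative_profit Rs per farmer.
#' @param annual_headroom remaining fractional yield gain allowed this year.
#' @param rate fraction of cumulative profit invested.
#' @param gain_per_rs fractional yield gain per rupee invested.
#' @return Named list: `increment` (fractional yield gain) and `spend` (Rs
#'   actually consumed).
#' @export
invest_in_yield <- function(cumulative_profit, annual_headroom = 0.015,
                            rate = 0.10, gain_per_rs = 0.01 / 20000) {
  if (cumulative_profit <= 0 || annual_headroom <= 0) {
    return(list(increment = 0, spend = 0))
  }
  spend <- rate * cumulative_profit
  increment <- spend * gain_per_rs
  if (increment > annual_headroom) {
    increment <- annual_headroom
    spend <- increment / gain_per_rs
  }
  list(increment = increment, spend = spend)
}
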