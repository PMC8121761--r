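#' Daily participation, market preference and trader choice
#'
#' Three nested choices route produce to buyers: (i) each morning a share
#' of scheme members opts into aggregation, driven by trailing weekly
#' profits and guaranteed sales relative to independent marketing; (ii)
#' aggregated supply is split between the large urban Market A and the
#' small retail Market B by a bounded preference stock; (iii) within a
#' market, supply is shared over the trader types present by a
#' softmax-style rule over expected price and guaranteed sales. Guaranteed
#' sales are weighted above price throughout.
#'
#' @name marketing
NULL

#' Share of members aggregating on a given morning
#'
#' A logistic function of the weighted difference in trailing 7-day
#' guaranteed-sales fractions and (normalised) profits between aggregation
#' and independent marketing, mapped onto `[share_min, 1]`. At parity the
#' share equals the neutral midpoint `(share_min + 1) / 2`.
#'
#' @param loop_profit_7d,nonloop_profit_7d trailing weekly profit,
#'   Rs/farmer.
#' @param loop_sales_7d,nonloop_sales_7d trailing weekly guaranteed-sales
#'   fractions.
#' @param w_sales,w_profit weights (sales-dominant by default).
#' @param kappa logistic steepness.
#' @param share_min lower bound of the participation share.
#' @param profit_scale Rs scale used to normalise the profit difference.
#' @return Fraction of members aggregating this morning.
#' @export
loop_participation_share <- function(loop_profit_7d, nonloop_profit_7d,
                                     loop_sales_7d, nonloop_sales_7d,
                                     w_sales = 0.6, w_profit = 0.4,
                                     kappa = 3, share_min = 0.2,
                                     profit_scale = 60) {
  x <- w_sales * (loop_sales_7d - nonloop_sales_7d) +
    w_profit * (loop_profit_7d - nonloop_profit_7d) / profit_scale
  share_min + (1 - share_min) * stats::plogis(kappa * x)
}

#' Update the Market A preference stock
#'
#' The preference (percentage of aggregated supply headed to Market A,
#' bounded in `[0, 100]`) adjusts towards whichever market offered better
#' trailing weekly guaranteed sales and expected marketing profit, with
#' guaranteed sales weighted more heavily. Higher supply to a market
#' depresses its price and sales, pushing the preference back: a balancing
#' loop verified as a closed-loop property of the full simulator.
#'
#' @param pref_A current preference, percentage points in `[0, 100]`.
#' @param exp_profit_A,exp_profit_B trailing expected marketing profit,
#'   Rs/kg.
#' @param sales_A,sales_B trailing guaranteed-sales fractions.
#' @param adjustment_rate percentage points per half-day at unit signal.
#' @param w_sales,w_profit weights.
#' @param price_scale Rs/kg scale normalising the profit difference.
#' @return Updated preference in `[0, 100]`.
#' @export
update_market_preference <- function(pref_A, exp_profit_A, exp_profit_B,
                                     sales_A, sales_B,
                                     adjustment_rate = 2,
                                     w_sales = 0.6, w_profit = 0.4,
                                     price_scale = 11) {
  d <- adjustment_rate * (w_sales * (sales_A - sales_B) +
    w_profit * (exp_profit_A - exp_profit_B) / price_scale)
  min(max(pref_A + d, 0), 100)
}

#' Noisy constant market split for independent farmers
#'
#' Independent farmers' market shares are constants jittered by up to
#' +/- `noise_bound` of the constant value per half-day, providing
#' background variability without large swings.
#'
#' @param base_A constant share of supply to Market A, in `(0, 1)`.
#' @param noise_bound maximum relative deviation.
#' @param u a uniform `[0, 1]` draw (pass pre-generated noise for
#'   reproducibility).
#' @return Share to Market A, clamped to `[0, 1]`.
#' @export
nonloop_market_split <- function(base_A, noise_bound = 0.10, u = stats::runif(1)) {
  min(max(base_A * (1 + noise_bound * (2 * u - 1)), 0), 1)
}

#' Allocate supply across trader types within a market
#'
#' Shares follow a softmax over `w_sales * sales_frac + w_profit *
#' price / price_scale` for the trader types present (distance traders are
#' morning-only and absent from Market B). Shares over present types sum
#' to 1, so allocation conserves mass; with no trader present the supply
#' is returned unallocated.
#'
#' @param supply kg to allocate.
#' @param sales_frac trailing guaranteed-sales fraction per type.
#' @param exp_price expected price per type, Rs/kg.
#' @param present logical vector: which types are buying this half-day.
#' @param w_sales,w_profit weights.
#' @param kappa softmax steepness.
#' @param price_scale Rs/kg normalisation.
#' @return Numeric vector of kg per trader type (zeros for absent types).
#' @export
trader_allocation <- function(supply, sales_frac, exp_price, present,
                              w_sales = 0.6, w_profit = 0.4, kappa = 2,
                              price_scale = 11) {
  alloc <- numeric(length(sales_frac))
  if (!any(present) || supply <= 0) return(alloc)
  attr_score <- w_sales * sales_frac[present] +
    w_profit * exp_price[present] / price_scale
  w <- exp(kappa * (attr_score - max(attr_score)))
  alloc[present] <- supply * w / sum(w)
  alloc
}

#' Sample a transport tariff and apply a subsidy
#'
#' Transport costs are drawn uniformly within the per-route range each
#' half-day; the farmer-paid cost is the draw times `1 - subsidy`.
#'
#' @param cost_range length-2 Rs/kg range for the route.
#' @param subsidy fraction in `[0, 1]`.
#' @param u uniform `[0, 1]` draw.
#' @return Farmer-paid Rs/kg.
#' @export
transport_cost <- function(cost_range, subsidy = 0, u = stats::runif(1)) {
  stopifnot(subsidy >= 0, subsidy <= 1)
  (cost_range[1] + u * (cost_range[2] - cost_range[1])) * (1 - subsidy)
}
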