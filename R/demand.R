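#' Price-responsive retail demand
#'
#' Customers in each market respond to retail selling prices through
#' constant-elasticity demand around a reference level, optionally inflated
#' by an external annual growth rate (compounded continuously from the
#' scenario start). Realised demand is smoothed towards its target with a
#' two-week (14 half-day) time constant, reflecting consumers adjusting
#' roughly once per week, i.e. every other market visit.
#'
#' @name retail_demand
NULL

#' Target purchase demand per customer
#'
#' `reference_demand * (price / reference_price)^elasticity *
#' (1 + g)^years` with negative elasticity, so higher prices depress
#' demand - the consumer side of the availability-price balancing loop.
#'
#' @param price current retail price, Rs/kg (> 0).
#' @param reference_price Rs/kg at which demand equals the reference.
#' @param reference_demand kg/customer/half-day.
#' @param elasticity expenditure elasticity (negative).
#' @param growth_rate external demand growth, fraction per year.
#' @param years_elapsed years since the scenario start (0 before it).
#' @return kg/customer/half-day.
#' @export
target_demand <- function(price, reference_price, reference_demand,
                          elasticity = -0.6, growth_rate = 0,
                          years_elapsed = 0) {
  if (price <= 0 || reference_price <= 0) {
    stop("prices must be positive", call. = FALSE)
  }
  reference_demand * (price / reference_price)^elasticity *
    (1 + growth_rate)^years_elapsed
}

#' First-order demand smoothing
#'
#' `current + (target - current) / time_constant`: exponential adjustment
#' with fixed point at the target; an infinite time constant freezes
#' demand.
#'
#' @param current,target kg/customer/half-day.
#' @param time_constant half-days (default 14, one week of visits).
#' @return Updated demand.
#' @export
smooth_demand <- function(current, target, time_constant = 14) {
  if (!is.finite(time_constant)) return(current)
  current + (target - current) / time_constant
}

#' Demand per retailer
#'
#' @param demand_per_customer kg/customer/half-day.
#' @param customers_per_retailer count.
#' @return kg/retailer/half-day.
#' @export
retailer_demand <- function(demand_per_customer, customers_per_retailer) {
  demand_per_customer * customers_per_retailer
}
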