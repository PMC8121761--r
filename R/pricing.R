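#' Market pricing, trader dynamics and perishable inventory
#'
#' Farmgate prices anchor on the out-of-state distance traders' expected
#' (reference) price, scaled by each trader's remaining downstream appetite
#' relative to the volume routed to them, and adjusted for produce quality
#' (low-grade produce fetches half price). Trader cohorts enter in
#' proportion to trailing monthly profits and exit under losses. Unsold
#' stock ages in half-day cohorts and spoils past its shelf life: 4
#' half-days (two days) at ambient conditions, 42 half-days (21 days) in
#' cold storage, whose capacity is shared among traders in proportion to
#' their supply shares.
#'
#' @name market_pricing
NULL

#' Cold-storage capacity from a scenario draw
#'
#' Storage exists only when the activation draw reaches the 0.5 threshold;
#' capacity is then linear in the investment level: one unit provides
#' 25,000 kg/half-day in Market A and 5,000 in Market B.
#'
#' @param active 0/1 indicator (activation draw already thresholded).
#' @param level investment level in `[0, 3]`.
#' @param market `"A"` or `"B"`.
#' @param capacity_A,capacity_B kg/half-day per unit level.
#' @return Storage capacity, kg/half-day.
#' @export
cold_storage_capacity <- function(active, level, market = c("A", "B"),
                                  capacity_A = 25000, capacity_B = 5000) {
  market <- match.arg(market)
  if (level < 0 || level > 3) stop("`level` must lie in [0, 3]", call. = FALSE)
  active * level * if (market == "A") capacity_A else capacity_B
}

#' Quality-adjusted price
#'
#' High-grade produce receives the full offered price and low-grade half
#' price, so the population average is `price * (h + 0.5 * (1 - h))` for
#' high-grade fraction `h`.
#'
#' @param offered_price Rs/kg.
#' @param high_grade_fraction fraction in `[0, 1]`.
#' @return Rs/kg.
#' @export
quality_adjusted_price <- function(offered_price, high_grade_fraction) {
  offered_price * (high_grade_fraction + 0.5 * (1 - high_grade_fraction))
}

#' Offered farmgate price from reference anchoring
#'
#' `reference_price * clamp((demand / availability)^eta, clamp)` - scarcity
#' relative to the trader's downstream demand raises the offer and gluts
#' depress it, within a +/-50% band around the anchor. Zero availability
#' maps to the upper clamp; `eta = 0` reproduces the anchor exactly.
#'
#' @param reference_price Rs/kg anchor (distance traders' expectation).
#' @param availability kg routed to the trader this half-day.
#' @param demand kg of remaining downstream appetite (capacity proxy).
#' @param eta price elasticity exponent (>= 0).
#' @param clamp length-2 relative price band.
#' @return Offered price, Rs/kg.
#' @export
offered_price <- function(reference_price, availability, demand,
                          eta = 0.4, clamp = c(0.5, 1.5)) {
  ratio <- if (availability <= 0) {
    clamp[2]
  } else if (demand <= 0) {
    clamp[1]
  } else {
    (demand / availability)^eta
  }
  reference_price * min(max(ratio, clamp[1]), clamp[2])
}

#' Trader profit for one half-day
#'
#' Revenue is sales (purchases minus wastage already netted out by the
#' inventory mechanics) times the selling price; costs are the purchase
#' bill plus operating costs (transport, commissions, cold-storage rent,
#' miscellaneous).
#'
#' @param sold kg sold onward.
#' @param purchases kg bought from farmers.
#' @param buy_price,sell_price Rs/kg.
#' @param costs Rs/half-day of operating costs.
#' @return Rs/half-day.
#' @export
trader_profit <- function(sold, purchases, buy_price, sell_price, costs = 0) {
  sold * sell_price - purchases * buy_price - costs
}

#' Trader cohort entry and exit
#'
#' Entries are proportional to the cohort's trailing 30-day profit when
#' positive; under trailing losses a fraction of the cohort exits each
#' half-day. Counts are continuous and floored at zero.
#'
#' @param count current trader count.
#' @param profit_30d trailing 30-day (60 half-day) cohort profit, Rs.
#' @param entry_coeff traders per Rs of trailing profit per half-day.
#' @param exit_coeff exit fraction per half-day under losses.
#' @return Updated count.
#' @export
trader_entry_exit <- function(count, profit_30d, entry_coeff = 1e-7,
                              exit_coeff = 0.001) {
  d <- entry_coeff * max(profit_30d, 0) -
    exit_coeff * count * (profit_30d < 0)
  max(count + d, 0)
}

#' Age, spoil and cap a perishable inventory queue
#'
#' `queue[i]` holds kg of age `i` half-days. Each call ages the queue by
#' one half-day; kg older than the hard maximum (the cold shelf life)
#' spoil, and kg older than the ambient shelf life survive only up to the
#' trader's cold-storage capacity share - the excess (oldest first)
#' spoils immediately. With no storage capacity this reduces to the
#' two-day ambient rule.
#'
#' @param queue numeric vector of age-cohort kg (index = age in half-days).
#' @param ambient_shelf half-days produce keeps without cold storage.
#' @param cold_capacity kg of cold storage available to this trader.
#' @return List with the aged `queue` and `spoiled` kg.
#' @export
age_inventory <- function(queue, ambient_shelf = 4, cold_capacity = 0) {
  n <- length(queue)
  spoiled <- queue[n] # pushed past the cold shelf life
  queue <- c(0, queue[-n])
  if (ambient_shelf < n) {
    old_idx <- (ambient_shelf + 1):n
    old_total <- sum(queue[old_idx])
    if (old_total > cold_capacity) {
      excess <- old_total - cold_capacity
      # spoil oldest first (highest index = oldest)
      rev_old <- queue[rev(old_idx)]
      ahead <- cumsum(rev_old) - rev_old
      take <- pmin(rev_old, pmax(excess - ahead, 0))
      queue[rev(old_idx)] <- rev_old - take
      spoiled <- spoiled + sum(take)
    }
  }
  list(queue = queue, spoiled = spoiled)
}

#' Sell from an inventory queue, oldest first
#'
#' @param queue age-cohort kg vector.
#' @param amount kg to sell (capped at the queue total).
#' @return List with the drained `queue` and `sold` kg.
#' @export
drain_inventory <- function(queue, amount) {
  total <- sum(queue)
  sold <- min(amount, total)
  rev_q <- rev(queue) # oldest first
  ahead <- cumsum(rev_q) - rev_q
  take <- pmin(rev_q, pmax(sold - ahead, 0))
  list(queue = rev(rev_q - take), sold = sold)
}

#' Spoilage update for unsold produce (convenience wrapper)
#'
#' Applies the ageing rule to a queue holding `unsold` fresh kg on top of
#' carried stock, returning carried and spoiled totals. Used for
#' single-step reasoning and tests; the simulator applies [age_inventory()]
#' and [drain_inventory()] directly.
#'
#' @param queue current age-cohort vector.
#' @param unsold kg left unsold this half-day (entered at age 1 next step).
#' @param shelf_life ambient shelf life, half-days.
#' @param cold_active logical: cold storage available.
#' @param cold_capacity kg of cold capacity for this trader.
#' @param max_shelf cold shelf life (queue length), half-days.
#' @return List: `carried` kg still held, `spoiled` kg.
#' @export
spoilage_update <- function(queue = NULL, unsold = 0, shelf_life = 4,
                            cold_active = FALSE, cold_capacity = 0,
                            max_shelf = 42) {
  if (is.null(queue)) queue <- numeric(max_shelf)
  queue[1] <- queue[1] + unsold
  aged <- age_inventory(queue,
    ambient_shelf = shelf_life,
    cold_capacity = if (cold_active) cold_capacity else 0
  )
  list(carried = sum(aged$queue), spoiled = aged$spoiled, queue = aged$queue)
}
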