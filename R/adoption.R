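#' Scheme membership dynamics
#'
#' Membership follows a Bass innovation-diffusion structure: an extension
#' (innovation) channel recruiting from the non-member pool plus a
#' word-of-mouth (imitation) channel proportional to the adopted fraction.
#' Both channels are gated multiplicatively by a trust stock in `[0, 1]`
#' and by the relative utility of aggregation versus independent marketing,
#' each normalised to 1 at parity; dis-adoption is driven by lack of trust.
#'
#' @name adoption
NULL

# Ratio clamped to [0, 2], defined as 1 when both arguments are <= 0 (no
# information either way) and 2/0 when exactly one side is positive.
ratio_clamped <- function(num, den) {
  if (num <= 0 && den <= 0) return(1)
  if (den <= 0) return(2)
  if (num <= 0) return(0)
  min(max(num / den, 0), 2)
}

#' Relative utility of aggregation
#'
#' Weighted combination of the member-to-independent ratios of trailing
#' weekly profit per farmer and trailing weekly guaranteed-sales fraction.
#' Each ratio is clamped to `[0, 2]` (parity when both sides are
#' non-positive), so utility equals 1 when the two populations fare
#' identically and 2 when members dominate on both dimensions by at least
#' a factor of two.
#'
#' @param loop_profit_7d,nonloop_profit_7d trailing 7-day profits, Rs/farmer.
#' @param loop_sales_frac_7d,nonloop_sales_frac_7d trailing 7-day
#'   guaranteed-sales fractions in `[0, 1]`.
#' @param w_profit,w_sales non-negative weights summing to 1.
#' @return Dimensionless utility index in `[0, 2]`.
#' @export
loop_utility <- function(loop_profit_7d, nonloop_profit_7d,
                         loop_sales_frac_7d, nonloop_sales_frac_7d,
                         w_profit = 0.4, w_sales = 0.6) {
  w_profit * ratio_clamped(loop_profit_7d, nonloop_profit_7d) +
    w_sales * ratio_clamped(loop_sales_frac_7d, nonloop_sales_frac_7d)
}

#' Update the trust stock from monthly profit and sales trends
#'
#' Trust rises when member profits and/or guaranteed sales have increased
#' over the trailing month and decays when they have decreased; flat trends
#' leave it unchanged. The update is
#' `trust + gain * n_pos/2 - decay * n_neg/2`, clamped to `[0, 1]`, where
#' `n_pos`/`n_neg` count the positive/negative trend signs among the two
#' monitored series.
#'
#' @param trust current trust in `[0, 1]`.
#' @param profit_trend_sign,sales_trend_sign -1, 0 or +1 trend signs over
#'   the trailing 60 half-days.
#' @param trust_gain,trust_decay per-half-day adjustment rates.
#' @return Updated trust in `[0, 1]`.
#' @export
update_trust <- function(trust, profit_trend_sign, sales_trend_sign,
                         trust_gain = 0.004, trust_decay = 0.004) {
  signs <- c(profit_trend_sign, sales_trend_sign)
  n_pos <- sum(signs > 0)
  n_neg <- sum(signs < 0)
  min(max(trust + trust_gain * n_pos / 2 - trust_decay * n_neg / 2, 0), 1)
}

#' Adoption and dis-adoption flows for one half-day
#'
#' Adoption combines the extension channel (`extension_rate` recruits per
#' 1000 non-members per half-day) with Bass imitation
#' (`imitation_coeff * adopted_fraction * non_members`), gated by trust and
#' utility. Dis-adoption removes members at `disadoption_rate * (1 - gate)`
#' where the gate is trust (default) or utility/2. Flows are capped so both
#' stocks stay non-negative.
#'
#' @param loop_farmers,nonloop_farmers current stocks (continuous).
#' @param trust trust stock in `[0, 1]`.
#' @param utility relative utility index (1 at parity).
#' @param extension_rate farmers per 1000 non-members per half-day.
#' @param imitation_coeff per half-day.
#' @param disadoption_rate per half-day.
#' @param total_farmers fixed population total.
#' @param disadoption_mode `"trust"` or `"utility"`.
#' @return Named list with `adoptions` and `disadoptions` (farmers/half-day).
#' @export
adoption_flow <- function(loop_farmers, nonloop_farmers, trust, utility,
                          extension_rate, imitation_coeff,
                          disadoption_rate, total_farmers = 12087,
                          disadoption_mode = "trust") {
  if (!disadoption_mode %in% c("trust", "utility")) {
    stop("unknown disadoption mode: ", disadoption_mode, call. = FALSE)
  }
  adoptions <- (extension_rate / 1000 * nonloop_farmers +
    imitation_coeff * (loop_farmers / total_farmers) * nonloop_farmers) *
    trust * utility
  gate <- if (disadoption_mode == "trust") trust else min(utility / 2, 1)
  disadoptions <- disadoption_rate * loop_farmers * (1 - gate)
  adoptions <- min(adoptions, nonloop_farmers)
  disadoptions <- min(disadoptions, loop_farmers)
  list(adoptions = adoptions, disadoptions = disadoptions)
}

#' Sign of a windowed trend with a dead band
#'
#' Compares the mean of the most recent half-window against the mean of the
#' preceding half-window; differences smaller than `deadband` count as flat.
#'
#' @param recent_mean,previous_mean window means.
#' @param deadband magnitude below which the trend is treated as flat.
#' @return -1, 0 or +1.
#' @export
trend_sign <- function(recent_mean, previous_mean, deadband = 1e-8) {
  d <- recent_mean - previous_mean
  if (d > deadband) 1L else if (d < -deadband) -1L else 0L
}
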