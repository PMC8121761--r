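#' Outcome accumulation and trade-off classification
#'
#' Every scenario run is summarised by three outcome dimensions measured
#' over the scenario horizon: cumulative F&V purchases per retail customer
#' in the small Market B, cumulative horticultural profit per member
#' farmer, and the mean scheme return on investment (transport fees
#' collected post-subsidy relative to aggregator compensation at 0.1
#' Rs/kg sold). Signs of the differences against a paired do-nothing
#' baseline place the run in one of six trade-off categories partitioning
#' the eight win/lose octants.
#'
#' @name outcomes
NULL

#' The six trade-off categories
#' @export
tradeoff_categories <- c(
  "win_win_win", "access_profit_wins", "access_wins",
  "profit_wins", "others", "lose_lose_lose"
)

#' Mean scheme return on investment
#'
#' Per half-day ratio of transport fees collected from member farmers
#' (post-subsidy) to the compensation paid to aggregators
#' (`compensation_rate` per kg sold), averaged over the horizon while
#' skipping half-days with zero sales. A horizon with no sales at all
#' yields `NA` with a warning.
#'
#' @param fees_collected Rs collected per half-day (vector).
#' @param kg_sold kg sold through aggregation per half-day (vector).
#' @param compensation_rate Rs/kg paid to aggregators.
#' @return Mean ROI ratio (dimensionless).
#' @export
loop_roi <- function(fees_collected, kg_sold, compensation_rate = 0.1) {
  stopifnot(length(fees_collected) == length(kg_sold), all(kg_sold >= 0))
  active <- kg_sold > 0
  if (!any(active)) {
    warning("no aggregated sales over the horizon; ROI undefined")
    return(NA_real_)
  }
  mean(fees_collected[active] / (compensation_rate * kg_sold[active]))
}

#' Classify a run against its baseline
#'
#' A dimension "wins" iff its outcome strictly exceeds the baseline (ties
#' count as losses). With the sign vector (purchases, profit, ROI):
#' `(+,+,+)` win-win-win; `(+,+,-)` access & profit wins; `(+,-,.)`
#' access wins; `(-,+,.)` profit wins; `(-,-,+)` others (only ROI wins);
#' `(-,-,-)` lose-lose-lose. The mapping is total: every octant falls in
#' exactly one category.
#'
#' @param outcome,baseline named lists or vectors with `cum_purchases_B`,
#'   `cum_profit_loop`, `mean_roi`.
#' @return One of [tradeoff_categories].
#' @export
classify_tradeoff <- function(outcome, baseline) {
  d <- c(
    outcome[["cum_purchases_B"]] - baseline[["cum_purchases_B"]],
    outcome[["cum_profit_loop"]] - baseline[["cum_profit_loop"]],
    outcome[["mean_roi"]] - baseline[["mean_roi"]]
  )
  classify_signs(d[1] > 0, d[2] > 0, d[3] > 0)
}

#' Classify a win/lose sign triple
#'
#' @param access_win,profit_win,roi_win logicals: strict wins on Market-B
#'   purchases, member profit, and scheme ROI.
#' @return One of [tradeoff_categories].
#' @export
classify_signs <- function(access_win, profit_win, roi_win) {
  if (access_win && profit_win) {
    if (roi_win) "win_win_win" else "access_profit_wins"
  } else if (access_win) {
    "access_wins"
  } else if (profit_win) {
    "profit_wins"
  } else if (roi_win) {
    "others"
  } else {
    "lose_lose_lose"
  }
}

#' Flag the core subset of each trade-off category
#'
#' Within each category, a run is "core" when its three-dimensional
#' distance from the baseline exceeds the category mean distance plus one
#' standard deviation. Because the three dimensions carry different units,
#' distances are computed on deltas scaled by their ensemble-wide standard
#' deviations (set `normalize = FALSE` for raw units). Singleton
#' categories have no defined spread and yield no core members.
#'
#' @param deltas matrix or data.frame with columns `d_purchases`,
#'   `d_profit`, `d_roi` (run minus baseline).
#' @param category character vector of per-run categories.
#' @param normalize z-scale dimensions by ensemble SD before measuring
#'   distance.
#' @return Logical core flag per run.
#' @export
core_subset <- function(deltas, category, normalize = TRUE) {
  deltas <- as.matrix(deltas)
  stopifnot(ncol(deltas) == 3, nrow(deltas) == length(category))
  scale_by <- if (normalize) {
    s <- apply(deltas, 2, stats::sd)
    ifelse(s > 0, s, 1)
  } else {
    rep(1, 3)
  }
  z <- sweep(deltas, 2, scale_by, "/")
  dist <- sqrt(rowSums(z^2))
  core <- logical(length(category))
  for (cat in unique(category)) {
    idx <- which(category == cat)
    if (length(idx) < 2) {
      if (length(idx) == 1) {
        warning("singleton category '", cat, "': no core members")
      }
      next
    }
    threshold <- mean(dist[idx]) + stats::sd(dist[idx])
    core[idx] <- dist[idx] > threshold
  }
  core
}

#' Conditional probability of each category across a scenario range
#'
#' Bins the per-run scenario magnitudes into equal-width bins and returns
#' the per-bin proportion of each trade-off category. Empty bins are
#' reported as `NA`.
#'
#' @param scenario_values numeric per-run scenario magnitudes.
#' @param labels per-run categories.
#' @param n_bins number of equal-width bins.
#' @param range optional length-2 range (defaults to the data range).
#' @return A data.frame: `bin`, `lower`, `upper`, `n`, one proportion
#'   column per category present.
#' @export
conditional_probability_profile <- function(scenario_values, labels,
                                            n_bins = 10, range = NULL) {
  stopifnot(length(scenario_values) == length(labels), n_bins >= 1)
  if (is.null(range)) range <- base::range(scenario_values)
  breaks <- seq(range[1], range[2], length.out = n_bins + 1)
  bin <- findInterval(scenario_values, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  cats <- intersect(tradeoff_categories, unique(labels))
  out <- data.frame(
    bin = seq_len(n_bins),
    lower = breaks[-(n_bins + 1)],
    upper = breaks[-1],
    n = as.integer(tabulate(bin, n_bins))
  )
  for (cat in cats) {
    prop <- vapply(seq_len(n_bins), function(b) {
      nb <- out$n[b]
      if (nb == 0) return(NA_real_)
      sum(labels[bin == b] == cat) / nb
    }, numeric(1))
    out[[cat]] <- prop
  }
  out
}
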