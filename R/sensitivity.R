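#' Two-stage regional sensitivity analysis
#'
#' Stage one perturbs each qualitatively uncertain parameter one at a time
#' by a multiplicative error `V = V0 * eps`, `eps ~ Uniform[0.75, 1.25]`,
#' and scores each perturbed run by the fraction of its output series
#' falling inside a constraint corridor - the 95% band of a locally
#' weighted (LOESS) regression fitted to an observed (here: synthetic
#' pseudo-observed) series. Variables whose runs keep at least 95% of
#' points in-corridor are triaged insensitive; the rest split into
#' "yellow" (moderately sensitive) and "red" (most sensitive) tiers and
#' are re-perturbed jointly at staged error ranges (±5%, ±10%, ±25%).
#' A two-sample Kolmogorov-Smirnov test on the error multipliers of
#' behaviour-giving versus non-giving runs screens for influential
#' parameters.
#'
#' @name sensitivity_calibration
NULL

#' Multiplicative parameter perturbation
#'
#' @param V0 central parameter value.
#' @param eps_range length-2 positive multiplier range.
#' @param n number of perturbed values.
#' @return `V0 * eps` with `eps ~ Uniform(eps_range)`.
#' @export
perturb <- function(V0, eps_range = c(0.75, 1.25), n = 1) {
  stopifnot(all(eps_range > 0), eps_range[1] <= eps_range[2])
  V0 * stats::runif(n, eps_range[1], eps_range[2])
}

#' Fit a LOESS constraint corridor
#'
#' Fits a locally weighted least-squares regression (span and degree
#' configurable) to an observed series and returns the pointwise 95%
#' band `fit +/- z * sqrt(se_fit^2 + sigma^2)`, where `sigma` is the
#' residual standard error - a prediction-style band, so a series
#' statistically indistinguishable from the observations keeps about 95%
#' of its points inside. A noiseless series collapses the band onto the
#' fitted line.
#'
#' @param series data.frame with `timestep` and `value` (>= 10 points).
#' @param span LOESS span.
#' @param degree local polynomial degree.
#' @param level band coverage level.
#' @return data.frame of class `fvchain_corridor`: `timestep`, `fit`,
#'   `lower`, `upper`.
#' @export
fit_corridor <- function(series, span = 0.3, degree = 1, level = 0.95) {
  if (nrow(series) < 10) stop("need at least 10 points", call. = FALSE)
  fit <- stats::loess(value ~ timestep, data = series, span = span,
                      degree = degree,
                      control = stats::loess.control(surface = "direct"))
  pred <- stats::predict(fit, se = TRUE)
  sigma <- fit$s
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(pred$se.fit^2 + sigma^2)
  out <- data.frame(timestep = series$timestep, fit = as.numeric(pred$fit),
                    lower = as.numeric(pred$fit) - half,
                    upper = as.numeric(pred$fit) + half)
  class(out) <- c("fvchain_corridor", "data.frame")
  out
}

#' Fraction of a series inside a corridor
#'
#' @param series data.frame with `timestep` and `value`.
#' @param corridor from [fit_corridor()].
#' @return Fraction of timesteps with `lower <= value <= upper`; errors if
#'   the timesteps do not align.
#' @export
coverage_fraction <- function(series, corridor) {
  m <- match(series$timestep, corridor$timestep)
  if (anyNA(m)) stop("series and corridor timesteps do not align", call. = FALSE)
  inside <- series$value >= corridor$lower[m] & series$value <= corridor$upper[m]
  mean(inside)
}

#' Triage a coverage fraction into a sensitivity tier
#'
#' At least 95% in-corridor is insensitive; 90-95% is "yellow"
#' (moderately sensitive); below 90% is "red" (most sensitive).
#'
#' @param coverage fraction(s) in `[0, 1]`.
#' @return Character vector: `"insensitive"`, `"yellow"` or `"red"`.
#' @export
triage <- function(coverage) {
  stopifnot(all(coverage >= 0 & coverage <= 1))
  ifelse(coverage >= 0.95, "insensitive",
         ifelse(coverage >= 0.90, "yellow", "red"))
}

#' Kolmogorov-Smirnov screen for influential parameters
#'
#' Two-sample KS test between the error multipliers of behaviour-giving
#' runs (>= 95% of outputs in-corridor) and the rest; a parameter is
#' influential when the distributions differ significantly, i.e. the
#' multiplier magnitude matters for whether behaviour is reproduced. When
#' either subset is empty the parameter is not screenable.
#'
#' @param eps_giving,eps_non_giving multiplier vectors for the two subsets.
#' @param alpha significance level.
#' @return List: `D`, `p_value`, `influential`, `screenable`.
#' @export
ks_screen <- function(eps_giving, eps_non_giving, alpha = 0.05) {
  if (length(eps_giving) == 0 || length(eps_non_giving) == 0) {
    return(list(D = NA_real_, p_value = NA_real_, influential = NA,
                screenable = FALSE))
  }
  kt <- suppressWarnings(stats::ks.test(eps_giving, eps_non_giving))
  list(D = unname(kt$statistic), p_value = kt$p.value,
       influential = kt$p.value < alpha, screenable = TRUE)
}

#' Default perturbation manifest
#'
#' The qualitatively uncertain parameters exposed to sensitivity
#' analysis, addressed by dotted config paths, with their second-stage
#' tier grouping ("yellow" for moderately sensitive supply-side levers,
#' "red" for the dominant drivers of market supply).
#'
#' @param config configuration used to resolve central values.
#' @return data.frame: `variable`, `V0`, `group`.
#' @export
default_sensitivity_manifest <- function(config = default_config()) {
  vars <- c(
    "marketing.nonloop_base_A",
    "production.yields.Rabi",
    "production.yields.Zaid",
    "production.yields.Kharif",
    "traders.price_elasticity",
    "demand.elasticity_urban",
    "demand.elasticity_rural",
    "demand.smoothing_halfdays",
    "marketing.pref_adjustment_rate",
    "marketing.alloc_kappa",
    "adoption.imitation_coeff",
    "adoption.trust_gain",
    "adoption.disadoption_rate",
    "production.own_consumption_rate",
    "transport.commission_A",
    "marketing.participation_kappa"
  )
  group <- c("red", "red", "yellow", "yellow", "yellow", "yellow",
             "insensitive", "insensitive", "yellow", "insensitive",
             "red", "insensitive", "insensitive", "yellow",
             "insensitive", "insensitive")
  data.frame(
    variable = vars,
    V0 = vapply(vars, function(v) get_config_value(config, v), numeric(1)),
    group = group,
    row.names = NULL
  )
}

#' Baseline series and corridor for calibration scoring
#'
#' Runs the unperturbed baseline, extracts daily aggregated sales in
#' Market A over the evaluation window, overlays multiplicative noise to
#' form the pseudo-observed record, and fits its constraint corridor.
#'
#' @param config configuration.
#' @param inputs fixture bundle (rebuilt when omitted).
#' @param seed seed for the baseline run and observation noise.
#' @param span LOESS span.
#' @return List: `baseline_series`, `observed`, `corridor`, `inputs`.
#' @export
make_calibration_target <- function(config = default_config(), inputs = NULL,
                                    seed = 1L, span = 0.3) {
  if (is.null(inputs)) inputs <- make_fixture_inputs(config, seed)
  base <- run_simulation(config, NULL, run_seed = seed, inputs = inputs,
                         keep_series = TRUE)
  daily <- daily_series(base$series, "loop_sold_A")
  win <- inputs$eval_days
  daily <- daily[daily$timestep >= win[1] & daily$timestep <= win[2], ]
  observed <- make_pseudo_observed_series(
    daily, config$fixtures$pseudo_observed_noise_sd, seed = seed + 11L
  )
  list(baseline_series = daily, observed = observed,
       corridor = fit_corridor(observed, span = span), inputs = inputs)
}

# Extract the scored series (daily Market-A aggregated sales in the
# evaluation window) from one perturbed run.
scored_series <- function(run, inputs) {
  daily <- daily_series(run$series, "loop_sold_A")
  win <- inputs$eval_days
  daily[daily$timestep >= win[1] & daily$timestep <= win[2], ]
}

#' One-at-a-time perturbation stage
#'
#' For each manifest variable, draws `n_sims` multipliers in `eps_range`,
#' reruns the model with only that variable perturbed, and records the
#' corridor coverage of each run. Coverages summarise to the per-variable
#' verdict; the multipliers feed the KS screen.
#'
#' @param manifest from [default_sensitivity_manifest()].
#' @param n_sims perturbed runs per variable.
#' @param eps_range multiplier range.
#' @param config configuration.
#' @param target from [make_calibration_target()].
#' @param seed RNG seed for the multiplier draws.
#' @return data.frame: `variable`, `eps`, `coverage` (one row per run).
#' @export
run_oat_stage <- function(manifest, n_sims = 10,
                          eps_range = c(0.75, 1.25),
                          config = default_config(),
                          target = make_calibration_target(config),
                          seed = 1L) {
  set.seed(seed)
  eps_draws <- matrix(stats::runif(nrow(manifest) * n_sims,
                                   eps_range[1], eps_range[2]),
                      nrow = nrow(manifest))
  rows <- vector("list", nrow(manifest) * n_sims)
  k <- 0
  for (v in seq_len(nrow(manifest))) {
    for (j in seq_len(n_sims)) {
      eps <- eps_draws[v, j]
      cfg <- set_config_value(config, manifest$variable[v],
                              manifest$V0[v] * eps)
      run <- run_simulation(cfg, NULL, run_seed = seed + j,
                            inputs = target$inputs, keep_series = TRUE)
      cov <- coverage_fraction(scored_series(run, target$inputs),
                               target$corridor)
      k <- k + 1
      rows[[k]] <- data.frame(variable = manifest$variable[v], eps = eps,
                              coverage = cov)
    }
  }
  do.call(rbind, rows)
}

#' Multivariable perturbation stage
#'
#' Jointly perturbs every variable in a tier group by independent
#' multipliers within `1 +/- half_width` and scores corridor coverage per
#' run; called sequentially with widening half-widths (0.05, 0.10, 0.25)
#' for the yellow then red groups.
#'
#' @param manifest perturbation manifest.
#' @param group tier to perturb (`"yellow"` or `"red"`).
#' @param half_width relative error half-width.
#' @param n_sims number of joint-perturbation runs.
#' @param config configuration.
#' @param target calibration target.
#' @param seed RNG seed.
#' @return Numeric vector of per-run coverages.
#' @export
run_multivariable_stage <- function(manifest, group, half_width,
                                    n_sims = 20, config = default_config(),
                                    target = make_calibration_target(config),
                                    seed = 1L) {
  vars <- manifest[manifest$group == group, , drop = FALSE]
  if (nrow(vars) == 0) stop("no variables in group '", group, "'", call. = FALSE)
  set.seed(seed)
  eps <- matrix(stats::runif(n_sims * nrow(vars),
                             1 - half_width, 1 + half_width),
                nrow = n_sims)
  vapply(seq_len(n_sims), function(j) {
    cfg <- config
    for (v in seq_len(nrow(vars))) {
      cfg <- set_config_value(cfg, vars$variable[v], vars$V0[v] * eps[j, v])
    }
    run <- run_simulation(cfg, NULL, run_seed = seed + j,
                          inputs = target$inputs, keep_series = TRUE)
    coverage_fraction(scored_series(run, target$inputs), target$corridor)
  }, numeric(1))
}

#' Summarise an OAT stage into verdicts and KS screens
#'
#' @param oat output of [run_oat_stage()].
#' @param alpha KS significance level.
#' @param behaviour_threshold in-corridor fraction defining
#'   behaviour-giving runs.
#' @return data.frame: `variable`, `mean_coverage`, `tier`, `ks_D`,
#'   `ks_p`, `influential`, `screenable`.
#' @export
summarise_sensitivity <- function(oat, alpha = 0.05,
                                  behaviour_threshold = 0.95) {
  vars <- unique(oat$variable)
  rows <- lapply(vars, function(v) {
    sub <- oat[oat$variable == v, ]
    giving <- sub$coverage >= behaviour_threshold
    ks <- ks_screen(sub$eps[giving], sub$eps[!giving], alpha)
    data.frame(variable = v, mean_coverage = mean(sub$coverage),
               tier = triage(mean(sub$coverage)), ks_D = ks$D,
               ks_p = ks$p_value, influential = ks$influential,
               screenable = ks$screenable)
  })
  do.call(rbind, rows)
}
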