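# Shared fixtures, memoised so expensive objects are built once per session.

shared_cache <- new.env(parent = emptyenv())

shared <- function(name, builder) {
  if (!exists(name, envir = shared_cache, inherits = FALSE)) {
    assign(name, builder(), envir = shared_cache)
  }
  get(name, envir = shared_cache, inherits = FALSE)
}

shared_config <- function() shared("config", default_config)

shared_inputs <- function() {
  shared("inputs", function() make_fixture_inputs(shared_config(), seed = 1L))
}

# One full-horizon baseline run with series, reused across files.
shared_baseline <- function() {
  shared("baseline", function() {
    run_simulation(shared_config(), NULL, run_seed = 1L,
                   inputs = shared_inputs(), keep_series = TRUE)
  })
}

# Brute-force empirical-CDF max-gap oracle for the two-sample KS statistic.
ks_D_oracle <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  Fx <- vapply(grid, function(g) mean(x <= g), numeric(1))
  Fy <- vapply(grid, function(g) mean(y <= g), numeric(1))
  max(abs(Fx - Fy))
}

# Closed-form Bass adoption fraction with a non-zero initial adopted share.
bass_closed_form <- function(t, p, q, F0 = 0) {
  A <- (1 - F0) / (1 + q * F0 / p)
  e <- exp(-(p + q) * t)
  (1 - A * e) / (1 + (q / p) * A * e)
}
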