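#' Define a simulation scenario
#'
#' A scenario is one cell of the factorial design used in the Monte Carlo
#' study: the number of sampling occasions `T`, the true fraction `r` of the
#' initial population remaining at the end of the study period, and the
#' bounds of the uniform distribution from which per-occasion coefficients
#' of variation (CVs) of the abundance estimates are drawn. `r = 1` encodes
#' the null scenario of no trend.
#'
#' @param T_occasions Integer number of evenly spaced sampling occasions
#'   (at least 3).
#' @param r True remaining fraction of the population at the end of the
#'   study period (positive; 0.5 means a 50% overall decline, 1 means no
#'   change).
#' @param cv_lower,cv_upper Lower and upper bounds of the CV of abundance
#'   estimates; `cv_lower == cv_upper` gives a fixed CV.
#' @param baseline_abundance Positive nuisance constant for the initial
#'   abundance; it cancels in the ratios and defaults to 1.
#' @return An object of class `"scenario"`.
#' @examples
#' scenario(T_occasions = 10, r = 1, cv_lower = 0.1, cv_upper = 0.3)
#' @export
scenario <- function(T_occasions, r, cv_lower, cv_upper = cv_lower,
                     baseline_abundance = 1) {
  T_occasions <- as.integer(T_occasions)
  if (is.na(T_occasions) || T_occasions < 3L)
    stop("T_occasions must be an integer >= 3")
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0)
    stop("r must be a positive finite number")
  if (!is.numeric(cv_lower) || cv_lower < 0)
    stop("cv_lower must be >= 0")
  if (!is.numeric(cv_upper) || cv_upper < cv_lower)
    stop("cv_upper must be >= cv_lower")
  if (!is.numeric(baseline_abundance) || baseline_abundance <= 0)
    stop("baseline_abundance must be positive")
  structure(
    list(T_occasions = T_occasions, r = r,
         cv_lower = cv_lower, cv_upper = cv_upper,
         baseline_abundance = baseline_abundance),
    class = "scenario"
  )
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf(
    "Scenario: T = %d occasions, r = %.4g (%s), CV ~ U(%.3g, %.3g)\n",
    x$T_occasions, x$r,
    if (x$r == 1) "null, no trend" else
      sprintf("%.1f%% overall decline", 100 * (1 - x$r)),
    x$cv_lower, x$cv_upper))
  invisible(x)
}

#' True remaining proportion at occasion t
#'
#' Under the geometric-decline model the true proportion of the population
#' at occasion `t`, relative to the baseline at `t = 1`, is
#' `r^((t - 1)/(T - 1))`: it equals 1 at the first occasion and `r` at the
#' last.
#'
#' @param r Remaining fraction at the end of the period (positive).
#' @param t Sampling occasion, in `1:T_occasions` (vectorised).
#' @param T_occasions Total number of occasions (at least 2).
#' @return The proportion `r^((t - 1)/(T_occasions - 1))`.
#' @examples
#' true_proportion(0.5, 1, 10)   # 1
#' true_proportion(0.5, 10, 10)  # 0.5
#' @export
true_proportion <- function(r, t, T_occasions) {
  if (!is.numeric(r) || any(r <= 0)) stop("r must be positive")
  if (T_occasions < 2) stop("T_occasions must be >= 2")
  if (any(t < 1 | t > T_occasions)) stop("t must lie in [1, T_occasions]")
  r ^ ((t - 1) / (T_occasions - 1))
}

#' Convert a coefficient of variation to a lognormal sdlog
#'
#' Maps the CV of a lognormally distributed estimate to the standard
#' deviation of its logarithm via the identity
#' `sigma = sqrt(log(1 + cv^2))`.
#'
#' @param cv Coefficient of variation (non-negative, vectorised).
#' @return The corresponding `sdlog`, monotone increasing in `cv`.
#' @export
cv_to_sdlog <- function(cv) {
  if (!is.numeric(cv) || any(cv < 0)) stop("cv must be >= 0")
  sqrt(log1p(cv^2))
}

#' Simulate one ratio series under a scenario
#'
#' Draws one synthetic series of abundance estimates and returns it in the
#' form the trend regression consumes: scaled times `x_t = (t-1)/(T-1)` in
#' `[0, 1]` and log ratios `log(y_t / y_1)`. Each occasion's estimate is
#' `baseline * p_t * exp(eps_t)` with `eps_t ~ Normal(0, sdlog_t^2)` and
#' `sdlog_t` derived from a CV drawn uniformly in
#' `[cv_lower, cv_upper]` — so estimates are median-unbiased on the natural
#' scale. Crucially, the baseline noise `eps_1` is shared through the
#' denominator of every ratio, which correlates the log ratios and drives
#' the inflated type-I error of the naive regression.
#'
#' Randomness comes from the R session RNG; call [set.seed()] (or use
#' [run_scenario()] / [run_grid()], which manage seeds) for
#' reproducibility.
#'
#' @param scen A [scenario()].
#' @param exact_baseline If `TRUE` the first estimate carries no noise
#'   (`eps_1 = 0`), giving independent errors across occasions. Used for
#'   calibration checks; the study design itself has `FALSE`.
#' @return An object of class `"ratio_series"`: list with `x`, `log_ratio`
#'   and `T_occasions`. `log_ratio[1]` is exactly 0.
#' @export
simulate_series <- function(scen, exact_baseline = FALSE) {
  stopifnot(inherits(scen, "scenario"))
  Tn <- scen$T_occasions
  tt <- seq_len(Tn)
  p <- true_proportion(scen$r, tt, Tn)
  cvs <- stats::runif(Tn, scen$cv_lower, scen$cv_upper)
  sdl <- cv_to_sdlog(cvs)
  eps <- stats::rnorm(Tn, mean = 0, sd = sdl)
  if (exact_baseline) eps[1L] <- 0
  log_y <- log(scen$baseline_abundance) + log(p) + eps
  log_ratio <- log_y - log_y[1L]
  log_ratio[1L] <- 0
  ratio_series((tt - 1) / (Tn - 1), log_ratio)
}

#' Construct a ratio series
#'
#' Container for the regression input: scaled times in `[0, 1]` and log
#' abundance ratios relative to the first estimate.
#'
#' @param x Scaled times; must start at 0, end at 1 and be strictly
#'   increasing.
#' @param log_ratio Log ratios; the first element must be 0 (the baseline
#'   ratio is identically 1).
#' @return An object of class `"ratio_series"`.
#' @export
ratio_series <- function(x, log_ratio) {
  if (length(x) != length(log_ratio))
    stop("x and log_ratio must have the same length")
  n <- length(x)
  if (n < 2L) stop("a ratio series needs at least 2 points")
  if (abs(x[1L]) > 1e-12 || abs(x[n] - 1) > 1e-12)
    stop("x must start at 0 and end at 1")
  if (any(diff(x) <= 0)) stop("x must be strictly increasing")
  if (abs(log_ratio[1L]) > 1e-12)
    stop("log_ratio[1] must be 0 (ratio to the baseline)")
  structure(list(x = as.numeric(x), log_ratio = as.numeric(log_ratio),
                 T_occasions = n),
            class = "ratio_series")
}

#' @export
print.ratio_series <- function(x, ...) {
  cat(sprintf("Ratio series with %d occasions\n", x$T_occasions))
  print(data.frame(x = x$x, log_ratio = x$log_ratio), row.names = FALSE)
  invisible(x)
}

#' Configure a factorial scenario grid
#'
#' @param T_values Integer study lengths.
#' @param r_values Overall remaining fractions.
#' @param cv_settings List of `c(lower, upper)` CV bounds.
#' @return An object of class `"scenario_grid_config"`.
#' @seealso [default_grid_config()] for the full published design.
#' @export
scenario_grid_config <- function(T_values, r_values, cv_settings) {
  if (length(T_values) == 0L || length(r_values) == 0L ||
      length(cv_settings) == 0L)
    stop("all grid axes must be non-empty")
  if (!is.list(cv_settings)) cv_settings <- list(cv_settings)
  for (cv in cv_settings)
    if (length(cv) != 2L || cv[1] > cv[2] || cv[1] < 0)
      stop("each cv setting must be c(lower, upper) with 0 <= lower <= upper")
  structure(list(T_values = as.integer(T_values),
                 r_values = as.numeric(r_values),
                 cv_settings = cv_settings),
            class = "scenario_grid_config")
}

#' Default factorial design
#'
#' The full design of the simulation study: study lengths 3 to 30, 38
#' equally spaced remaining fractions from 0.50 to 0.99, and five CV
#' settings (exactly 0.1, then uniform with lower bound 0.1 and upper
#' bounds 0.2 to 0.5), giving 28 x 38 x 5 = 5,320 scenarios.
#'
#' @return A [scenario_grid_config()].
#' @export
default_grid_config <- function() {
  scenario_grid_config(
    T_values = 3:30,
    r_values = seq(0.50, 0.99, length.out = 38),
    cv_settings = list(c(0.1, 0.1), c(0.1, 0.2), c(0.1, 0.3),
                       c(0.1, 0.4), c(0.1, 0.5))
  )
}

#' Expand a grid configuration into scenarios
#'
#' Cartesian product with deterministic ordering: study length varies
#' slowest, then `r`, then the CV setting.
#'
#' @param config A [scenario_grid_config()].
#' @return A list of [scenario()] objects.
#' @export
build_scenario_grid <- function(config) {
  stopifnot(inherits(config, "scenario_grid_config"))
  out <- vector("list",
                length(config$T_values) * length(config$r_values) *
                  length(config$cv_settings))
  i <- 0L
  for (Tv in config$T_values)
    for (rv in config$r_values)
      for (cv in config$cv_settings) {
        i <- i + 1L
        out[[i]] <- scenario(Tv, rv, cv[1], cv[2])
      }
  out
}

#' Convert an annual decline rate to an overall decline
#'
#' An annual decline of `annual_decline` sustained over `years` years
#' yields an overall decline of `1 - (1 - annual_decline)^years`. A 1% per
#' year decline corresponds to overall declines of about 5, 10, 18 and 26%
#' over 5, 10, 20 and 30 years.
#'
#' @param annual_decline Annual fractional decline in `[0, 1)`.
#' @param years Number of years (at least 1).
#' @return Overall decline as a fraction of the initial abundance.
#' @export
annual_rate_to_overall <- function(annual_decline, years) {
  if (any(annual_decline < 0) || any(annual_decline >= 1))
    stop("annual_decline must be in [0, 1)")
  if (any(years < 1)) stop("years must be >= 1")
  1 - (1 - annual_decline) ^ years
}

#' Export simulated replicates as a tidy data frame
#'
#' Debugging aid: simulates `n_reps` series under one scenario and stacks
#' them in long format (replicate, occasion, scaled time, log ratio).
#'
#' @param scen A [scenario()].
#' @param n_reps Number of replicates.
#' @param seed Optional seed applied before simulation.
#' @return A data frame with columns `replicate`, `t`, `x`, `log_ratio`.
#' @export
simulate_tidy <- function(scen, n_reps, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  reps <- lapply(seq_len(n_reps), function(i) {
    s <- simulate_series(scen)
    data.frame(replicate = i, t = seq_len(s$T_occasions),
               x = s$x, log_ratio = s$log_ratio)
  })
  do.call(rbind, reps)
}
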