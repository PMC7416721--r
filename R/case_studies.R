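#' Construct an abundance series
#'
#' A named series of abundance (or density) estimates at strictly
#' increasing survey years, the raw material of a case study. Estimate
#' CVs may be carried along for reporting but are deliberately not used
#' in fitting: the trend model only assumes a rough upper bound on their
#' magnitude.
#'
#' @param years Integer survey years, distinct; sorted on construction
#'   (with a warning if reordering was needed).
#' @param estimates Positive abundance estimates, one per year.
#' @param cv Optional CVs of the estimates.
#' @param name Label for the population.
#' @return An object of class `"abundance_series"`.
#' @export
abundance_series <- function(years, estimates, cv = NULL, name = "series") {
  if (length(years) != length(estimates))
    stop("years and estimates must have the same length")
  if (length(years) < 3L)
    stop("an abundance series needs at least 3 estimates")
  if (anyDuplicated(years)) stop("duplicate years")
  if (any(!is.finite(estimates)) || any(estimates <= 0))
    stop("estimates must be positive and finite")
  if (!is.null(cv) && length(cv) != length(years))
    stop("cv must match years in length")
  o <- order(years)
  if (any(o != seq_along(years))) {
    warning("years were not sorted; reordering")
    years <- years[o]; estimates <- estimates[o]
    if (!is.null(cv)) cv <- cv[o]
  }
  structure(list(name = name, years = as.integer(years),
                 estimates = as.numeric(estimates), cv = cv),
            class = "abundance_series")
}

#' @export
print.abundance_series <- function(x, ...) {
  cat(sprintf("Abundance series '%s': %d estimates, %d-%d\n",
              x$name, length(x$years), x$years[1],
              x$years[length(x$years)]))
  d <- data.frame(year = x$years, estimate = x$estimates)
  if (!is.null(x$cv)) d$cv <- x$cv
  print(d, row.names = FALSE)
  invisible(x)
}

#' Read an abundance series from CSV
#'
#' Expects a header row and columns `year`, `estimate` and optionally
#' `cv` and `name`.
#'
#' @param path CSV file path.
#' @return An [abundance_series()].
#' @export
read_abundance_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "estimate")
  if (!all(need %in% names(d)))
    stop("CSV must have columns 'year' and 'estimate' (header required)")
  abundance_series(d$year, d$estimate,
                   cv = if ("cv" %in% names(d)) d$cv else NULL,
                   name = if ("name" %in% names(d)) d$name[1] else
                     tools::file_path_sans_ext(basename(path)))
}

#' Write an abundance series to CSV
#'
#' @param series An [abundance_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance_csv <- function(series, path) {
  stopifnot(inherits(series, "abundance_series"))
  d <- data.frame(name = series$name, year = series$years,
                  estimate = series$estimates)
  if (!is.null(series$cv)) d$cv <- series$cv
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Transform an abundance series into regression form
#'
#' Scales calendar time to `[0, 1]` over the observed span and expresses
#' each estimate as a log ratio to the first one. Handles unevenly
#' spaced years.
#'
#' @param series An [abundance_series()].
#' @return A [ratio_series()].
#' @examples
#' s <- abundance_series(c(2000, 2002, 2005), c(100, 80, 50))
#' to_ratio_series(s)  # x = (0, 0.4, 1)
#' @export
to_ratio_series <- function(series) {
  stopifnot(inherits(series, "abundance_series"))
  yr <- series$years
  span <- yr[length(yr)] - yr[1]
  x <- (yr - yr[1]) / span
  lr <- log(series$estimates / series$estimates[1])
  lr[1] <- 0
  ratio_series(x, lr)
}

#' Annual growth rate from a trend fit
#'
#' Converts the overall remaining fraction `r_hat` estimated over a study
#' span into a per-year multiplicative growth rate,
#' `r_a = r_hat^(1/span_years)`, with confidence-interval endpoints
#' transformed the same (monotone) way. For unevenly spaced real series
#' the span is the elapsed calendar years between first and last
#' estimate, not the number of estimates.
#'
#' @param fit A [fit_trend()] result.
#' @param span_years Elapsed years of the study period (at least 1).
#' @return An object of class `"growth_report"`: list with `fit`, `r_a`,
#'   `ci_r_a` and `span_years`.
#' @export
annual_growth_rate <- function(fit, span_years) {
  stopifnot(inherits(fit, "trend_fit"))
  if (span_years < 1) stop("span_years must be >= 1")
  structure(list(fit = fit,
                 r_a = fit$r_hat ^ (1 / span_years),
                 ci_r_a = fit$ci_r ^ (1 / span_years),
                 span_years = span_years),
            class = "growth_report")
}

#' @export
print.growth_report <- function(x, ...) {
  cat(sprintf(
    "Annual growth rate %.4f (%g%% CI %.4f-%.4f) over %d years (p = %.3g)\n",
    x$r_a, 100 * x$fit$ci_level, x$ci_r_a[1], x$ci_r_a[2],
    x$span_years, x$fit$p_value))
  invisible(x)
}

#' Expanding-window stability of the annual growth rate
#'
#' Mimics an ongoing monitoring programme: refits the trend on each
#' prefix of the series (the first 3 estimates, then 4, ... up to all N)
#' and reports the annual growth rate of each window using that window's
#' elapsed years. A fit failure in one window is recorded and the
#' analysis continues.
#'
#' @param series An [abundance_series()].
#' @param prior A [trend_prior()] selecting the estimator.
#' @param alpha Significance level (intervals at `1 - alpha`).
#' @param em_variant EM variant for the Cauchy prior, see [fit_trend()].
#' @return A list of [annual_growth_rate()] reports (entries may carry
#'   class `"try-error"` for failed windows), named by window length.
#' @export
expanding_window_stability <- function(series,
                                       prior = weakly_informative_prior(),
                                       alpha = 0.20,
                                       em_variant = c("with_variance",
                                                      "map")) {
  stopifnot(inherits(series, "abundance_series"))
  em_variant <- match.arg(em_variant)
  n <- length(series$years)
  ks <- 3:n
  out <- lapply(ks, function(k) {
    tryCatch({
      sub <- abundance_series(series$years[1:k], series$estimates[1:k],
                              cv = if (!is.null(series$cv))
                                series$cv[1:k] else NULL,
                              name = series$name)
      fit <- fit_trend(to_ratio_series(sub), prior, alpha = alpha,
                       em_variant = em_variant)
      annual_growth_rate(fit, sub$years[k] - sub$years[1])
    }, error = function(e) structure(conditionMessage(e),
                                     class = "try-error"))
  })
  names(out) <- paste0("n", ks)
  out
}

#' Tidy table of an expanding-window analysis
#'
#' @param reports Result of [expanding_window_stability()].
#' @return Data frame with one row per window.
#' @export
stability_table <- function(reports) {
  rows <- lapply(seq_along(reports), function(i) {
    rep <- reports[[i]]
    if (inherits(rep, "try-error"))
      return(data.frame(window = names(reports)[i], n_points = NA,
                        span_years = NA, r_a = NA, r_a_lo = NA,
                        r_a_hi = NA, p_value = NA,
                        error = as.character(rep)))
    data.frame(window = names(reports)[i],
               n_points = rep$fit$df + 1L,
               span_years = rep$span_years, r_a = rep$r_a,
               r_a_lo = rep$ci_r_a[1], r_a_hi = rep$ci_r_a[2],
               p_value = rep$fit$p_value, error = NA_character_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic case-study series
#'
#' Builds a yearly abundance series following a constant annual growth
#' rate with the same median-unbiased lognormal noise model as the
#' simulator, as a synthetic stand-in for published cetacean series
#' (3 to 13 estimates, CVs up to 0.5).
#'
#' @param n_points Number of yearly estimates, between 3 and 13.
#' @param year_start First survey year.
#' @param annual_rate Per-year multiplicative change (e.g., 0.95 for a 5%
#'   annual decline).
#' @param cv CV of each estimate, between 0 and 0.5.
#' @param baseline Abundance in the first year.
#' @param name Series label.
#' @return An [abundance_series()] (randomness from the session RNG; use
#'   [set.seed()] for reproducibility).
#' @export
generate_case_fixture <- function(n_points, year_start = 2004,
                                  annual_rate = 0.95, cv = 0.2,
                                  baseline = 1000, name = "synthetic") {
  if (n_points < 3 || n_points > 13)
    stop("n_points must be between 3 and 13")
  if (cv < 0 || cv > 0.5) stop("cv must be in [0, 0.5]")
  if (annual_rate <= 0) stop("annual_rate must be positive")
  yrs <- year_start + seq_len(n_points) - 1L
  truth <- baseline * annual_rate ^ (seq_len(n_points) - 1)
  eps <- stats::rnorm(n_points, 0, cv_to_sdlog(cv))
  abundance_series(yrs, truth * exp(eps),
                   cv = rep(cv, n_points), name = name)
}
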