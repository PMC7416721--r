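#' Construct a prior on the trend slope
#'
#' Priors are placed directly on the slope `beta = log(r)` of the
#' no-intercept log-ratio regression, so their scales have absolute
#' meaning: `log(2)` is a halving or doubling of the population over the
#' study period. Three families are supported: `"none"` (maximum
#' likelihood, no regularization), `"normal"` (informative ridge-type
#' shrinkage) and `"cauchy"` (weakly informative, heavy tailed: strong
#' shrinkage of weak signals, little shrinkage of strong ones).
#'
#' @param family One of `"none"`, `"normal"`, `"cauchy"`.
#' @param location Prior location on the log-r scale (default 0, i.e. no
#'   trend).
#' @param scale Positive prior scale; required for `"normal"` and
#'   `"cauchy"` unless `xi` is given.
#' @param xi For the Cauchy family only: the skeptical prior probability
#'   that the population at least halves or doubles, i.e.
#'   `P(beta > log 2) = xi`. When supplied, `scale` is derived via
#'   [cauchy_scale_from_xi()].
#' @return An object of class `"trend_prior"`.
#' @examples
#' informative_prior()                 # normal, scale log(2)/2
#' weakly_informative_prior(xi = 0.025)
#' @export
trend_prior <- function(family = c("none", "normal", "cauchy"),
                        location = 0, scale = NULL, xi = NULL) {
  family <- match.arg(family)
  if (family == "none") {
    if (!is.null(scale) || !is.null(xi))
      stop("family 'none' takes no scale or xi")
    return(structure(list(family = "none", location = NA_real_,
                          scale = NA_real_, xi = NULL),
                     class = "trend_prior"))
  }
  if (!is.null(xi)) {
    if (family != "cauchy") stop("xi applies to the cauchy family only")
    scale <- cauchy_scale_from_xi(xi)
  }
  if (is.null(scale) || !is.finite(scale) || scale <= 0)
    stop("scale must be a positive finite number (or supply xi)")
  structure(list(family = family, location = location, scale = scale,
                 xi = xi),
            class = "trend_prior")
}

#' @export
print.trend_prior <- function(x, ...) {
  if (x$family == "none") {
    cat("Trend prior: none (unregularized maximum likelihood)\n")
  } else {
    cat(sprintf("Trend prior: %s(location = %g, scale = %.6g)%s\n",
                x$family, x$location, x$scale,
                if (!is.null(x$xi)) sprintf(" [xi = %g]", x$xi) else ""))
  }
  invisible(x)
}

#' The informative normal prior
#'
#' Normal prior centred on 0 with scale `log(2)/2`, chosen so that the
#' central two-standard-deviation range spans a halving to a doubling of
#' the population over the study period.
#'
#' @return A `"trend_prior"` of family `"normal"`.
#' @export
informative_prior <- function() {
  trend_prior("normal", location = 0, scale = log(2) / 2)
}

#' The weakly-informative Cauchy prior
#'
#' Cauchy prior centred on 0 whose scale encodes a small skeptical
#' probability `xi` that the population at least halves (or doubles) over
#' the study period. At `xi = 0.025` the null of no change holds a priori
#' with odds `(1 - xi)/xi = 39:1`.
#'
#' @param xi Skeptical tail probability in (0, 0.5); default 0.025.
#' @return A `"trend_prior"` of family `"cauchy"`.
#' @export
weakly_informative_prior <- function(xi = 0.025) {
  trend_prior("cauchy", location = 0, xi = xi)
}

#' Cauchy scale from a skeptical tail probability
#'
#' Solves `P(X > log 2) = xi` for the scale of a Cauchy distribution
#' centred at 0, giving `-log(2) / tan(pi * (xi - 1/2))`.
#'
#' @param xi Tail probability, strictly between 0 and 0.5.
#' @return The positive Cauchy scale.
#' @examples
#' cauchy_scale_from_xi(0.25)  # log(2)
#' @export
cauchy_scale_from_xi <- function(xi) {
  if (!is.numeric(xi) || any(xi <= 0) || any(xi >= 0.5))
    stop("xi must lie strictly between 0 and 0.5")
  -log(2) / tan(pi * (xi - 0.5))
}

#' Prior tail probability of the slope
#'
#' `P(beta > threshold)` under a normal or Cauchy trend prior. For the
#' Cauchy prior built from `xi`, `prior_tail_probability(prior, log(2))`
#' returns `xi` by construction.
#'
#' @param prior A [trend_prior()] with family `"normal"` or `"cauchy"`.
#' @param threshold Threshold on the log-r scale.
#' @return The upper-tail probability.
#' @export
prior_tail_probability <- function(prior, threshold) {
  stopifnot(inherits(prior, "trend_prior"))
  if (prior$family == "none")
    stop("family 'none' has no prior density")
  switch(prior$family,
    normal = stats::pnorm(threshold, mean = prior$location,
                          sd = prior$scale, lower.tail = FALSE),
    cauchy = stats::pcauchy(threshold, location = prior$location,
                            scale = prior$scale, lower.tail = FALSE)
  )
}

#' Prior density of the slope
#'
#' @param prior A [trend_prior()] with family `"normal"` or `"cauchy"`.
#' @param beta Slope values on the log-r scale.
#' @return Density values.
#' @export
prior_density <- function(prior, beta) {
  stopifnot(inherits(prior, "trend_prior"))
  if (prior$family == "none")
    stop("family 'none' has no prior density")
  switch(prior$family,
    normal = stats::dnorm(beta, mean = prior$location, sd = prior$scale),
    cauchy = stats::dcauchy(beta, location = prior$location,
                            scale = prior$scale)
  )
}
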