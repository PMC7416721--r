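# Independent oracles used across tests. They share no code with the
# package's fitters: maximization is by brute-force grid search or
# stats::optimize over the penalized log-likelihood profile, with the
# dispersion made self-consistent by outer iteration started from the
# null (beta = 0), the same starting point the fitters declare.

# Brute-force MAP under a Cauchy(0, scale) prior. The residual sum of
# squares is quadratic in the slope, so the grid of RSS values is exact.
# On conflicted data the penalized surface can be bimodal; like the
# fitter, the oracle starts at the null and follows its own basin (the
# local maximum nearest the current iterate), with the dispersion made
# self-consistent by outer iteration.
grid_map_cauchy <- function(series, scale, df, lim = 1, step = 1e-5) {
  x <- series$x
  y <- series$log_ratio
  bgrid <- seq(-lim, lim, by = step)
  rss_grid <- sum(y^2) - 2 * bgrid * sum(x * y) + bgrid^2 * sum(x^2)
  sigma2 <- sum(y^2) / df
  b <- 0
  nearest_local_max <- function(obj, from) {
    n <- length(obj)
    is_max <- c(obj[1] >= obj[2],
                obj[2:(n - 1)] >= obj[1:(n - 2)] &
                  obj[2:(n - 1)] >= obj[3:n],
                obj[n] >= obj[n - 1])
    cand <- which(is_max)
    cand[which.min(abs(bgrid[cand] - from))]
  }
  for (k in 1:200) {
    obj <- -rss_grid / (2 * sigma2) - log(1 + (bgrid / scale)^2)
    bn <- bgrid[nearest_local_max(obj, b)]
    sigma2 <- sum((y - bn * x)^2) / df
    if (abs(bn - b) < 1e-9) break
    b <- bn
  }
  bn
}

# 1-D numerical maximizer of the normal-prior penalized profile.
numeric_map_normal <- function(series, scale, df, lim = 2) {
  x <- series$x
  y <- series$log_ratio
  sigma2 <- sum(y^2) / df
  b <- 0
  for (k in 1:200) {
    obj <- function(beta)
      -sum((y - beta * x)^2) / (2 * sigma2) - beta^2 / (2 * scale^2)
    bn <- stats::optimize(obj, c(-lim, lim), maximum = TRUE,
                          tol = 1e-10)$maximum
    sigma2 <- sum((y - bn * x)^2) / df
    if (abs(bn - b) < 1e-10) break
    b <- bn
  }
  bn
}

# Minimal hand-built fit object for exercising the metric arithmetic
# without running the fitters.
fake_fit <- function(p_value, beta_hat, alpha, ci_halfwidth = 0.05) {
  structure(
    list(beta_hat = beta_hat, se = ci_halfwidth, df = 9L,
         p_value = p_value, ci_level = 1 - alpha,
         ci_beta = beta_hat + c(-1, 1) * ci_halfwidth,
         r_hat = exp(beta_hat),
         ci_r = exp(beta_hat + c(-1, 1) * ci_halfwidth),
         prior = trend_prior("none"), n_iter = 0L, converged = TRUE,
         degenerate = FALSE),
    class = "trend_fit")
}

# Noiseless geometric ratio series for a given overall remaining
# fraction.
noiseless_series <- function(r, T_occasions) {
  x <- (seq_len(T_occasions) - 1) / (T_occasions - 1)
  ratio_series(x, x * log(r))
}
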