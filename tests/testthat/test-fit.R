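test_that("maximum likelihood fit matches the closed form through the origin", {
  s <- ratio_series(c(0, 0.5, 1), c(0, -0.2, -0.5))
  f <- fit_unregularized(s, alpha = 0.05)
  # beta = (0.5*-0.2 + 1*-0.5) / (0.25 + 1) = -0.48
  expect_equal(f$beta_hat, -0.48, tolerance = 1e-12)
  expect_equal(f$r_hat, 0.61878, tolerance = 1e-5)
  # RSS = (-0.2 + 0.24)^2 + (-0.5 + 0.48)^2 = 0.0020
  rss <- 0.04^2 + 0.02^2
  expect_equal(f$se, sqrt((rss / 2) / 1.25), tolerance = 1e-12)
  expect_equal(f$se, 0.028284, tolerance = 1e-4)
  expect_identical(f$df, 2L)
  # independent t-CDF evaluation of the two-tailed p
  expect_equal(f$p_value, 2 * pt(-abs(-0.48 / f$se), 2),
               tolerance = 1e-12)
  expect_equal(f$p_value, 0.00345, tolerance = 1e-2)
})

test_that("closed-form equivalence holds on random inputs", {
  set.seed(31)
  for (i in 1:50) {
    Tn <- sample(3:20, 1)
    x <- (seq_len(Tn) - 1) / (Tn - 1)
    y <- c(0, rnorm(Tn - 1, sd = 0.4))
    s <- ratio_series(x, y)
    f <- fit_unregularized(s)
    expect_equal(f$beta_hat, sum(x * y) / sum(x^2), tolerance = 1e-12)
  }
})

test_that("noiseless data give an exact, degenerate fit for every estimator", {
  s <- noiseless_series(0.5, 5)
  for (f in list(fit_unregularized(s),
                 fit_normal_prior(s),
                 fit_cauchy_prior(s, em_variant = "map"),
                 fit_cauchy_prior(s, em_variant = "with_variance"))) {
    expect_equal(f$beta_hat, log(0.5), tolerance = 1e-10)
    expect_true(f$degenerate)
    expect_identical(f$se, 0)
    expect_identical(f$p_value, 0)
  }
})

test_that("an all-zero response returns the null trend", {
  s <- ratio_series(c(0, 0.5, 1), c(0, 0, 0))
  f <- fit_unregularized(s)
  expect_identical(f$beta_hat, 0)
  expect_identical(f$r_hat, 1)
  fc <- fit_cauchy_prior(s)
  expect_identical(fc$beta_hat, 0)
})

test_that("a vanishing penalty recovers maximum likelihood", {
  set.seed(8)
  s <- ratio_series(c(0, 0.25, 0.5, 0.75, 1),
                    c(0, rnorm(4, sd = 0.3)))
  ml <- fit_unregularized(s)
  wide_n <- fit_trend(s, trend_prior("normal", scale = 1e8))
  expect_equal(wide_n$beta_hat, ml$beta_hat, tolerance = 1e-6)
  expect_equal(wide_n$se, ml$se, tolerance = 1e-6)
  for (v in c("map", "with_variance")) {
    wide_c <- fit_trend(s, trend_prior("cauchy", scale = 1e8),
                        em_variant = v)
    expect_equal(wide_c$beta_hat, ml$beta_hat, tolerance = 1e-6)
    expect_equal(wide_c$se, ml$se, tolerance = 1e-6)
  }
})

test_that("a vanishing prior scale shrinks the slope to zero", {
  s <- ratio_series(c(0, 0.5, 1), c(0, -0.2, -0.5))
  tiny_n <- fit_trend(s, trend_prior("normal", scale = 1e-8))
  expect_lt(abs(tiny_n$beta_hat), 1e-6)
  tiny_c <- fit_trend(s, trend_prior("cauchy", scale = 1e-8))
  expect_lt(abs(tiny_c$beta_hat), 1e-6)
})

test_that("normal-prior ridge agrees with an independent numerical maximizer", {
  s <- ratio_series(c(0, 0.5, 1), c(0, -0.2, -0.5))
  f <- fit_normal_prior(s)
  expect_lt(abs(f$beta_hat), 0.48)  # shrunk toward 0
  expect_equal(f$beta_hat,
               numeric_map_normal(s, log(2) / 2, df = 2),
               tolerance = 1e-6)
  set.seed(55)
  for (i in 1:30) {
    Tn <- sample(3:12, 1)
    x <- (seq_len(Tn) - 1) / (Tn - 1)
    y <- c(0, x[-1] * rnorm(1, 0, 0.3) + rnorm(Tn - 1, sd = 0.3))
    s <- ratio_series(x, y)
    f <- fit_normal_prior(s)
    expect_equal(f$beta_hat,
                 numeric_map_normal(s, log(2) / 2, df = Tn - 1),
                 tolerance = 1e-5)
  }
})

test_that("Cauchy EM fixed points match brute-force grid-search MAP", {
  sc <- cauchy_scale_from_xi(0.025)
  s <- ratio_series(c(0, 0.5, 1), c(0, -0.2, -0.5))
  f <- fit_cauchy_prior(s, em_variant = "map")
  expect_lt(abs(f$beta_hat - grid_map_cauchy(s, sc, df = 2)), 1e-4)
  set.seed(77)
  for (i in 1:100) {
    Tn <- sample(3:12, 1)
    x <- (seq_len(Tn) - 1) / (Tn - 1)
    beta_true <- rnorm(1, 0, 0.3)
    y <- c(0, x[-1] * beta_true + rnorm(Tn - 1, sd = 0.25))
    s <- ratio_series(x, y)
    f <- fit_cauchy_prior(s, em_variant = "map")
    expect_lt(abs(f$beta_hat - grid_map_cauchy(s, sc, df = Tn - 1)),
              1e-4)
  }
})

test_that("the EM fixed point solves the penalized score equation", {
  set.seed(19)
  sc <- cauchy_scale_from_xi(0.025)
  for (i in 1:20) {
    x <- (0:9) / 9
    y <- c(0, x[-1] * -0.4 + rnorm(9, sd = 0.2))
    s <- ratio_series(x, y)
    f <- fit_cauchy_prior(s, em_variant = "map")
    b <- f$beta_hat
    sigma2 <- sum((y - b * x)^2) / 9
    score <- sum(x * (y - b * x)) / sigma2 - 2 * b / (sc^2 + b^2)
    expect_lt(abs(score), 1e-4)
  }
})

test_that("regularized slopes never exceed the ML slope in magnitude", {
  set.seed(91)
  for (i in 1:60) {
    Tn <- sample(3:15, 1)
    x <- (seq_len(Tn) - 1) / (Tn - 1)
    y <- c(0, rnorm(Tn - 1, sd = 0.5))
    s <- ratio_series(x, y)
    ml <- abs(fit_unregularized(s)$beta_hat)
    for (f in list(fit_normal_prior(s),
                   fit_cauchy_prior(s, em_variant = "map"),
                   fit_cauchy_prior(s, em_variant = "with_variance"))) {
      expect_lte(abs(f$beta_hat), ml + 1e-12)
    }
  }
})

test_that("shrinkage is monotone in the prior scale", {
  set.seed(14)
  x <- (0:7) / 7
  y <- c(0, x[-1] * -0.5 + rnorm(7, sd = 0.25))
  s <- ratio_series(x, y)
  scales <- 10^seq(-4, 4, by = 0.25)
  for (fam in c("normal", "cauchy")) {
    b <- vapply(scales, function(sc)
      abs(fit_trend(s, trend_prior(fam, scale = sc))$beta_hat),
      numeric(1))
    expect_true(all(diff(b) > -1e-8))
    expect_lt(b[1], 1e-6)
    expect_equal(b[length(b)], abs(fit_unregularized(s)$beta_hat),
                 tolerance = 1e-6)
  }
})

test_that("CI exclusion of zero is dual to significance for the ML fit", {
  set.seed(23)
  for (i in 1:40) {
    Tn <- sample(3:12, 1)
    x <- (seq_len(Tn) - 1) / (Tn - 1)
    y <- c(0, x[-1] * rnorm(1, 0, 0.4) + rnorm(Tn - 1, sd = 0.3))
    for (a in c(0.05, 0.20)) {
      f <- fit_unregularized(ratio_series(x, y), alpha = a)
      excludes <- f$ci_beta[1] > 0 || f$ci_beta[2] < 0
      expect_identical(excludes, is_significant(f, a))
    }
  }
})

test_that("significance uses a strict inequality", {
  f <- fake_fit(p_value = 0.05, beta_hat = -0.1, alpha = 0.05)
  expect_false(is_significant(f, 0.05))
  f$p_value <- 0.03
  expect_true(is_significant(f, 0.05))
  f$p_value <- 0.19
  expect_true(is_significant(f, 0.20))
})

test_that("fit objects carry coherent intervals on both scales", {
  set.seed(5)
  x <- (0:9) / 9
  y <- c(0, x[-1] * -0.3 + rnorm(9, sd = 0.2))
  s <- ratio_series(x, y)
  for (f in list(fit_unregularized(s), fit_normal_prior(s),
                 fit_cauchy_prior(s))) {
    expect_true(f$ci_beta[1] <= f$beta_hat &&
                  f$beta_hat <= f$ci_beta[2])
    expect_equal(f$ci_r, exp(f$ci_beta), tolerance = 1e-12)
    expect_gt(f$r_hat, 0)
    expect_true(f$p_value >= 0 && f$p_value <= 1)
  }
})

test_that("fits with too few points are rejected", {
  expect_error(ratio_series(c(0, 1), c(0, -1)) |> fit_unregularized(),
               "at least 3")
})
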