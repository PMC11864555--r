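# bins following an exact concave quadratic on centres 12.5..23.5
quad_bins <- function(b1 = 0.1, b2 = 0.04, b3 = -0.001,
                      lefts = 12:23, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- lefts + 0.5
  y <- b1 + b2 * x + b3 * x^2
  if (noise_sd > 0) y <- y + rnorm(length(y), 0, noise_sd)
  data.frame(bin_left = lefts, volume = y)
}

test_that("an exact quadratic is interpolated to machine precision", {
  f <- fit_response(quad_bins(), "polynomial", min_volume_frac = 0)
  expect_equal(f$coefficients$estimate, c(0.1, 0.04, -0.001),
               tolerance = 1e-8)
  expect_lt(f$mse, 1e-20)
  expect_equal(f$coefficients$term, c("b1", "b2", "b3"))
})

test_that("constant volumes give a flat response", {
  bins <- data.frame(bin_left = 14:20, volume = rep(0.25, 7))
  f <- fit_response(bins, "polynomial", min_volume_frac = 0)
  expect_equal(f$coefficients$estimate[1], 0.25)
  expect_equal(f$coefficients$estimate[2], 0, tolerance = 1e-10)
  expect_equal(f$coefficients$estimate[3], 0, tolerance = 1e-10)
})

test_that("polynomial least squares matches the normal-equations oracle", {
  set.seed(91)
  for (i in 1:25) {
    lefts <- sort(sample(10:25, 9))
    bins <- data.frame(bin_left = lefts,
                       volume = runif(9, 0, 0.3))
    f <- fit_response(bins, "polynomial", min_volume_frac = 0)
    x <- lefts + 0.5
    X <- cbind(1, x, x^2)
    beta <- solve(t(X) %*% X, t(X) %*% bins$volume)
    expect_equal(f$coefficients$estimate, as.numeric(beta), tolerance = 1e-8)
    expect_equal(f$mse, mean((bins$volume - X %*% beta)^2), tolerance = 1e-8)
  }
})

test_that("AIC identity holds and is invariant to bin order", {
  bins <- quad_bins(noise_sd = 0.01, seed = 4)
  for (fam in c("polynomial", "exponential", "logistic")) {
    f <- fit_response(bins, fam, min_volume_frac = 0)
    expect_lt(abs(f$aic - (2 * f$k - 2 * f$log_likelihood)), 1e-8)
  }
  shuffled <- bins[sample(nrow(bins)), ]
  a <- fit_response(bins, "polynomial", min_volume_frac = 0)$aic
  b <- fit_response(shuffled, "polynomial", min_volume_frac = 0)$aic
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("too few bins is a fit error", {
  bins <- quad_bins()[1:3, ]
  expect_error(fit_response(bins, "polynomial"), "too few")
  expect_error(fit_response(quad_bins()[1:2, ], "exponential"), "too few")
})

test_that("peak_temperature is the analytic vertex and requires concavity", {
  mk <- function(b1, b2, b3)
    fit_response(quad_bins(b1, b2, b3, lefts = 10:25), "polynomial",
                 min_volume_frac = 0)
  expect_equal(peak_temperature(mk(0.3, 4.2, -0.105)), 20.0, tolerance = 1e-6)
  expect_equal(peak_temperature(mk(0.3, 0, -1)), 0.0, tolerance = 1e-6)
  expect_error(peak_temperature(mk(0.1, 0.01, 0.002)), "interior peak")
  expect_error(peak_temperature(structure(list(family = "logistic"),
                                          class = "chum_nla")),
               "polynomial")
})

test_that("coefficient p-values agree with the reference t computation", {
  bins <- quad_bins(noise_sd = 0.005, seed = 12)
  f <- fit_response(bins, "polynomial", min_volume_frac = 0)
  co <- f$coefficients
  df <- f$n_bins - 3
  p_ref <- 2 * pt(-abs(co$estimate / co$se), df)
  expect_equal(co$p, p_ref, tolerance = 1e-6)
})

test_that("family selection recovers the generating shape", {
  # concave quadratic + small noise: polynomial should win almost always
  picks <- vapply(1:100, function(s) {
    bins <- quad_bins(0.05, 0.045, -0.0012, lefts = 12:23,
                      noise_sd = 0.005, seed = s)
    fits <- lapply(c("polynomial", "exponential", "logistic"), function(fam)
      tryCatch(fit_response(bins, fam, min_volume_frac = 0),
               error = function(e) NULL))
    compare_families(Filter(Negate(is.null), fits))$family
  }, character(1))
  expect_gte(mean(picks == "polynomial"), 0.9)

  # monotone saturating curve: logistic should win the majority
  picks2 <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    x <- 12:23 + 0.5
    y <- 0.3 / (1 + exp(-1.2 * (x - 18))) + rnorm(12, 0, 0.005)
    bins <- data.frame(bin_left = 12:23, volume = y)
    fits <- lapply(c("polynomial", "exponential", "logistic"), function(fam)
      tryCatch(fit_response(bins, fam, min_volume_frac = 0),
               error = function(e) NULL))
    compare_families(Filter(Negate(is.null), fits))$family
  }, character(1))
  expect_gt(mean(picks2 == "logistic"), 0.5)
})

test_that("a single converged fit is returned with the single-candidate flag", {
  f <- fit_response(quad_bins(), "polynomial", min_volume_frac = 0)
  sel <- compare_families(list(f))
  expect_true(attr(sel, "single_candidate"))
  expect_equal(sel$family, "polynomial")
  expect_error(compare_families(list()), "no converged")
})

test_that("high-MSE comparisons are flagged against the 0.002 benchmark", {
  noisy <- quad_bins(noise_sd = 0.08, seed = 2)
  clean <- quad_bins(noise_sd = 0.001, seed = 2)
  sel_noisy <- compare_families(list(
    fit_response(noisy, "polynomial", min_volume_frac = 0)))
  sel_clean <- compare_families(list(
    fit_response(clean, "polynomial", min_volume_frac = 0)))
  expect_true(attr(sel_noisy, "comparison")$mse_flag)
  expect_false(attr(sel_clean, "comparison")$mse_flag)
})

test_that("the estimated peak converges to the pulse temperature as bin
           noise shrinks", {
  true_peak <- 18.5
  err_at <- function(sd) {
    # bin centres symmetric about the true peak, so the quadratic vertex is
    # unbiased in the noise-free limit
    mean(vapply(1:30, function(s) {
      set.seed(s)
      x <- 12:24 + 0.5
      y <- 0.28 * exp(-(x - true_peak)^2 / 8) + rnorm(13, 0, sd)
      f <- fit_response(data.frame(bin_left = 12:24, volume = y),
                        "polynomial", min_volume_frac = 0)
      abs(peak_temperature(f) - true_peak)
    }, numeric(1)))
  }
  errs <- vapply(c(0.02, 0.005, 0.001), err_at, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.1)
})
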