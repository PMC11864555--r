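#' Fit a thermal-response family to temperature-binned migration volumes
#'
#' Least-squares fit of normalised migration volume on bin-centre SST, for
#' one of three families:
#' * `polynomial` — `y = b1 + b2 x + b3 x^2` (intercept, linear, quadratic);
#' * `exponential` — `y = a exp(b x)`;
#' * `logistic` — `y = L / (1 + exp(-k (x - x0)))`.
#'
#' Bin centres (left edge + width/2) are the regression abscissae. Empty
#' bins are absent from the input rather than treated as zeros, and bins
#' holding less than `min_volume_frac` of the largest bin are likewise
#' excluded: a handful of stray fish caught far from the migration pulse
#' otherwise contributes long near-zero tails that drag the fitted curve
#' away from the thermal response (set `min_volume_frac = 0` to fit every
#' non-empty bin). AIC is
#' computed from the Gaussian log-likelihood of the residuals with the error
#' variance estimated by maximum likelihood, and the parameter count
#' includes that variance, so AIC is comparable across families with
#' different numbers of coefficients. The nonlinear families use five
#' deterministic starts spanning the data range to avoid silent local
#' minima.
#'
#' @param bins data.frame with columns `bin_left` and `volume` for one
#'   region-regime (as produced by [bin_by_temperature()]).
#' @param family `"polynomial"`, `"exponential"` or `"logistic"`.
#' @param bin_width deg C, used to place bin centres.
#' @param min_volume_frac bins below this fraction of the largest bin's
#'   volume are excluded from the regression (default 0.01).
#' @return an object of class `"chum_nla"`: list with `family`,
#'   `coefficients` (term, estimate, se, p), `mse`, `log_likelihood`, `k`,
#'   `aic`, `n_bins`, `fit`, and any `region`/`regime` columns carried
#'   through.
#' @export
fit_response <- function(bins, family = c("polynomial", "exponential",
                                          "logistic"), bin_width = 1,
                         min_volume_frac = 0.01) {
  family <- match.arg(family)
  if (!all(c("bin_left", "volume") %in% names(bins)))
    stopf("bins must have columns bin_left and volume")
  if (min_volume_frac > 0 && max(bins$volume) > 0) {
    keep <- bins$volume >= min_volume_frac * max(bins$volume)
    bins <- bins[keep, , drop = FALSE]
  }
  x <- bins$bin_left + bin_width / 2
  y <- bins$volume
  n <- length(x)
  npar <- c(polynomial = 3L, exponential = 2L, logistic = 3L)[[family]]
  if (n < npar + 1L)
    stopf("too few non-empty bins (%d) to fit a %d-parameter %s model",
          n, npar, family)
  d <- data.frame(x = x, y = y)

  fit <- switch(family,
    polynomial = stats::lm(y ~ x + I(x^2), data = d),
    exponential = fit_exponential(d),
    logistic = fit_logistic(d))

  res <- y - stats::predict(fit, d)
  rss <- sum(res^2)
  mse <- rss / n
  ll <- stats::logLik(fit)          # Gaussian ML; df counts sigma
  k <- attr(ll, "df")
  aic <- 2 * k - 2 * as.numeric(ll)

  sm <- summary(fit)$coefficients
  term <- switch(family,
    polynomial = c("b1", "b2", "b3"),
    exponential = c("a", "b"),
    logistic = c("L", "k", "x0"))
  coefs <- data.frame(term = term, estimate = sm[, 1], se = sm[, 2],
                      p = sm[, 4], stringsAsFactors = FALSE)
  rownames(coefs) <- NULL

  structure(list(family = family,
                 region = bins$region[1] %||% NA_character_,
                 regime = bins$regime[1] %||% NA_character_,
                 coefficients = coefs, mse = mse,
                 log_likelihood = as.numeric(ll), k = k, aic = aic,
                 n_bins = n, fit = fit), class = "chum_nla")
}

# exponential y = a exp(bx): log-linear seed plus deterministic b-starts
fit_exponential <- function(d) {
  pos <- d$y > 0
  b0 <- if (sum(pos) >= 2)
    stats::coef(stats::lm(log(y) ~ x, data = d[pos, ]))[2] else 0.1
  span <- diff(range(d$x)); span <- if (span > 0) span else 1
  starts <- unique(c(b0, -2 / span, -0.5 / span, 0.5 / span, 2 / span))
  best <- NULL
  for (b in starts) {
    a <- mean(d$y) / mean(exp(b * d$x))
    f <- tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(b * x), data = d,
                        start = list(a = a, b = b),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(f)) {
      rss <- sum(stats::residuals(f)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = f, rss = rss)
    }
  }
  if (is.null(best)) stopf("exponential fit failed to converge")
  best$fit
}

# logistic y = L / (1 + exp(-k (x - x0))): starts span both signs of k and
# the observed x range
fit_logistic <- function(d) {
  span <- diff(range(d$x)); span <- if (span > 0) span else 1
  qs <- stats::quantile(d$x, c(0.25, 0.5, 0.75), names = FALSE)
  Lmax <- max(d$y) * 1.05
  starts <- list(
    list(L = Lmax, k = 4 / span, x0 = qs[2]),
    list(L = Lmax, k = -4 / span, x0 = qs[2]),
    list(L = Lmax, k = 1 / span, x0 = qs[1]),
    list(L = Lmax, k = -1 / span, x0 = qs[3]),
    list(L = Lmax * 1.5, k = 8 / span, x0 = qs[2]))
  best <- NULL
  for (s in starts) {
    f <- tryCatch(
      minpack.lm::nlsLM(y ~ L / (1 + exp(-k * (x - x0))), data = d,
                        start = s,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(f)) {
      rss <- sum(stats::residuals(f)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = f, rss = rss)
    }
  }
  if (is.null(best)) stopf("logistic fit failed to converge")
  best$fit
}

#' Compare thermal-response families by AIC
#'
#' Selects the converged fit with minimal AIC (ties broken by fewer
#' parameters, then by family order polynomial, exponential, logistic) and
#' attaches the full comparison table, including each family's MSE and a
#' flag where the MSE exceeds the 0.002 reporting benchmark on the 0-1
#' volume scale.
#'
#' @param fits list of `"chum_nla"` fits on the same bins.
#' @return the selected `"chum_nla"`, with attributes `comparison`
#'   (data.frame: family, k, logLik, AIC, MSE, mse_flag, selected) and
#'   `single_candidate` (TRUE when only one fit was supplied).
#' @export
compare_families <- function(fits) {
  if (!length(fits)) stopf("no converged fits to compare")
  fam_order <- c(polynomial = 1L, exponential = 2L, logistic = 3L)
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  k <- vapply(fits, function(f) as.numeric(f$k), numeric(1))
  fam <- vapply(fits, `[[`, character(1), "family")
  best_aic <- min(aic)
  cand <- which(aic <= best_aic + 1e-8)
  cand <- cand[order(k[cand], fam_order[fam[cand]])]
  sel <- fits[[cand[1]]]
  comparison <- data.frame(
    family = fam, k = k,
    logLik = vapply(fits, `[[`, numeric(1), "log_likelihood"),
    AIC = aic,
    MSE = vapply(fits, `[[`, numeric(1), "mse"),
    stringsAsFactors = FALSE)
  comparison$mse_flag <- comparison$MSE > 0.002
  comparison$selected <- seq_along(fits) == cand[1]
  attr(sel, "comparison") <- comparison
  attr(sel, "single_candidate") <- length(fits) == 1L
  sel
}

#' Peak temperature of a quadratic thermal response
#'
#' The vertex `-b2 / (2 b3)` of the fitted quadratic; defined only for a
#' concave fit (`b3 < 0`), i.e. when migration volume peaks at an interior
#' temperature.
#'
#' @param fit a polynomial `"chum_nla"`.
#' @return deg C.
#' @examples
#' \dontrun{peak_temperature(fit)  # -b2 / (2 b3)}
#' @export
peak_temperature <- function(fit) {
  if (!inherits(fit, "chum_nla") || fit$family != "polynomial")
    stopf("peak temperature is defined for polynomial fits only")
  b <- fit$coefficients$estimate
  if (b[3] >= 0)
    stopf("no interior peak: quadratic coefficient b3 = %.4g is not negative",
          b[3])
  -b[2] / (2 * b[3])
}

#' Fit all families to every region-regime of a binned-volume table
#'
#' @param bins data.frame from [bin_by_temperature()].
#' @param families families to attempt; a family that fails to converge on
#'   some region-regime is dropped from that comparison.
#' @param bin_width deg C.
#' @return list with `selected` (named list of selected fits per
#'   region-regime), `comparison` (long data.frame over region, regime,
#'   family) and `peaks` (data.frame region, regime, selected family, peak
#'   deg C where defined).
#' @export
fit_response_table <- function(bins, families = c("polynomial", "exponential",
                                                  "logistic"), bin_width = 1,
                               min_volume_frac = 0.01) {
  groups <- split(bins, interaction(bins$region, bins$regime, drop = TRUE))
  selected <- list(); comp_l <- list(); peak_l <- list()
  for (g in names(groups)) {
    d <- groups[[g]]
    fits <- list()
    for (fam in families) {
      f <- tryCatch(fit_response(d, fam, bin_width, min_volume_frac),
                    error = function(e) NULL)
      if (!is.null(f)) fits[[fam]] <- f
    }
    if (!length(fits))
      stopf("all response families failed for %s", g)
    sel <- compare_families(unname(fits))
    selected[[g]] <- sel
    cmp <- attr(sel, "comparison")
    cmp$region <- d$region[1]; cmp$regime <- d$regime[1]
    comp_l[[g]] <- cmp
    pk <- if (sel$family == "polynomial" &&
              sel$coefficients$estimate[3] < 0)
      peak_temperature(sel) else NA_real_
    peak_l[[g]] <- data.frame(region = d$region[1], regime = d$regime[1],
                              family = sel$family, peak_sst = pk,
                              stringsAsFactors = FALSE)
  }
  comparison <- do.call(rbind, comp_l)
  rownames(comparison) <- NULL
  peaks <- do.call(rbind, peak_l)
  peaks <- peaks[order(peaks$region, peaks$regime), ]
  rownames(peaks) <- NULL
  list(selected = selected, comparison = comparison, peaks = peaks)
}

#' @export
print.chum_nla <- function(x, ...) {
  cat(sprintf("<chum_nla> %s fit, n_bins = %d, AIC = %.3f, MSE = %.5f\n",
              x$family, x$n_bins, x$aic, x$mse))
  invisible(x)
}
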