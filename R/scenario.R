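#' Construct a synthetic-data scenario
#'
#' A Scenario bundles every parameter of the synthetic generator: the autumn
#' cooling ramp, the regime-specific timing shifts that create the three SST
#' distribution types, and the temperature-cued migration pulses. All timing
#' parameters are integer day offsets from October 1 (day 0; window ends at
#' day 91).
#'
#' Regime timing semantics, relative to each region's climatological crossing
#' day `base_cross_day`:
#' * T1 — whole coast cools `early_shift` days early;
#' * T3 — whole coast cools `late_shift` days late;
#' * T2 — north cools `early_shift` days early while the south cools
#'   `ns_offset` days late (the north-south contrast that defines the type).
#'
#' Coastal arrival pulses are centred on the region's climatological crossing
#' plus `arrival_lag` (per area), advanced by `t2_arrival_advance` days in T2
#' years; river-entry counts are the coastal counts shifted by
#' `residence_mean` days. See [simulate_catch()] for the `arrival_anchor`
#' option.
#'
#' @param n_years number of simulated years.
#' @param regime_sequence character vector of per-year labels in
#'   `c("T1","T2","T3")`, length `n_years`.
#' @param base_cross_day named numeric vector, per-region mean day the SST
#'   first falls below the threshold in an average year.
#' @param early_shift,late_shift,ns_offset regime timing shifts (days).
#' @param sst_start,sst_end mean SST (deg C) at window start/end of the
#'   cooling ramp; must bracket `sst_threshold`.
#' @param sst_shape logistic time-scale of the cooling ramp (days).
#' @param sst_threshold deg C; the crossing threshold the ramp is anchored to.
#' @param sst_noise_sd deg C, sd of i.i.d. daily SST noise.
#' @param run_size expected total fish per region-year.
#' @param arrival_lag days between climatological crossing and coastal pulse
#'   centre; a scalar, or a vector `c(north = , south = )`.
#' @param pulse_sd days, spread of the arrival pulse.
#' @param arrival_jitter_sd days; sd of region-year Gaussian jitter on the
#'   coastal pulse centre (interannual process noise in arrival timing).
#' @param residence_jitter_sd days; sd of region-year jitter on the coastal
#'   residence time (rounded to whole days, so the river pulse stays a pure
#'   shift of the coastal pulse).
#' @param residence_mean named numeric vector, per-region days between coastal
#'   and riverine median migration dates.
#' @param t2_arrival_advance days by which coastal arrival is earlier in T2
#'   years (the injected effect recovered by the mixed-model analysis).
#' @param catch_noise logical; `FALSE` replaces Poisson counts by the rounded
#'   pulse intensity (used with `sst_noise_sd = 0` for exact-identity checks).
#' @param arrival_anchor `"climatology"` (default) anchors arrival pulses on
#'   `base_cross_day`; `"yearly"` anchors on the year's realised crossing day.
#' @param seed master RNG seed; every region-year draws from its own stream
#'   derived from `(seed, region, year)`.
#' @param years calendar years to attach to the simulated seasons (defaults
#'   to consecutive years starting in 2006).
#' @return an object of class `"chum_scenario"`.
#' @export
scenario <- function(n_years = 13L,
                     regime_sequence = rep("T1", n_years),
                     base_cross_day = c(CR1 = 25, CR2 = 28, CR3 = 31,
                                        CR4 = 33, CR5 = 36, CR6 = 39),
                     early_shift = 6,
                     late_shift = 6,
                     ns_offset = 10,
                     sst_start = 24,
                     sst_end = 12,
                     sst_shape = 8,
                     sst_threshold = 20,
                     sst_noise_sd = 0.3,
                     run_size = 1000,
                     arrival_lag = c(north = 4, south = -2),
                     pulse_sd = 4,
                     arrival_jitter_sd = 3,
                     residence_jitter_sd = 2,
                     residence_mean = c(CR1 = 20, CR2 = 12, CR3 = 10,
                                        CR4 = 8, CR5 = 5, CR6 = 4),
                     t2_arrival_advance = 4,
                     catch_noise = TRUE,
                     arrival_anchor = c("climatology", "yearly"),
                     seed = 1L,
                     years = NULL) {
  arrival_anchor <- match.arg(arrival_anchor)
  if (length(arrival_lag) == 1L)
    arrival_lag <- c(north = unname(arrival_lag), south = unname(arrival_lag))
  if (!all(c("north", "south") %in% names(arrival_lag)))
    stopf("arrival_lag must be a scalar or a c(north=, south=) vector")
  n_years <- as.integer(n_years)
  if (length(regime_sequence) != n_years)
    stopf("regime_sequence must have length n_years (%d)", n_years)
  if (!all(regime_sequence %in% c("T1", "T2", "T3")))
    stopf("unknown regime label in regime_sequence: %s",
          paste(setdiff(regime_sequence, c("T1", "T2", "T3")), collapse = ", "))
  if (is.null(years)) years <- seq_len(n_years) + 2005L
  if (length(years) != n_years) stopf("years must have length n_years")

  sc <- structure(list(
    n_years = n_years, years = as.integer(years),
    regime_sequence = as.character(regime_sequence),
    base_cross_day = base_cross_day,
    early_shift = early_shift, late_shift = late_shift, ns_offset = ns_offset,
    sst_start = sst_start, sst_end = sst_end, sst_shape = sst_shape,
    sst_threshold = sst_threshold, sst_noise_sd = sst_noise_sd,
    run_size = run_size, arrival_lag = arrival_lag, pulse_sd = pulse_sd,
    arrival_jitter_sd = arrival_jitter_sd,
    residence_jitter_sd = residence_jitter_sd,
    residence_mean = residence_mean, t2_arrival_advance = t2_arrival_advance,
    catch_noise = isTRUE(catch_noise), arrival_anchor = arrival_anchor,
    seed = as.integer(seed)
  ), class = "chum_scenario")
  validate_scenario(sc)
  sc
}

#' @keywords internal
validate_scenario <- function(sc) {
  if (!inherits(sc, "chum_scenario")) stopf("not a chum_scenario")
  day_pars <- c(sc$base_cross_day,
                abs(sc$early_shift), abs(sc$late_shift), abs(sc$ns_offset),
                abs(sc$t2_arrival_advance), sc$pulse_sd, sc$residence_mean)
  if (any(!is.finite(day_pars)) || any(sc$base_cross_day < 0 | sc$base_cross_day > 91))
    stopf("day parameters must be finite and base_cross_day within 0..91")
  if (!(sc$sst_start > sc$sst_threshold && sc$sst_threshold > sc$sst_end))
    stopf("need sst_start > threshold > sst_end so a crossing always exists")
  if (sc$run_size <= 0) stopf("run_size must be positive")
  if (sc$pulse_sd <= 0) stopf("pulse_sd must be positive")
  if (sc$sst_noise_sd < 0) stopf("sst_noise_sd must be non-negative")
  if (sc$arrival_jitter_sd < 0 || sc$residence_jitter_sd < 0)
    stopf("jitter sds must be non-negative")
  invisible(sc)
}

#' Named scenario presets
#'
#' `"mixed-13yr"` mirrors the 13-year study composition: 3 T1, 5 T3 and 5 T2
#' years in the fixed order T1, T3, T1, T2, T3, T2, T3, T2, T3, T2, T2, T3, T1
#' (years 2006-2018). `"T1-like"`, `"T2-like"` and `"T3-like"` repeat one
#' regime for 13 years. All presets use the default generator magnitudes,
#' including the 4-day T2 arrival advance.
#'
#' @param name preset name.
#' @param ... overrides passed on to [scenario()] (e.g. `seed`,
#'   `sst_noise_sd`).
#' @return a `"chum_scenario"`.
#' @examples
#' table(make_scenario_preset("mixed-13yr")$regime_sequence)
#' @export
make_scenario_preset <- function(name = c("mixed-13yr", "T1-like",
                                          "T2-like", "T3-like"), ...) {
  name <- match.arg(name)
  seqs <- list(
    "mixed-13yr" = c("T1", "T3", "T1", "T2", "T3", "T2", "T3",
                     "T2", "T3", "T2", "T2", "T3", "T1"),
    "T1-like" = rep("T1", 13L),
    "T2-like" = rep("T2", 13L),
    "T3-like" = rep("T3", 13L)
  )
  scenario(n_years = 13L, regime_sequence = seqs[[name]],
           years = 2006:2018, ...)
}

#' @export
print.chum_scenario <- function(x, ...) {
  cat(sprintf("<chum_scenario> %d years (%s), seed %d\n", x$n_years,
              paste0(names(table(x$regime_sequence)), ":",
                     table(x$regime_sequence), collapse = " "),
              x$seed))
  cat(sprintf("  cooling %.1f -> %.1f degC, shape %.1f d, noise sd %.2f degC\n",
              x$sst_start, x$sst_end, x$sst_shape, x$sst_noise_sd))
  cat(sprintf("  shifts: T1 -%g, T3 +%g, T2 north -%g / south +%g d; T2 arrival advance %g d\n",
              x$early_shift, x$late_shift, x$early_shift, x$ns_offset,
              x$t2_arrival_advance))
  invisible(x)
}
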