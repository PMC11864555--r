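#' Mean autumn cooling curve
#'
#' The generator's mean SST trajectory is a logistic-in-time cooling ramp from
#' `sst_start` to `sst_end`. The ramp is time-shifted so that its continuous
#' threshold crossing falls at `cross_day - 0.5`, which makes `cross_day` the
#' first integer day strictly below the threshold in the noise-free series —
#' truth is analytic.
#'
#' @param scenario a [scenario()].
#' @param cross_day target integer crossing day (days since Oct 1).
#' @param days day indices at which to evaluate (default the full window).
#' @return numeric vector of mean SST (deg C).
#' @export
sst_mean_curve <- function(scenario, cross_day, days = 0:91) {
  rng <- scenario$sst_start - scenario$sst_end
  r <- rng / (scenario$sst_threshold - scenario$sst_end) - 1
  mid <- (cross_day - 0.5) - scenario$sst_shape * log(r)
  scenario$sst_end + rng / (1 + exp((days - mid) / scenario$sst_shape))
}

#' True threshold-crossing day for a region under a regime
#'
#' @param scenario a [scenario()].
#' @param region a region id present in `names(scenario$base_cross_day)`.
#' @param regime one of `"T1"`, `"T2"`, `"T3"`.
#' @param registry region registry (for the north/south split).
#' @return integer day since Oct 1.
#' @export
true_cross_day <- function(scenario, region, regime,
                           registry = default_registry()) {
  base <- scenario$base_cross_day[[region]]
  area <- registry$area[match(region, registry$id)]
  if (is.na(area)) stopf("region %s not in registry", region)
  shift <- switch(regime,
    T1 = -scenario$early_shift,
    T3 = +scenario$late_shift,
    T2 = if (area == "north") -scenario$early_shift else +scenario$ns_offset,
    stopf("unknown regime label: %s", regime))
  base + shift
}

#' True migration-pulse centres for a region-year
#'
#' Coastal arrival is anchored on the region's climatological crossing day
#' (or, with `arrival_anchor = "yearly"`, on the year's realised crossing),
#' offset by the area's `arrival_lag` and advanced by `t2_arrival_advance`
#' in T2 years. River entry is the coastal centre plus the region's mean
#' residence time.
#'
#' @inheritParams true_cross_day
#' @return list with `coastal`, `riverine` (day indices) and `residence`.
#' @export
true_pulse_centers <- function(scenario, region, regime,
                               registry = default_registry()) {
  area <- registry$area[match(region, registry$id)]
  if (is.na(area)) stopf("region %s not in registry", region)
  anchor <- if (scenario$arrival_anchor == "climatology")
    scenario$base_cross_day[[region]]
  else
    true_cross_day(scenario, region, regime, registry)
  coastal <- anchor + scenario$arrival_lag[[area]] -
    scenario$t2_arrival_advance * (regime == "T2")
  res <- round(scenario$residence_mean[[region]])
  riverine <- coastal + res
  if (coastal < 0 || coastal > 91 || riverine < 0 || riverine > 91)
    stopf("pulse centre outside the 0..91 window for %s/%s (coastal %.1f, riverine %.1f); reparameterise the scenario",
          region, regime, coastal, riverine)
  list(coastal = coastal, riverine = riverine, residence = res)
}

#' Mean SST at the coastal pulse centre (generator truth)
#'
#' Evaluates the year's mean cooling curve at the true coastal pulse centre;
#' this is the temperature at which the quadratic thermal-response peak is
#' expected for that region and regime.
#'
#' @inheritParams true_cross_day
#' @return deg C.
#' @export
true_pulse_sst <- function(scenario, region, regime,
                           registry = default_registry()) {
  ctr <- true_pulse_centers(scenario, region, regime, registry)$coastal
  cross <- true_cross_day(scenario, region, regime, registry)
  sst_mean_curve(scenario, cross, days = ctr)
}

#' Simulate one region-year of daily SST
#'
#' 92 daily values: the logistic cooling ramp time-shifted by the year's
#' regime (T1: all regions early; T3: all late; T2: north early, south late),
#' plus i.i.d. Gaussian noise. Each region-year has its own RNG stream
#' derived from `(seed, region, year)`, so series are reproducible and
#' independent of which other region-years are generated.
#'
#' @param scenario a [scenario()].
#' @param region region id.
#' @param year a year in `scenario$years`.
#' @param registry region registry.
#' @return numeric vector of length 92 (deg C).
#' @export
simulate_sst <- function(scenario, region, year,
                         registry = default_registry()) {
  iy <- match(year, scenario$years)
  if (is.na(iy)) stopf("year %s not in scenario", year)
  regime <- scenario$regime_sequence[iy]
  cross <- true_cross_day(scenario, region, regime, registry)
  mu <- sst_mean_curve(scenario, cross, days = 0:91)
  if (scenario$sst_noise_sd > 0) {
    withr_seed <- sub_seed(scenario$seed, "sst", region, year)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(withr_seed)
    mu <- mu + rnorm(92L, 0, scenario$sst_noise_sd)
  }
  mu
}

#' Simulate one region-year of daily coastal and riverine catch
#'
#' Coastal counts are Poisson draws around a Gaussian arrival pulse
#' (expected total `run_size`, centre per [true_pulse_centers()] plus a
#' region-year timing jitter of sd `arrival_jitter_sd`, spread `pulse_sd`).
#' Riverine counts are the realised coastal counts shifted by the region's
#' residence time (plus its own whole-day jitter) — a pure shift, so no fish
#' are created in the river; counts shifted past day 91 are lost to the
#' window. The realised (jittered) pulse centres are returned as the truth
#' for this region-year.
#'
#' @inheritParams simulate_sst
#' @param sst_series optional, the region-year's SST series (accepted for
#'   interface symmetry; pulse timing is computed analytically from the
#'   scenario).
#' @return list with integer vectors `coastal` and `riverine` (length 92)
#'   and `centers` (realised `coastal`, `riverine`, `residence`).
#' @export
simulate_catch <- function(scenario, region, year, sst_series = NULL,
                           registry = default_registry()) {
  iy <- match(year, scenario$years)
  if (is.na(iy)) stopf("year %s not in scenario", year)
  regime <- scenario$regime_sequence[iy]
  ctr <- true_pulse_centers(scenario, region, regime, registry)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  if (scenario$arrival_jitter_sd > 0 || scenario$residence_jitter_sd > 0) {
    set.seed(sub_seed(scenario$seed, "arrival", region, year))
    ctr$coastal <- ctr$coastal + rnorm(1, 0, scenario$arrival_jitter_sd)
    ctr$residence <- ctr$residence +
      as.integer(round(rnorm(1, 0, scenario$residence_jitter_sd)))
    ctr$riverine <- ctr$coastal + ctr$residence
    if (ctr$coastal < 0 || ctr$coastal > 91 ||
        ctr$riverine < 0 || ctr$riverine > 91)
      stopf("jittered pulse centre outside the window for %s/%s; reparameterise",
            region, year)
  }
  days <- 0:91
  w <- dnorm(days, ctr$coastal, scenario$pulse_sd)
  intensity <- scenario$run_size * w / sum(w)
  if (scenario$catch_noise) {
    set.seed(sub_seed(scenario$seed, "catch", region, year))
    coastal <- rpois(92L, intensity)
  } else {
    coastal <- as.integer(round(intensity))
  }
  riverine <- integer(92L)
  src <- days + 1L
  dst <- days + ctr$residence + 1L
  keep <- dst >= 1L & dst <= 92L
  riverine[dst[keep]] <- coastal[src[keep]]
  list(coastal = as.integer(coastal), riverine = as.integer(riverine),
       centers = ctr)
}

# save/restore the global RNG state so simulators do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Simulate a full synthetic dataset
#'
#' Generates daily SST and coastal/riverine catch for every region-year of a
#' scenario, together with the truth record (regime labels, crossing days,
#' pulse centres, residence times, pulse-centre SSTs) used by the
#' parameter-recovery tests.
#'
#' @param scenario a [scenario()].
#' @param registry region registry.
#' @return an object of class `"chum_dataset"`: a list with long-format
#'   data.frames `sst` (`region, year, day, sst`), `coastal` and `riverine`
#'   (`region, year, day, catch`) and `truth` (one row per region-year).
#' @export
simulate_dataset <- function(scenario, registry = default_registry()) {
  validate_scenario(scenario)
  regions <- names(scenario$base_cross_day)
  check_region_ids(regions, registry)
  days <- 0:91
  sst_l <- list(); co_l <- list(); ri_l <- list(); tr_l <- list()
  k <- 0L
  for (region in regions) {
    for (iy in seq_len(scenario$n_years)) {
      year <- scenario$years[iy]
      regime <- scenario$regime_sequence[iy]
      k <- k + 1L
      sst <- simulate_sst(scenario, region, year, registry)
      cat2 <- simulate_catch(scenario, region, year, sst, registry)
      ctr <- cat2$centers
      sst_l[[k]] <- data.frame(region = region, year = year, day = days,
                               sst = sst, stringsAsFactors = FALSE)
      co_l[[k]] <- data.frame(region = region, year = year, day = days,
                              catch = cat2$coastal, stringsAsFactors = FALSE)
      ri_l[[k]] <- data.frame(region = region, year = year, day = days,
                              catch = cat2$riverine, stringsAsFactors = FALSE)
      tr_l[[k]] <- data.frame(
        region = region, year = year, regime = regime,
        cross_day = true_cross_day(scenario, region, regime, registry),
        coastal_mdmt = ctr$coastal, riverine_mdmt = ctr$riverine,
        residence_days = ctr$residence,
        pulse_sst = true_pulse_sst(scenario, region, regime, registry),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(sst = do.call(rbind, sst_l),
                 coastal = do.call(rbind, co_l),
                 riverine = do.call(rbind, ri_l),
                 truth = do.call(rbind, tr_l),
                 scenario = scenario),
            class = "chum_dataset")
}

#' Write or read a synthetic dataset as plain text
#'
#' The dataset is stored as one long CSV (`series.csv` with columns
#' `region, year, date, location, value`, where `location` is `"sst"`,
#' `"coast"` or `"river"`) plus a JSON truth sidecar (`truth.json`). Numeric
#' values are written with 17 significant digits so a read-back is
#' bit-identical.
#'
#' @param dataset a `"chum_dataset"`.
#' @param dir directory to write into (created if missing).
#' @return `write_dataset` returns `dir` invisibly; `read_dataset` returns a
#'   `"chum_dataset"` (without the scenario, which is not serialised).
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- function(df, loc, col) {
    data.frame(region = df$region, year = df$year,
               date = format(as.Date(sprintf("%d-10-01", df$year)) + df$day),
               location = loc, value = sprintf("%.17g", df[[col]]),
               stringsAsFactors = FALSE)
  }
  long <- rbind(rows(dataset$sst, "sst", "sst"),
                rows(dataset$coastal, "coast", "catch"),
                rows(dataset$riverine, "river", "catch"))
  utils::write.csv(long, file.path(dir, "series.csv"), row.names = FALSE)
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", digits = NA)
  invisible(dir)
}

#' Write a dataset as the pipeline's three input CSVs
#'
#' Writes `sst.csv`, `coastal.csv` and `riverine.csv` in the pipeline's
#' ingestion schema (`region, year, date, value`), suitable for
#' [pipeline_config()]'s `paths` argument and [validate_inputs()].
#'
#' @param dataset a `"chum_dataset"`.
#' @param dir directory to write into (created if missing).
#' @return named list of the three paths, invisibly.
#' @export
write_input_csvs <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, col, name) {
    out <- data.frame(region = df$region, year = df$year,
                      date = format(as.Date(sprintf("%d-10-01", df$year)) + df$day),
                      value = sprintf("%.17g", df[[col]]),
                      stringsAsFactors = FALSE)
    path <- file.path(dir, name)
    utils::write.csv(out, path, row.names = FALSE)
    path
  }
  invisible(list(sst = wr(dataset$sst, "sst", "sst.csv"),
                 coastal = wr(dataset$coastal, "catch", "coastal.csv"),
                 riverine = wr(dataset$riverine, "catch", "riverine.csv")))
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  path <- file.path(dir, "series.csv")
  if (!file.exists(path)) stopf("no series.csv under %s", dir)
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("region", "year", "date", "location", "value")
  miss <- setdiff(need, names(long))
  if (length(miss))
    stopf("series.csv is missing columns: %s", paste(miss, collapse = ", "))
  long$day <- as.integer(as.Date(long$date) -
                           as.Date(sprintf("%d-10-01", long$year)))
  pick <- function(loc, col) {
    df <- long[long$location == loc,
               c("region", "year", "day", "value"), drop = FALSE]
    df <- df[order(df$region, df$year, df$day), , drop = FALSE]
    names(df)[4] <- col
    df[[col]] <- if (col == "catch") as.integer(df[[col]])
                 else as.numeric(df[[col]])
    rownames(df) <- NULL
    df
  }
  truth <- NULL
  tpath <- file.path(dir, "truth.json")
  if (file.exists(tpath))
    truth <- as.data.frame(jsonlite::read_json(tpath, simplifyVector = TRUE))
  structure(list(sst = pick("sst", "sst"), coastal = pick("coast", "catch"),
                 riverine = pick("river", "catch"), truth = truth,
                 scenario = NULL),
            class = "chum_dataset")
}

#' Simulate phenology records directly from a mixed-model structure
#'
#' Bypasses the daily-series generator and draws per region-year responses
#' straight from one of the three candidate model structures: (1) regime
#' fixed effect only, (2) regime fixed effect plus a Gaussian region random
#' intercept, (3) regime-by-region fixed interaction. Used for
#' structure-recovery experiments.
#'
#' @param structure generating structure, 1, 2 or 3.
#' @param regime_sequence per-year regime labels.
#' @param regions region ids.
#' @param intercept grand mean of the response (days).
#' @param regime_effects named shifts for T1/T2/T3 (days).
#' @param region_sd sd of the region random intercept (structure 2), days.
#' @param interaction_sd sd of region-by-regime effects (structure 3), days.
#' @param resid_sd residual sd, days.
#' @param response name of the response column to emit.
#' @param seed RNG seed.
#' @return data.frame with columns `region`, `year`, `regime` and the
#'   response.
#' @export
simulate_phenology_records <- function(structure = 2L,
                                       regime_sequence = make_scenario_preset("mixed-13yr")$regime_sequence,
                                       regions = paste0("CR", 1:6),
                                       intercept = 40,
                                       regime_effects = c(T1 = 0, T2 = -4, T3 = 0),
                                       region_sd = 2.7,
                                       interaction_sd = 3,
                                       resid_sd = 2,
                                       response = "coastal_mdmt",
                                       seed = 1L) {
  if (!structure %in% 1:3) stopf("structure must be 1, 2 or 3")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(sub_seed(seed, "lme-sim", structure))
  n_y <- length(regime_sequence)
  years <- seq_len(n_y) + 2005L
  reg_int <- if (structure >= 2L)
    stats::setNames(rnorm(length(regions), 0, region_sd), regions)
  else stats::setNames(numeric(length(regions)), regions)
  inter <- matrix(0, length(regions), 3,
                  dimnames = list(regions, c("T1", "T2", "T3")))
  if (structure == 3L)
    inter[] <- rnorm(length(inter), 0, interaction_sd)
  out <- expand.grid(region = regions, year = years,
                     stringsAsFactors = FALSE)
  out$regime <- regime_sequence[match(out$year, years)]
  mu <- intercept + regime_effects[out$regime] + reg_int[out$region] +
    inter[cbind(out$region, out$regime)]
  out[[response]] <- as.numeric(mu + rnorm(nrow(out), 0, resid_sd))
  rownames(out) <- NULL
  out
}
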