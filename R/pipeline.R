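#' Pipeline configuration
#'
#' One configuration object drives the whole analysis. Exactly one of
#' `preset` (a synthetic scenario name, see [make_scenario_preset()]) or
#' `paths` (a named list with `sst`, `coastal`, `riverine` CSV paths) must
#' be given. All thresholds the analysis depends on live here with their
#' defaults: the 20 degC crossing threshold, the 7-day north-south gap for
#' T2, and the 1 degC bin width.
#'
#' @param preset scenario preset name, or `NULL`.
#' @param paths named list of input CSV paths, or `NULL`.
#' @param threshold crossing threshold, deg C.
#' @param ns_gap_threshold days, T2 classification gap.
#' @param bin_width deg C.
#' @param structures LME structures to fit.
#' @param families response families to fit.
#' @param out output directory for intermediate artifacts, or `NULL` to keep
#'   everything in memory.
#' @param seed RNG seed (forwarded to the scenario when simulating).
#' @param registry region registry.
#' @param ... scenario overrides forwarded to [make_scenario_preset()].
#' @return a list of class `"chum_config"`.
#' @export
pipeline_config <- function(preset = NULL, paths = NULL, threshold = 20,
                            ns_gap_threshold = 7, bin_width = 1,
                            structures = 1:3,
                            families = c("polynomial", "exponential",
                                         "logistic"),
                            out = NULL, seed = 1L,
                            registry = default_registry(), ...) {
  if (is.null(preset) == is.null(paths))
    stopf("config error: give exactly one of preset or paths")
  if (threshold <= 0 || ns_gap_threshold <= 0 || bin_width <= 0)
    stopf("config error: thresholds must be positive")
  structure(list(preset = preset, paths = paths, threshold = threshold,
                 ns_gap_threshold = ns_gap_threshold, bin_width = bin_width,
                 structures = structures, families = families, out = out,
                 seed = as.integer(seed), registry = registry,
                 scenario_args = list(...)),
            class = "chum_config")
}

#' Run the full analysis pipeline
#'
#' Stages, in order: simulate (or ingest) daily series; detect threshold
#' crossings and classify years into T1/T2/T3; compute MDMTs and residence
#' times; fit and AIC-select the mixed-model structures for both responses;
#' bin catch by temperature and fit/AIC-select the thermal-response families;
#' extract quadratic peak temperatures. Any stage failure aborts with the
#' stage named. Identical config and seed yield a byte-identical serialised
#' report. When `config$out` is set, every intermediate table is also
#' written there as CSV.
#'
#' @param config a [pipeline_config()].
#' @return a `"chum_report"`: list with `labels`, `crossings`, `phenology`,
#'   `lme` (per response: comparison table, selected structure, contrasts),
#'   `bins`, `nla` (comparison and peaks) and a `provenance` block (config
#'   hash, seed, package version).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "chum_config")) stopf("not a chum_config")
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    message(sprintf("[chumphen] stage %-12s %.2fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    res
  }
  registry <- config$registry

  dataset <- stage("ingest", {
    if (!is.null(config$preset)) {
      sc <- do.call(make_scenario_preset,
                    c(list(name = config$preset, seed = config$seed),
                      config$scenario_args))
      simulate_dataset(sc, registry)
    } else {
      ingest_inputs(config$paths)
    }
  })
  check_region_ids(dataset$sst$region, registry)

  crossings <- stage("crossings",
    crossing_table(dataset$sst, threshold = config$threshold))
  labels <- stage("typing",
    type_years(crossings, config$ns_gap_threshold, registry))
  phen <- stage("phenology", phenology_table(dataset, labels))
  lme <- stage("lme", {
    lapply(stats::setNames(nm = c("coastal_mdmt", "residence_days")),
           function(resp) {
             cmp <- compare_lme(phen, resp, config$structures)
             list(comparison = cmp$comparison,
                  selected_structure = cmp$selected$structure,
                  contrasts = cmp$selected$contrasts,
                  fits = cmp$fits)
           })
  })
  bins <- stage("binning",
    bin_by_temperature(dataset$coastal, dataset$sst, labels,
                       config$bin_width))
  nla <- stage("nla",
    fit_response_table(bins, config$families, config$bin_width))

  report <- structure(list(
    labels = labels, crossings = crossings, phenology = phen,
    lme = lapply(lme, function(l) l[c("comparison", "selected_structure",
                                      "contrasts")]),
    bins = bins,
    nla = list(comparison = nla$comparison, peaks = nla$peaks),
    provenance = list(
      config_hash = object_hash(config[setdiff(names(config), "registry")]),
      seed = config$seed,
      package_version = as.character(utils::packageVersion("chumphen")))
  ), class = "chum_report")
  attr(report, "dataset") <- dataset
  attr(report, "lme_fits") <- lapply(lme, `[[`, "fits")
  attr(report, "nla_fits") <- nla$selected

  if (!is.null(config$out)) stage("write", write_report(report, config$out))
  report
}

# ingest the three long CSVs into a chum_dataset
ingest_inputs <- function(paths) {
  need <- c("sst", "coastal", "riverine")
  if (!all(need %in% names(paths)))
    stopf("paths must name sst, coastal and riverine files")
  rd <- function(path, value_col) {
    if (!file.exists(path)) stopf("input file not found: %s", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    cols <- c("region", "year", "date", "value")
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stopf("%s is missing columns: %s", path, paste(miss, collapse = ", "))
    df$day <- as.integer(as.Date(df$date) -
                           as.Date(sprintf("%d-10-01", df$year)))
    out <- df[, c("region", "year", "day")]
    out[[value_col]] <- if (value_col == "catch") as.integer(df$value)
                        else as.numeric(df$value)
    out[order(out$region, out$year, out$day), , drop = FALSE]
  }
  structure(list(sst = rd(paths$sst, "sst"),
                 coastal = rd(paths$coastal, "catch"),
                 riverine = rd(paths$riverine, "catch"),
                 truth = NULL, scenario = NULL),
            class = "chum_dataset")
}

#' Validate input CSVs before running the pipeline
#'
#' Checks, per file: schema (`region, year, date, value`), coverage of the
#' October-December window (SST gaps longer than 3 consecutive days fail,
#' mirroring the interpolation limit), and non-negative catch counts (with
#' offending rows cited).
#'
#' @param paths named list with `sst`, `coastal`, `riverine` CSV paths.
#' @return data.frame with columns `file`, `pass`, `messages`.
#' @export
validate_inputs <- function(paths) {
  out <- lapply(names(paths), function(nm) {
    path <- paths[[nm]]
    msgs <- character()
    if (!file.exists(path))
      return(data.frame(file = nm, pass = FALSE,
                        messages = "file not found", stringsAsFactors = FALSE))
    df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                   error = function(e) NULL)
    if (is.null(df))
      return(data.frame(file = nm, pass = FALSE,
                        messages = "unreadable CSV", stringsAsFactors = FALSE))
    need <- c("region", "year", "date", "value")
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      msgs <- c(msgs, sprintf("missing columns: %s",
                              paste(miss, collapse = ", ")))
    } else {
      day <- as.integer(as.Date(df$date) -
                          as.Date(sprintf("%d-10-01", df$year)))
      if (any(is.na(day) | day < 0 | day > 91))
        msgs <- c(msgs, sprintf("dates outside the Oct 1 - Dec 31 window in rows: %s",
                                paste(utils::head(which(is.na(day) | day < 0 | day > 91), 5),
                                      collapse = ", ")))
      if (nm != "sst" && any(df$value < 0, na.rm = TRUE))
        msgs <- c(msgs, sprintf("negative catch in rows: %s",
                                paste(utils::head(which(df$value < 0), 5),
                                      collapse = ", ")))
      if (nm == "sst") {
        for (key in unique(paste(df$region, df$year))) {
          sub <- df[paste(df$region, df$year) == key, ]
          have <- sort(unique(day[paste(df$region, df$year) == key]))
          gaps <- diff(have) - 1L
          miss_days <- 92L - length(have)
          if (length(have) && (max(c(gaps, 0L)) > 3L ||
                               have[1] > 3L || (91L - have[length(have)]) > 3L))
            msgs <- c(msgs, sprintf("%s: SST gap longer than 3 days", key))
          if (miss_days > 0L && !length(msgs))
            msgs <- c(msgs, sprintf("%s: %d missing days", key, miss_days))
        }
      }
    }
    data.frame(file = nm, pass = !length(msgs),
               messages = paste(msgs, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Serialise a report deterministically
#'
#' @param report a `"chum_report"`.
#' @return a JSON string; identical config and seed give an identical
#'   string.
#' @export
report_json <- function(report) {
  payload <- unclass(report)
  attr(payload, "dataset") <- NULL
  jsonlite::toJSON(payload, dataframe = "rows", digits = NA, auto_unbox = TRUE,
                   na = "null")
}

#' Write a report's tables under a directory
#'
#' @param report a `"chum_report"`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, name)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  wr(report$crossings, "crossings.csv")
  wr(report$labels, "labels.csv")
  wr(report$phenology, "phenology.csv")
  wr(report$bins, "bins.csv")
  for (resp in names(report$lme)) {
    wr(report$lme[[resp]]$comparison, sprintf("lme_comparison_%s.csv", resp))
    wr(report$lme[[resp]]$contrasts, sprintf("lme_contrasts_%s.csv", resp))
  }
  wr(report$nla$comparison, "nla_comparison.csv")
  wr(report$nla$peaks, "nla_peaks.csv")
  writeLines(report_json(report), file.path(dir, "report.json"))
  invisible(dir)
}
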