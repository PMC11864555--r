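#' First day the SST falls strictly below a threshold
#'
#' The crossing day is the first day index whose value is strictly below the
#' threshold ("decreased below 20 degC"); a value exactly at the threshold
#' does not trigger. Interior gaps of up to `max_gap` consecutive missing
#' days are linearly interpolated; longer (or leading/trailing) gaps are a
#' data-quality error, since the reanalysis products this mirrors are
#' gap-free.
#'
#' @param series numeric vector of daily SST (deg C), day 0 first.
#' @param threshold deg C (default 20).
#' @param max_gap longest interpolatable run of missing days (default 3).
#' @return 0-based integer day of the first strict sub-threshold value, or
#'   `NA_integer_` if the series never crosses within the window.
#' @examples
#' crossing_date(c(21, 20.5, 19.8, 18))  # 2
#' @export
crossing_date <- function(series, threshold = 20, max_gap = 3L) {
  if (length(series) == 0L) stopf("empty SST series")
  if (anyNA(series)) {
    series <- zoo::na.approx(series, maxgap = max_gap, na.rm = FALSE)
    if (anyNA(series))
      stopf("missing SST values beyond the %d-day interpolation limit", max_gap)
  }
  hit <- which(series < threshold)
  if (!length(hit)) return(NA_integer_)
  as.integer(hit[1] - 1L)
}

#' Crossing dates for every region-year of an SST table
#'
#' @param sst long data.frame with columns `region`, `year`, `day`, `sst`.
#' @param threshold deg C.
#' @param max_gap see [crossing_date()].
#' @return data.frame with columns `region`, `year`, `cross_day`
#'   (`NA` when the series never crosses).
#' @export
crossing_table <- function(sst, threshold = 20, max_gap = 3L) {
  need <- c("region", "year", "day", "sst")
  miss <- setdiff(need, names(sst))
  if (length(miss))
    stopf("sst table is missing columns: %s", paste(miss, collapse = ", "))
  sst <- sst[order(sst$region, sst$year, sst$day), , drop = FALSE]
  key <- interaction(sst$region, sst$year, drop = TRUE)
  out <- do.call(rbind, lapply(split(sst, key), function(d)
    data.frame(region = d$region[1], year = d$year[1],
               cross_day = crossing_date(d$sst, threshold, max_gap),
               stringsAsFactors = FALSE)))
  out <- out[order(out$region, out$year), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-region climatological mean crossing day
#'
#' Operationalises the "average year": the per-region arithmetic mean of the
#' crossing day over all years in the dataset (leave-self-in).
#'
#' @param crossings data.frame from [crossing_table()].
#' @return named numeric vector, mean crossing day per region.
#' @export
climatology <- function(crossings) {
  sp <- split(crossings$cross_day, crossings$region)
  out <- vapply(names(sp), function(r) {
    x <- sp[[r]][!is.na(sp[[r]])]
    if (length(x) < 2L)
      stopf("region %s has fewer than 2 years with a crossing", r)
    mean(x)
  }, numeric(1))
  out
}

#' Classify one year into SST distribution type T1, T2 or T3
#'
#' Anomalies are each region's crossing day minus its climatological
#' baseline. The year is T2 when the south-minus-north mean anomaly gap
#' reaches `ns_gap_threshold` — regardless of whether cooling was early or
#' late overall; otherwise T1 when the mean anomaly over all regions is
#' negative (cooling earlier than average) and T3 when non-negative.
#'
#' @param year_crossings data.frame (`region`, `cross_day`) for one year;
#'   must cover every registry region.
#' @param baseline named vector from [climatology()].
#' @param ns_gap_threshold days; minimum south-minus-north anomaly gap for
#'   T2 (default 7).
#' @param registry region registry.
#' @return a one-row data.frame: `label`, `overall_anomaly`, `ns_gap`.
#' @export
classify_year <- function(year_crossings, baseline, ns_gap_threshold = 7,
                          registry = default_registry()) {
  ids <- registry$id
  m <- match(ids, year_crossings$region)
  if (anyNA(m))
    stopf("no crossing record for region(s): %s",
          paste(ids[is.na(m)], collapse = ", "))
  cross <- year_crossings$cross_day[m]
  if (anyNA(cross))
    stopf("region(s) without a threshold crossing this year: %s",
          paste(ids[is.na(cross)], collapse = ", "))
  if (anyNA(match(ids, names(baseline))))
    stopf("baseline missing for some regions")
  anom <- cross - baseline[ids]
  north <- registry$area == "north"
  ns_gap <- mean(anom[!north]) - mean(anom[north])
  overall <- mean(anom)
  label <- if (ns_gap >= ns_gap_threshold) "T2"
           else if (overall < 0) "T1" else "T3"
  data.frame(label = label, overall_anomaly = overall, ns_gap = ns_gap,
             stringsAsFactors = FALSE)
}

#' Label every year of a crossing table
#'
#' Computes the leave-self-in climatology and classifies each year; every
#' year with complete crossings receives a label.
#'
#' @param crossings data.frame from [crossing_table()].
#' @inheritParams classify_year
#' @return data.frame with columns `year`, `label`, `overall_anomaly`,
#'   `ns_gap`.
#' @export
type_years <- function(crossings, ns_gap_threshold = 7,
                       registry = default_registry()) {
  check_region_ids(crossings$region, registry)
  base <- climatology(crossings)
  out <- do.call(rbind, lapply(split(crossings, crossings$year), function(d) {
    cbind(data.frame(year = d$year[1]),
          classify_year(d, base, ns_gap_threshold, registry))
  }))
  out <- out[order(out$year), , drop = FALSE]
  rownames(out) <- NULL
  out
}
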