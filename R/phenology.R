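#' Median date of migration timing (MDMT)
#'
#' The smallest day index at which the running cumulative catch strictly
#' exceeds 50% of the window total ("more than 50%"): with an even total
#' split exactly at one half, the next day wins.
#'
#' @param catch numeric vector of daily non-negative counts, day 0 first.
#' @return 0-based integer day index.
#' @examples
#' mdmt(c(0, 0, 10, 0))          # 2
#' mdmt(rep(1, 4))               # 2: cumulative first exceeds 2 on day 2
#' @export
mdmt <- function(catch) {
  if (length(catch) == 0L) stopf("empty catch series")
  if (any(catch < 0, na.rm = TRUE)) stopf("negative catch counts")
  total <- sum(catch)
  if (!is.finite(total) || total <= 0)
    stopf("MDMT undefined: zero total catch in the window")
  as.integer(which(cumsum(catch) > total / 2)[1] - 1L)
}

#' Coastal residence time
#'
#' Signed difference between the riverine and coastal median migration
#' dates. Negative values are permitted (and flagged downstream), since
#' nothing in the definition rules them out.
#'
#' @param coastal_mdmt,riverine_mdmt day indices for the same region-year.
#' @return days (signed).
#' @export
residence_time <- function(coastal_mdmt, riverine_mdmt) {
  if (anyNA(coastal_mdmt) || anyNA(riverine_mdmt))
    stopf("residence time undefined: missing MDMT")
  riverine_mdmt - coastal_mdmt
}

#' Phenology table for a dataset
#'
#' Per region-year: coastal and riverine MDMT, residence time, and the
#' year's regime label. Region-years whose riverine total is zero get `NA`
#' MDMTs and are flagged rather than dropped.
#'
#' @param dataset a `"chum_dataset"` (or any list with `coastal`/`riverine`
#'   long tables).
#' @param labels data.frame from [type_years()] (`year`, `label`).
#' @return data.frame with columns `region`, `year`, `regime`,
#'   `coastal_mdmt`, `riverine_mdmt`, `residence_days`, `flag`
#'   (`""`, `"negative_residence"` or `"undefined"`).
#' @export
phenology_table <- function(dataset, labels) {
  md <- function(df) {
    df <- df[order(df$region, df$year, df$day), , drop = FALSE]
    key <- interaction(df$region, df$year, drop = TRUE)
    do.call(rbind, lapply(split(df, key), function(d)
      data.frame(region = d$region[1], year = d$year[1],
                 mdmt = if (sum(d$catch) > 0) mdmt(d$catch) else NA_integer_,
                 stringsAsFactors = FALSE)))
  }
  co <- md(dataset$coastal); names(co)[3] <- "coastal_mdmt"
  ri <- md(dataset$riverine); names(ri)[3] <- "riverine_mdmt"
  out <- merge(co, ri, by = c("region", "year"), all = TRUE)
  out$regime <- labels$label[match(out$year, labels$year)]
  out$residence_days <- out$riverine_mdmt - out$coastal_mdmt
  out$flag <- ifelse(is.na(out$residence_days), "undefined",
                     ifelse(out$residence_days < 0, "negative_residence", ""))
  out <- out[order(out$region, out$year),
             c("region", "year", "regime", "coastal_mdmt", "riverine_mdmt",
               "residence_days", "flag")]
  rownames(out) <- NULL
  out
}

#' Accumulate a catch series into SST bins
#'
#' Each day's catch is added to the temperature bin containing that day's
#' SST. Bins are left-closed right-open `[t, t + width)` and labelled by
#' their left edge.
#'
#' @param catch,sst aligned numeric vectors (same days).
#' @param bin_width deg C (default 1).
#' @return named numeric vector of per-bin accumulated catch (unnormalised);
#'   names are left edges.
#' @export
accumulate_by_temperature <- function(catch, sst, bin_width = 1) {
  if (length(catch) != length(sst))
    stopf("catch and sst series are not aligned (%d vs %d days)",
          length(catch), length(sst))
  if (bin_width <= 0) stopf("bin_width must be positive")
  left <- floor(sst / bin_width) * bin_width
  tapply(catch, factor(left), sum)
}

#' Temperature-binned migration volumes per region and regime
#'
#' Pools all years of each regime within a region, accumulates daily catch
#' by that day's SST bin, and normalises to fractions summing to one per
#' (region, regime) — the "migration volume" response fitted by the
#' nonlinear thermal-response models.
#'
#' @param catch_df long data.frame (`region`, `year`, `day`, `catch`).
#' @param sst_df long data.frame (`region`, `year`, `day`, `sst`).
#' @param labels data.frame from [type_years()].
#' @param bin_width deg C.
#' @return data.frame with columns `region`, `regime`, `bin_left`, `volume`;
#'   only non-empty bins are retained, and volumes sum to 1 within each
#'   (region, regime) with any catch.
#' @export
bin_by_temperature <- function(catch_df, sst_df, labels, bin_width = 1) {
  m <- merge(catch_df, sst_df, by = c("region", "year", "day"))
  if (nrow(m) != nrow(catch_df) || nrow(catch_df) != nrow(sst_df))
    stopf("catch and SST tables are not aligned on (region, year, day)")
  m$regime <- labels$label[match(m$year, labels$year)]
  if (anyNA(m$regime)) stopf("years without a regime label in catch table")
  out <- do.call(rbind, lapply(
    split(m, interaction(m$region, m$regime, drop = TRUE)), function(d) {
      acc <- accumulate_by_temperature(d$catch, d$sst, bin_width)
      tot <- sum(acc)
      if (tot <= 0) return(NULL)
      acc <- acc[acc > 0]
      data.frame(region = d$region[1], regime = d$regime[1],
                 bin_left = as.numeric(names(acc)),
                 volume = as.numeric(acc) / tot, stringsAsFactors = FALSE)
    }))
  out <- out[order(out$region, out$regime, out$bin_left), , drop = FALSE]
  rownames(out) <- NULL
  out
}
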