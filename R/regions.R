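#' Default study-region registry
#'
#' Six coastal regions along the eastern and southern coastal waters of Korea
#' (ESCK), split into a northern (CR1-CR3) and a southern (CR4-CR6) area at
#' latitude 37 degrees N, where the subpolar front sits during the autumn
#' spawning-migration season. Each region carries both its SST-averaging box
#' and a representative point (river mouth); the north/south assignment follows
#' the representative latitude.
#'
#' @return a data.frame with one row per region and columns `id`, `lat_min`,
#'   `lat_max`, `lon_min`, `lon_max`, `rep_lat`, `rep_lon`, `area`
#'   (`"north"` or `"south"`).
#' @examples
#' default_registry()
#' @export
default_registry <- function() {
  reg <- data.frame(
    id      = paste0("CR", 1:6),
    lat_min = c(38.5, 37.8, 37.4, 37.0, 35.4, 34.9),
    lat_max = c(38.7, 38.0, 37.6, 37.2, 35.6, 35.1),
    lon_min = c(128.4, 128.9, 129.1, 129.5, 129.4, 127.8),
    lon_max = c(128.6, 129.0, 129.3, 129.7, 129.6, 128.0),
    rep_lat = c(38.55, 37.86, 37.44, 36.97, 35.47, 34.95),
    rep_lon = c(128.41, 128.85, 129.15, 129.41, 129.39, 127.77),
    stringsAsFactors = FALSE
  )
  reg$area <- ifelse(reg$rep_lat >= 37.0, "north", "south")
  validate_registry(reg)
  reg
}

#' @keywords internal
validate_registry <- function(registry) {
  need <- c("id", "lat_min", "lat_max", "lon_min", "lon_max",
            "rep_lat", "rep_lon", "area")
  miss <- setdiff(need, names(registry))
  if (length(miss))
    stopf("registry is missing columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(registry$id))
    stopf("registry region ids must be unique")
  if (!all(registry$area %in% c("north", "south")))
    stopf("registry area must be 'north' or 'south'")
  bad <- registry$area != ifelse(registry$rep_lat >= 37.0, "north", "south")
  if (any(bad))
    stopf("area assignment inconsistent with 37 N split for: %s",
          paste(registry$id[bad], collapse = ", "))
  invisible(registry)
}

#' Check that a set of region ids resolves in a registry
#'
#' @param ids character vector of region ids used by a dataset.
#' @param registry a registry data.frame (see [default_registry()]).
#' @return invisibly `TRUE`; errors naming unresolved ids otherwise.
#' @export
check_region_ids <- function(ids, registry = default_registry()) {
  bad <- setdiff(unique(ids), registry$id)
  if (length(bad))
    stopf("region ids not in registry: %s", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Read or write a region registry as YAML
#'
#' @param path file path.
#' @param registry registry data.frame to write.
#' @return `read_registry` returns a validated registry data.frame.
#' @export
read_registry <- function(path) {
  lst <- yaml::read_yaml(path)
  reg <- do.call(rbind, lapply(lst$regions, function(r)
    data.frame(id = r$id, lat_min = r$lat[1], lat_max = r$lat[2],
               lon_min = r$lon[1], lon_max = r$lon[2],
               rep_lat = r$rep[1], rep_lon = r$rep[2],
               area = r$area, stringsAsFactors = FALSE)))
  validate_registry(reg)
  reg
}

#' @rdname read_registry
#' @export
write_registry <- function(registry, path) {
  validate_registry(registry)
  lst <- list(regions = lapply(seq_len(nrow(registry)), function(i) {
    r <- registry[i, ]
    list(id = r$id, lat = c(r$lat_min, r$lat_max),
         lon = c(r$lon_min, r$lon_max),
         rep = c(r$rep_lat, r$rep_lon), area = r$area)
  }))
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' The October-December analysis window
#'
#' All phenology statistics are expressed as integer day offsets from
#' October 1 (day 0) through December 31 (day 91) of the migration year.
#' October-December never contains February 29, so the window is always
#' 92 days.
#'
#' @param year calendar year of the window.
#' @return a list with `start`, `end` (Dates) and `year`.
#' @export
analysis_window <- function(year = 2000L) {
  list(start = as.Date(sprintf("%d-10-01", year)),
       end   = as.Date(sprintf("%d-12-31", year)),
       year  = as.integer(year))
}

#' Convert dates to day indices within the analysis window and back
#'
#' @param date a Date (or coercible) vector.
#' @param window an [analysis_window()].
#' @return `day_index` returns 0-based integer offsets from the window start;
#'   `index_day` is its inverse.
#' @examples
#' w <- analysis_window(2010)
#' day_index(as.Date("2010-11-15"), w)  # 45
#' @export
day_index <- function(date, window = analysis_window()) {
  date <- as.Date(date)
  idx <- as.integer(date - window$start)
  n <- as.integer(window$end - window$start)
  if (any(idx < 0L | idx > n, na.rm = TRUE))
    stopf("date outside the %s..%s analysis window",
          format(window$start), format(window$end))
  idx
}

#' @rdname day_index
#' @param index 0-based integer day offsets.
#' @export
index_day <- function(index, window = analysis_window()) {
  n <- as.integer(window$end - window$start)
  if (any(index < 0L | index > n, na.rm = TRUE))
    stopf("day index outside 0..%d", n)
  window$start + as.integer(index)
}

#' Average gridded SST cells inside a region's box
#'
#' Region boxes are closed; a grid cell contributes when its centre falls
#' inside the box. Operates on an in-memory long table of grid-cell values,
#' as produced by any gridded-SST reader.
#'
#' @param grid a data.frame with columns `lat`, `lon`, `date`, `sst`.
#' @param region one row of a registry data.frame.
#' @return a data.frame with columns `date`, `sst` (box-mean per date).
#' @export
extract_box_mean <- function(grid, region) {
  need <- c("lat", "lon", "date", "sst")
  miss <- setdiff(need, names(grid))
  if (length(miss))
    stopf("grid is missing columns: %s", paste(miss, collapse = ", "))
  inside <- grid$lat >= region$lat_min & grid$lat <= region$lat_max &
            grid$lon >= region$lon_min & grid$lon <= region$lon_max
  if (!any(inside))
    stopf("no grid cells fall inside region %s's box", region$id)
  sub <- grid[inside, , drop = FALSE]
  agg <- aggregate(sst ~ date, data = sub, FUN = mean)
  agg[order(agg$date), , drop = FALSE]
}
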