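## riskstats: class-area accounting, elevation-band stratification,
## ensemble means, per-decade trend rates and period-over-period change
## rates. Area = cell count x cell area (no latitude correction; the grid
## projection is opaque to the package).

#' Elevation bands
#'
#' @param edges Strictly increasing interior altitudes; the defaults
#'   2300/3600/4400/5000 m define the five bands used in the reference
#'   elevation accounting.
#' @param labels Optional band names (length `length(edges) + 1`).
#' @return Object of class `elevation_bands`.
#' @export
elevation_bands <- function(edges = c(2300, 3600, 4400, 5000),
                            labels = NULL) {
  edges <- as.numeric(edges)
  if (is.unsorted(edges, strictly = TRUE))
    stop("band edges must be strictly increasing")
  if (is.null(labels)) {
    lo <- c(-Inf, edges); hi <- c(edges, Inf)
    labels <- sprintf("%s-%s", lo, hi)
    labels[1L] <- paste0("<", edges[1L])
    labels[length(labels)] <- paste0(">", edges[length(edges)])
  }
  if (length(labels) != length(edges) + 1L)
    stop("need one more label than edges")
  structure(list(edges = edges, labels = as.character(labels)),
            class = "elevation_bands")
}

.class_levels <- function(class_raster) {
  if (is.null(class_raster$levels))
    stop("class raster carries no `levels` legend")
  class_raster$levels
}

#' Class-area proportions of a raster
#'
#' Percentage of unmasked cells in each class; classes absent from the
#' raster report 0. The `percent` column sums to 100 per stratum.
#'
#' @param class_raster Integer-coded class grid with `levels`.
#' @return Data frame with columns `stratum` (`"all"`), `class`, `percent`.
#' @export
class_proportions <- function(class_raster) {
  lv <- .class_levels(class_raster)
  codes <- class_raster$values[!class_raster$mask]
  if (!length(codes)) stop("raster has no unmasked cells")
  cnt <- tabulate(as.integer(codes), length(lv))
  data.frame(stratum = "all", class = lv,
             percent = 100 * cnt / sum(cnt),
             stringsAsFactors = FALSE)
}

#' Class proportions stratified by elevation band
#'
#' Per-band class percentages plus each band's share of the total unmasked
#' area. Bands containing no cells are omitted from the table (they are
#' listed in the `"empty_bands"` attribute), never reported as 0/0.
#'
#' @param class_raster Integer-coded class grid with `levels`.
#' @param dem Elevation grid aligned with `class_raster`.
#' @param bands An [elevation_bands()].
#' @return Data frame with columns `stratum`, `band_share`, `class`,
#'   `percent`; `percent` sums to 100 within each stratum.
#' @export
band_proportions <- function(class_raster, dem,
                             bands = elevation_bands()) {
  stopifnot(inherits(bands, "elevation_bands"))
  if (!same_geometry(class_raster, dem))
    stop("class raster and DEM are not aligned")
  lv <- .class_levels(class_raster)
  live <- !(class_raster$mask | dem$mask)
  if (!any(live)) stop("no cells unmasked in both rasters")
  codes <- as.integer(class_raster$values[live])
  band_of <- findInterval(dem$values[live], bands$edges) + 1L
  total <- sum(live)
  rows <- list()
  empty <- character(0)
  for (b in seq_along(bands$labels)) {
    in_b <- band_of == b
    if (!any(in_b)) {
      empty <- c(empty, bands$labels[b])
      next
    }
    cnt <- tabulate(codes[in_b], length(lv))
    rows[[length(rows) + 1L]] <- data.frame(
      stratum = bands$labels[b],
      band_share = 100 * sum(in_b) / total,
      class = lv,
      percent = 100 * cnt / sum(cnt),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "empty_bands") <- empty
  out
}

#' Ensemble mean of scenario series
#'
#' Unweighted per-year mean across ensemble members of one scenario and
#' variable. Members must agree on scenario, variable, units and the year
#' grid.
#'
#' @param members Long data frame with columns `scenario`, `member`,
#'   `year`, `variable`, `value`, `units` (one or more members), or a list
#'   of such single-member frames.
#' @return The same format with `member = "ensemble"`.
#' @export
ensemble_mean <- function(members) {
  if (is.data.frame(members)) df <- members
  else df <- do.call(rbind, members)
  need <- c("scenario", "member", "year", "variable", "value", "units")
  stopifnot(all(need %in% names(df)))
  if (length(unique(df$scenario)) != 1L || length(unique(df$variable)) != 1L
      || length(unique(df$units)) != 1L)
    stop("members must share scenario, variable and units")
  parts <- split(df, df$member)
  years <- sort(unique(parts[[1L]]$year))
  for (p in parts) {
    if (!identical(sort(unique(p$year)), years) || nrow(p) != length(years))
      stop("members have mismatched year grids")
  }
  mean_by_year <- tapply(df$value, df$year, mean)
  data.frame(scenario = df$scenario[1L], member = "ensemble",
             year = as.numeric(names(mean_by_year)),
             variable = df$variable[1L],
             value = as.numeric(mean_by_year),
             units = df$units[1L],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-decade linear trend of a series
#'
#' Ordinary-least-squares slope of value on calendar year, scaled to a
#' per-decade rate, with the R-squared of the fit. A constant series
#' reports rate 0 and R-squared 0 (the no-trend convention).
#'
#' @param series Data frame with columns `year` and `value` (a single
#'   member and variable); at least 3 years.
#' @return List with `rate_per_decade` and `r_squared`.
#' @export
trend_rate <- function(series) {
  stopifnot(all(c("year", "value") %in% names(series)))
  x <- series$year; y <- series$value
  if (length(x) < 3L) stop("need at least 3 years")
  if (stats::var(x) == 0) stop("constant year vector")
  if (stats::var(y) == 0) return(list(rate_per_decade = 0, r_squared = 0))
  fit <- stats::lm(y ~ x)
  # R^2 from the residuals directly; summary.lm warns on perfect fits
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  list(rate_per_decade = unname(stats::coef(fit)[2L]) * 10,
       r_squared = r2)
}

#' The four forecast periods
#'
#' @return Named list of year vectors: 2021-2040, 2041-2060, 2061-2080,
#'   2081-2100.
#' @export
eai_periods <- function() {
  list("2021-2040" = 2021:2040, "2041-2060" = 2041:2060,
       "2061-2080" = 2061:2080, "2081-2100" = 2081:2100)
}

#' Cell-wise mean over a period
#'
#' @param per_year_rasters List of grids named by year.
#' @param period Period name (see [eai_periods()]) or integer year vector.
#' @return Grid of cell-wise means; a cell masked in any year is masked.
#' @export
period_mean_stack <- function(per_year_rasters, period) {
  years <- if (is.character(period) && length(period) == 1L) {
    p <- eai_periods()[[period]]
    if (is.null(p)) stop("unknown period: ", period)
    p
  } else as.integer(period)
  have <- names(per_year_rasters)
  missing_y <- setdiff(as.character(years), have)
  if (length(missing_y))
    stop("missing year(s): ", paste(missing_y, collapse = ", "))
  grids <- per_year_rasters[as.character(years)]
  grid_map(grids, function(...) Reduce(`+`, list(...)) / length(grids))
}

#' Period-over-period change in class shares
#'
#' Percentage-point differences `prop_t2 - prop_t1`, per class and
#' stratum. Within each stratum the differences sum to zero because each
#' proportion table sums to 100.
#'
#' @param prop_t1,prop_t2 Proportion tables from [class_proportions()] or
#'   [band_proportions()] with identical class/stratum sets.
#' @return Data frame with columns `stratum`, `class`, `delta_pp`.
#' @export
change_rates <- function(prop_t1, prop_t2) {
  k1 <- paste(prop_t1$stratum, prop_t1$class, sep = "\r")
  k2 <- paste(prop_t2$stratum, prop_t2$class, sep = "\r")
  if (!setequal(k1, k2) || anyDuplicated(k1) || anyDuplicated(k2))
    stop("proportion tables have mismatched class/stratum sets")
  i <- match(k1, k2)
  data.frame(stratum = prop_t1$stratum, class = prop_t1$class,
             delta_pp = prop_t2$percent[i] - prop_t1$percent,
             stringsAsFactors = FALSE)
}

#' Regional mean of a grid
#'
#' @param grid An `eai_grid`.
#' @return Mean over unmasked cells.
#' @export
regional_mean <- function(grid) {
  v <- grid$values[!grid$mask]
  if (!length(v)) stop("grid has no unmasked cells")
  mean(v)
}
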