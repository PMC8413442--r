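## scoring: raw factor rasters -> score rasters via reclassification
## lookup tables. Interval convention throughout: bins printed "a-b" are
## half-open [a, b); "< a" is (-Inf, a); "> b" is [b, Inf). Scores are a
## fixed printed set -- no interpolation ever.

#' Construct a score table
#'
#' A reclassification lookup: either ordered value bins covering
#' (-Inf, Inf) mapped to scores, or a category-to-score map. All scores
#' must lie in (0, 10] so downstream geometric means are defined.
#'
#' @param table_id Factor name the table applies to.
#' @param kind `"binned"` or `"categorical"`.
#' @param bins For binned tables, a data frame with columns `lower`,
#'   `upper`, `score`; bins must be contiguous, non-overlapping and cover
#'   the whole real line. Intervals are closed on the left, open on the
#'   right.
#' @param categories For categorical tables, a named numeric vector
#'   (category code -> score).
#' @return An object of class `score_table`.
#' @export
score_table <- function(table_id, kind = c("binned", "categorical"),
                        bins = NULL, categories = NULL) {
  kind <- match.arg(kind)
  if (kind == "binned") {
    stopifnot(is.data.frame(bins),
              all(c("lower", "upper", "score") %in% names(bins)))
    bins <- bins[order(bins$lower), c("lower", "upper", "score")]
    if (bins$lower[1L] != -Inf || bins$upper[nrow(bins)] != Inf)
      stop("bins of `", table_id, "` do not cover (-Inf, Inf)")
    if (nrow(bins) > 1L &&
        any(bins$upper[-nrow(bins)] != bins$lower[-1L]))
      stop("bins of `", table_id, "` are not contiguous")
    scores <- bins$score
  } else {
    stopifnot(is.numeric(categories), !is.null(names(categories)),
              !anyDuplicated(names(categories)))
    scores <- unname(categories)
  }
  if (any(scores <= 0 | scores > 10))
    stop("scores of `", table_id, "` must lie in (0, 10]")
  direction <- if (kind == "categorical") "categorical"
  else if (!is.unsorted(scores)) "ascending_scores_with_value"
  else if (!is.unsorted(rev(scores))) "descending_scores_with_value"
  else "nonmonotone"
  structure(list(table_id = table_id, kind = kind, bins = bins,
                 categories = categories, direction = direction),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("<score_table> %s (%s, %s)\n", x$table_id, x$kind, x$direction))
  if (x$kind == "binned") print(x$bins) else print(x$categories)
  invisible(x)
}

#' Read score tables from CSV
#'
#' @param path CSV with columns `table_id`, `kind`, `lower`, `upper`,
#'   `category`, `score` (binned rows leave `category` empty, categorical
#'   rows leave the bounds empty).
#' @return Named list of [score_table()] objects.
#' @export
read_score_tables <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(lower = "character",
                                       upper = "character"))
  out <- list()
  for (id in unique(df$table_id)) {
    rows <- df[df$table_id == id, ]
    kind <- rows$kind[1L]
    if (kind == "binned") {
      out[[id]] <- score_table(
        id, "binned",
        bins = data.frame(lower = as.numeric(rows$lower),
                          upper = as.numeric(rows$upper),
                          score = rows$score))
    } else {
      out[[id]] <- score_table(
        id, "categorical",
        categories = stats::setNames(rows$score, rows$category))
    }
  }
  out
}

#' Write score tables to CSV
#'
#' Inverse of [read_score_tables()]; the shipped defaults live in
#' `system.file("extdata", "score_tables.csv", package = "eairisk")` and can
#' be copied, edited and passed back to the pipeline.
#'
#' @param tables Named list of score tables.
#' @param path Output CSV path.
#' @export
write_score_tables <- function(tables, path) {
  rows <- lapply(tables, function(tb) {
    if (tb$kind == "binned") {
      data.frame(table_id = tb$table_id, kind = "binned",
                 lower = tb$bins$lower, upper = tb$bins$upper,
                 category = "", score = tb$bins$score)
    } else {
      data.frame(table_id = tb$table_id, kind = "categorical",
                 lower = NA_real_, upper = NA_real_,
                 category = names(tb$categories),
                 score = unname(tb$categories))
    }
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
}

#' Default factor score tables
#'
#' The sixteen shipped lookup tables, one per factor of the three quality
#' indices: precipitation (mm), temperature (deg C), drought index,
#' altitude (m; the one table whose scores DECREASE with the raw value),
#' photosynthetically active radiation (MJ/m2), accumulated temperature
#' >= 10 deg C (degree-days); soil depth (cm, a step function through the
#' printed points), texture, erosion class, organic matter, moisture
#' (m3/m3); vegetation coverage, richness, resistance class, NPP
#' (gC/m2/yr) and aspect class. The global minimum score is 1.25
#' (accumulated temperature), so every geometric mean is defined.
#'
#' @return Named list of 16 [score_table()] objects.
#' @export
default_tables <- function() {
  path <- system.file("extdata", "score_tables.csv", package = "eairisk")
  if (path == "") stop("shipped score_tables.csv not found")
  read_score_tables(path)
}

#' Score a factor raster through a lookup table
#'
#' Each unmasked cell receives the score of the bin or category containing
#' its value; the mask is unchanged. Categorical rasters are integer-coded
#' and must carry a `levels` vector naming the codes; codes absent from the
#' table raise an error listing the offending codes and their cell counts.
#' Vegetation-cover inputs above 100 trigger a validation warning (the
#' printed bins extend beyond 100 and are applied as printed).
#'
#' @param raster An `eai_grid`.
#' @param table A [score_table()].
#' @return Score grid with the same geometry and mask.
#' @export
score_factor <- function(raster, table) {
  stopifnot(is_grid(raster), inherits(table, "score_table"))
  v <- raster$values
  out <- matrix(NA_real_, nrow(v), ncol(v))
  live <- !raster$mask
  if (table$kind == "binned") {
    if (table$table_id == "Vc" && any(v[live] > 100))
      warning("vegetation coverage values exceed 100; ",
              "bins above 100 applied as printed")
    breaks <- table$bins$lower[-1L]            # interior lower edges
    idx <- findInterval(v[live], breaks) + 1L  # [lower, upper)
    out[live] <- table$bins$score[idx]
  } else {
    if (is.null(raster$levels))
      stop("categorical factor `", table$table_id,
           "` requires an integer-coded grid with `levels`")
    codes <- raster$levels[v[live]]
    hit <- match(codes, names(table$categories))
    if (anyNA(hit)) {
      bad <- table(codes[is.na(hit)])
      stop("categorical code(s) absent from table `", table$table_id,
           "`: ", paste(sprintf("%s (%d cells)", names(bad), bad),
                        collapse = ", "))
    }
    out[live] <- unname(table$categories)[hit]
  }
  grid_create(out, raster$mask, raster$cell_size, raster$origin,
              raster$crs_tag)
}

#' Derive aspect classes from a DEM
#'
#' Computes the downslope azimuth from central differences of the elevation
#' surface and buckets it into the four insolation classes used by the
#' vegetation aspect table, northern-hemisphere convention: south-facing
#' slopes are sunny, north-facing shady. Flat cells default to
#' `"Half sunny"`.
#'
#' @param dem Elevation grid.
#' @return Integer-coded categorical grid with levels
#'   `c("Sunny", "Half sunny", "Half shady", "Shady")`.
#' @export
aspect_from_dem <- function(dem) {
  stopifnot(is_grid(dem))
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  pad <- function(m, dr, dc) {
    r <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
    c <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
    m[r, c, drop = FALSE]
  }
  dz_dx <- (pad(z, 0, 1) - pad(z, 0, -1)) / (2 * dem$cell_size)  # east +
  dz_dy <- (pad(z, -1, 0) - pad(z, 1, 0)) / (2 * dem$cell_size)  # north +
  # azimuth of the downslope direction, degrees clockwise from north
  az <- (atan2(-dz_dx, -dz_dy) * 180 / pi) %% 360
  lv <- c("Sunny", "Half sunny", "Half shady", "Shady")
  code <- matrix(2L, nr, nc)  # flat -> Half sunny
  steep <- sqrt(dz_dx^2 + dz_dy^2) > 1e-12
  code[steep & (az < 45 | az >= 315)] <- 4L                   # north: shady
  code[steep & az >= 45 & az < 135] <- 3L                     # east
  code[steep & az >= 135 & az < 225] <- 1L                    # south: sunny
  code[steep & az >= 225 & az < 315] <- 2L                    # west
  g <- grid_create(code, dem$mask, dem$cell_size, dem$origin, dem$crs_tag,
                   levels = lv)
  g
}
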