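## gridcore: in-memory raster model + ESRI ASCII grid I/O + alignment.
## A grid is row-major north-up: row 1 is the northernmost row, column 1
## the westernmost column. `origin` is the (x, y) of the TOP-LEFT corner.

#' Construct a grid
#'
#' The raster unit used by every stage of the pipeline: a numeric matrix of
#' cell values, a logical nodata mask of the same shape (`TRUE` = missing),
#' a square cell size, the coordinates of the top-left corner and an opaque
#' CRS tag that is carried through but never interpreted.
#'
#' @param values Numeric matrix; row 1 is the northernmost row.
#' @param mask Logical matrix of the same shape, `TRUE` where the cell is
#'   missing. Defaults to `is.na(values)`.
#' @param cell_size Positive cell edge length (the reference analyses use
#'   500 m cells).
#' @param origin Numeric length-2, (x, y) of the top-left corner.
#' @param crs_tag Opaque coordinate-reference string, carried verbatim.
#' @param levels Optional character vector naming the categories of an
#'   integer-coded categorical raster (value `v` means `levels[v]`).
#' @return An object of class `eai_grid`.
#' @export
grid_create <- function(values, mask = NULL, cell_size = 500,
                        origin = c(0, 0), crs_tag = "", levels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(mask)) mask <- is.na(values)
  mask <- as.matrix(mask)
  if (!is.logical(mask)) stop("`mask` must be logical")
  if (!identical(dim(values), dim(mask)))
    stop("`values` and `mask` must have identical shape")
  if (!(is.numeric(cell_size) && length(cell_size) == 1L && cell_size > 0))
    stop("`cell_size` must be a single positive number")
  mask <- mask | is.na(values)
  values[mask] <- NA_real_
  structure(
    list(values = values, mask = mask, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin)[1:2], crs_tag = as.character(crs_tag),
         levels = levels),
    class = "eai_grid")
}

#' @export
print.eai_grid <- function(x, ...) {
  cat(sprintf("<eai_grid> %d x %d cells, cell size %g, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cell_size,
              x$origin[1], x$origin[2]))
  v <- x$values[!x$mask]
  if (length(v)) {
    cat(sprintf("  unmasked: %d cells, range [%g, %g]\n",
                length(v), min(v), max(v)))
  } else cat("  fully masked\n")
  if (!is.null(x$levels))
    cat("  categorical levels:", paste(x$levels, collapse = ", "), "\n")
  invisible(x)
}

is_grid <- function(x) inherits(x, "eai_grid")

#' Test whether two grids share the same geometry
#'
#' Same shape, cell size and origin (within a small tolerance proportional
#' to the cell size).
#' @param a,b Grids.
#' @return Logical scalar.
#' @export
same_geometry <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(abs(a$cell_size - b$cell_size) <= 1e-9 * a$cell_size) &&
    all(abs(a$origin - b$origin) <= 1e-6 * a$cell_size)
}

#' Apply a cell-wise function across aligned grids
#'
#' Nodata propagates: a cell masked in any input is masked in the output.
#'
#' @param grids List of aligned grids.
#' @param f Function of one numeric matrix argument per grid.
#' @return A grid with the combined mask.
#' @export
grid_map <- function(grids, f) {
  stopifnot(length(grids) >= 1L)
  ref <- grids[[1L]]
  for (g in grids) {
    if (!same_geometry(ref, g)) stop("grids are not aligned")
  }
  mask <- Reduce(`|`, lapply(grids, `[[`, "mask"))
  vals <- do.call(f, lapply(grids, `[[`, "values"))
  vals[mask] <- NA_real_
  grid_create(vals, mask, ref$cell_size, ref$origin, ref$crs_tag)
}

## ---------------------------------------------------------------- registry

#' Environmental factor registry
#'
#' The factor names admitted in a [factor_stack()]: six climate factors
#' (Pr precipitation, T temperature, Di drought index, Al altitude,
#' Par photosynthetically active radiation, At accumulated temperature
#' over 10 degrees C), five soil factors (Sd depth, St texture, Sei erosion
#' class, Som organic matter, Sm moisture), five vegetation factors
#' (Vc cover, Vr richness, Vrr resistance class, NPP net primary
#' productivity, A aspect class) and the DEM. The `kind` column drives the
#' resampling contract: categorical factors may only be aligned with
#' nearest-neighbour.
#'
#' @return Data frame with columns `name`, `kind`, `group`.
#' @export
factor_registry <- function() {
  data.frame(
    name = c("Pr", "T", "Di", "Al", "Par", "At",
             "Sd", "St", "Sei", "Som", "Sm",
             "Vc", "Vr", "Vrr", "NPP", "A", "DEM"),
    kind = c(rep("continuous", 8L), "categorical", "continuous",
             "continuous", "continuous", "continuous", "categorical",
             "continuous", "categorical", "continuous"),
    group = c(rep("climate", 6L), rep("soil", 5L),
              rep("vegetation", 5L), "terrain"),
    stringsAsFactors = FALSE)
}

factor_kind <- function(name) {
  reg <- factor_registry()
  i <- match(name, reg$name)
  if (is.na(i)) NA_character_ else reg$kind[i]
}

#' Bundle aligned factor grids into a stack
#'
#' @param grids Named list of grids; names must come from [factor_registry()]
#'   and all grids must share one geometry (checked, not assumed).
#' @return An object of class `eai_stack` (a named list of grids).
#' @export
factor_stack <- function(grids) {
  if (is.null(names(grids)) || any(names(grids) == ""))
    stop("factor grids must be named")
  unknown <- setdiff(names(grids), factor_registry()$name)
  if (length(unknown))
    stop("unknown factor name(s): ", paste(unknown, collapse = ", "))
  ref <- grids[[1L]]
  for (nm in names(grids)) {
    if (!is_grid(grids[[nm]])) stop("`", nm, "` is not a grid")
    if (!same_geometry(ref, grids[[nm]]))
      stop("factor `", nm, "` is not aligned with the rest of the stack")
  }
  structure(grids, class = "eai_stack")
}

#' @export
print.eai_stack <- function(x, ...) {
  cat(sprintf("<eai_stack> %d factors (%s), %d x %d cells\n",
              length(x), paste(names(x), collapse = ", "),
              nrow(x[[1]]$values), ncol(x[[1]]$values)))
  invisible(x)
}

## ---------------------------------------------------------------------- IO

#' Read a raster from an ESRI ASCII grid file
#'
#' Plain-text `.asc` rasters with the usual six-line header; the nodata mask
#' is derived from the file's `NODATA_value`. If the header declares no
#' nodata value an all-false mask is used and a warning is emitted. A `.prj`
#' sidecar, when present, is read verbatim into `crs_tag`.
#'
#' @param path Path to an `.asc` file.
#' @param band Band index; ASCII grids are single-band, so only 1 is valid.
#' @return An `eai_grid`.
#' @export
read_grid <- function(path, band = 1L) {
  if (!file.exists(path)) stop("cannot read raster: no such file: ", path)
  if (!grepl("\\.(asc|agr)$", path, ignore.case = TRUE))
    stop("unsupported raster format (expected ESRI ASCII .asc): ", path)
  if (band != 1L) stop("ASCII grids are single-band; band must be 1")
  lines <- readLines(path, n = 7L)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(parts) == 2L && grepl("^[A-Za-z_]+$", parts[1L])) {
      hdr[[tolower(parts[1L])]] <- parts[2L]
      n_hdr <- n_hdr + 1L
    } else break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("cannot read raster: malformed ASCII grid header: ", path)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  cs <- as.numeric(hdr$cellsize)
  vals <- scan(path, what = double(), skip = n_hdr, quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("cannot read raster: expected ", nr * nc, " cells, got ",
         length(vals), ": ", path)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) {
    nd <- as.numeric(hdr$nodata_value)
    mask <- !is.na(m) & m == nd
    mask <- mask | is.na(m)
  } else {
    warning("no NODATA_value declared in ", path, "; assuming all cells valid")
    mask <- is.na(m)
  }
  prj <- sub("\\.(asc|agr)$", ".prj", path, ignore.case = TRUE)
  crs <- if (file.exists(prj)) paste(readLines(prj), collapse = "\n") else ""
  origin <- c(as.numeric(hdr$xllcorner),
              as.numeric(hdr$yllcorner) + nr * cs)
  m[mask] <- NA_real_
  grid_create(m, mask, cs, origin, crs)
}

#' Write a raster to an ESRI ASCII grid file
#'
#' Values are written with 17 significant digits so a read/write round trip
#' reproduces doubles bit-for-bit; masked cells are written as the nodata
#' value (-9999, shifted if -9999 is a real data value). A non-empty
#' `crs_tag` is written to a `.prj` sidecar.
#'
#' @param grid An `eai_grid`.
#' @param path Output path (`.asc`).
#' @export
write_grid <- function(grid, path) {
  stopifnot(is_grid(grid))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("cannot write raster: no such directory: ", dir)
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  nodata <- -9999
  v <- grid$values[!grid$mask]
  while (length(v) && any(v == nodata, na.rm = TRUE)) nodata <- nodata * 3 - 1
  m <- grid$values
  m[grid$mask] <- nodata
  hdr <- c(sprintf("ncols %d", nc),
           sprintf("nrows %d", nr),
           sprintf("xllcorner %.17g", grid$origin[1]),
           sprintf("yllcorner %.17g", grid$origin[2] - nr * grid$cell_size),
           sprintf("cellsize %.17g", grid$cell_size),
           sprintf("NODATA_value %.17g", nodata))
  body <- apply(m, 1L, function(row)
    paste(sprintf("%.17g", row), collapse = " "))
  ok <- tryCatch({
    writeLines(c(hdr, body), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write raster: ", path)
  if (nzchar(grid$crs_tag)) {
    writeLines(grid$crs_tag,
               sub("\\.(asc|agr)$", ".prj", path, ignore.case = TRUE))
  }
  invisible(path)
}

## --------------------------------------------------------------- alignment

# Fractional source position (in cell-center units) of target cell centers.
.target_centers <- function(target) {
  nr <- nrow(target$values); nc <- ncol(target$values)
  list(x = target$origin[1] + (seq_len(nc) - 0.5) * target$cell_size,
       y = target$origin[2] - (seq_len(nr) - 0.5) * target$cell_size)
}

.resample_one <- function(g, target, method) {
  if (same_geometry(g, target)) return(g)
  nr_t <- nrow(target$values); nc_t <- ncol(target$values)
  ctr <- .target_centers(target)
  # continuous source index of each target center (1-based, cell centers)
  u <- (ctr$x - g$origin[1]) / g$cell_size + 0.5       # columns
  w <- (g$origin[2] - ctr$y) / g$cell_size + 0.5       # rows
  nr_s <- nrow(g$values); nc_s <- ncol(g$values)
  out <- matrix(NA_real_, nr_t, nc_t)
  if (method == "nearest") {
    ci <- pmin(pmax(round(u), 1L), nc_s)
    ri <- pmin(pmax(round(w), 1L), nr_s)
    inside <- outer(w >= 0.5 - 1e-9 & w <= nr_s + 0.5 + 1e-9,
                    u >= 0.5 - 1e-9 & u <= nc_s + 0.5 + 1e-9, `&`)
    idx <- cbind(rep(ri, times = nc_t), rep(ci, each = nr_t))
    vals <- g$values[idx]
    vals[!inside] <- NA_real_
    out[] <- vals
  } else { # bilinear
    c0 <- pmin(pmax(floor(u), 1L), nc_s - 1L)
    r0 <- pmin(pmax(floor(w), 1L), nr_s - 1L)
    fu <- pmin(pmax(u - c0, 0), 1)
    fw <- pmin(pmax(w - r0, 0), 1)
    V <- g$values
    for (j in seq_len(nc_t)) {
      cj <- c0[j]; fj <- fu[j]
      v00 <- V[cbind(r0, cj)];     v01 <- V[cbind(r0, cj + 1L)]
      v10 <- V[cbind(r0 + 1L, cj)]; v11 <- V[cbind(r0 + 1L, cj + 1L)]
      out[, j] <- (1 - fw) * ((1 - fj) * v00 + fj * v01) +
        fw * ((1 - fj) * v10 + fj * v11)
    }
    inside <- outer(w >= 0.5 - 1e-9 & w <= nr_s + 0.5 + 1e-9,
                    u >= 0.5 - 1e-9 & u <= nc_s + 0.5 + 1e-9, `&`)
    out[!inside] <- NA_real_
  }
  grid_create(out, is.na(out), target$cell_size, target$origin,
              g$crs_tag, g$levels)
}

#' Align grids onto a target geometry
#'
#' Resamples each grid onto the target's shape, origin and cell size.
#' Nearest-neighbour never invents values and is mandatory for categorical
#' factors; bilinear is for continuous fields. When `grids` is named, names
#' are checked against [factor_registry()] and requesting bilinear for a
#' factor registered as categorical is a contract error. Cells whose centre
#' falls outside the source extent, or that draw on any masked source cell,
#' come out masked.
#'
#' @param grids A grid or (possibly named) list of grids.
#' @param target Grid supplying the output geometry.
#' @param method `"nearest"` or `"bilinear"`.
#' @return A list of aligned grids (or a single grid if one was given).
#' @export
align <- function(grids, target, method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  single <- is_grid(grids)
  if (single) grids <- list(grids)
  if (method == "bilinear" && !is.null(names(grids))) {
    kinds <- vapply(names(grids), factor_kind, character(1))
    bad <- names(grids)[!is.na(kinds) & kinds == "categorical"]
    if (length(bad))
      stop("bilinear resampling requested for categorical factor(s): ",
           paste(bad, collapse = ", "))
  }
  out <- lapply(grids, .resample_one, target = target, method = method)
  if (single) out[[1L]] else out
}
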