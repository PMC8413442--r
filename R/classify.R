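## classify: five-class grading of index rasters, either by the fixed
## published breakpoints or by Fisher-Jenks natural breaks. Endpoint
## convention everywhere: intervals are closed below, [b_i, b_{i+1}); the
## lowest class is open below and the highest closed above, so a value
## equal to a break belongs to the upper class.

#' Construct a classification scheme
#'
#' @param scheme_id Name of the scheme.
#' @param breaks Strictly increasing interior break values (k-1 of them).
#' @param labels k class labels ordered from low index value to high.
#' @param orientation `"quality"` (higher value = better) or `"risk"`
#'   (higher value = lower risk; the EAI convention).
#' @return Object of class `class_scheme`.
#' @export
class_scheme <- function(scheme_id, breaks, labels,
                         orientation = c("quality", "risk")) {
  orientation <- match.arg(orientation)
  breaks <- as.numeric(breaks)
  if (is.unsorted(breaks, strictly = TRUE))
    stop("breaks must be strictly increasing")
  if (length(labels) != length(breaks) + 1L)
    stop("need exactly one more label than breaks")
  structure(list(scheme_id = scheme_id, breaks = breaks,
                 labels = as.character(labels), orientation = orientation),
            class = "class_scheme")
}

#' @export
print.class_scheme <- function(x, ...) {
  cat(sprintf("<class_scheme> %s (%s)\n", x$scheme_id, x$orientation))
  lo <- c(-Inf, x$breaks); hi <- c(x$breaks, Inf)
  for (i in seq_along(x$labels))
    cat(sprintf("  [%g, %g) -> %s\n", lo[i], hi[i], x$labels[i]))
  invisible(x)
}

#' Published five-class grading schemes
#'
#' The fixed breakpoints of the reference study for the three quality
#' indices and for EAI-based ecological risk. The risk labels run HeERA,
#' HERA, LERA, LeERA, PERA from low to high EAI: LOW EAI means HIGH risk,
#' so the "potential risk" class PERA sits above 6.18.
#'
#' @return Named list of [class_scheme()] objects with ids `cqi`, `sqi`,
#'   `vqi` and `eai_risk`.
#' @export
paper_schemes <- function() {
  list(
    cqi = class_scheme("cqi", c(2.89, 3.82, 4.85, 6.21),
                       c("LeCQ", "LCQ", "GCQ", "HCQ", "HeCQ"), "quality"),
    sqi = class_scheme("sqi", c(3.88, 5.14, 6.36, 7.41),
                       c("LeSQ", "LSQ", "GSQ", "HSQ", "HeSQ"), "quality"),
    vqi = class_scheme("vqi", c(3.53, 5.02, 6.55, 7.80),
                       c("LeVQ", "LVQ", "GVQ", "HVQ", "HeVQ"), "quality"),
    eai_risk = class_scheme("eai_risk", c(2.66, 3.66, 4.86, 6.18),
                            c("HeERA", "HERA", "LERA", "LeERA", "PERA"),
                            "risk"))
}

#' Classify a raster by fixed breaks
#'
#' Assigns each unmasked cell the integer code of its interval (1 = first
#' label). A value exactly equal to a break belongs to the upper class.
#' Masked cells stay masked.
#'
#' @param raster Index grid to classify.
#' @param scheme A [class_scheme()].
#' @return Integer-coded grid whose `levels` are the scheme labels.
#' @export
classify_by_breaks <- function(raster, scheme) {
  stopifnot(is_grid(raster), inherits(scheme, "class_scheme"))
  v <- raster$values
  out <- matrix(NA_real_, nrow(v), ncol(v))
  live <- !raster$mask
  out[live] <- findInterval(v[live], scheme$breaks) + 1L
  grid_create(out, raster$mask, raster$cell_size, raster$origin,
              raster$crs_tag, levels = scheme$labels)
}

#' Write a class legend CSV
#'
#' Sidecar legend for an integer-coded class raster: columns `code`,
#' `label`, `lower`, `upper`.
#'
#' @param scheme A [class_scheme()].
#' @param path Output CSV path.
#' @export
write_class_legend <- function(scheme, path) {
  df <- data.frame(code = seq_along(scheme$labels),
                   label = scheme$labels,
                   lower = c(-Inf, scheme$breaks),
                   upper = c(scheme$breaks, Inf))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Prefix-sum machinery for weighted within-class sums of squares.
.wss_prefix <- function(v, w) {
  list(W = cumsum(w), S1 = cumsum(w * v), S2 = cumsum(w * v^2))
}

# SSE of values i..j (1-based, inclusive) given prefix sums; i and j may
# be vectors.
.wss_range <- function(ps, i, j) {
  W0 <- c(0, ps$W); S10 <- c(0, ps$S1); S20 <- c(0, ps$S2)
  W <- W0[j + 1L] - W0[i]
  S1 <- S10[j + 1L] - S10[i]
  S2 <- S20[j + 1L] - S20[i]
  pmax(S2 - S1^2 / W, 0)
}

#' Fisher-Jenks natural breaks
#'
#' Exact optimal 1-D classification: the k-class partition minimising the
#' total within-class sum of squared deviations, found by dynamic
#' programming over the sorted unique values with frequency weights. No
#' sampling is involved, so the result is deterministic. Returned breaks
#' follow the lower-closed convention: each break is the smallest value of
#' the class above it, so `findInterval`-style classification reproduces
#' the optimal partition.
#'
#' @param values Numeric vector (NAs dropped); needs at least `k` distinct
#'   finite values.
#' @param k Number of classes.
#' @return Numeric vector of k-1 interior breaks, with the achieved
#'   within-class SSD in attribute `"ssd"`.
#' @export
jenks_breaks <- function(values, k) {
  v <- values[is.finite(values)]
  if (k < 1L) stop("k must be at least 1")
  tab <- table(v)
  vs <- as.numeric(names(tab))
  wt <- as.numeric(tab)
  u <- length(vs)
  if (u < k)
    stop("need at least ", k, " distinct finite values, got ", u)
  if (k == 1L) {
    ps <- .wss_prefix(vs, wt)
    return(structure(numeric(0), ssd = .wss_range(ps, 1L, u)))
  }
  ps <- .wss_prefix(vs, wt)
  D <- matrix(Inf, k, u)      # D[m, j]: best SSD for vs[1..j] in m classes
  A <- matrix(0L, k, u)       # A[m, j]: start index of the m-th class
  D[1L, ] <- .wss_range(ps, 1L, seq_len(u))
  A[1L, ] <- 1L
  for (m in 2L:k) {
    for (j in m:u) {
      i <- m:j                # candidate start of class m
      cand <- D[m - 1L, i - 1L] + .wss_range(ps, i, j)
      best <- which.min(cand)
      D[m, j] <- cand[best]
      A[m, j] <- i[best]
    }
  }
  starts <- integer(k)
  j <- u
  for (m in k:1L) {
    starts[m] <- A[m, j]
    j <- starts[m] - 1L
  }
  structure(vs[starts[-1L]], ssd = D[k, u])
}

#' Within-class sum of squared deviations for given breaks
#'
#' Objective value of a 1-D classification under the package's endpoint
#' convention (lower-closed intervals). Used to compare natural-breaks
#' output against alternative break sets.
#'
#' @param values Numeric vector (non-finite values dropped).
#' @param breaks Interior break values.
#' @return Total within-class SSD.
#' @export
class_ssd <- function(values, breaks) {
  v <- values[is.finite(values)]
  cls <- findInterval(v, breaks) + 1L
  sum(vapply(split(v, cls), function(x) sum((x - mean(x))^2), numeric(1)))
}
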