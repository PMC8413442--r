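## indices: the three quality indices (geometric means of scored factors)
## and the weighted Environmental Area Index. Low EAI = high ecological
## risk.

.CQI_FACTORS <- c("Pr", "T", "Di", "Al", "Par", "At")
.SQI_FACTORS <- c("Sd", "St", "Sei", "Som", "Sm")
.VQI_FACTORS <- c("Vc", "Vr", "Vrr", "NPP", "A")

#' Construct an index raster
#'
#' @param index_id One of `"CQI"`, `"SQI"`, `"VQI"`, `"EAI"`.
#' @param grid The index values as an `eai_grid`.
#' @return Object of class `index_raster`.
#' @export
index_raster <- function(index_id, grid) {
  index_id <- match.arg(index_id, c("CQI", "SQI", "VQI", "EAI"))
  stopifnot(is_grid(grid))
  structure(list(index_id = index_id, grid = grid), class = "index_raster")
}

#' @export
print.index_raster <- function(x, ...) {
  cat("<index_raster>", x$index_id, "\n")
  print(x$grid)
  invisible(x)
}

#' Index weights for the Environmental Area Index
#'
#' The default weights 0.6 (climate), 0.2 (soil), 0.2 (vegetation) are the
#' coefficients selected by random-forest importance screening in the
#' reference analysis; they must be non-negative and sum to one.
#'
#' @param w_cqi,w_sqi,w_vqi Non-negative weights summing to 1 within 1e-9.
#' @return Named numeric vector of class `index_weights`.
#' @export
index_weights <- function(w_cqi = 0.6, w_sqi = 0.2, w_vqi = 0.2) {
  w <- c(w_cqi = w_cqi, w_sqi = w_sqi, w_vqi = w_vqi)
  if (any(w < 0)) stop("index weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-9)
    stop("index weights must sum to 1 (got ", format(sum(w)), ")")
  structure(w, class = "index_weights")
}

#' Geometric mean of aligned score grids
#'
#' Cell-wise n-th root of the product of n score grids; the output mask is
#' the union of the input masks. A non-positive score at an unmasked cell
#' signals a corrupted score table and is an error.
#'
#' @param scores List of aligned score grids.
#' @param index_id Index identifier for the result.
#' @return An [index_raster()].
#' @export
geometric_mean_index <- function(scores, index_id) {
  stopifnot(length(scores) >= 1L)
  for (g in scores) {
    bad <- !g$mask & g$values <= 0
    if (any(bad, na.rm = TRUE))
      stop("non-positive score at ", sum(bad, na.rm = TRUE),
           " unmasked cell(s); score tables guarantee positivity")
  }
  n <- length(scores)
  g <- grid_map(scores, function(...) {
    args <- list(...)
    Reduce(`*`, args)^(1 / n)
  })
  index_raster(index_id, g)
}

.compute_index <- function(stack, tables, factors, index_id) {
  stopifnot(inherits(stack, "eai_stack"))
  missing_f <- setdiff(factors, names(stack))
  if (length(missing_f))
    stop("stack is missing factor(s) required for ", index_id, ": ",
         paste(missing_f, collapse = ", "))
  missing_t <- setdiff(factors, names(tables))
  if (length(missing_t))
    stop("no score table for factor(s): ",
         paste(missing_t, collapse = ", "))
  scored <- lapply(factors, function(f) score_factor(stack[[f]], tables[[f]]))
  geometric_mean_index(scored, index_id)
}

#' Climate quality index
#'
#' Sixth root of the product of the six climate factor scores:
#' precipitation, temperature, drought index, altitude, photosynthetically
#' active radiation and accumulated temperature.
#'
#' @param stack A [factor_stack()] holding the six climate factors.
#' @param tables Score tables, e.g. [default_tables()].
#' @return An [index_raster()] with values in (0, 10].
#' @export
compute_cqi <- function(stack, tables = default_tables())
  .compute_index(stack, tables, .CQI_FACTORS, "CQI")

#' Soil quality index
#'
#' Fifth root of the product of the five soil factor scores: depth,
#' texture, erosion intensity class, organic matter and moisture.
#'
#' @inheritParams compute_cqi
#' @return An [index_raster()].
#' @export
compute_sqi <- function(stack, tables = default_tables())
  .compute_index(stack, tables, .SQI_FACTORS, "SQI")

#' Vegetation quality index
#'
#' Fifth root of the product of the five vegetation factor scores: cover,
#' richness, resistance class, net primary productivity and aspect class.
#'
#' @inheritParams compute_cqi
#' @return An [index_raster()].
#' @export
compute_vqi <- function(stack, tables = default_tables())
  .compute_index(stack, tables, .VQI_FACTORS, "VQI")

#' Environmental Area Index
#'
#' Weighted combination of the three quality indices. The default
#' three-term form is `EAI = 0.6 CQI + 0.2 SQI + 0.2 VQI`; the two-term
#' form `EAI = w_cqi CQI + w_vqi VQI` (soil term dropped) is selectable for
#' comparison. Low EAI marks high ecological risk.
#'
#' @param cqi,sqi,vqi [index_raster()] objects (or bare grids) on one
#'   geometry.
#' @param w An [index_weights()] object.
#' @param form `"three_term"` (default) or `"two_term"`.
#' @return An [index_raster()] with `index_id = "EAI"`.
#' @export
compute_eai <- function(cqi, sqi, vqi, w = index_weights(),
                        form = c("three_term", "two_term")) {
  form <- match.arg(form)
  as_g <- function(x) if (inherits(x, "index_raster")) x$grid else x
  if (!inherits(w, "index_weights")) w <- do.call(index_weights, as.list(w))
  g <- if (form == "three_term") {
    grid_map(list(as_g(cqi), as_g(sqi), as_g(vqi)), function(a, b, c)
      w[["w_cqi"]] * a + w[["w_sqi"]] * b + w[["w_vqi"]] * c)
  } else {
    grid_map(list(as_g(cqi), as_g(vqi)), function(a, c)
      w[["w_cqi"]] * a + w[["w_vqi"]] * c)
  }
  index_raster("EAI", g)
}

#' Estimate index weights by random-forest importance
#'
#' Fits a random-forest classifier of a reference risk label on the three
#' quality indices and converts the mean-decrease-in-impurity importances
#' into weights by normalising them to sum to one. Out-of-bag accuracy is
#' reported as the goodness of the weighting. The reference analysis used
#' `mtry = 2` and `ntree = 1000`.
#'
#' @param samples Data frame with columns `CQI`, `SQI`, `VQI` and `label`
#'   (the reference risk class); at least 100 rows.
#' @param n_trees Trees in the forest (default 1000).
#' @param mtry Features tried per split, 1..3 (default 2).
#' @param seed Integer seed; results are reproducible for a fixed seed.
#' @param round_weights Round weights to one decimal (renormalised); off by
#'   default.
#' @return List with `weights` (an [index_weights()]), `goodness` (OOB
#'   accuracy as a fraction) and `importance` (raw impurity decreases).
#' @export
estimate_weights <- function(samples, n_trees = 1000L, mtry = 2L,
                             seed = 1L, round_weights = FALSE) {
  need <- c("CQI", "SQI", "VQI", "label")
  if (!all(need %in% names(samples)))
    stop("samples must have columns ", paste(need, collapse = ", "))
  if (nrow(samples) < 100L)
    stop("need at least 100 labelled samples, got ", nrow(samples))
  if (!(mtry %in% 1:3)) stop("mtry must be 1, 2 or 3")
  X <- as.matrix(samples[, c("CQI", "SQI", "VQI")])
  fit <- random_forest(X, samples$label, n_trees = n_trees, mtry = mtry,
                       seed = seed)
  imp <- pmax(fit$importance, 0)
  if (sum(imp) <= 0) stop("degenerate forest: zero total importance")
  w <- imp / sum(imp)
  if (round_weights) {
    w <- round(w, 1)
    w <- w / sum(w)
  }
  list(weights = index_weights(w[[1L]], w[[2L]], w[[3L]]),
       goodness = fit$oob_accuracy,
       importance = fit$importance)
}
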