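## synthetic: self-contained scene and scenario generators with the
## statistical structure the analysis assumes -- a northwest-to-southeast
## quality gradient, a DEM reproducing the published elevation-band area
## shares, and linear-in-time scenario trends at the published per-decade
## rates plus seeded noise. Everything is a pure function of its seeds.

# Stable sub-seed scheme: adding a factor never perturbs the others.
.sub_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + i * 7919) %% 2147483629)
}

# One pass of a 3x3 moving-average kernel (edge-replicated).
.smooth3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  sh <- function(dr, dc) {
    r <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
    c <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
    m[r, c, drop = FALSE]
  }
  (sh(-1, -1) + sh(-1, 0) + sh(-1, 1) +
     sh(0, -1) + sh(0, 0) + sh(0, 1) +
     sh(1, -1) + sh(1, 0) + sh(1, 1)) / 9
}

# Spatially coherent noise field, sd-calibrated after smoothing.
.noise_field <- function(nr, nc, sd, seed) {
  if (sd <= 0) return(matrix(0, nr, nc))
  set.seed(seed)
  z <- .smooth3(matrix(stats::rnorm(nr * nc), nr, nc))
  z * (sd / stats::sd(z))
}

#' Specify a synthetic base scene
#'
#' The stated world of the generator: a latent habitat-quality field rising
#' from northwest to southeast, a DEM highest in the northwest whose five
#' elevation bands (split at 2300/3600/4400/5000 m) occupy the published
#' area shares 1.97/16.11/21.52/37.75/22.65 percent, and per-factor noise.
#'
#' @param shape `c(rows, cols)` of the scene.
#' @param seed Integer master seed; all sub-streams derive from it.
#' @param band_shares Target area fractions of the five elevation bands,
#'   summing to 1.
#' @param noise_sd Per-factor spatial noise, in units of the latent
#'   quality field (which spans [0, 1]).
#' @param cell_size,origin,crs_tag Grid geometry of the scene.
#' @return Object of class `scene_spec`.
#' @export
scene_spec <- function(shape = c(200L, 200L), seed = 42L,
                       band_shares = c(0.0197, 0.1611, 0.2152,
                                       0.3775, 0.2265),
                       noise_sd = 0.05, cell_size = 500,
                       origin = c(0, 0), crs_tag = "synthetic") {
  if (abs(sum(band_shares) - 1) > 1e-9)
    stop("band_shares must sum to 1")
  if (length(band_shares) != 5L) stop("exactly 5 band shares required")
  structure(list(shape = as.integer(shape), seed = as.integer(seed),
                 band_shares = band_shares, noise_sd = noise_sd,
                 cell_size = cell_size, origin = origin, crs_tag = crs_tag),
            class = "scene_spec")
}

# raw value ranges the factors are drawn over; each spans the full extent
# of its score table's printed bins.
.FACTOR_RANGES <- list(
  Pr = c(50, 950), T = c(-8, 14), Di = c(0.02, 0.92),
  Par = c(3250, 3900), At = c(200, 6700),
  Sd = c(2, 130), St = c(0.05, 0.95), Som = c(0.3, 11),
  Sm = c(0.03, 0.18),
  Vc = c(1, 175), Vr = c(0.002, 0.28), NPP = c(20, 1150))

.SEI_LEVELS <- c("Severe", "Extreme slightly", "Strength", "Moderate",
                 "Mild", "Slightly")
.VRR_LEVELS <- c("Desert", "Grassland", "Shrub", "Woodland")
.ASPECT_LEVELS <- c("Sunny", "Half sunny", "Half shady", "Shady")

#' Generate a synthetic base scene
#'
#' Builds the full 16-factor stack plus DEM. All quality factors are
#' monotone functions of a shared NW-to-SE latent quality ramp with
#' factor-specific smoothed noise; aspect is spatially random (insolation
#' does not follow the quality gradient). The DEM is mapped through the
#' empirical ranks of an inverted ramp so its realised elevation-band
#' shares match the spec's targets; altitude `Al` equals the DEM.
#' Deterministic for a fixed seed.
#'
#' @param spec A [scene_spec()].
#' @return An `eai_stack` containing all registry factors and `DEM`.
#' @export
generate_base_scene <- function(spec = scene_spec()) {
  stopifnot(inherits(spec, "scene_spec"))
  nr <- spec$shape[1L]; nc <- spec$shape[2L]
  mk <- function(values, levels = NULL)
    grid_create(values, matrix(FALSE, nr, nc), spec$cell_size,
                spec$origin, spec$crs_tag, levels)
  rf <- matrix((seq_len(nr) - 0.5) / nr, nr, nc)        # 0 north -> 1 south
  cf <- matrix((seq_len(nc) - 0.5) / nc, nr, nc, byrow = TRUE)
  q0 <- (rf + cf) / 2                                   # low NW, high SE

  latent <- function(i) {
    pmin(pmax(q0 + .noise_field(nr, nc, spec$noise_sd,
                                .sub_seed(spec$seed, i)), 0), 1)
  }

  # DEM: highest in the NW; rank-mapped so band shares hit the targets.
  e <- pmin(pmax((1 - q0) + .noise_field(nr, nc, spec$noise_sd,
                                         .sub_seed(spec$seed, 100L)), 0), 1)
  p <- (rank(e, ties.method = "first") - 0.5) / length(e)
  knots_p <- c(0, cumsum(spec$band_shares))
  knots_z <- c(1200, 2300, 3600, 4400, 5000, 6400)
  dem_vals <- matrix(stats::approx(knots_p, knots_z, xout = p,
                                   rule = 2)$y, nr, nc)
  dem <- mk(dem_vals)

  grids <- list(DEM = dem, Al = mk(dem_vals))
  i <- 0L
  for (f in names(.FACTOR_RANGES)) {
    i <- i + 1L
    r <- .FACTOR_RANGES[[f]]
    grids[[f]] <- mk(r[1L] + (r[2L] - r[1L]) * latent(i))
  }
  # soil erosion: better (lighter erosion) toward the SE
  q_sei <- latent(50L)
  grids$Sei <- mk(matrix(findInterval(q_sei, seq(1, 5) / 6) + 1L, nr, nc),
                  levels = .SEI_LEVELS)
  # vegetation resistance: desert in the NW through woodland in the SE
  q_vrr <- latent(51L)
  grids$Vrr <- mk(matrix(findInterval(q_vrr, c(0.25, 0.5, 0.75)) + 1L,
                         nr, nc),
                  levels = .VRR_LEVELS)
  # aspect: spatially random insolation classes
  set.seed(.sub_seed(spec$seed, 52L))
  grids$A <- mk(matrix(sample.int(4L, nr * nc, replace = TRUE), nr, nc),
                levels = .ASPECT_LEVELS)
  factor_stack(grids)
}

#' Specify a synthetic climate scenario
#'
#' Defaults per scenario follow the published ensemble trend rates:
#' precipitation 7.2/10.5/12.3/16.6 mm per decade and temperature
#' 0.07/0.28/0.56/0.62 deg C per decade for SSP126/245/370/585.
#' Interannual variability enters as per-member regional anomalies
#' (defaults 25 mm and 0.4 deg C), and the optional
#' `pr_fast_SE_t_fast_NW` pattern makes precipitation trends strongest in
#' the southeast and warming strongest in the northwest.
#'
#' @param scenario_id `"SSP126"`, `"SSP245"`, `"SSP370"`, `"SSP585"` or a
#'   user-defined id (then supply both rates).
#' @param pr_rate,t_rate Trend rates (mm per decade, deg C per decade);
#'   defaulted from the scenario id when known.
#' @param spatial_rate_pattern `"uniform"` or `"pr_fast_SE_t_fast_NW"`.
#' @param pr_noise_sd,t_noise_sd Interannual regional anomaly SDs.
#' @param n_members Ensemble size.
#' @param seed Integer seed.
#' @param years Simulation years, within 2021-2100.
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario_id = "SSP126", pr_rate = NULL,
                          t_rate = NULL,
                          spatial_rate_pattern = c("uniform",
                                                   "pr_fast_SE_t_fast_NW"),
                          pr_noise_sd = 25, t_noise_sd = 0.4,
                          n_members = 3L, seed = 1L, years = 2021:2100) {
  spatial_rate_pattern <- match.arg(spatial_rate_pattern)
  defaults <- scenario_defaults()
  if (is.null(pr_rate) || is.null(t_rate)) {
    if (!scenario_id %in% defaults$scenario)
      stop("unknown scenario `", scenario_id,
           "`; supply pr_rate and t_rate explicitly")
    row <- defaults[defaults$scenario == scenario_id, ]
    if (is.null(pr_rate)) pr_rate <- row$pr_rate
    if (is.null(t_rate)) t_rate <- row$t_rate
  }
  years <- as.integer(years)
  if (any(years < 2021L | years > 2100L))
    stop("years must lie within 2021-2100")
  structure(list(scenario_id = scenario_id, pr_rate = pr_rate,
                 t_rate = t_rate,
                 spatial_rate_pattern = spatial_rate_pattern,
                 pr_noise_sd = pr_noise_sd, t_noise_sd = t_noise_sd,
                 n_members = as.integer(n_members), seed = as.integer(seed),
                 years = years),
            class = "scenario_spec")
}

#' Published scenario trend rates
#'
#' @return Data frame with the per-decade precipitation and temperature
#'   trend rates (and reported R-squared) of the four SSP scenarios.
#' @export
scenario_defaults <- function() {
  data.frame(
    scenario = c("SSP126", "SSP245", "SSP370", "SSP585"),
    pr_rate = c(7.2, 10.5, 12.3, 16.6),
    pr_r2 = c(0.15, 0.27, 0.30, 0.44),
    t_rate = c(0.07, 0.28, 0.56, 0.62),
    t_r2 = c(0.13, 0.75, 0.93, 0.93),
    stringsAsFactors = FALSE)
}

#' Generate future scenario fields and series
#'
#' Yearly precipitation and temperature for the requested years: the base
#' field plus a linear trend at the spec's per-decade rate (spatially
#' patterned if requested) plus a seeded per-member regional anomaly.
#' Static factors are untouched, mirroring the assumption that soil
#' properties remain unchanged. Returns per-year ensemble-mean fields for
#' the raster pipeline and per-member regional-mean series for trend
#' statistics; `trend_rate` on a noiseless series recovers the spec rate
#' exactly.
#'
#' @param base An `eai_stack` with `Pr` and `T` grids.
#' @param spec A [scenario_spec()].
#' @return List with `series` (long data frame: scenario, member, year,
#'   variable pr/tas, value, units) and `year_fields` (per-year lists of
#'   ensemble-mean `Pr` and `T` grids).
#' @export
generate_scenario_series <- function(base, spec = scenario_spec()) {
  stopifnot(inherits(base, "eai_stack"), inherits(spec, "scenario_spec"))
  for (f in c("Pr", "T")) {
    if (is.null(base[[f]])) stop("base stack lacks factor ", f)
  }
  nr <- nrow(base$Pr$values); nc <- ncol(base$Pr$values)
  rfm <- matrix((seq_len(nr) - 0.5) / nr, nr, nc)
  cfm <- matrix((seq_len(nc) - 0.5) / nc, nr, nc, byrow = TRUE)
  q0 <- (rfm + cfm) / 2
  if (spec$spatial_rate_pattern == "uniform") {
    pat_pr <- matrix(1, nr, nc); pat_t <- matrix(1, nr, nc)
  } else {                      # pr fastest SE, warming fastest NW
    pat_pr <- 2 * q0
    pat_t <- 2 * (1 - q0)
  }
  years <- spec$years
  y0 <- 2021L
  n_y <- length(years); n_m <- spec$n_members
  set.seed(.sub_seed(spec$seed, 1L))
  eps_pr <- matrix(stats::rnorm(n_m * n_y, 0, spec$pr_noise_sd), n_m, n_y)
  set.seed(.sub_seed(spec$seed, 2L))
  eps_t <- matrix(stats::rnorm(n_m * n_y, 0, spec$t_noise_sd), n_m, n_y)
  if (spec$pr_noise_sd <= 0) eps_pr[] <- 0
  if (spec$t_noise_sd <= 0) eps_t[] <- 0

  base_pr_mean <- regional_mean(base$Pr)
  base_t_mean <- regional_mean(base$T)
  mean_pat_pr <- mean(pat_pr); mean_pat_t <- mean(pat_t)

  rows <- vector("list", 2L * n_m)
  for (m in seq_len(n_m)) {
    dt <- (years - y0) / 10
    rows[[2L * m - 1L]] <- data.frame(
      scenario = spec$scenario_id, member = sprintf("member%02d", m),
      year = years, variable = "pr",
      value = base_pr_mean + spec$pr_rate * dt * mean_pat_pr + eps_pr[m, ],
      units = "mm", stringsAsFactors = FALSE)
    rows[[2L * m]] <- data.frame(
      scenario = spec$scenario_id, member = sprintf("member%02d", m),
      year = years, variable = "tas",
      value = base_t_mean + spec$t_rate * dt * mean_pat_t + eps_t[m, ],
      units = "degC", stringsAsFactors = FALSE)
  }

  year_fields <- stats::setNames(vector("list", n_y), as.character(years))
  mk <- function(vals) grid_create(vals, base$Pr$mask, base$Pr$cell_size,
                                   base$Pr$origin, base$Pr$crs_tag)
  for (j in seq_len(n_y)) {
    dt <- (years[j] - y0) / 10
    year_fields[[j]] <- list(
      Pr = mk(base$Pr$values + spec$pr_rate * dt * pat_pr +
                mean(eps_pr[, j])),
      T = mk(base$T$values + spec$t_rate * dt * pat_t + mean(eps_t[, j])))
  }
  list(series = do.call(rbind, rows), year_fields = year_fields,
       spec = spec)
}

#' Labelled samples for weight-recovery experiments
#'
#' Samples cells from a scene, computes the three quality indices, forms a
#' hidden ground-truth EAI with configurable true weights and labels each
#' cell with its fixed-break risk class. Supports recovery tests of
#' [estimate_weights()].
#'
#' @param stack An `eai_stack` on which the indices are computable.
#' @param n Number of cells to sample (without replacement).
#' @param seed Integer seed.
#' @param true_weights Hidden EAI weights (default 0.6/0.2/0.2).
#' @param tables Score tables.
#' @return Data frame with columns `CQI`, `SQI`, `VQI`, `label`.
#' @export
generate_weight_training_samples <- function(stack, n, seed = 1L,
                                             true_weights = c(0.6, 0.2, 0.2),
                                             tables = default_tables()) {
  cqi <- compute_cqi(stack, tables)$grid
  sqi <- compute_sqi(stack, tables)$grid
  vqi <- compute_vqi(stack, tables)$grid
  live <- which(!(cqi$mask | sqi$mask | vqi$mask))
  if (n > length(live))
    stop("n = ", n, " exceeds the ", length(live), " unmasked cells")
  set.seed(.sub_seed(seed, 7L))
  pick <- sample(live, n)
  cq <- cqi$values[pick]; sq <- sqi$values[pick]; vq <- vqi$values[pick]
  w <- true_weights / sum(true_weights)
  eai_true <- w[1L] * cq + w[2L] * sq + w[3L] * vq
  scheme <- paper_schemes()$eai_risk
  label <- scheme$labels[findInterval(eai_true, scheme$breaks) + 1L]
  data.frame(CQI = cq, SQI = sq, VQI = vq, label = label,
             stringsAsFactors = FALSE)
}
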