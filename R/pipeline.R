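## cli_pipeline: orchestrate base-period and future runs from one config,
## with JSON provenance. Deterministic: identical config + seed give
## byte-identical text outputs (no timestamps are recorded).

# cheap config fingerprint (not cryptographic)
.fingerprint <- function(s) {
  h <- 0
  for (b in as.integer(charToRaw(s))) h <- (h * 131 + b) %% 2147483647
  sprintf("%010d", h)
}

#' Build a pipeline run configuration
#'
#' Exactly one of `synthetic` (a list of [scene_spec()] arguments) or
#' `factors` (named list of raster file paths covering all sixteen factors
#' plus `DEM`) must be supplied.
#'
#' @param out_dir Output directory (created if needed).
#' @param synthetic List of arguments for [scene_spec()], or `NULL`.
#' @param factors Named list of `.asc` paths, or `NULL`.
#' @param factor_levels Named list of category-level vectors for
#'   integer-coded categorical factor files.
#' @param tables_path Optional score-table CSV overriding the shipped
#'   defaults.
#' @param weights Numeric EAI weights (CQI, SQI, VQI) or `"estimate"` to
#'   estimate them from synthetic labelled samples.
#' @param eai_form `"three_term"` or `"two_term"` (see [compute_eai()]).
#' @param classification `"paper"` (fixed published breaks; default, keeps
#'   periods comparable) or `"jenks"` (natural breaks on the base EAI).
#' @param jenks_per_period Re-run natural breaks inside each future period
#'   instead of reusing the base scheme.
#' @param bands Elevation band edges.
#' @param scenarios Scenario ids for [run_future()].
#' @param periods Period names (see [eai_periods()]).
#' @param rate_pattern Spatial trend pattern for the generator.
#' @param n_members Ensemble size for synthetic scenarios.
#' @param seed Master seed for the future-run noise streams.
#' @return Validated config list of class `eai_config`.
#' @export
eai_config <- function(out_dir,
                       synthetic = list(), factors = NULL,
                       factor_levels = NULL, tables_path = NULL,
                       weights = c(0.6, 0.2, 0.2),
                       eai_form = "three_term",
                       classification = c("paper", "jenks"),
                       jenks_per_period = FALSE,
                       bands = c(2300, 3600, 4400, 5000),
                       scenarios = c("SSP126", "SSP245", "SSP370",
                                     "SSP585"),
                       periods = names(eai_periods()),
                       rate_pattern = "pr_fast_SE_t_fast_NW",
                       n_members = 3L, seed = 1L) {
  classification <- match.arg(classification)
  has_syn <- is.list(synthetic) && !is.null(synthetic)
  has_real <- !is.null(factors)
  if (has_real && length(synthetic) > 0)
    stop("supply exactly one of `synthetic` and `factors`")
  if (!has_syn && !has_real)
    stop("supply exactly one of `synthetic` and `factors`")
  structure(list(out_dir = out_dir, synthetic = if (has_real) NULL
                 else synthetic,
                 factors = factors, factor_levels = factor_levels,
                 tables_path = tables_path, weights = weights,
                 eai_form = eai_form, classification = classification,
                 jenks_per_period = jenks_per_period, bands = bands,
                 scenarios = scenarios, periods = periods,
                 rate_pattern = rate_pattern,
                 n_members = as.integer(n_members),
                 seed = as.integer(seed)),
            class = "eai_config")
}

#' Read a pipeline config from JSON
#'
#' @param path JSON file whose keys mirror the arguments of
#'   [eai_config()].
#' @return An `eai_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(eai_config, raw)
}

.load_tables <- function(config) {
  if (is.null(config$tables_path)) default_tables()
  else read_score_tables(config$tables_path)
}

.load_stack <- function(config) {
  if (!is.null(config$synthetic)) {
    return(generate_base_scene(do.call(scene_spec, config$synthetic)))
  }
  required <- factor_registry()$name
  missing_f <- setdiff(required, names(config$factors))
  bad <- names(config$factors)[
    !vapply(unlist(config$factors), file.exists, logical(1))]
  problems <- c(
    if (length(missing_f)) paste("missing factor path(s):",
                                 paste(missing_f, collapse = ", ")),
    if (length(bad)) paste("unreadable factor file(s):",
                           paste(bad, collapse = ", ")))
  if (length(problems)) stop(paste(problems, collapse = "; "))
  grids <- lapply(names(config$factors), function(f) {
    g <- read_grid(config$factors[[f]])
    lv <- config$factor_levels[[f]]
    if (!is.null(lv)) g$levels <- lv
    g
  })
  factor_stack(stats::setNames(grids, names(config$factors)))
}

.resolve_weights <- function(config, stack, tables) {
  if (identical(config$weights, "estimate")) {
    samples <- generate_weight_training_samples(
      stack, n = min(2000L, length(stack$DEM$values)),
      seed = config$seed, tables = tables)
    estimate_weights(samples, n_trees = 200L, mtry = 2L,
                     seed = config$seed)$weights
  } else {
    w <- as.numeric(config$weights)
    index_weights(w[1L], w[2L], w[3L])
  }
}

.write_provenance <- function(config, extras, path) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL   # location-independent provenance
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, null = "null",
                               digits = NA)
  prov <- c(list(config = cfg,
                 config_fingerprint = .fingerprint(as.character(cfg_json)),
                 package_version =
                   as.character(utils::packageVersion("eairisk"))),
            extras)
  jsonlite::write_json(prov, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
}

#' Run the base-period assessment
#'
#' Loads or generates the factor stack, computes CQI/SQI/VQI and the EAI,
#' classifies risk, and writes all rasters (`.asc`), proportion tables
#' (CSV), the class legend and a JSON provenance record to
#' `config$out_dir`. Validation happens before any output is written, and
#' identical configs produce byte-identical outputs.
#'
#' @param config An [eai_config()].
#' @return (Invisibly) a list with the stack, index rasters, risk raster,
#'   scheme, weights and proportion tables.
#' @export
run_base_period <- function(config) {
  stopifnot(inherits(config, "eai_config"))
  tables <- .load_tables(config)
  stack <- .load_stack(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  cqi <- compute_cqi(stack, tables)
  sqi <- compute_sqi(stack, tables)
  vqi <- compute_vqi(stack, tables)
  w <- .resolve_weights(config, stack, tables)
  eai <- compute_eai(cqi, sqi, vqi, w, form = config$eai_form)

  scheme <- if (config$classification == "paper") paper_schemes()$eai_risk
  else {
    br <- jenks_breaks(eai$grid$values[!eai$grid$mask], 5L)
    class_scheme("eai_jenks", as.numeric(br),
                 paper_schemes()$eai_risk$labels, "risk")
  }
  risk <- classify_by_breaks(eai$grid, scheme)
  props <- class_proportions(risk)
  bands <- elevation_bands(config$bands)
  bprops <- band_proportions(risk, stack$DEM, bands)

  od <- config$out_dir
  write_grid(cqi$grid, file.path(od, "cqi.asc"))
  write_grid(sqi$grid, file.path(od, "sqi.asc"))
  write_grid(vqi$grid, file.path(od, "vqi.asc"))
  write_grid(eai$grid, file.path(od, "eai.asc"))
  write_grid(risk, file.path(od, "risk.asc"))
  write_class_legend(scheme, file.path(od, "risk_legend.csv"))
  utils::write.csv(props, file.path(od, "proportions.csv"),
                   row.names = FALSE)
  utils::write.csv(bprops, file.path(od, "band_proportions.csv"),
                   row.names = FALSE)
  .write_provenance(config,
                    list(stage = "base_period",
                         weights = as.numeric(w),
                         scheme_breaks = scheme$breaks),
                    file.path(od, "provenance_base.json"))
  invisible(list(config = config, tables = tables, stack = stack,
                 cqi = cqi, sqi = sqi, vqi = vqi, eai = eai,
                 weights = w, scheme = scheme, risk = risk,
                 proportions = props, band_proportions = bprops,
                 bands = bands))
}

#' Run the future-scenario assessment
#'
#' For every scenario and 20-year period: generates (or receives) the
#' dynamic precipitation and temperature fields, takes the period mean,
#' rescored them into a fresh CQI, recombines the EAI with the static soil
#' and vegetation indices, classifies risk and accounts it by elevation
#' band, and differences each period against the base period. Also writes
#' the per-scenario trend-rate table (OLS slope per decade and R-squared
#' of the ensemble-mean series).
#'
#' @param config An [eai_config()].
#' @param base Result of [run_base_period()] for this config; computed if
#'   `NULL`.
#' @return (Invisibly) list with `rates` (trend-rate table), `periods`
#'   (per scenario-period proportion and change tables) and `base`.
#' @export
run_future <- function(config, base = NULL) {
  stopifnot(inherits(config, "eai_config"))
  if (is.null(base)) base <- run_base_period(config)
  od <- config$out_dir
  periods <- eai_periods()[config$periods]
  if (anyNA(names(periods))) stop("unknown period name(s)")
  rates <- list()
  results <- list()
  for (si in seq_along(config$scenarios)) {
    scen <- config$scenarios[si]
    sspec <- scenario_spec(scen,
                           spatial_rate_pattern = config$rate_pattern,
                           n_members = config$n_members,
                           seed = .sub_seed(config$seed, 1000L + si))
    sim <- generate_scenario_series(base$stack, sspec)
    for (v in c("pr", "tas")) {
      em <- ensemble_mean(sim$series[sim$series$variable == v, ])
      tr <- trend_rate(em)
      rates[[length(rates) + 1L]] <- data.frame(
        scenario = scen, variable = v,
        rate_per_decade = tr$rate_per_decade,
        r_squared = tr$r_squared, stringsAsFactors = FALSE)
    }
    for (p in names(periods)) {
      pr_mean <- period_mean_stack(lapply(sim$year_fields, `[[`, "Pr"), p)
      t_mean <- period_mean_stack(lapply(sim$year_fields, `[[`, "T"), p)
      stack_p <- base$stack
      stack_p$Pr <- pr_mean
      stack_p$T <- t_mean
      cqi_p <- compute_cqi(stack_p, base$tables)
      eai_p <- compute_eai(cqi_p, base$sqi, base$vqi, base$weights,
                           form = config$eai_form)
      scheme_p <- if (config$jenks_per_period) {
        br <- jenks_breaks(eai_p$grid$values[!eai_p$grid$mask], 5L)
        class_scheme("eai_jenks", as.numeric(br), base$scheme$labels,
                     "risk")
      } else base$scheme
      risk_p <- classify_by_breaks(eai_p$grid, scheme_p)
      bprops_p <- band_proportions(risk_p, base$stack$DEM, base$bands)
      change_p <- change_rates(base$band_proportions,
                               bprops_p[, c("stratum", "class", "percent")])
      tag <- paste0(scen, "_", p)
      write_grid(risk_p, file.path(od, paste0("risk_", tag, ".asc")))
      utils::write.csv(bprops_p,
                       file.path(od, paste0("band_props_", tag, ".csv")),
                       row.names = FALSE)
      utils::write.csv(change_p,
                       file.path(od, paste0("change_", tag, ".csv")),
                       row.names = FALSE)
      results[[tag]] <- list(scenario = scen, period = p,
                             band_proportions = bprops_p,
                             change = change_p)
    }
  }
  rates <- do.call(rbind, rates)
  utils::write.csv(rates, file.path(od, "rates.csv"), row.names = FALSE)
  .write_provenance(config, list(stage = "future"),
                    file.path(od, "provenance_future.json"))
  invisible(list(rates = rates, periods = results, base = base))
}
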