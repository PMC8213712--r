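#' Load and validate a pipeline configuration
#'
#' Reads a YAML document describing a full synthetic scenario run: the seed,
#' the landscape geometry, the period spanned by the generated map pair, the
#' projection horizon and one or more scenario blocks (name, elas, optional
#' allowed-conversion matrix and iteration controls). Unknown keys are
#' rejected; missing values get defaults that are echoed in the returned
#' object.
#'
#' @param path Path to a YAML config.
#' @return Validated configuration list of class `lulcsim_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  known <- c("seed", "geometry", "transition_period", "horizon_years",
             "scenarios")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg$seed <- check_scalar(cfg$seed, "seed", integerish = TRUE, default = 1)
  if (is.null(cfg$geometry)) cfg$geometry <- list()
  gunknown <- setdiff(names(cfg$geometry), c("nrows", "ncols", "cellsize"))
  if (length(gunknown))
    stop("unknown geometry key(s): ", paste(gunknown, collapse = ", "))
  cfg$geometry$nrows <- check_scalar(cfg$geometry$nrows, "geometry$nrows",
                                     integerish = TRUE, default = 120, min = 16)
  cfg$geometry$ncols <- check_scalar(cfg$geometry$ncols, "geometry$ncols",
                                     integerish = TRUE, default = 120, min = 16)
  cfg$geometry$cellsize <- check_scalar(cfg$geometry$cellsize,
                                        "geometry$cellsize", default = 60,
                                        min = 1e-9)
  cfg$transition_period <- check_scalar(cfg$transition_period,
                                        "transition_period",
                                        integerish = TRUE, default = 11, min = 1)
  cfg$horizon_years <- check_scalar(cfg$horizon_years, "horizon_years",
                                    integerish = TRUE, default = 9, min = 1)
  if (is.null(cfg$scenarios) || !length(cfg$scenarios))
    stop("config must define at least one scenario under 'scenarios'")
  cfg$scenarios <- lapply(cfg$scenarios, validate_scenario_block)
  structure(cfg, class = "lulcsim_config")
}

check_scalar <- function(x, key, integerish = FALSE, default = NULL,
                         min = -Inf, max = Inf) {
  if (is.null(x)) {
    if (is.null(default)) stop("missing required config key '", key, "'")
    x <- default
  }
  if (!is.numeric(x) || length(x) != 1 || is.na(x))
    stop("config key '", key, "' must be a single number")
  if (integerish && x != round(x))
    stop("config key '", key, "' must be an integer")
  if (x < min || x > max)
    stop("config key '", key, "' out of range [", min, ", ", max, "]")
  x
}

validate_scenario_block <- function(s) {
  known <- c("name", "elas", "allowed", "max_iterations", "tolerance",
             "damping")
  unknown <- setdiff(names(s), known)
  if (length(unknown))
    stop("unknown scenario key(s): ", paste(unknown, collapse = ", "))
  if (is.null(s$name) || !nzchar(s$name)) stop("scenario is missing 'name'")
  if (is.null(s$elas)) stop("scenario '", s$name, "' is missing 'elas'")
  elas <- as.numeric(unlist(s$elas))
  if (length(elas) != 6 || any(is.na(elas)))
    stop("scenario '", s$name, "': elas must be 6 numbers")
  if (any(elas < 0 | elas > 1))
    stop("scenario '", s$name, "': elas values must lie in [0, 1]")
  allowed <- if (is.null(s$allowed) || identical(s$allowed, "all")) {
    matrix(TRUE, 6, 6)
  } else {
    m <- do.call(rbind, lapply(s$allowed, as.numeric))
    if (!all(dim(m) == c(6, 6)))
      stop("scenario '", s$name, "': allowed must be a 6x6 matrix")
    m != 0
  }
  if (any(!diag(allowed)))
    stop("scenario '", s$name, "': the diagonal of allowed must be 1")
  list(name = s$name, elas = elas, allowed = allowed,
       max_iterations = check_scalar(s$max_iterations,
                                     paste0(s$name, "$max_iterations"),
                                     integerish = TRUE, default = 2000, min = 1),
       tolerance = if (is.null(s$tolerance)) NULL else
         check_scalar(s$tolerance, paste0(s$name, "$tolerance"), min = 0),
       damping = check_scalar(s$damping, paste0(s$name, "$damping"),
                              default = 0.5, min = 1e-9, max = 1))
}

#' Write a complete synthetic fixture set to a directory
#'
#' Generates a landscape and writes `lulc_t0.asc`, `lulc_t1.asc`, the seven
#' driver rasters, `truth.json` (generative coefficients, transition matrix,
#' seed, geometry) and a manifest.
#'
#' @param out_dir Output directory (created if needed).
#' @param nrows,ncols,cellsize Geometry (minimum 16 x 16).
#' @param seed Integer seed.
#' @return Invisibly, the landscape list from [generate_landscape()].
#' @export
write_fixture_set <- function(out_dir, nrows = 120, ncols = 120,
                              cellsize = 60, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  land <- generate_landscape(nrows, ncols, cellsize, seed = seed)
  files <- c(lulc_t0 = "lulc_t0.asc", lulc_t1 = "lulc_t1.asc")
  write_ascii_grid(land$lulc_t0, file.path(out_dir, "lulc_t0.asc"))
  write_ascii_grid(land$lulc_t1, file.path(out_dir, "lulc_t1.asc"))
  for (nm in names(land$drivers)) {
    f <- paste0(nm, ".asc")
    write_ascii_grid(land$drivers[[nm]], file.path(out_dir, f))
    files[nm] <- f
  }
  truth <- list(true_betas = land$truth$true_betas,
                true_transition = land$truth$true_transition,
                target_proportions = land$truth$target_proportions,
                seed = seed,
                geometry = list(nrows = nrows, ncols = ncols,
                                cellsize = cellsize))
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files["truth"] <- "truth.json"
  write_manifest(out_dir, seed, files)
  invisible(land)
}

write_manifest <- function(out_dir, seed, files, extra = list()) {
  manifest <- c(list(
    tool = "lulcsim",
    version = as.character(utils::packageVersion("lulcsim")),
    seed = seed,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = as.list(files)), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Run the full scenario pipeline on a synthetic landscape
#'
#' Reproduces the study workflow end to end on generated data: (1) generate
#' the landscape and a t0/t1 map pair with known structure; (2) fit the six
#' suitability models on the t1 map; (3) hindcast t1 from t0 with the
#' allocator and validate against the actual t1 (kappa report); (4) estimate
#' and annualize the t0 -> t1 transition matrix, project class demands over
#' the horizon; (5) allocate each scenario year by year. All rasters, demand
#' tables, validation JSON, a convergence log and a manifest are written
#' under `out_dir`.
#'
#' @param config A `lulcsim_config` from [load_config()] (or a path to one).
#' @param out_dir Output directory.
#' @return List: landscape, model, validation (hindcast report), demand (per
#'   scenario), runs (per scenario), converged (all scenarios, all years).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "lulcsim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  g <- config$geometry
  land <- generate_landscape(g$nrows, g$ncols, g$cellsize, seed = config$seed)
  write_ascii_grid(land$lulc_t0, file.path(out_dir, "lulc_t0.asc"))
  write_ascii_grid(land$lulc_t1, file.path(out_dir, "lulc_t1.asc"))
  model <- fit_suitability_model(land$lulc_t1, land$drivers)
  write_suitability_model(model, file.path(out_dir, "suitability_model.json"))
  probs <- predict_all_probabilities(model, land$drivers)
  # hindcast validation: reallocate t0 toward the actual t1 areas
  hind_cfg <- scenario_config("hindcast", elas = rep(0.6, 6))
  hind <- allocate(land$lulc_t0, probs, hind_cfg,
                   demand_areas = class_areas(land$lulc_t1))
  validation <- accuracy_report(land$lulc_t1, hind$map)
  write_validation_report(validation, file.path(out_dir, "validation.json"))
  # demand projection from the estimated transition structure
  tm <- estimate_transition(land$lulc_t0, land$lulc_t1,
                            period = config$transition_period)
  annual <- annualize(tm)
  files <- c("lulc_t0.asc", "lulc_t1.asc", "suitability_model.json",
             "validation.json")
  runs <- list(); demands <- list(); conv_log <- list()
  for (sc in config$scenarios) {
    demand <- project_demand(class_areas(land$lulc_t1), annual,
                             n_years = config$horizon_years, start_year = 0)
    cfg <- scenario_config(sc$name, elas = sc$elas, allowed = sc$allowed,
                           demand = demand,
                           max_iterations = sc$max_iterations,
                           tolerance = sc$tolerance, damping = sc$damping)
    run <- run_scenario(land$lulc_t1, probs, cfg)
    slug <- gsub("[^a-z0-9]+", "_", tolower(sc$name))
    dfile <- paste0("demand_", slug, ".csv")
    write_demand_csv(demand, file.path(out_dir, dfile))
    files <- c(files, dfile)
    for (y in names(run$maps)) {
      f <- sprintf("%s_%s.asc", slug, y)
      write_ascii_grid(run$maps[[y]], file.path(out_dir, f))
      files <- c(files, f)
    }
    conv_log[[sc$name]] <- data.frame(
      scenario = sc$name, year = as.integer(names(run$results)),
      iterations = vapply(run$results, function(r) r$iterations_used, integer(1)),
      max_deviation_ha = vapply(run$results, function(r) max(r$deviations),
                                numeric(1)),
      converged = vapply(run$results, function(r) r$converged, logical(1)))
    runs[[sc$name]] <- run
    demands[[sc$name]] <- demand
  }
  log_df <- do.call(rbind, conv_log)
  utils::write.csv(log_df, file.path(out_dir, "convergence_log.csv"),
                   row.names = FALSE)
  files <- c(files, "convergence_log.csv")
  write_manifest(out_dir, config$seed, files,
                 extra = list(scenarios = vapply(config$scenarios,
                                                 `[[`, "", "name")))
  invisible(list(landscape = land, model = model, validation = validation,
                 demand = demands, runs = runs,
                 converged = all(vapply(runs, function(r) r$converged,
                                        logical(1)))))
}
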