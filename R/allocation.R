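#' Scenario configuration for the iterative allocator
#'
#' Bundles the conversion elasticities (ELAS, one per class in \[0, 1\]:
#' higher means more resistant to conversion away from its current cells),
#' the boolean allowed-conversion matrix (diagonal always allowed), the
#' demand trajectory and the iteration controls for one named scenario.
#'
#' @param name Scenario name (e.g. "natural development").
#' @param elas Numeric vector of 6 elasticities in \[0, 1\].
#' @param allowed 6x6 logical (or 0/1) matrix; `allowed[u, v]` permits u -> v.
#' @param demand A `demand_table` covering the years to simulate.
#' @param max_iterations Iteration cap per year (default 2000).
#' @param tolerance Per-class convergence tolerance in ha; default
#'   `max(one cell's area, 0.1% of the class demand)` computed at run time.
#' @param damping Offset update step in (0, 1], halved on oscillation.
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(name, elas, allowed = NULL, demand = NULL,
                            max_iterations = 2000, tolerance = NULL,
                            damping = 0.5) {
  if (length(elas) != N_CLASSES || any(elas < 0 | elas > 1))
    stop("elas must be 6 values in [0,1]")
  if (is.null(allowed)) allowed <- matrix(TRUE, N_CLASSES, N_CLASSES)
  allowed <- matrix(as.logical(allowed), N_CLASSES, N_CLASSES)
  if (any(!diag(allowed))) stop("the diagonal of the allowed matrix must be TRUE")
  if (damping <= 0 || damping > 1) stop("damping must lie in (0, 1]")
  if (max_iterations < 1) stop("max_iterations must be positive")
  structure(list(name = name, elas = as.numeric(elas), allowed = allowed,
                 demand = demand, max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, damping = damping),
            class = "scenario_config")
}

#' Total allocation probability of one cell-class pair
#'
#' The CLUE-S composition: TPROP = P(cell, class) + ELAS_class * \[cell
#' currently holds the class\] + offset_class, defined only for transitions
#' the allowed matrix permits (NA otherwise). The per-class offset is the
#' iteration variable the allocator balances until demands are met.
#'
#' @param p Suitability probability of the class at the cell.
#' @param class_code Candidate class.
#' @param current_class The cell's current class.
#' @param config A `scenario_config`.
#' @param offsets Numeric vector of 6 per-class offsets.
#' @return TPROP, or NA if the conversion is disallowed.
#' @export
total_probability <- function(p, class_code, current_class, config, offsets) {
  if (!config$allowed[current_class, class_code]) return(NA_real_)
  p + config$elas[class_code] * (current_class == class_code) +
    offsets[class_code]
}

#' Allocate one year's class-area demand over the map
#'
#' The iterative CLUE-S balancing loop: every cell is scored for every
#' allowed class (suitability + incumbency elasticity + per-class offset),
#' assigned its argmax class, and the offsets are nudged by the damped
#' relative deficit `damping * (demand - allocated) / demand` until every
#' class's allocated area is within tolerance of its demand or the iteration
#' cap is reached. Ties at the argmax go to the smallest class code, then
#' cell index; the allocator uses no randomness. Cells whose current class
#' allows no conversion are frozen and excluded from the balancing
#' arithmetic. Demand is converted to integer cell counts by
#' largest-remainder rounding; non-convergence is flagged, not raised.
#'
#' @param current `lulc_map` state.
#' @param suitability List of six probability grids or a cells x 6 matrix.
#' @param config A `scenario_config` (its demand may be overridden).
#' @param demand_year Year to draw from the config's demand table, or a
#'   plain 6-vector of areas (ha) passed via `demand_areas`.
#' @param demand_areas Optional explicit demand vector (ha), bypassing the
#'   table.
#' @return `allocation_result`: map, iterations_used, final_offsets,
#'   deviations (ha per class), converged.
#' @export
allocate <- function(current, suitability, config, demand_year = NULL,
                     demand_areas = NULL) {
  stopifnot(inherits(current, "lulc_map"), inherits(config, "scenario_config"))
  if (is.null(demand_areas)) {
    if (is.null(config$demand)) stop("no demand table in config and no demand_areas")
    demand_areas <- demand_for_year(config$demand, demand_year)
  }
  demand_areas <- as.numeric(demand_areas)
  cell_ha <- cell_area_ha(current)
  v <- as.vector(current$values)
  valid <- which(!is.na(v))
  n <- length(valid)
  tol <- if (is.null(config$tolerance))
    pmax(cell_ha, 0.001 * demand_areas) else rep(config$tolerance, N_CLASSES)
  if (abs(sum(demand_areas) - n * cell_ha) > max(sum(tol), cell_ha))
    stop("demand total (", round(sum(demand_areas), 2),
         " ha) does not match the map's valid area (",
         round(n * cell_ha, 2), " ha)")
  # integer cell targets summing exactly to the number of valid cells
  target <- largest_remainder(demand_areas / sum(demand_areas) * n, n)
  P <- suitability_matrix(suitability, current)[valid, , drop = FALSE]
  cur <- v[valid]
  # frozen cells: current class permits no conversion at all, or carries the
  # maximal elasticity (ELAS = 1 means the class is not allowed to convert
  # away, per the standard CLUE-S reading)
  frozen_class <- union(which(rowSums(config$allowed) == 1L),
                        which(config$elas >= 1))
  frozen <- cur %in% frozen_class
  frozen_counts <- tabulate(cur[frozen], nbins = N_CLASSES)
  free <- !frozen
  Pf <- P[free, , drop = FALSE]
  curf <- cur[free]
  base <- Pf
  for (k in seq_len(N_CLASSES)) {
    base[, k] <- base[, k] + config$elas[k] * (curf == k)
    base[!config$allowed[curf, k], k] <- -Inf
  }
  offsets <- numeric(N_CLASSES)
  damping <- config$damping
  prev_sign <- NULL
  assigned <- curf
  deficit_cells <- rep(Inf, N_CLASSES)
  iter <- 0L
  while (iter < config$max_iterations) {
    iter <- iter + 1L
    score <- sweep(base, 2, offsets, "+")
    assigned <- max.col(score, ties.method = "first")
    counts <- tabulate(assigned, nbins = N_CLASSES) + frozen_counts
    deficit <- (target - counts) * cell_ha
    if (all(abs(deficit) <= tol)) break
    sgn <- sign(deficit)
    if (!is.null(prev_sign) && any(sgn != 0) &&
        all(sgn[sgn != 0] == -prev_sign[sgn != 0]))
      damping <- max(damping / 2, 1e-4)
    prev_sign <- sgn
    offsets <- offsets + damping * deficit / pmax(demand_areas, cell_ha)
  }
  counts <- tabulate(assigned, nbins = N_CLASSES) + frozen_counts
  deviations <- abs(target - counts) * cell_ha
  out <- v
  newv <- cur
  newv[free] <- assigned
  out[valid] <- newv
  res <- current
  res$values <- matrix(out, current$nrows, current$ncols)
  structure(list(map = res, iterations_used = iter,
                 final_offsets = offsets, deviations = deviations,
                 tolerance = tol,
                 converged = all(deviations <= tol)),
            class = "allocation_result")
}

#' @export
print.allocation_result <- function(x, ...) {
  cat(sprintf("<allocation_result> %s after %d iteration(s); max deviation %.2f ha\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations_used, max(x$deviations)))
  invisible(x)
}

#' Run a multi-year scenario simulation
#'
#' Applies [allocate()] year by year along the config's demand table, each
#' year's output map seeding the next; the final map is the target-year
#' prediction. The suitability surfaces are held fixed, as in a single
#' calibrated CLUE-S run.
#'
#' @param lulc_start `lulc_map` at the first demand year.
#' @param suitability List of six probability grids or a cells x 6 matrix.
#' @param config `scenario_config` whose demand table covers every year.
#' @return List: `maps` (one `lulc_map` per simulated year, named by year),
#'   `results` (per-year `allocation_result`s), `final_map` (the target-year
#'   prediction; the start map for a zero-year horizon), `converged`.
#' @export
run_scenario <- function(lulc_start, suitability, config) {
  if (is.null(config$demand)) stop("config carries no demand table")
  years <- sort(unique(config$demand$year))
  current <- lulc_start
  maps <- list(); results <- list()
  for (y in years[-1]) {
    res <- allocate(current, suitability, config, demand_year = y)
    current <- res$map
    maps[[as.character(y)]] <- current
    results[[as.character(y)]] <- res
  }
  list(maps = maps, results = results, final_map = current,
       converged = all(vapply(results, function(r) r$converged, logical(1))))
}
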