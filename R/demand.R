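#' Estimate a transition probability matrix from a map pair
#'
#' Row u is the cross-tabulation row of class u normalised by the number of
#' class-u cells at t0; the matrix spans the caller-supplied number of years.
#'
#' @param map_t0,map_t1 Aligned `lulc_map`s. Every class must be present at t0.
#' @param period Years elapsed between the maps.
#' @return `transition_matrix`: list(P = 6x6 row-stochastic matrix, period).
#' @export
estimate_transition <- function(map_t0, map_t1, period = 1) {
  tab <- cross_tabulate(map_t0, map_t1)
  rs <- rowSums(tab)
  undefined <- rs == 0 & colSums(tab) > 0
  if (any(undefined))
    stop("class ", paste(which(undefined), collapse = ", "),
         " absent at t0 but present at t1: transition row undefined")
  P <- tab / pmax(rs, 1)
  diag(P)[rs == 0] <- 1   # classes absent from both maps: inert identity row
  new_transition_matrix(P, period = period)
}

#' @export
new_transition_matrix <- function(P, period = 1) {
  P <- as.matrix(P)
  check_row_stochastic(P)
  if (period < 1) stop("period must be >= 1 year")
  dimnames(P) <- list(as.character(seq_len(nrow(P))),
                      as.character(seq_len(ncol(P))))
  structure(list(P = P, period = period), class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> %d classes over %g year(s)\n",
              nrow(x$P), x$period))
  print(round(x$P, 4))
  invisible(x)
}

#' Annualize a multi-year transition matrix
#'
#' Computes the period-th matrix root by eigendecomposition, the standard way
#' to turn a 2005-2016-style matrix into a year-by-year Markov step. Tiny
#' negative entries produced by the root are clipped to zero and rows
#' renormalised. Requires (near-)real positive eigenvalues, which
#' diagonal-dominant LULC matrices have; otherwise an error recommends
#' projecting at the period level instead.
#'
#' @param tm A `transition_matrix` with period >= 1.
#' @param tol Tolerance on imaginary parts / negative eigenvalues.
#' @return A `transition_matrix` with period 1. Its `root_residual` field
#'   records the max-abs defect of the raw (pre-clipping) root raised back to
#'   the original period — the defining property of the matrix root.
#' @export
annualize <- function(tm, tol = 1e-8) {
  stopifnot(inherits(tm, "transition_matrix"))
  if (tm$period == 1) return(tm)
  e <- eigen(tm$P)
  if (any(abs(Im(e$values)) > tol) || any(Re(e$values) <= tol))
    stop("complex or non-positive eigenvalues: no reliable matrix root; ",
         "project at the period level instead")
  lam <- Re(e$values)^(1 / tm$period)
  V <- Re(e$vectors)
  R <- V %*% diag(lam) %*% solve(V)
  raw <- R
  back <- diag(nrow(raw))
  for (i in seq_len(tm$period)) back <- back %*% raw
  R[R < 0] <- 0
  R <- R / rowSums(R)
  out <- new_transition_matrix(R, period = 1)
  out$root_residual <- max(abs(back - tm$P))
  out
}

#' Raise a transition matrix to an integer power
#' @param tm A `transition_matrix`.
#' @param k Nonnegative integer.
#' @return A `transition_matrix` spanning `period * k` years.
#' @export
transition_power <- function(tm, k) {
  stopifnot(inherits(tm, "transition_matrix"), k == round(k), k >= 0)
  M <- diag(nrow(tm$P))
  for (i in seq_len(k)) M <- M %*% tm$P
  new_transition_matrix(M, period = max(tm$period * k, 1))
}

#' Project class-area demands year by year
#'
#' Propagates the class-area state vector s_{t+1} = s_t M through an annual
#' transition matrix, recording every yearly row. Row-stochasticity conserves
#' the total area exactly.
#'
#' @param initial_areas Named/plain numeric vector of 6 areas (ha), >= 0.
#' @param annual `transition_matrix` with period 1.
#' @param n_years Number of annual steps.
#' @param start_year Calendar year of the initial state (default 0).
#' @return A `demand_table`: data frame (year, class_code, class_name,
#'   area_ha) covering years start_year .. start_year + n_years.
#' @export
project_demand <- function(initial_areas, annual, n_years, start_year = 0) {
  stopifnot(inherits(annual, "transition_matrix"))
  if (length(initial_areas) != nrow(annual$P))
    stop("initial areas and transition matrix dimensions differ")
  if (any(initial_areas < 0)) stop("areas must be nonnegative")
  s <- as.numeric(initial_areas)
  rows <- matrix(NA_real_, n_years + 1, length(s))
  rows[1, ] <- s
  for (t in seq_len(n_years)) {
    s <- as.vector(s %*% annual$P)
    rows[t + 1, ] <- s
  }
  new_demand_table(rows, years = start_year + 0:n_years)
}

#' @export
new_demand_table <- function(area_matrix, years) {
  stopifnot(nrow(area_matrix) == length(years))
  if (any(area_matrix < -1e-9)) stop("demand areas must be nonnegative")
  totals <- rowSums(area_matrix)
  if (max(totals) - min(totals) > 0.5)
    stop("demand rows must conserve total area within 0.5 ha")
  cb <- lulc_codebook()
  out <- data.frame(
    year = rep(years, each = ncol(area_matrix)),
    class_code = rep(seq_len(ncol(area_matrix)), times = length(years)),
    class_name = rep(unname(cb), times = length(years)),
    area_ha = as.vector(t(area_matrix)))
  class(out) <- c("demand_table", "data.frame")
  out
}

#' Demand for one year as a class-area vector
#' @param demand A `demand_table`.
#' @param year Year present in the table.
#' @return Named numeric vector of 6 areas (ha).
#' @export
demand_for_year <- function(demand, year) {
  rows <- demand[demand$year == year, ]
  if (!nrow(rows)) stop("no demand recorded for year ", year)
  stats::setNames(rows$area_ha[order(rows$class_code)],
                  as.character(sort(rows$class_code)))
}

#' Restrict conversions in a transition matrix for a policy scenario
#'
#' Each rule multiplies one off-diagonal entry by a retention factor in
#' \[0, 1\] (0 forbids the conversion, 1 leaves it unchanged); the removed
#' probability mass is returned to the source diagonal so rows stay
#' stochastic. This is how ecological-protection rules (keeping tidal
#' wetland, water and garden/woodland-type land from converting away) and
#' farmland-protection rules are encoded.
#'
#' @param tm A `transition_matrix`.
#' @param rules Data frame with columns source, destination (class codes) and
#'   factor in \[0, 1\].
#' @return Adjusted `transition_matrix`.
#' @export
adjust_for_scenario <- function(tm, rules) {
  stopifnot(inherits(tm, "transition_matrix"))
  P <- tm$P
  for (i in seq_len(nrow(rules))) {
    u <- rules$source[i]; v <- rules$destination[i]; f <- rules$factor[i]
    if (is.na(f) || f < 0 || f > 1) stop("retention factor must lie in [0,1]")
    if (u == v) next
    removed <- P[u, v] * (1 - f)
    P[u, v] <- P[u, v] * f
    P[u, u] <- P[u, u] + removed
  }
  new_transition_matrix(P, period = tm$period)
}

#' Single land-use dynamic degree
#'
#' The annualised percentage rate of change of one class's area:
#' 100 * area_change / (start_area * span). Reported values are rounded to
#' 2 decimals by convention in the printed tables; the raw value is returned.
#'
#' @param area_change Signed change in ha over the span.
#' @param start_area Area at the start of the span (ha, > 0).
#' @param span_years Length of the span in years (> 0).
#' @return Percent per year (signed).
#' @export
dynamic_degree <- function(area_change, start_area, span_years) {
  if (any(start_area <= 0)) stop("start_area must be positive")
  if (any(span_years <= 0)) stop("span_years must be positive")
  100 * area_change / (start_area * span_years)
}

#' Calibrate an annual transition matrix to hit target areas
#'
#' Constructs a diagonal-dominant annual row-stochastic matrix whose
#' `years`-step projection from `start_areas` reproduces `target_areas`. Net
#' annual flows are routed from shrinking to growing classes proportionally
#' to their imbalances and corrected iteratively until every projected class
#' area is within `rel_tol` of its target. Used to build scenario demand
#' trajectories when only the endpoint areas of a published scenario table
#' are known.
#'
#' @param start_areas,target_areas Length-6 area vectors (ha) with equal
#'   totals (within 0.5% — endpoints from rounded tables are rescaled).
#' @param years Projection horizon in years.
#' @param rel_tol Per-class relative tolerance (default 0.005).
#' @param max_iter Maximum correction sweeps.
#' @return A period-1 `transition_matrix`.
#' @export
calibrate_transition <- function(start_areas, target_areas, years,
                                 rel_tol = 0.005, max_iter = 400) {
  s0 <- as.numeric(start_areas)
  tgt <- as.numeric(target_areas)
  if (abs(sum(s0) - sum(tgt)) > 0.005 * sum(s0))
    stop("start and target totals differ by more than 0.5%")
  tgt <- tgt * sum(s0) / sum(tgt)
  n <- length(s0)
  F <- matrix(0, n, n)   # annual flows, ha
  for (it in seq_len(max_iter)) {
    M <- F / s0
    diag(M) <- 0
    M[M < 0] <- 0
    rs <- rowSums(M)
    if (any(rs >= 1)) M <- M * pmin(1, 0.95 / pmax(rs, 1e-12))
    diag(M) <- 1 - rowSums(M)
    s <- s0
    for (t in seq_len(years)) s <- as.vector(s %*% M)
    err <- tgt - s
    if (max(abs(err) / pmax(tgt, 1)) < rel_tol)
      return(new_transition_matrix(M, period = 1))
    gain <- pmax(err, 0); loss <- pmax(-err, 0)
    if (sum(gain) > 1e-12) {
      # route the residual annual flow from shrinking to growing classes;
      # subtracting the transpose first unwinds any reverse flow built up
      # by earlier overshoot
      delta <- outer(loss, gain / sum(gain)) / years
      F <- pmax(F + 0.8 * (delta - t(delta)), 0)
    }
    diag(F) <- 0
  }
  stop("calibration did not converge within ", max_iter, " iterations")
}

#' Read/write demand tables as CSV
#' @param demand A `demand_table`.
#' @param path CSV path.
#' @return Invisibly `path` (write) or a `demand_table` (read).
#' @export
write_demand_csv <- function(demand, path) {
  utils::write.csv(as.data.frame(demand), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_demand_csv
#' @export
read_demand_csv <- function(path) {
  df <- utils::read.csv(path)
  years <- sort(unique(df$year))
  m <- matrix(NA_real_, length(years), N_CLASSES)
  for (i in seq_along(years)) {
    rows <- df[df$year == years[i], ]
    m[i, rows$class_code] <- rows$area_ha
  }
  new_demand_table(m, years)
}
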