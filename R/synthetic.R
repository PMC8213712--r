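#' Default generative coefficients for the synthetic landscape
#'
#' One row per class, columns `(intercept, dist_residential, dist_mines,
#' dist_roads, dist_rivers, dist_ditches, elevation, slope)`, applied to
#' standardized drivers. Signs mirror the published regression pattern for
#' the six classes of the Weishan mining-region case study (construction land
#' strongly tied to residential proximity, subsided seeper area to mines,
#' water to rivers, etc.). Magnitudes follow a dominance design: each class
#' is driven by one or two strong factors (|beta| >= 1.2) while all secondary
#' effects stay below 0.45, so the marginal class-driver associations cannot
#' be flipped by chance correlation between distance fields.
#'
#' @return 6 x 8 numeric matrix with class-code rownames.
#' @export
default_true_betas <- function() {
  b <- rbind(
    c(0,  -1.2,  0.0,  0.45, -0.45,  0.45, -0.2, -0.15),
    c(0,   0.2,  0.3, -0.10, -1.20,  0.40,  0.1,  0.10),
    c(0,  -2.4, -0.45, -0.20,  0.0,  0.20,  0.1, -0.05),
    c(0,   0.45, -2.4, -0.45, -0.45,  0.30,  0.45, 0.0),
    c(0,   0.45, -0.3, -0.45,  1.60, -1.60,  0.2, -0.05),
    c(0,   0.45,  1.2, -0.45,  0.0,  -1.40,  0.2,  0.20)
  )
  dimnames(b) <- list(as.character(1:N_CLASSES), c("intercept", driver_names()))
  b
}

#' Default target class proportions
#'
#' Class shares matching the natural-development scenario of the case-study
#' demand table (farmland 0.220, other agricultural 0.355, construction
#' 0.056, subsided seeper 0.010, water 0.333, tidal wetland 0.025).
#'
#' @return Numeric vector of length 6 summing to 1.
#' @export
default_target_proportions <- function() {
  p <- c(0.220, 0.355, 0.056, 0.010, 0.333, 0.026)
  p / sum(p)
}

#' Generate a spatially autocorrelated DEM
#'
#' Gaussian-filtered white noise (periodic FFT convolution) rescaled to a
#' lowland lake-plain elevation range of about 30-60 m. Fully reproducible
#' per seed.
#'
#' @param nrows,ncols Grid dimensions (each >= 16).
#' @param cellsize Cell size in meters.
#' @param seed Integer seed.
#' @param smoothness Gaussian kernel standard deviation in cells (> 0).
#' @return `lulc_grid` DEM.
#' @export
generate_dem <- function(nrows, ncols, cellsize = 60, seed = 1,
                         smoothness = 4) {
  if (nrows < 16 || ncols < 16) stop("DEM dimensions must be at least 16x16")
  if (smoothness <= 0) stop("smoothness must be positive")
  rng <- local_rng(seed, "dem")
  z <- matrix(rng$norm(nrows * ncols), nrows, ncols)
  z <- gaussian_smooth(z, smoothness)
  z <- (z - min(z)) / (max(z) - min(z)) * 30 + 30   # 30..60 m
  new_grid(z, cellsize = cellsize)
}

# periodic Gaussian smoothing via FFT
gaussian_smooth <- function(m, sigma) {
  nr <- nrow(m); nc <- ncol(m)
  gr <- dnorm(pmin(0:(nr - 1), nr - 0:(nr - 1)), sd = sigma)
  gc <- dnorm(pmin(0:(nc - 1), nc - 0:(nc - 1)), sd = sigma)
  k <- outer(gr, gc); k <- k / sum(k)
  Re(fft(fft(m) * fft(k), inverse = TRUE)) / (nr * nc)
}

#' Generate feature networks for the accessibility drivers
#'
#' Roads, rivers and ditches are random rasterised polylines (8-connected);
#' mines are scattered points; residential areas are small square patches.
#' Every mask is non-empty.
#'
#' @param nrows,ncols,cellsize Geometry.
#' @param seed Integer seed.
#' @return Named list of binary `lulc_grid` masks: roads, rivers, ditches,
#'   mines, residential.
#' @export
generate_features <- function(nrows, ncols, cellsize = 60, seed = 1) {
  if (nrows < 16 || ncols < 16) stop("feature geometry must be at least 16x16")
  rng <- local_rng(seed, "features")
  mk <- function(n_lines) {
    m <- matrix(0, nrows, ncols)
    for (i in seq_len(n_lines)) m <- m | rasterize_polyline(nrows, ncols, rng)
    m
  }
  masks <- list(
    roads = mk(3), rivers = mk(2), ditches = mk(4),
    mines = scatter_points(nrows, ncols, 8, rng),
    residential = scatter_patches(nrows, ncols, 10, rng)
  )
  lapply(masks, function(m) new_grid(m + 0, cellsize = cellsize))
}

# a jittered polyline across the grid, rasterised segment by segment
rasterize_polyline <- function(nrows, ncols, rng) {
  horiz <- rng$unif(1) < 0.5
  nseg <- 4L
  if (horiz) {
    xs <- round(seq(1, ncols, length.out = nseg + 1))
    ys <- pmin(pmax(round(rng$unif(nseg + 1) * (nrows - 1)) + 1 +
                      round(rng$norm(nseg + 1) * 2), 1), nrows)
    ys <- round(stats::filter(c(ys[1], ys, ys[nseg + 1]), rep(1 / 3, 3)))[2:(nseg + 2)]
  } else {
    ys <- round(seq(1, nrows, length.out = nseg + 1))
    xs <- pmin(pmax(round(rng$unif(nseg + 1) * (ncols - 1)) + 1 +
                      round(rng$norm(nseg + 1) * 2), 1), ncols)
    xs <- round(stats::filter(c(xs[1], xs, xs[nseg + 1]), rep(1 / 3, 3)))[2:(nseg + 2)]
  }
  m <- matrix(FALSE, nrows, ncols)
  for (s in seq_len(nseg)) {
    m <- m | bresenham(ys[s], xs[s], ys[s + 1], xs[s + 1], nrows, ncols)
  }
  m
}

# 8-connected line rasterisation between two cells
bresenham <- function(r0, c0, r1, c1, nrows, ncols) {
  m <- matrix(FALSE, nrows, ncols)
  n <- max(abs(r1 - r0), abs(c1 - c0)) + 1L
  rr <- round(seq(r0, r1, length.out = n))
  cc <- round(seq(c0, c1, length.out = n))
  m[cbind(pmin(pmax(rr, 1), nrows), pmin(pmax(cc, 1), ncols))] <- TRUE
  m
}

scatter_points <- function(nrows, ncols, n, rng) {
  m <- matrix(0, nrows, ncols)
  r <- pmax(1, pmin(nrows, floor(rng$unif(n) * nrows) + 1))
  c_ <- pmax(1, pmin(ncols, floor(rng$unif(n) * ncols) + 1))
  m[cbind(r, c_)] <- 1
  m
}

scatter_patches <- function(nrows, ncols, n, rng) {
  m <- matrix(0, nrows, ncols)
  r <- pmax(2, pmin(nrows - 1, floor(rng$unif(n) * nrows) + 1))
  c_ <- pmax(2, pmin(ncols - 1, floor(rng$unif(n) * ncols) + 1))
  for (i in seq_len(n)) m[(r[i] - 1):(r[i] + 1), (c_[i] - 1):(c_[i] + 1)] <- 1
  m
}

#' Derive the seven-driver stack from a DEM and feature masks
#'
#' Five accessibility layers via the Euclidean distance transform, slope via
#' Horn's method, elevation taken from the DEM itself.
#'
#' @param dem `lulc_grid` DEM.
#' @param features Named mask list from [generate_features()].
#' @return A `driver_stack`.
#' @export
generate_drivers <- function(dem, features) {
  new_driver_stack(list(
    dist_residential = euclidean_distance(features$residential),
    dist_mines = euclidean_distance(features$mines),
    dist_roads = euclidean_distance(features$roads),
    dist_rivers = euclidean_distance(features$rivers),
    dist_ditches = euclidean_distance(features$ditches),
    elevation = dem,
    slope = slope_from_dem(dem)
  ))
}

#' Sample an LULC map from a known logistic structure
#'
#' Per-class linear scores on standardized drivers are combined by softmax
#' and each cell's class is sampled from the resulting distribution (exactly
#' one class per cell). Intercepts are auto-tuned so realised class
#' proportions land within +-3 percentage points of the targets, and one
#' 3x3 majority-filter pass gives the map patch structure.
#'
#' @param drivers A `driver_stack`.
#' @param true_betas 6 x 8 coefficient matrix (see [default_true_betas()]).
#' @param target_proportions Length-6 vector summing to 1.
#' @param seed Integer seed.
#' @param patch_sigma,patch_strength Texture knobs: standard deviation (in
#'   cells) and amplitude (in logit units) of the smooth per-class random
#'   fields added to the scores so sampled classes form patches rather than
#'   salt-and-pepper noise. The fields are independent of the drivers, so
#'   the signed driver-class structure is preserved.
#' @return List with `map` (an `lulc_map`) and `truth` (a `synthetic_truth`
#'   record holding the betas, tuned intercepts, seed and geometry).
#' @export
generate_lulc <- function(drivers, true_betas = default_true_betas(),
                          target_proportions = default_target_proportions(),
                          seed = 1, patch_sigma = 4, patch_strength = 2.5) {
  if (abs(sum(target_proportions) - 1) > 1e-6)
    stop("target proportions must sum to 1")
  std <- standardize_drivers(drivers)
  X <- driver_matrix(std$drivers)[, colnames(true_betas)[-1], drop = FALSE]
  eta0 <- X %*% t(true_betas[, -1, drop = FALSE])   # cells x classes, no intercepts
  g1 <- drivers[[1]]
  noise_rng <- local_rng(seed, "patch")
  for (k in seq_len(N_CLASSES)) {
    f <- gaussian_smooth(matrix(noise_rng$norm(g1$nrows * g1$ncols),
                                g1$nrows, g1$ncols), patch_sigma)
    eta0[, k] <- eta0[, k] + as.vector(f) / stats::sd(f) * patch_strength
  }
  a <- true_betas[, 1]
  # inner loop: tune intercepts on expected softmax proportions
  tune <- function(a, targets) {
    for (it in 1:200) {
      p <- softmax_rows(sweep(eta0, 2, a, "+"))
      share <- colMeans(p)
      if (all(share <= 0)) stop("unattainable proportions: a class has all-zero scores")
      if (max(abs(share - targets)) < 1e-4) break
      a <- a + log(targets / pmax(share, 1e-12))
      a <- a - mean(a)
    }
    a
  }
  targets <- target_proportions
  rng <- local_rng(seed, "lulc")
  map <- NULL
  for (outer in 1:8) {
    a <- tune(a, targets)
    p <- softmax_rows(sweep(eta0, 2, a, "+"))
    u <- rng$unif(nrow(p))
    cls <- sample_classes(p, u)
    g <- drivers[[1]]
    m <- new_lulc_map(new_grid(matrix(cls, g$nrows, g$ncols),
                               cellsize = g$cellsize, xllcorner = g$xllcorner,
                               yllcorner = g$yllcorner))
    map <- majority_filter(m)
    realised <- class_areas(map) / sum(class_areas(map))
    err <- realised - target_proportions
    if (max(abs(err)) <= 0.02) break
    # damped nudge of the tuning targets against sampling + smoothing drift
    ratio <- pmin(pmax((target_proportions / pmax(realised, 1e-4))^0.7, 0.5), 2)
    targets <- pmax(targets * ratio, 1e-4)
    targets <- targets / sum(targets)
  }
  truth <- structure(list(
    true_betas = cbind(intercept = a, true_betas[, -1, drop = FALSE]),
    target_proportions = target_proportions,
    seed = seed,
    geometry = list(nrows = map$nrows, ncols = map$ncols, cellsize = map$cellsize),
    standardization = std$params
  ), class = "synthetic_truth")
  list(map = map, truth = truth)
}

softmax_rows <- function(eta) {
  e <- exp(eta - apply(eta, 1, max))
  e / rowSums(e)
}

# inverse-CDF sampling of one class per row of a probability matrix
sample_classes <- function(p, u) {
  cum <- p %*% upper.tri(diag(ncol(p)), diag = TRUE)   # row-wise cumsum
  cls <- rowSums(cum < u) + 1L
  pmin(cls, ncol(p))
}

#' Evolve an LULC map by a known transition matrix
#'
#' Within each source class u, the number of cells converting to each
#' destination v is the matrix entry times the class count (largest-remainder
#' rounding); among cells of u slated to become v, those with the highest
#' suitability for v convert first (a seeded micro-jitter breaks exact ties
#' deterministically).
#'
#' @param map `lulc_map` without nodata.
#' @param true_transition 6x6 row-stochastic matrix.
#' @param suitability List of six probability `lulc_grid`s (or a cells x 6
#'   matrix) scoring each class.
#' @param seed Integer seed for tie jitter.
#' @return Evolved `lulc_map`.
#' @export
evolve_lulc <- function(map, true_transition, suitability, seed = 1) {
  stopifnot(inherits(map, "lulc_map"))
  check_row_stochastic(true_transition)
  S <- suitability_matrix(suitability, map)
  rng <- local_rng(seed, "evolve")
  S <- S + matrix(rng$unif(length(S)) * 1e-9, nrow(S), ncol(S))
  v <- as.vector(map$values)
  out <- v
  for (u in seq_len(N_CLASSES)) {
    idx <- which(v == u)
    if (!length(idx)) next
    quota <- largest_remainder(true_transition[u, ] * length(idx), length(idx))
    remaining <- idx
    for (dest in order(true_transition[u, ], decreasing = TRUE)) {
      if (dest == u || quota[dest] == 0L) next
      take <- remaining[order(S[remaining, dest], decreasing = TRUE)[seq_len(quota[dest])]]
      out[take] <- dest
      remaining <- setdiff(remaining, take)
    }
    out[remaining] <- u
  }
  map$values <- matrix(out, map$nrows, map$ncols)
  map
}

# round nonnegative reals to integers that sum to `total`
largest_remainder <- function(x, total) {
  fl <- floor(x)
  rem <- as.integer(total - sum(fl))
  add <- integer(length(x))
  if (rem > 0) {
    ord <- order(x - fl, decreasing = TRUE)
    add[ord[seq_len(rem)]] <- 1L
  }
  as.integer(fl + add)
}

check_row_stochastic <- function(P, tol = 1e-9) {
  if (!is.matrix(P) || nrow(P) != ncol(P)) stop("transition matrix must be square")
  if (any(P < -tol) || any(P > 1 + tol)) stop("transition entries must lie in [0,1]")
  if (any(abs(rowSums(P) - 1) > 1e-6)) stop("transition matrix rows must sum to 1")
  invisible(TRUE)
}

# accept either a list of 6 grids or a cells x 6 matrix
suitability_matrix <- function(suitability, map) {
  if (is.matrix(suitability)) {
    stopifnot(nrow(suitability) == map$nrows * map$ncols, ncol(suitability) == N_CLASSES)
    return(suitability)
  }
  stopifnot(is.list(suitability), length(suitability) == N_CLASSES)
  vapply(suitability, function(g) as.vector(g$values),
         numeric(map$nrows * map$ncols))
}

#' Default generative transition matrix for synthetic map pairs
#'
#' Diagonal-dominant with off-diagonal flows echoing the case-study change
#' directions (farmland and tidal wetland losing to other agricultural land
#' and water; subsided seeper reclaiming to water).
#'
#' @return 6x6 row-stochastic matrix.
#' @export
default_true_transition <- function() {
  P <- diag(6) * 0
  P[1, ] <- c(0.86, 0.08, 0.01, 0.00, 0.05, 0.00)
  P[2, ] <- c(0.04, 0.90, 0.01, 0.00, 0.05, 0.00)
  P[3, ] <- c(0.05, 0.15, 0.78, 0.00, 0.02, 0.00)
  P[4, ] <- c(0.00, 0.05, 0.00, 0.75, 0.20, 0.00)
  P[5, ] <- c(0.01, 0.02, 0.00, 0.00, 0.96, 0.01)
  P[6, ] <- c(0.00, 0.25, 0.00, 0.00, 0.25, 0.50)
  dimnames(P) <- list(as.character(1:6), as.character(1:6))
  P
}

#' Generate a complete synthetic landscape
#'
#' Convenience wrapper producing DEM, features, the seven-driver stack, a t0
#' LULC map sampled from a known logistic structure and a t1 map evolved by a
#' known transition matrix. Everything is reproducible from the single seed.
#'
#' @param nrows,ncols,cellsize Geometry (default 200 x 200 at 60 m).
#' @param seed Integer seed.
#' @param true_betas,target_proportions,true_transition Generative structure.
#' @return List: dem, features, drivers, lulc_t0, lulc_t1, truth.
#' @export
generate_landscape <- function(nrows = 200, ncols = 200, cellsize = 60,
                               seed = 1,
                               true_betas = default_true_betas(),
                               target_proportions = default_target_proportions(),
                               true_transition = default_true_transition()) {
  dem <- generate_dem(nrows, ncols, cellsize, seed = seed)
  features <- generate_features(nrows, ncols, cellsize, seed = seed)
  drivers <- generate_drivers(dem, features)
  gen <- generate_lulc(drivers, true_betas, target_proportions, seed = seed)
  suit <- true_suitability(gen$truth, drivers)
  t1 <- evolve_lulc(gen$map, true_transition, suit, seed = seed)
  list(dem = dem, features = features, drivers = drivers,
       lulc_t0 = gen$map, lulc_t1 = t1,
       truth = c(unclass(gen$truth), list(true_transition = true_transition)))
}

#' Per-class softmax probabilities under the generative truth
#'
#' @param truth A `synthetic_truth` (or the `truth` element of
#'   [generate_landscape()]).
#' @param drivers The `driver_stack` the truth was generated on.
#' @return cells x 6 matrix of class probabilities.
#' @export
true_suitability <- function(truth, drivers) {
  std <- standardize_drivers(drivers, params = truth$standardization)
  X <- driver_matrix(std$drivers)[, colnames(truth$true_betas)[-1], drop = FALSE]
  eta <- sweep(X %*% t(truth$true_betas[, -1, drop = FALSE]), 2,
               truth$true_betas[, 1], "+")
  softmax_rows(eta)
}

# A small deterministic RNG wrapper: every generator draws from its own
# stream keyed by (seed, label), so stages stay reproducible independently.
local_rng <- function(seed, label) {
  sub <- (as.numeric(seed) * 131 + sum(utf8ToInt(label))) %% 2147483647
  env <- new.env()
  env$state <- sub
  draw <- function(n, fn) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old))
    set.seed(env$state)
    x <- fn(n)
    env$state <- (env$state * 48271) %% 2147483647
    x
  }
  list(unif = function(n) draw(n, stats::runif),
       norm = function(n) draw(n, stats::rnorm))
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
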