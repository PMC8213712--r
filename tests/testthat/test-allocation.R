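test_that("total probability composes suitability, elasticity and offset", {
  cfg <- scenario_config("toy", elas = c(0.7, 0.5, 0.9, 0.6, 0.6, 0.55))
  # incumbent class: suitability + its elasticity
  expect_equal(total_probability(0.4, 1, 1, cfg, rep(0, 6)), 1.1)
  # non-incumbent: suitability + offset only
  expect_equal(total_probability(0.4, 2, 1, cfg, c(0, 0.25, 0, 0, 0, 0)), 0.65)
  # disallowed conversions are not scored
  cfg2 <- scenario_config("toy", elas = rep(0.5, 6),
                          allowed = {m <- matrix(TRUE, 6, 6); m[1, 3] <- FALSE; m})
  expect_true(is.na(total_probability(0.9, 3, 1, cfg2, rep(0, 6))))
  # with zero elasticity and offsets the ranking is the suitability ranking
  p <- c(0.2, 0.5, 0.3)
  scores <- sapply(1:3, function(k)
    total_probability(p[k], k, 4, scenario_config("z", rep(0, 6)), rep(0, 6)))
  expect_equal(order(scores), order(p))
})

test_that("demand equal to current areas is a fixed point", {
  set.seed(61)
  v <- matrix(rep(1:6, length.out = 64), 8, 8)
  map <- toy_map(v)
  # moderate suitabilities: elasticity dominates any cross-class difference
  S <- matrix(runif(64 * 6, 0.3, 0.5), 64, 6)
  cfg <- scenario_config("fp", elas = rep(0.6, 6), tolerance = 0.05)
  res <- allocate(map, S, cfg, demand_areas = class_areas(map))
  expect_true(res$converged)
  expect_identical(res$map$values, map$values)
})

test_that("the allocator matches exhaustive search on 4-cell toys", {
  # 2-class problems on 4 cells: enumerate every assignment meeting the
  # demanded counts and maximise summed TPROP
  oracle <- function(P, cur, elas, n1) {
    cells <- seq_len(4)
    best <- NULL; best_val <- -Inf
    for (ones in if (n1 == 0) list(integer(0)) else asplit(utils::combn(4, n1), 2)) {
      assign <- rep(2L, 4); assign[unlist(ones)] <- 1L
      val <- sum(P[cbind(cells, assign)] + elas[assign] * (assign == cur))
      if (val > best_val) { best_val <- val; best <- assign }
    }
    best
  }
  set.seed(62)
  for (rep in 1:20) {
    P <- cbind(runif(4), runif(4))
    cur <- sample(1:2, 4, replace = TRUE)
    elas <- c(runif(1, 0, 0.6), runif(1, 0, 0.6), 0, 0, 0, 0)
    n1 <- sample(0:4, 1)
    map <- toy_map(cur)
    S <- cbind(P, matrix(0, 4, 4))
    demand <- c(n1, 4 - n1, 0, 0, 0, 0) * 0.36
    cfg <- scenario_config("toy", elas = elas, tolerance = 0.01,
                           max_iterations = 5000)
    res <- allocate(map, S, cfg, demand_areas = demand)
    expect_true(res$converged, info = paste("rep", rep))
    got <- as.vector(res$map$values)
    want <- oracle(P, cur, elas, n1)
    expect_equal(sum(P[cbind(1:4, got)] + elas[got] * (got == cur)),
                 sum(P[cbind(1:4, want)] + elas[want] * (want == cur)),
                 tolerance = 1e-12, info = paste("rep", rep))
  }
})

test_that("allocation meets demand, conserves cells and honours bans", {
  land <- test_landscape(100, 7)
  model <- test_model(100, 7)
  probs <- lulcsim:::suitability_matrix(
    predict_all_probabilities(model, land$drivers), land$lulc_t1)
  tm <- annualize(estimate_transition(land$lulc_t0, land$lulc_t1, period = 11))
  demand <- project_demand(class_areas(land$lulc_t1), tm, 5)

  allowed <- matrix(TRUE, 6, 6)
  allowed[3, 6] <- FALSE   # construction land may not become tidal wetland
  cfg <- scenario_config("natural development", elas = weishan_elas("natural"),
                         allowed = allowed, demand = demand)
  run <- run_scenario(land$lulc_t1, probs, cfg)
  expect_true(run$converged)

  prev <- land$lulc_t1
  for (y in names(run$maps)) {
    cur <- run$maps[[y]]
    # cell conservation
    expect_equal(sum(!is.na(cur$values)), sum(!is.na(prev$values)))
    # class areas within tolerance of the year's demand (one cell of slack
    # for the integer-count rounding of fractional demands)
    dv <- abs(class_areas(cur) - demand_for_year(demand, as.integer(y)))
    expect_true(all(dv <= run$results[[y]]$tolerance + 0.36 + 1e-9))
    # forbidden transition never observed
    tab <- cross_tabulate(prev, cur)
    expect_equal(tab[3, 6], 0L)
    prev <- cur
  }
})

test_that("raising a class's demand never shrinks its converged area", {
  land <- test_landscape(100, 7)
  model <- test_model(100, 7)
  probs <- lulcsim:::suitability_matrix(
    predict_all_probabilities(model, land$drivers), land$lulc_t1)
  base <- class_areas(land$lulc_t1)
  cfg <- scenario_config("mono", elas = weishan_elas("natural"))
  r1 <- allocate(land$lulc_t1, probs, cfg, demand_areas = base)
  shift <- c(200, -200, 0, 0, 0, 0)
  r2 <- allocate(land$lulc_t1, probs, cfg, demand_areas = base + shift)
  expect_gte(class_areas(r2$map)[1], class_areas(r1$map)[1])
})

test_that("relabelling cell order leaves class areas unchanged", {
  set.seed(63)
  v <- sample(1:6, 100, replace = TRUE)
  S <- matrix(runif(600), 100, 6)
  demand <- (tabulate(v, 6) + c(3, -3, 2, -2, 0, 0)) * 0.36
  cfg <- scenario_config("perm", elas = rep(0.4, 6), tolerance = 0.05,
                         max_iterations = 5000)
  r1 <- allocate(toy_map(matrix(v, 10, 10)), S, cfg, demand_areas = demand)
  perm <- sample(100)
  r2 <- allocate(toy_map(matrix(v[perm], 10, 10)), S[perm, ], cfg,
                 demand_areas = demand)
  expect_equal(class_areas(r1$map), class_areas(r2$map))
})

test_that("a fully elastic class never converts away when demand permits", {
  set.seed(64)
  v <- sample(1:6, 400, replace = TRUE)
  S <- matrix(runif(2400), 400, 6)
  cfg <- scenario_config("elas1", elas = c(1, 0, 0, 0, 0, 0), tolerance = 0.05,
                         max_iterations = 5000)
  res <- allocate(toy_map(matrix(v, 20, 20)), S, cfg,
                  demand_areas = tabulate(v, 6) * 0.36)
  expect_true(all(res$map$values[matrix(v, 20, 20) == 1] == 1))
})

test_that("a zero-year horizon returns the start map", {
  land <- test_landscape(100, 7)
  dem <- new_demand_table(matrix(class_areas(land$lulc_t1), 1), years = 0)
  cfg <- scenario_config("null", elas = rep(0.5, 6), demand = dem)
  probs <- matrix(0.5, 10000, 6)
  run <- run_scenario(land$lulc_t1, probs, cfg)
  expect_length(run$maps, 0)
  expect_identical(run$final_map$values, land$lulc_t1$values)
  expect_true(run$converged)
})

test_that("infeasible demand totals are rejected before iterating", {
  map <- toy_map(matrix(rep(1:6, length.out = 36), 6, 6))
  S <- matrix(0.5, 36, 6)
  cfg <- scenario_config("bad", elas = rep(0.5, 6))
  expect_error(allocate(map, S, cfg, demand_areas = rep(100, 6)),
               "does not match")
})
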