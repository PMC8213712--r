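# Shared synthetic fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

test_landscape <- function(size = 100, seed = 7) {
  key <- sprintf("land_%d_%d", size, seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generate_landscape(size, size, 60, seed = seed)
  .fixture_cache[[key]]
}

test_model <- function(size = 100, seed = 7) {
  key <- sprintf("model_%d_%d", size, seed)
  if (is.null(.fixture_cache[[key]])) {
    land <- test_landscape(size, seed)
    .fixture_cache[[key]] <- suppressWarnings(
      fit_suitability_model(land$lulc_t1, land$drivers))
  }
  .fixture_cache[[key]]
}

# small categorical map from a vector/matrix of codes
toy_map <- function(v, nrow = NULL, cellsize = 60) {
  if (!is.matrix(v)) v <- matrix(v, nrow = if (is.null(nrow)) 1 else nrow)
  new_lulc_map(new_grid(v, cellsize = cellsize))
}

# random driver stack of independent smooth layers (no feature structure)
random_driver_stack <- function(n = 30, k = 4, seed = 1, names = NULL) {
  set.seed(seed)
  if (is.null(names)) names <- paste0("v", seq_len(k))
  layers <- lapply(seq_len(k), function(i) new_grid(matrix(rnorm(n * n), n, n), 60))
  names(layers) <- names
  new_driver_stack(layers)
}
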