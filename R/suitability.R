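#' Zero-mean standardization of a driver stack
#'
#' Each layer is transformed to mean 0 and standard deviation 1 over its
#' valid cells (population, divide-by-n, convention). The returned parameters
#' are reused at prediction time so new rasters are placed on the fit-time
#' scale.
#'
#' @param drivers A `driver_stack`.
#' @param params Optional data frame (driver, mean, sd) from an earlier call;
#'   when supplied those parameters are applied instead of re-estimating.
#' @return List: `drivers` (standardized stack), `params` (data frame).
#' @export
standardize_drivers <- function(drivers, params = NULL) {
  stopifnot(inherits(drivers, "driver_stack"))
  if (is.null(params)) {
    params <- data.frame(driver = names(drivers), mean = NA_real_, sd = NA_real_)
    for (k in seq_along(drivers)) {
      v <- drivers[[k]]$values[!is.na(drivers[[k]]$values)]
      if (length(unique(v)) < 2)
        stop("driver '", names(drivers)[k], "' is constant: cannot standardize")
      params$mean[k] <- mean(v)
      params$sd[k] <- sqrt(mean((v - mean(v))^2))
    }
  }
  out <- drivers
  for (k in seq_along(drivers)) {
    row <- match(names(drivers)[k], params$driver)
    if (is.na(row)) stop("no standardization parameters for driver '",
                         names(drivers)[k], "'")
    out[[k]]$values <- (drivers[[k]]$values - params$mean[row]) / params$sd[row]
  }
  list(drivers = new_driver_stack(unclass(out), standardized = TRUE),
       params = params)
}

#' Tolerance and variance-inflation-factor collinearity diagnostics
#'
#' For each driver j, tolerance_j = 1 - R^2 from the least-squares regression
#' of driver j on all the other drivers, and VIF_j = 1 / tolerance_j. Drivers
#' with tolerance < 0.1 (equivalently VIF > 5 at the usual cutoffs 0.1 / 5)
#' are flagged as collinear.
#'
#' @param drivers A `driver_stack` with at least two layers.
#' @return Data frame (driver, tolerance, vif, flagged) of class
#'   `collinearity_report`.
#' @export
collinearity_diagnostics <- function(drivers) {
  stopifnot(inherits(drivers, "driver_stack"), length(drivers) >= 2)
  X <- driver_matrix(drivers)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) <= ncol(X)) stop("need more valid cells than drivers")
  tol <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    if (tss == 0) stop("driver '", colnames(X)[j], "' is constant")
    max(rss / tss, 0)
  }, numeric(1))
  out <- data.frame(driver = colnames(X), tolerance = tol, vif = 1 / tol,
                    flagged = tol < 0.1)
  class(out) <- c("collinearity_report", "data.frame")
  out
}

#' Fit a one-vs-rest binary logistic suitability model for one class
#'
#' Maximum-likelihood logistic regression of class presence/absence on a
#' subset of standardized drivers, exactly the per-class binary formulation
#' used to parameterise CLUE-S suitability surfaces. Non-convergence and
#' quasi-complete separation are flagged on the result, not raised.
#'
#' @param lulc An `lulc_map`.
#' @param class_code Class in 1..6.
#' @param drivers Standardized `driver_stack`.
#' @param included Character vector of driver names to include (default all).
#' @return List: class_code, intercept, coefficients (named), converged,
#'   separation, n, prevalence.
#' @export
fit_binary_logistic <- function(lulc, class_code, drivers,
                                included = names(drivers)) {
  stopifnot(inherits(lulc, "lulc_map"), class_code %in% 1:N_CLASSES)
  bad <- setdiff(included, names(drivers))
  if (length(bad)) stop("unknown driver(s): ", paste(bad, collapse = ", "))
  X <- driver_matrix(drivers)[, included, drop = FALSE]
  y <- as.vector(lulc$values) == class_code
  keep <- stats::complete.cases(X) & !is.na(as.vector(lulc$values))
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  if (sum(y) == 0) stop("class ", class_code, " absent from the map")
  if (sum(y) < 30 || sum(!y) < 30)
    stop("class ", class_code, " needs >= 30 presence and absence cells")
  dat <- data.frame(y = y, X)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- stats::coef(fit)
  if (sep) warning("possible complete separation for class ", class_code,
                   "; coefficients reported with a flag")
  list(class_code = as.integer(class_code),
       intercept = unname(cf[1]),
       coefficients = cf[-1][included],
       converged = fit$converged,
       separation = sep,
       n = length(y),
       prevalence = mean(y))
}

#' Fit the full six-class suitability model
#'
#' Standardizes the drivers, then fits one binary logistic model per class.
#' Per-class driver subsets allow excluded drivers (structural zero
#' coefficients), mirroring published coefficient tables with absent cells.
#'
#' @param lulc An `lulc_map`.
#' @param drivers A raw (unstandardized) `driver_stack`.
#' @param included Optional named list: class code -> character vector of
#'   included drivers; default all drivers for every class.
#' @return Object of class `suitability_model`: per-class entries plus the
#'   standardization parameters.
#' @export
fit_suitability_model <- function(lulc, drivers, included = NULL) {
  std <- standardize_drivers(drivers)
  models <- lapply(seq_len(N_CLASSES), function(k) {
    inc <- if (is.null(included)) names(drivers) else included[[as.character(k)]]
    if (is.null(inc)) inc <- names(drivers)
    fit_binary_logistic(lulc, k, std$drivers, included = inc)
  })
  structure(list(models = models, standardization = std$params,
                 codebook = lulc_codebook()),
            class = "suitability_model")
}

#' @export
print.suitability_model <- function(x, ...) {
  cat("<suitability_model> 6 one-vs-rest binary logistic models\n")
  for (m in x$models)
    cat(sprintf("  class %d (%s): intercept %.3f, %d drivers%s\n",
                m$class_code, x$codebook[[as.character(m$class_code)]],
                m$intercept, length(m$coefficients),
                if (!m$converged) " [not converged]" else if (m$separation) " [separation]" else ""))
  invisible(x)
}

#' Predict the suitability probability surface for one class
#'
#' Applies the logistic transform P = exp(eta) / (1 + exp(eta)) with
#' eta = beta0 + sum(beta_j X_j), after standardizing the drivers with the
#' parameters stored in the model. Numerically stable for any finite eta.
#'
#' @param model A `suitability_model`.
#' @param drivers A raw `driver_stack` on any aligned geometry.
#' @param class_code Class in 1..6.
#' @return `lulc_grid` of probabilities in (0, 1).
#' @export
predict_probability <- function(model, drivers, class_code) {
  stopifnot(inherits(model, "suitability_model"), class_code %in% 1:N_CLASSES)
  entry <- model$models[[class_code]]
  std <- standardize_drivers(drivers, params = model$standardization)
  need <- names(entry$coefficients)
  if (!all(need %in% names(std$drivers)))
    stop("missing included driver(s): ",
         paste(setdiff(need, names(std$drivers)), collapse = ", "))
  X <- driver_matrix(std$drivers)[, need, drop = FALSE]
  eta <- entry$intercept + as.vector(X %*% entry$coefficients)
  p <- stats::plogis(eta)
  g <- drivers[[1]]
  new_grid(matrix(p, g$nrows, g$ncols), cellsize = g$cellsize,
           xllcorner = g$xllcorner, yllcorner = g$yllcorner,
           nodata_value = g$nodata_value)
}

#' Predicted probability surfaces for all six classes
#' @inheritParams predict_probability
#' @return List of six probability grids, one per class code.
#' @export
predict_all_probabilities <- function(model, drivers) {
  lapply(seq_len(N_CLASSES), function(k) predict_probability(model, drivers, k))
}

#' Area under the ROC curve
#'
#' Rank-statistic (Mann-Whitney) estimator with ties averaged: identical to
#' the exhaustive pairwise comparison of positive/negative score pairs.
#'
#' @param prob Probability `lulc_grid` (or numeric vector of scores).
#' @param truth Binary `lulc_grid` (or logical/0-1 vector).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(prob, truth) {
  s <- if (inherits(prob, "lulc_grid")) as.vector(prob$values) else as.numeric(prob)
  y <- if (inherits(truth, "lulc_grid")) as.vector(truth$values) else as.numeric(truth)
  keep <- !is.na(s) & !is.na(y)
  s <- s[keep]; y <- y[keep] != 0
  npos <- sum(y); nneg <- sum(!y)
  if (npos == 0 || nneg == 0) stop("truth must contain both outcome values")
  r <- rank(s)   # ties averaged
  (sum(r[y]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Multi-scale regression comparison
#'
#' Resamples the map (majority) and drivers (mean) by each factor, refits the
#' six suitability models at that scale and reports the per-class AUC of the
#' fitted probability surface against class presence. Used to choose the
#' working resolution: the scale that keeps the explanatory power (AUC above
#' the conventional 0.7 bar) while shedding redundant detail.
#'
#' @param lulc Fine-scale `lulc_map`.
#' @param drivers Fine-scale raw `driver_stack`.
#' @param factors Integer aggregation factors (e.g. 2:5 for 60-150 m from
#'   30 m).
#' @return Data frame (factor, cellsize, class_code, auc), sorted by scale;
#'   `auc` is NA for a class that vanished at that scale.
#' @export
scale_selection <- function(lulc, drivers, factors = 2:5) {
  res <- list()
  for (f in sort(factors)) {
    map_f <- resample_categorical(lulc, f)
    drv_f <- new_driver_stack(lapply(unclass(drivers), resample_continuous,
                                     factor = f))
    std <- standardize_drivers(drv_f)
    for (k in seq_len(N_CLASSES)) {
      auc <- tryCatch({
        fit <- fit_binary_logistic(map_f, k, std$drivers)
        X <- driver_matrix(std$drivers)[, names(fit$coefficients), drop = FALSE]
        eta <- fit$intercept + as.vector(X %*% fit$coefficients)
        y <- as.vector(map_f$values) == k
        keep <- !is.na(as.vector(map_f$values)) & stats::complete.cases(X)
        roc_auc(eta[keep], y[keep])
      }, error = function(e) NA_real_)
      res[[length(res) + 1]] <- data.frame(
        factor = f, cellsize = lulc$cellsize * f, class_code = k, auc = auc)
    }
  }
  do.call(rbind, res)
}

#' Serialize a suitability model to JSON
#' @param model A `suitability_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_suitability_model <- function(model, path) {
  doc <- list(
    classes = lapply(model$models, function(m) list(
      class_code = m$class_code, intercept = m$intercept,
      coefficients = as.list(m$coefficients),
      converged = m$converged, separation = m$separation)),
    standardization = list(driver = model$standardization$driver,
                           mean = model$standardization$mean,
                           sd = model$standardization$sd))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a suitability model from JSON
#' @param path Path written by [write_suitability_model()].
#' @return A `suitability_model`.
#' @export
read_suitability_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  models <- lapply(doc$classes, function(m) list(
    class_code = as.integer(m$class_code),
    intercept = as.numeric(m$intercept),
    coefficients = unlist(m$coefficients),
    converged = isTRUE(m$converged),
    separation = isTRUE(m$separation)))
  std <- data.frame(driver = unlist(doc$standardization$driver),
                    mean = unlist(doc$standardization$mean),
                    sd = unlist(doc$standardization$sd))
  structure(list(models = models, standardization = std,
                 codebook = lulc_codebook()),
            class = "suitability_model")
}
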