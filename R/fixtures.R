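#' Packaged case-study tables for the Weishan mining region
#'
#' Loads the plain-text fixture tables shipped with the package: the 2025
#' scenario demand endpoints (`"demand"`), the per-scenario signed area
#' changes and single dynamic degrees (`"change"`), the published logistic
#' regression coefficients (`"coefficients"`), the per-scenario conversion
#' elasticities (`"elasticities"`) and the collinearity diagnostics
#' (`"collinearity"`).
#'
#' @param name One of "demand", "change", "coefficients", "elasticities",
#'   "collinearity".
#' @return A data frame.
#' @export
weishan_table <- function(name = c("demand", "change", "coefficients",
                                   "elasticities", "collinearity")) {
  name <- match.arg(name)
  file <- c(demand = "weishan_demand_2025.csv",
            change = "weishan_change_2025.csv",
            coefficients = "weishan_coefficients.csv",
            elasticities = "weishan_elasticities.csv",
            collinearity = "weishan_collinearity.csv")[[name]]
  path <- system.file("extdata", file, package = "lulcsim")
  if (path == "") stop("fixture '", file, "' not found; is the package installed?")
  utils::read.csv(path, comment.char = "#")
}

#' 2025 demand endpoint of one scenario as an area vector
#' @param scenario One of "natural", "ecological", "farmland".
#' @return Named numeric vector of 6 areas (ha).
#' @export
weishan_demand_2025 <- function(scenario = c("natural", "ecological", "farmland")) {
  scenario <- match.arg(scenario)
  df <- weishan_table("demand")
  df <- df[df$scenario == scenario, ]
  stats::setNames(df$area_ha[order(df$class_code)],
                  as.character(sort(df$class_code)))
}

#' Implied 2016 start areas of one scenario
#'
#' The case-study tables print only the 2025 endpoint areas and the signed
#' 2017-2025 changes; the start areas are recovered as endpoint minus change.
#'
#' @inheritParams weishan_demand_2025
#' @return Named numeric vector of 6 areas (ha).
#' @export
weishan_start_areas <- function(scenario = c("natural", "ecological", "farmland")) {
  scenario <- match.arg(scenario)
  end <- weishan_demand_2025(scenario)
  ch <- weishan_table("change")
  ch <- ch[ch$scenario == scenario, ]
  end - stats::setNames(ch$area_change_ha[order(ch$class_code)], NULL)
}

#' ELAS vector of one scenario
#' @inheritParams weishan_demand_2025
#' @return Numeric vector of 6 elasticities in \[0, 1\].
#' @export
weishan_elas <- function(scenario = c("natural", "ecological", "farmland")) {
  scenario <- match.arg(scenario)
  df <- weishan_table("elasticities")
  df <- df[df$scenario == scenario, ]
  df$elas[order(df$class_code)]
}

#' Suitability model built from the published coefficient table
#'
#' Assembles a `suitability_model` from the packaged coefficient fixture so
#' case-study-parameterised runs need no refitting. Excluded cells
#' (structural zeros) carry no coefficient. The model expects drivers that
#' are already standardized (its stored standardization is the identity).
#'
#' @return A `suitability_model`.
#' @export
weishan_suitability_model <- function() {
  df <- weishan_table("coefficients")
  models <- lapply(seq_len(N_CLASSES), function(k) {
    rows <- df[df$class_code == k & df$included == 1, ]
    b0 <- rows$beta[rows$driver == "constant"]
    rows <- rows[rows$driver != "constant", ]
    list(class_code = k, intercept = b0,
         coefficients = stats::setNames(rows$beta, rows$driver),
         converged = TRUE, separation = FALSE)
  })
  std <- data.frame(driver = driver_names(), mean = 0, sd = 1)
  structure(list(models = models, standardization = std,
                 codebook = lulc_codebook()),
            class = "suitability_model")
}
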