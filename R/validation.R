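#' Kappa index with a uniform-chance baseline
#'
#' kappa = (Po - Pc) / (Pp - Pc) with Pc = 1/n, the chance proportion correct
#' for n equiprobable classes, and Pp the proportion correct under perfect
#' classification (1 unless a ceiling applies).
#'
#' @param po Observed proportion correct in \[0, 1\].
#' @param n Number of classes (>= 2).
#' @param pp Perfect proportion (default 1); must exceed 1/n.
#' @return Kappa.
#' @export
kappa_index <- function(po, n = 6, pp = 1) {
  if (any(po < 0 | po > 1)) stop("po must lie in [0,1]")
  if (n < 2) stop("n must be >= 2")
  pc <- 1 / n
  if (pp <= pc) stop("pp must exceed the chance proportion 1/n")
  (po - pc) / (pp - pc)
}

#' Cohen's kappa from a confusion matrix (marginal-product chance)
#' @param confusion Square count matrix.
#' @return Kappa with the expected agreement computed from the marginals.
#' @export
cohen_kappa <- function(confusion) {
  total <- sum(confusion)
  po <- sum(diag(confusion)) / total
  pe <- sum(rowSums(confusion) * colSums(confusion)) / total^2
  (po - pe) / (1 - pe)
}

#' Kappa for quantity
#'
#' Agreement in class quantities (area proportions) irrespective of location,
#' rescaled against the uniform chance level: Kq = (Aq - 1/n) / (1 - 1/n)
#' with Aq = 1 - 0.5 * sum |p_u - q_u| over the class proportions of the two
#' maps.
#'
#' @param actual_areas,simulated_areas Nonnegative class-area vectors (ha)
#'   with equal totals (within 0.5 ha).
#' @return Kquantity.
#' @export
kappa_quantity <- function(actual_areas, simulated_areas) {
  a <- as.numeric(actual_areas); s <- as.numeric(simulated_areas)
  if (any(a < 0) || any(s < 0)) stop("areas must be nonnegative")
  if (sum(a) == 0 || sum(s) == 0) stop("zero total area")
  if (abs(sum(a) - sum(s)) > 0.5)
    stop("area totals differ by more than 0.5 ha")
  n <- length(a)
  aq <- 1 - 0.5 * sum(abs(a / sum(a) - s / sum(s)))
  (aq - 1 / n) / (1 - 1 / n)
}

#' Full map-agreement report
#'
#' Confusion matrix (rows = simulated, columns = actual), overall proportion
#' correct, the uniform-chance kappa, Cohen's kappa, kappa-for-quantity and
#' per-class producer/user accuracies (percent).
#'
#' @param actual,simulated Aligned `lulc_map`s.
#' @return Object of class `validation_report`.
#' @export
accuracy_report <- function(actual, simulated) {
  stop_if_geometry_mismatch(actual, simulated)
  confusion <- cross_tabulate(simulated, actual)   # rows = simulated
  total <- sum(confusion)
  if (total == 0) stop("no jointly valid cells")
  po <- sum(diag(confusion)) / total
  producer <- ifelse(colSums(confusion) > 0,
                     100 * diag(confusion) / colSums(confusion), NA_real_)
  user <- ifelse(rowSums(confusion) > 0,
                 100 * diag(confusion) / rowSums(confusion), NA_real_)
  structure(list(
    confusion = confusion,
    n_cells = total,
    po = po, pc = 1 / N_CLASSES, pp = 1,
    kappa = kappa_index(po, N_CLASSES, 1),
    cohen_kappa = cohen_kappa(confusion),
    kquantity = kappa_quantity(class_areas(actual), class_areas(simulated)),
    producer_accuracy = producer,
    user_accuracy = user
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat(sprintf("  Po %.3f | kappa %.3f | Cohen %.3f | Kquantity %.3f | n = %d\n",
              x$po, x$kappa, x$cohen_kappa, x$kquantity, x$n_cells))
  cb <- lulc_codebook()
  for (k in seq_len(N_CLASSES))
    cat(sprintf("  %-33s producer %6.2f%%  user %6.2f%%\n",
                cb[[k]], x$producer_accuracy[k], x$user_accuracy[k]))
  invisible(x)
}

#' Write a validation report as JSON
#' @param report A `validation_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_validation_report <- function(report, path) {
  doc <- list(confusion = unclass(report$confusion),
              n_cells = report$n_cells,
              po = report$po, pc = report$pc, pp = report$pp,
              kappa = round(report$kappa, 3),
              cohen_kappa = round(report$cohen_kappa, 3),
              kquantity = round(report$kquantity, 3),
              producer_accuracy = round(report$producer_accuracy, 2),
              user_accuracy = round(report$user_accuracy, 2))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Per-class change accounting between two maps
#'
#' Signed per-class area change (ha), the single land-use dynamic degree
#' (percent per year), and a per-cell change raster coding each (from, to)
#' pair as `10 * from + to`.
#'
#' @param map_t0,map_t1 Aligned `lulc_map`s.
#' @param span_years Span of the comparison in years (> 0).
#' @return Object of class `change_report`: data frame `changes` (class_code,
#'   class_name, start_area_ha, end_area_ha, area_change_ha,
#'   dynamic_degree_pct) plus `change_raster`.
#' @export
change_report <- function(map_t0, map_t1, span_years) {
  stop_if_geometry_mismatch(map_t0, map_t1)
  if (span_years <= 0) stop("span_years must be positive")
  a0 <- class_areas(map_t0); a1 <- class_areas(map_t1)
  change <- a1 - a0
  dyn <- ifelse(a0 > 0, dynamic_degree(change, pmax(a0, 1e-12), span_years),
                NA_real_)
  cb <- lulc_codebook()
  changes <- data.frame(class_code = seq_len(N_CLASSES),
                        class_name = unname(cb),
                        start_area_ha = unname(a0), end_area_ha = unname(a1),
                        area_change_ha = unname(change),
                        dynamic_degree_pct = unname(dyn))
  raster <- map_t0
  raster$values <- 10 * map_t0$values + map_t1$values
  class(raster) <- "lulc_grid"
  structure(list(changes = changes, change_raster = raster,
                 span_years = span_years),
            class = "change_report")
}

#' @export
print.change_report <- function(x, ...) {
  cat(sprintf("<change_report> span %g year(s)\n", x$span_years))
  df <- x$changes
  df$area_change_ha <- round(df$area_change_ha, 2)
  df$dynamic_degree_pct <- round(df$dynamic_degree_pct, 2)
  print(df[, c("class_name", "area_change_ha", "dynamic_degree_pct")],
        row.names = FALSE)
  invisible(x)
}
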