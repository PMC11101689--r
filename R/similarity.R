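#' Dice similarity coefficient
#'
#' `DSC = 2|A ∩ B| / (|A| + |B|)` on voxel counts: 0 means no overlap, 1 means
#' identical occupancy.
#'
#' @param a,b [structure_mask()]s on the same geometry, not both empty.
#' @return Coefficient in \[0, 1\].
#' @export
dice <- function(a, b) {
  check_same_geometry(a$geometry, b$geometry, "masks")
  na <- sum(a$occupancy); nb <- sum(b$occupancy)
  if (na + nb == 0) abort("Dice of two empty masks is undefined", class = "planqa_empty_mask")
  2 * sum(a$occupancy & b$occupancy) / (na + nb)
}

#' Directed surface-to-surface distances
#'
#' For every surface voxel of `a`, the Euclidean distance (mm, anisotropic
#' spacing honored) to the nearest surface voxel of `b`. These directed
#' distance lists are the raw material of the (percentile) Hausdorff
#' distances. Distances are between boundary voxel centers ("outer surface
#' points"), computed exactly via the distance transform of the target
#' surface.
#'
#' @param a,b Non-empty [structure_mask()]s on the same geometry.
#' @return Numeric vector of mm distances, one per surface voxel of `a`.
#' @export
directed_surface_distances <- function(a, b) {
  check_same_geometry(a$geometry, b$geometry, "masks")
  if (!any(a$occupancy) || !any(b$occupancy)) {
    abort("surface distances require two non-empty masks", class = "planqa_empty_mask")
  }
  surf_a <- surface_occupancy(a$occupancy)
  surf_b <- surface_occupancy(b$occupancy)
  d2 <- edt_sq(surf_b, a$geometry)
  sqrt(d2[surf_a])
}

#' Hausdorff distance between two contours
#'
#' `HD(A, B) = max(h(A, B), h(B, A))`: the maximum Euclidean distance between
#' closest outer surface points of the two contours, symmetric by
#' construction. `hausdorff_percentile()` is the outlier-robust variant that
#' replaces each directed maximum by the `p`-th percentile of the directed
#' distances (default 95, linear interpolation between order statistics);
#' by default the two directed percentiles are combined with `max`, with the
#' pooled-distances convention available as an option.
#'
#' @param a,b Non-empty [structure_mask()]s on the same geometry.
#' @return Distance in mm.
#' @export
hausdorff <- function(a, b) {
  max(max(directed_surface_distances(a, b)),
      max(directed_surface_distances(b, a)))
}

#' @rdname hausdorff
#' @param p Percentile in (0, 100\].
#' @param symmetrize `"max"` (max of the two directed percentiles, default) or
#'   `"pooled"` (percentile of the pooled directed distances).
#' @export
hausdorff_percentile <- function(a, b, p = 95, symmetrize = c("max", "pooled")) {
  symmetrize <- match.arg(symmetrize)
  if (!is.finite(p) || p <= 0 || p > 100) {
    abort("`p` must be in (0, 100]", class = "planqa_parameter_error")
  }
  dab <- directed_surface_distances(a, b)
  dba <- directed_surface_distances(b, a)
  if (symmetrize == "max") {
    max(quantile(dab, p / 100, names = FALSE, type = 7),
        quantile(dba, p / 100, names = FALSE, type = 7))
  } else {
    quantile(c(dab, dba), p / 100, names = FALSE, type = 7)
  }
}

#' Contour-similarity report between two structure sets
#'
#' Compares every structure of a submitted set with its namesake in the
#' reference set (case-insensitive TG-263 name matching) using DSC, HD and
#' HD95, plus both volumes. Structures present in only one set, or empty in
#' either, are flagged not-evaluable rather than dropped.
#'
#' @param reference,submitted [structure_set()]s on a shared geometry.
#' @param structures Structure names to compare; defaults to the union of
#'   both sets' names.
#' @param p Percentile for the robust Hausdorff variant.
#' @return A `similarity_report`; `tidy()` yields the per-structure tibble
#'   with columns `structure`, `dsc`, `hd_mm`, `hd95_mm`, `volume_ref_cc`,
#'   `volume_sub_cc`, `evaluable`.
#' @export
compare_structure_sets <- function(reference, submitted,
                                   structures = NULL, p = 95) {
  check_same_geometry(reference$geometry, submitted$geometry, "structure sets")
  if (is.null(structures)) {
    structures <- union(names(reference$masks), names(submitted$masks))
  }
  common <- structures[vapply(structures, function(nm) {
    has_structure(reference, nm) && has_structure(submitted, nm)
  }, logical(1))]
  if (length(common) == 0) {
    abort("no common structures between the two sets", class = "planqa_missing_structure")
  }
  rows <- purrr::map_dfr(structures, function(nm) {
    in_ref <- has_structure(reference, nm)
    in_sub <- has_structure(submitted, nm)
    ref_m <- if (in_ref) get_structure(reference, nm) else NULL
    sub_m <- if (in_sub) get_structure(submitted, nm) else NULL
    evaluable <- in_ref && in_sub && any(ref_m$occupancy) && any(sub_m$occupancy)
    tibble::tibble(
      structure = nm,
      dsc = if (evaluable) dice(ref_m, sub_m) else NA_real_,
      hd_mm = if (evaluable) hausdorff(ref_m, sub_m) else NA_real_,
      hd95_mm = if (evaluable) hausdorff_percentile(ref_m, sub_m, p) else NA_real_,
      volume_ref_cc = if (in_ref) volume_cc(ref_m) else NA_real_,
      volume_sub_cc = if (in_sub) volume_cc(sub_m) else NA_real_,
      evaluable = evaluable
    )
  })
  structure(list(table = rows, percentile = p), class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat("<similarity_report> DSC / HD / HD", x$percentile, "\n", sep = "")
  print(x$table, n = Inf)
  invisible(x)
}

#' @describeIn compare_structure_sets Per-structure similarity tibble.
#' @param x A `similarity_report`.
#' @param ... Unused.
#' @export
tidy.similarity_report <- function(x, ...) x$table

#' @describeIn compare_structure_sets One-row summary (medians over evaluable
#'   structures).
#' @export
glance.similarity_report <- function(x, ...) {
  t <- dplyr::filter(x$table, .data$evaluable)
  tibble::tibble(
    n_structures = nrow(x$table),
    n_evaluable = nrow(t),
    median_dsc = median(t$dsc),
    median_hd_mm = median(t$hd_mm),
    median_hd95_mm = median(t$hd95_mm)
  )
}

#' @describeIn compare_structure_sets Faceted per-structure metric chart.
#' @param object A `similarity_report`.
#' @export
autoplot.similarity_report <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::filter(object$table, .data$evaluable),
    cols = c("dsc", "hd_mm", "hd95_mm"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$structure, .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
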