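#' Cumulative dose-volume histogram
#'
#' Bins the in-mask voxel doses into a uniform-width histogram and accumulates
#' it into the cumulative DVH: for each bin edge `d`, the absolute volume (cc)
#' receiving at least `d` Gy. The curve starts at the total structure volume
#' at 0 Gy and reaches 0 beyond the maximum dose. The raw sorted voxel doses
#' are kept alongside the binned curve so every metric is also computable
#' bin-free (`method = "exact"`), which removes binning as a hidden tolerance.
#'
#' @param dose A [dose_grid()].
#' @param mask A non-empty [structure_mask()] on the same geometry.
#' @param bin_width Bin width in Gy, default 0.1.
#' @return A `dvh_curve` object.
#' @export
#' @examples
#' geom <- grid_geometry(spacing = c(2, 2, 2), shape = c(10, 10, 10))
#' m <- structure_mask("ROI", geom, array(TRUE, geom$shape), "oar")
#' d <- dose_grid(geom, array(runif(1000, 0, 60), geom$shape))
#' dvh <- cumulative_dvh(d, m)
#' dose_at_relative_volume(dvh, 98)
cumulative_dvh <- function(dose, mask, bin_width = 0.1) {
  check_same_geometry(dose$geometry, mask$geometry, "dose grid and mask")
  if (!any(mask$occupancy)) abort("DVH of an empty mask is undefined", class = "planqa_empty_mask")
  if (!is.finite(bin_width) || bin_width <= 0) {
    abort("`bin_width` must be > 0", class = "planqa_parameter_error")
  }
  vv <- voxel_volume_cc(dose$geometry)
  doses <- sort(dose$dose[mask$occupancy])
  n <- length(doses)
  edges <- seq(0, (ceiling(max(doses) / bin_width) + 1) * bin_width, by = bin_width)
  # volume receiving >= edge: count of doses >= edge
  n_below <- findInterval(edges, doses, left.open = TRUE)  # doses < edge
  vol <- (n - n_below) * vv
  structure(
    list(structure = mask$name, bin_edges = edges, volume_cc = vol,
         total_cc = n * vv, bin_width = bin_width, voxel_doses = doses,
         voxel_volume_cc = vv),
    class = "dvh_curve"
  )
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve> %s: %.2f cc, dose 0-%.1f Gy, bin %.2g Gy\n",
              x$structure, x$total_cc, max(x$bin_edges), x$bin_width))
  invisible(x)
}

#' @describeIn cumulative_dvh Curve as a tibble with `dose_gy`, `volume_cc`,
#'   `volume_pct` columns.
#' @param x A `dvh_curve`.
#' @param ... Unused.
#' @export
tidy.dvh_curve <- function(x, ...) {
  tibble::tibble(
    structure = x$structure,
    dose_gy = x$bin_edges,
    volume_cc = x$volume_cc,
    volume_pct = 100 * x$volume_cc / x$total_cc
  )
}

#' @describeIn cumulative_dvh Cumulative-DVH line plot.
#' @param object A `dvh_curve`.
#' @export
autoplot.dvh_curve <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$dose_gy, .data$volume_pct)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::labs(x = "Dose [Gy]", y = "Volume [%]", title = object$structure) +
    ggplot2::theme_minimal()
}

# Dose at which the cumulative (absolute-volume) curve falls below
# `target_cc`: largest bin edge still covering the target volume, linearly
# interpolated into the crossing bin.
interp_dose_at_volume <- function(edges, vol, target_cc) {
  covered <- which(vol >= target_cc - 1e-12)
  if (length(covered) == 0) return(edges[1])
  j <- max(covered)
  if (j == length(vol)) return(edges[j])
  v1 <- vol[j]; v2 <- vol[j + 1]
  if (v1 <= v2) return(edges[j + 1])
  edges[j] + (edges[j + 1] - edges[j]) * (v1 - target_cc) / (v1 - v2)
}

# Bin-free path: exact voxel-count semantics. The dose received by at least
# `target_cc` of the structure is the k-th hottest voxel dose with
# k = ceiling(target_cc / voxel volume).
exact_dose_at_volume <- function(doses_sorted_asc, vv, target_cc) {
  n <- length(doses_sorted_asc)
  k <- ceiling(target_cc / vv - 1e-9)
  k <- min(n, max(1, k))
  doses_sorted_asc[n - k + 1]
}

#' Dose covering a relative volume (D98, D50, D2)
#'
#' `dose_at_relative_volume(dvh, 98)` is D98 (near-minimum dose), `..., 2` is
#' D2 (near-maximum), `..., 50` the median dose: the dose received by at least
#' `percent` % of the structure volume, linearly interpolated.
#'
#' @param dvh A [cumulative_dvh()] result.
#' @param percent Relative volume in (0, 100].
#' @param method `"bins"` interpolates the binned curve; `"exact"` uses the
#'   sorted voxel doses directly.
#' @return Dose in Gy.
#' @export
dose_at_relative_volume <- function(dvh, percent, method = c("bins", "exact")) {
  method <- match.arg(method)
  if (!is.finite(percent) || percent <= 0 || percent > 100) {
    abort("`percent` must be in (0, 100]", class = "planqa_parameter_error")
  }
  target_cc <- dvh$total_cc * percent / 100
  if (method == "bins") interp_dose_at_volume(dvh$bin_edges, dvh$volume_cc, target_cc)
  else exact_dose_at_volume(dvh$voxel_doses, dvh$voxel_volume_cc, target_cc)
}

#' Dose to the hottest absolute volume (D0.03cc)
#'
#' The dose received by the hottest `cc` cubic centimeters of the structure —
#' the near-maximum point-dose metric used for serial organs such as the
#' brainstem (D0.03 cc).
#'
#' @inheritParams dose_at_relative_volume
#' @param cc Absolute volume in cc, 0 < cc <= total structure volume.
#' @return Dose in Gy.
#' @export
dose_at_absolute_volume <- function(dvh, cc, method = c("bins", "exact")) {
  method <- match.arg(method)
  if (!is.finite(cc) || cc <= 0) abort("`cc` must be > 0", class = "planqa_parameter_error")
  if (cc > dvh$total_cc + 1e-9) {
    abort("`cc` exceeds the structure volume", class = "planqa_parameter_error")
  }
  if (method == "bins") interp_dose_at_volume(dvh$bin_edges, dvh$volume_cc, cc)
  else exact_dose_at_volume(dvh$voxel_doses, dvh$voxel_volume_cc, cc)
}

#' Volume receiving at least a threshold dose (V40, V45)
#'
#' @param dose A [dose_grid()].
#' @param mask A [structure_mask()] on the same geometry.
#' @param threshold Threshold dose in Gy, >= 0.
#' @return Absolute volume in cc with dose >= `threshold`.
#' @export
volume_at_dose <- function(dose, mask, threshold) {
  check_same_geometry(dose$geometry, mask$geometry, "dose grid and mask")
  if (!is.finite(threshold) || threshold < 0) {
    abort("`threshold` must be >= 0", class = "planqa_parameter_error")
  }
  sum(dose$dose[mask$occupancy] >= threshold) * voxel_volume_cc(dose$geometry)
}

#' Mean structure dose
#'
#' @inheritParams volume_at_dose
#' @return Arithmetic mean of the in-mask voxel doses, Gy.
#' @export
mean_dose <- function(dose, mask) {
  check_same_geometry(dose$geometry, mask$geometry, "dose grid and mask")
  if (!any(mask$occupancy)) abort("mean dose of an empty mask is undefined",
                                  class = "planqa_empty_mask")
  mean(dose$dose[mask$occupancy])
}

#' Plan metric table
#'
#' Evaluates a standard panel of DVH metrics for a set of structures of one
#' plan bundle, mirroring the per-structure metric tables of a trial QA
#' report.
#'
#' @param bundle A [plan_bundle()].
#' @param structures Character vector of structure names; defaults to all.
#' @param metrics Character vector of metric specs, e.g.
#'   `c("D98%", "D50%", "D2%", "D0.03cc", "Dmean", "Dmax", "V40Gy", "V45Gy")`.
#' @param bin_width DVH bin width in Gy.
#' @return A tibble with columns `structure`, `metric`, `value`, `unit`.
#' @export
dvh_metric_table <- function(bundle,
                             structures = names(bundle$structures$masks),
                             metrics = c("D98%", "D50%", "D2%", "D0.03cc",
                                         "Dmean", "Dmax", "V40Gy", "V45Gy"),
                             bin_width = 0.1) {
  rows <- purrr::map(structures, function(nm) {
    mask <- get_structure(bundle$structures, nm)
    if (!any(mask$occupancy)) {
      return(tibble::tibble(structure = nm, metric = metrics,
                            value = NA_real_,
                            unit = ifelse(grepl("^V", metrics), "cc", "Gy")))
    }
    dvh <- cumulative_dvh(bundle$dose, mask, bin_width)
    purrr::map_dfr(metrics, function(m) {
      spec <- parse_metric_spec(m)
      val <- evaluate_metric_spec(spec, bundle$dose, mask, dvh)
      tibble::tibble(structure = nm, metric = m, value = val,
                     unit = if (spec$kind == "V") "cc" else "Gy")
    })
  })
  dplyr::bind_rows(rows)
}

# Parse "D98%", "D0.03cc", "Dmean", "Dmax", "V40Gy" into a structured spec.
parse_metric_spec <- function(spec) {
  s <- trimws(spec)
  if (grepl("^[Dd]mean$", s)) return(list(kind = "Dmean"))
  if (grepl("^[Dd]max$", s)) return(list(kind = "Dmax"))
  m <- regmatches(s, regexec("^[Dd]([0-9.]+)%$", s))[[1]]
  if (length(m) == 2) {
    p <- as.numeric(m[2])
    if (!is.finite(p) || p <= 0 || p > 100) {
      abort(paste0("invalid relative-volume metric: ", spec), class = "planqa_parameter_error")
    }
    return(list(kind = "Dpct", percent = p))
  }
  m <- regmatches(s, regexec("^[Dd]([0-9.]+)cc$", s))[[1]]
  if (length(m) == 2) {
    v <- as.numeric(m[2])
    if (!is.finite(v) || v <= 0) {
      abort(paste0("invalid absolute-volume metric: ", spec), class = "planqa_parameter_error")
    }
    return(list(kind = "Dcc", cc = v))
  }
  m <- regmatches(s, regexec("^[Vv]([0-9.]+)(Gy)?$", s))[[1]]
  if (length(m) >= 2 && nzchar(m[2])) {
    d <- as.numeric(m[2])
    if (!is.finite(d) || d < 0) {
      abort(paste0("invalid volume-at-dose metric: ", spec), class = "planqa_parameter_error")
    }
    return(list(kind = "V", threshold = d))
  }
  abort(paste0("unknown metric spec: '", spec,
               "' (expected D{p}%, D{v}cc, Dmean, Dmax or V{d}Gy)"),
        class = "planqa_parameter_error")
}

# Metric dispatch for tables and scorecards; uses the voxel-exact DVH path
# so values at protocol bounds are not smeared by binning.
evaluate_metric_spec <- function(spec, dose, mask, dvh = NULL) {
  if (is.null(dvh) && spec$kind %in% c("Dpct", "Dcc")) dvh <- cumulative_dvh(dose, mask)
  switch(spec$kind,
    Dmean = mean_dose(dose, mask),
    Dmax = max(dose$dose[mask$occupancy]),
    Dpct = dose_at_relative_volume(dvh, spec$percent, method = "exact"),
    Dcc = {
      if (spec$cc > dvh$total_cc + 1e-9) NA_real_
      else dose_at_absolute_volume(dvh, spec$cc, method = "exact")
    },
    V = volume_at_dose(dose, mask, spec$threshold)
  )
}
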