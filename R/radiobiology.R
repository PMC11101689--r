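#' Radiobiological model parameters
#'
#' Parameters of the EUD-based logistic NTCP model for brain radionecrosis:
#' the volume-effect parameter `a` of the generalized-mean EUD (a = 1 gives
#' the mean dose, a -> Inf the maximum dose; the serial-behaviour default is
#' 9), the logistic midpoint `td50` (EUD at which the complication probability
#' is 50%, default 55.5 Gy), the logistic slope exponent (default 10), the
#' late-reacting brain alpha/beta ratio for fractionation conversion (default
#' 2 Gy) and the fractionation the model is referenced to (default 30
#' fractions, matching both the 60 Gy standard and 75 Gy escalated plan).
#'
#' @param a Volume-effect parameter, >= 1.
#' @param td50 Gy; EUD of 50% complication probability, > 0.
#' @param slope_exponent Dimensionless logistic steepness, > 0.
#' @param alpha_beta Gy; alpha/beta ratio for isoeffect conversion, > 0.
#' @param target_fractions Fraction count the model expects, >= 1.
#' @return A `radiobiology_params` object.
#' @export
radiobiology_params <- function(a = 9, td50 = 55.5, slope_exponent = 10,
                                alpha_beta = 2, target_fractions = 30L) {
  if (a < 1) abort("`a` must be >= 1", class = "planqa_parameter_error")
  if (td50 <= 0) abort("`td50` must be > 0", class = "planqa_parameter_error")
  if (slope_exponent <= 0) abort("`slope_exponent` must be > 0", class = "planqa_parameter_error")
  if (alpha_beta <= 0) abort("`alpha_beta` must be > 0", class = "planqa_parameter_error")
  if (target_fractions < 1) abort("`target_fractions` must be >= 1", class = "planqa_parameter_error")
  structure(
    list(a = a, td50 = td50, slope_exponent = slope_exponent,
         alpha_beta = alpha_beta, target_fractions = as.integer(target_fractions)),
    class = "radiobiology_params"
  )
}

#' @export
print.radiobiology_params <- function(x, ...) {
  cat(sprintf("<radiobiology_params> a=%g, TD50=%g Gy, slope=%g, a/b=%g Gy, %d fx\n",
              x$a, x$td50, x$slope_exponent, x$alpha_beta, x$target_fractions))
  invisible(x)
}

#' Isoeffective dose at a different fractionation
#'
#' Converts a per-voxel physical dose delivered in `n_s` fractions into the
#' equieffective dose delivered in `target_fractions`, using the
#' linear-quadratic isoeffect relation
#' `D'(1 + D'/(n_t * alpha/beta)) = D(1 + D/(n_s * alpha/beta))`
#' solved per voxel by its positive root. When source and target fraction
#' numbers agree — as for the two 30-fraction trial plans — the conversion is
#' the identity.
#'
#' @param dose A [dose_grid()] (its `n_fractions` is the source schedule).
#' @param params A [radiobiology_params()].
#' @param target_fractions Target fraction count; defaults to
#'   `params$target_fractions`.
#' @return A [dose_grid()] with converted doses and `n_fractions` set to the
#'   target.
#' @export
equieffective_dose <- function(dose, params = radiobiology_params(),
                               target_fractions = params$target_fractions) {
  if (params$alpha_beta <= 0) abort("`alpha_beta` must be > 0", class = "planqa_parameter_error")
  n_s <- dose$n_fractions
  n_t <- as.integer(target_fractions)
  if (n_t < 1) abort("`target_fractions` must be >= 1", class = "planqa_parameter_error")
  if (n_s == n_t) return(dose)
  ab <- params$alpha_beta
  bed <- dose$dose * (1 + dose$dose / (n_s * ab))
  conv <- (n_t * ab / 2) * (sqrt(1 + 4 * bed / (n_t * ab)) - 1)
  dose_grid(dose$geometry, conv, n_fractions = n_t, plan_label = dose$plan_label)
}

#' Equivalent uniform dose (EUD)
#'
#' The generalized power mean of order `a` over the in-mask voxel doses:
#' `EUD = (sum_i v_i * D_i^a)^(1/a)` with equal fractional voxel volumes
#' `v_i`. Equals the mean dose at `a = 1` and approaches the maximum dose as
#' `a` grows. The voxel-exact path is the default; `eud_from_dvh()` evaluates
#' the same quantity from a binned DVH's partial volumes for cross-checks.
#'
#' @param dose A [dose_grid()].
#' @param mask A non-empty [structure_mask()] on the same geometry.
#' @param a Volume-effect parameter, >= 1.
#' @return EUD in Gy.
#' @export
eud <- function(dose, mask, a = 9) {
  check_same_geometry(dose$geometry, mask$geometry, "dose grid and mask")
  if (!any(mask$occupancy)) abort("EUD of an empty mask is undefined", class = "planqa_empty_mask")
  if (a < 1) abort("`a` must be >= 1", class = "planqa_parameter_error")
  d <- dose$dose[mask$occupancy]
  generalized_mean(d, a)
}

# Power mean computed in log space for numerical stability at large `a`.
generalized_mean <- function(d, a) {
  if (all(d == 0)) return(0)
  dmax <- max(d)
  mean((d / dmax)^a)^(1 / a) * dmax
}

#' @rdname eud
#' @param dvh A [cumulative_dvh()] result.
#' @export
eud_from_dvh <- function(dvh, a = 9) {
  if (a < 1) abort("`a` must be >= 1", class = "planqa_parameter_error")
  # differential partial volumes per bin, midpoint dose
  vol <- dvh$volume_cc
  edges <- dvh$bin_edges
  dv <- vol[-length(vol)] - vol[-1]
  mid <- (edges[-length(edges)] + edges[-1]) / 2
  vi <- dv / dvh$total_cc
  keep <- vi > 0
  generalized_mean_weighted(mid[keep], vi[keep], a)
}

generalized_mean_weighted <- function(d, w, a) {
  if (length(d) == 0 || all(d == 0)) return(0)
  dmax <- max(d)
  (sum(w * (d / dmax)^a) / sum(w))^(1 / a) * dmax
}

#' Normal tissue complication probability (NTCP)
#'
#' Logistic dose-response in the brain EUD:
#' `NTCP = 1 / (1 + (TD50 / EUD)^k)` with `TD50 = 55.5` Gy and slope exponent
#' `k = 10` by default. Strictly increasing in EUD, equal to 0.5 at
#' `EUD = TD50`.
#'
#' @param eud_gy EUD in Gy, > 0 (vectorized).
#' @param params A [radiobiology_params()].
#' @return Complication probability in \[0, 1).
#' @export
#' @examples
#' ntcp(55.5)       # 0.5 at TD50
#' round(ntcp(49.0), 2)
ntcp <- function(eud_gy, params = radiobiology_params()) {
  if (any(!is.finite(eud_gy)) || any(eud_gy <= 0)) {
    abort("`eud_gy` must be > 0", class = "planqa_parameter_error")
  }
  1 / (1 + (params$td50 / eud_gy)^params$slope_exponent)
}

#' NTCP ratio and logarithmic increased risk
#'
#' `ntcp_ratio()` is the plain quotient `NTCP_ex / NTCP_ref`: 1, 2 or 3 means
#' the radionecrosis risk of the experimental plan is the same as, double or
#' triple that of the reference plan. `increased_risk()` is the sharper
#' log-survival comparison `IR = ln(1 - NTCP_ex) / ln(1 - NTCP_ref)`; both
#' equal 1 for identical risks, and IR tends to the plain ratio as both NTCPs
#' tend to 0.
#'
#' @param ntcp_ex,ntcp_ref Complication probabilities of the experimental and
#'   reference plan.
#' @return Dimensionless risk multiplier, >= 0.
#' @export
ntcp_ratio <- function(ntcp_ex, ntcp_ref) {
  if (any(ntcp_ref <= 0)) abort("reference NTCP must be > 0", class = "planqa_parameter_error")
  ntcp_ex / ntcp_ref
}

#' @rdname ntcp_ratio
#' @export
increased_risk <- function(ntcp_ex, ntcp_ref) {
  if (any(ntcp_ex <= 0 | ntcp_ex >= 1) || any(ntcp_ref <= 0 | ntcp_ref >= 1)) {
    abort("NTCP values must lie strictly between 0 and 1", class = "planqa_parameter_error")
  }
  log(1 - ntcp_ex) / log(1 - ntcp_ref)
}

#' Radionecrosis-risk comparison of two plans
#'
#' Chains the full risk model for a reference/experimental plan pair: derives
#' the normal-brain NTCP structure (brain minus OAR exclusions minus GTVu) in
#' each bundle, converts doses to the model's fractionation, computes the
#' brain EUD (`a = 9`), maps it through the logistic NTCP, and reports both
#' comparison statistics.
#'
#' @param ref,ex Reference and experimental [plan_bundle()]s.
#' @param params A [radiobiology_params()].
#' @param brain_structure Name of a precomputed NTCP brain structure; if
#'   absent from a bundle it is derived via [derive_ntcp_brain_structure()].
#' @param exclusion_names Exclusions used when deriving the brain structure.
#' @return A `risk_report` object (see [tidy.risk_report()]).
#' @export
evaluate_radionecrosis_risk <- function(ref, ex, params = radiobiology_params(),
                                        brain_structure = "Brain_NTCP",
                                        exclusion_names = c("Brainstem", "OpticChiasm",
                                                            "OpticNrv_L", "OpticNrv_R",
                                                            "Pituitary", "GTVu")) {
  get_brain <- function(bundle) {
    if (has_structure(bundle$structures, brain_structure)) {
      get_structure(bundle$structures, brain_structure)
    } else {
      suppressMessages(derive_ntcp_brain_structure(
        bundle$structures, exclusion_names = exclusion_names, name = brain_structure))
    }
  }
  d_ref <- equieffective_dose(ref$dose, params)
  d_ex <- equieffective_dose(ex$dose, params)
  eud_ref <- eud(d_ref, get_brain(ref), a = params$a)
  eud_ex <- eud(d_ex, get_brain(ex), a = params$a)
  ntcp_ref <- ntcp(eud_ref, params)
  ntcp_ex <- ntcp(eud_ex, params)
  structure(
    list(eud_ref = eud_ref, eud_ex = eud_ex,
         ntcp_ref = ntcp_ref, ntcp_ex = ntcp_ex,
         ntcp_ratio = ntcp_ratio(ntcp_ex, ntcp_ref),
         ir = increased_risk(ntcp_ex, ntcp_ref),
         center_label = ex$center_label, params = params),
    class = "risk_report"
  )
}

#' @export
print.risk_report <- function(x, ...) {
  cat(sprintf(paste0("<risk_report> center '%s'\n",
                     "  EUD  ref %.1f Gy / ex %.1f Gy\n",
                     "  NTCP ref %.2f / ex %.2f  (ratio %.2f, IR %.2f)\n"),
              x$center_label, x$eud_ref, x$eud_ex,
              x$ntcp_ref, x$ntcp_ex, x$ntcp_ratio, x$ir))
  invisible(x)
}

#' Tidiers for risk reports
#'
#' `tidy()` returns one row per plan with EUD and NTCP; `glance()` returns the
#' one-row comparison summary (all six fields, full precision — rounding to
#' two decimals is a presentation concern).
#'
#' @param x A `risk_report`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.risk_report <- function(x, ...) {
  tibble::tibble(
    center = x$center_label,
    plan = c("reference", "experimental"),
    eud_gy = c(x$eud_ref, x$eud_ex),
    ntcp = c(x$ntcp_ref, x$ntcp_ex)
  )
}

#' @rdname tidy.risk_report
#' @export
glance.risk_report <- function(x, ...) {
  tibble::tibble(
    center = x$center_label,
    eud_ref = x$eud_ref, eud_ex = x$eud_ex,
    ntcp_ref = x$ntcp_ref, ntcp_ex = x$ntcp_ex,
    ntcp_ratio = x$ntcp_ratio, ir = x$ir
  )
}

#' @rdname tidy.risk_report
#' @param object A `risk_report`.
#' @export
autoplot.risk_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$plan, .data$ntcp, fill = .data$plan)) +
    ggplot2::geom_col(width = 0.6, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "NTCP",
                  title = sprintf("Radionecrosis risk (ratio %.2f, IR %.2f)",
                                  object$ntcp_ratio, object$ir)) +
    ggplot2::theme_minimal()
}
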