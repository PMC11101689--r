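#' Head-phantom configuration
#'
#' Geometry of the synthetic head phantom: a spherical brain, an ellipsoidal
#' contrast-enhancing lesion (GTV) with a partially overlapping PET-avid
#' region (BTV), the protocol margin recipe growing the unified GTV into the
#' boost and standard target volumes, and primitive organs at risk (brainstem
#' cylinder, optic nerves as thin tubes, optic chiasm and pituitary as small
#' spheres). All sizes in mm. The margin recipe defaults are illustrative —
#' real trials define theirs in the protocol manual — and are chosen so the
#' default target volumes land at a clinically plausible scale (GTVu tens of
#' cc, PTV60 a couple of hundred cc).
#'
#' @param spacing,shape,origin Grid geometry (mm / voxel counts).
#' @param brain_center,brain_radius Brain sphere, mm.
#' @param gtv_center,gtv_semiaxes Lesion ellipsoid, mm.
#' @param btv_center,btv_semiaxes PET-avid ellipsoid, mm.
#' @param gtv_to_ptv75 Margin GTVu -> PTV75, mm.
#' @param ptv75_to_ptv60 Margin PTV75 -> PTV60ex, mm.
#' @param gtvu_to_ptv60 Margin GTVu -> PTV60 (standard plan), mm.
#' @param oars Named list of OAR primitive specs (see defaults).
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(spacing = c(2, 2, 2), shape = c(96, 96, 96),
                           origin = c(0, 0, 0),
                           brain_center = (shape - 1) * spacing / 2,
                           brain_radius = 70,
                           gtv_center = brain_center + c(25, 10, 5),
                           gtv_semiaxes = c(26, 21, 17),
                           btv_center = gtv_center + c(10, 8, 4),
                           btv_semiaxes = c(18, 15, 12),
                           gtv_to_ptv75 = 5, ptv75_to_ptv60 = 10,
                           gtvu_to_ptv60 = 18,
                           oars = NULL) {
  if (is.null(oars)) {
    bc <- brain_center
    oars <- list(
      Brainstem = list(type = "cylinder", center_xy = bc[1:2] + c(0, -10),
                       radius = 8, z_range = bc[3] + c(-55, -5)),
      OpticChiasm = list(type = "sphere", center = bc + c(0, -5, -15), radius = 4),
      Pituitary = list(type = "sphere", center = bc + c(0, -5, -24), radius = 4),
      OpticNrv_L = list(type = "tube_x", center_yz = bc[2:3] + c(-5, -15),
                        radius = 2, x_range = bc[1] + c(-28, -4)),
      OpticNrv_R = list(type = "tube_x", center_yz = bc[2:3] + c(-5, -15),
                        radius = 2, x_range = bc[1] + c(4, 28))
    )
  }
  structure(
    list(spacing = spacing, shape = shape, origin = origin,
         brain_center = brain_center, brain_radius = brain_radius,
         gtv_center = gtv_center, gtv_semiaxes = gtv_semiaxes,
         btv_center = btv_center, btv_semiaxes = btv_semiaxes,
         gtv_to_ptv75 = gtv_to_ptv75, ptv75_to_ptv60 = ptv75_to_ptv60,
         gtvu_to_ptv60 = gtvu_to_ptv60, oars = oars),
    class = "phantom_config"
  )
}

# mm coordinates of every voxel center along each axis
axis_coords <- function(geometry) {
  purrr::map(1:3, function(ax) {
    geometry$origin[ax] + (seq_len(geometry$shape[ax]) - 1) * geometry$spacing[ax]
  })
}

ellipsoid_occ <- function(geometry, center, semiaxes) {
  co <- axis_coords(geometry)
  u <- (co[[1]] - center[1]) / semiaxes[1]
  v <- (co[[2]] - center[2]) / semiaxes[2]
  w <- (co[[3]] - center[3]) / semiaxes[3]
  outer(outer(u^2, v^2, `+`), w^2, `+`) <= 1
}

cylinder_occ <- function(geometry, center_xy, radius, z_range) {
  co <- axis_coords(geometry)
  u <- (co[[1]] - center_xy[1])^2
  v <- (co[[2]] - center_xy[2])^2
  inz <- co[[3]] >= min(z_range) & co[[3]] <= max(z_range)
  outer(outer(u, v, `+`) <= radius^2, inz, `&`)
}

tube_x_occ <- function(geometry, center_yz, radius, x_range) {
  co <- axis_coords(geometry)
  inx <- co[[1]] >= min(x_range) & co[[1]] <= max(x_range)
  v <- (co[[2]] - center_yz[1])^2
  w <- (co[[3]] - center_yz[2])^2
  aperm(outer(outer(v, w, `+`) <= radius^2, inx, `&`), c(3, 1, 2))
}

oar_occ <- function(geometry, spec) {
  switch(spec$type,
    sphere = ellipsoid_occ(geometry, spec$center, rep(spec$radius, 3)),
    cylinder = cylinder_occ(geometry, spec$center_xy, spec$radius, spec$z_range),
    tube_x = tube_x_occ(geometry, spec$center_yz, spec$radius, spec$x_range),
    abort(paste0("unknown OAR primitive type: ", spec$type), class = "planqa_parameter_error")
  )
}

#' Generate the phantom structure set
#'
#' Builds the full structure hierarchy deterministically from the config:
#' Brain, GTV, BTV, GTVu = GTV ∪ BTV, PTV75 = GTVu + margin,
#' PTV60ex = PTV75 + margin, PTV60 = GTVu + standard margin, plus the OAR
#' primitives. Nesting GTVu ⊆ PTV75 ⊆ PTV60ex (and ⊆ PTV60) is guaranteed by
#' the dilation chain.
#'
#' @param config A [phantom_config()].
#' @return A [structure_set()].
#' @export
generate_phantom <- function(config = phantom_config()) {
  geom <- grid_geometry(origin = config$origin, spacing = config$spacing,
                        shape = config$shape)
  check_inside <- function(center, extent, what) {
    lo <- geom$origin
    hi <- geom$origin + (geom$shape - 1) * geom$spacing
    if (any(center - extent < lo) || any(center + extent > hi)) {
      abort(paste0("phantom primitive '", what, "' extends outside the grid"),
            class = "planqa_parameter_error")
    }
  }
  check_inside(config$brain_center, rep(config$brain_radius, 3), "Brain")
  check_inside(config$gtv_center, config$gtv_semiaxes, "GTV")
  check_inside(config$btv_center, config$btv_semiaxes, "BTV")

  brain <- structure_mask("Brain", geom,
                          ellipsoid_occ(geom, config$brain_center,
                                        rep(config$brain_radius, 3)), "oar")
  gtv <- structure_mask("GTV", geom,
                        ellipsoid_occ(geom, config$gtv_center, config$gtv_semiaxes),
                        "target")
  btv <- structure_mask("BTV", geom,
                        ellipsoid_occ(geom, config$btv_center, config$btv_semiaxes),
                        "target")
  gtvu <- mask_union(gtv, btv, name = "GTVu")
  ptv75 <- dilate_mask(gtvu, config$gtv_to_ptv75, name = "PTV75")
  ptv60ex <- dilate_mask(ptv75, config$ptv75_to_ptv60, name = "PTV60ex")
  ptv60 <- dilate_mask(gtvu, config$gtvu_to_ptv60, name = "PTV60")
  masks <- list(brain, gtv, btv, gtvu, ptv75, ptv60ex, ptv60)
  for (nm in names(config$oars)) {
    masks <- c(masks, list(structure_mask(nm, geom, oar_occ(geom, config$oars[[nm]]), "oar")))
  }
  structure_set(geom, masks)
}

#' Dose-model configuration
#'
#' Parameters of the geometric dose model: prescriptions per plan, fraction
#' count, Gaussian penumbra width (mm falloff of dose outside each target),
#' brain-scatter background dose and additive voxel noise. The model is
#' geometric, not physical — the analysis consumes DVHs, not fluence.
#'
#' @param standard_rx Named Gy map for the standard plan.
#' @param experimental_rx Named Gy map for the escalated plan (simultaneous
#'   integrated boost: both levels in one 30-fraction course).
#' @param n_fractions Fraction count.
#' @param penumbra_sigma Gaussian falloff sigma, mm, > 0.
#' @param background_dose Scatter floor inside the brain, Gy.
#' @param noise_sd Additive Gaussian dose noise, Gy, >= 0.
#' @return A `dose_model_config` list.
#' @export
dose_model_config <- function(standard_rx = c(PTV60 = 60),
                              experimental_rx = c(PTV60ex = 60, PTV75 = 75),
                              n_fractions = 30L,
                              penumbra_sigma = 5,
                              background_dose = 1,
                              noise_sd = 0.3) {
  if (any(c(standard_rx, experimental_rx) <= 0)) {
    abort("prescriptions must be > 0", class = "planqa_parameter_error")
  }
  if (penumbra_sigma <= 0) abort("`penumbra_sigma` must be > 0", class = "planqa_parameter_error")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0", class = "planqa_parameter_error")
  structure(
    list(standard_rx = standard_rx, experimental_rx = experimental_rx,
         n_fractions = as.integer(n_fractions), penumbra_sigma = penumbra_sigma,
         background_dose = background_dose, noise_sd = noise_sd),
    class = "dose_model_config"
  )
}

#' Simulate a dose distribution for a plan
#'
#' Each prescription target receives its prescribed dose inside the target
#' mask, with a Gaussian distance-based penumbra outside; for the
#' simultaneous-integrated-boost plan the per-voxel dose is the maximum over
#' targets. A scatter background floor applies inside the brain, and seeded
#' Gaussian noise is added (doses clamped at 0). With zero noise, the median
#' dose of each target equals its prescription.
#'
#' @param structures A [structure_set()] holding the targets (and `Brain`).
#' @param config A [dose_model_config()].
#' @param plan `"standard"` or `"experimental"`.
#' @param seed Integer seed fixing the noise field.
#' @return A [dose_grid()].
#' @export
simulate_dose <- function(structures, config = dose_model_config(),
                          plan = c("standard", "experimental"), seed = 1L) {
  plan <- match.arg(plan)
  rx <- if (plan == "standard") config$standard_rx else config$experimental_rx
  geom <- structures$geometry
  dose <- array(0, dim = geom$shape)
  for (nm in names(rx)) {
    if (!has_structure(structures, nm)) {
      abort(paste0("prescription target '", nm, "' missing from structure set"),
            class = "planqa_missing_structure")
    }
    m <- get_structure(structures, nm)
    d_out <- sqrt(edt_sq(m$occupancy, geom))  # 0 inside the target
    dose <- pmax(dose, rx[[nm]] * exp(-d_out^2 / (2 * config$penumbra_sigma^2)))
  }
  if (has_structure(structures, "Brain") && config$background_dose > 0) {
    brain <- get_structure(structures, "Brain")
    dose <- pmax(dose, config$background_dose * brain$occupancy)
  }
  if (config$noise_sd > 0) {
    noise <- withr::with_seed(seed, rnorm(length(dose), 0, config$noise_sd))
    dose <- pmax(dose + noise, 0)
  }
  dose_grid(geom, dose, n_fractions = config$n_fractions, plan_label = plan)
}

#' Simulate a PET-like uptake grid
#'
#' Flat background uptake inside the brain, the PET-avid lesion region at
#' `background_uptake * lesion_tbr`, plus seeded additive noise — the minimal
#' statistical structure the threshold-based biological-target-volume
#' segmentation assumes.
#'
#' @param structures A [structure_set()] with `Brain` and the lesion mask.
#' @param background_uptake Background tracer level (arbitrary units), > 0.
#' @param lesion_tbr Lesion-to-background ratio, > 1.
#' @param noise_sd Additive noise SD (same units), >= 0.
#' @param seed Integer seed.
#' @param lesion_name Name of the PET-avid mask, default `"BTV"`.
#' @return A `pet_grid` (geometry + uptake array).
#' @export
simulate_pet <- function(structures, background_uptake = 1, lesion_tbr = 2.5,
                         noise_sd = 0, seed = 1L, lesion_name = "BTV") {
  if (lesion_tbr <= 1) abort("`lesion_tbr` must be > 1", class = "planqa_parameter_error")
  if (background_uptake <= 0) abort("`background_uptake` must be > 0", class = "planqa_parameter_error")
  geom <- structures$geometry
  brain <- get_structure(structures, "Brain")
  lesion <- get_structure(structures, lesion_name)
  uptake <- array(0, dim = geom$shape)
  uptake[brain$occupancy] <- background_uptake
  uptake[lesion$occupancy] <- background_uptake * lesion_tbr
  if (noise_sd > 0) {
    uptake <- uptake + withr::with_seed(seed, rnorm(length(uptake), 0, noise_sd))
  }
  structure(list(geometry = geom, uptake = uptake), class = "pet_grid")
}

#' Threshold segmentation of the biological target volume
#'
#' Voxels whose uptake reaches `tbr_threshold` times the mean uptake of the
#' background region become the BTV. The dummy-run threshold is 1.8; the
#' threshold is configurable (e.g. 1.6 for the main trial), and lowering it
#' can only grow the BTV.
#'
#' @param pet A [simulate_pet()] result.
#' @param background_region Non-empty [structure_mask()] of normal background
#'   (e.g. brain minus the dilated lesion).
#' @param tbr_threshold Target-to-background ratio threshold, default 1.8.
#' @return A derived [structure_mask()] named `"BTV"`.
#' @export
btv_from_pet <- function(pet, background_region, tbr_threshold = 1.8) {
  check_same_geometry(pet$geometry, background_region$geometry, "PET grid and background region")
  if (!any(background_region$occupancy)) {
    abort("background region is empty", class = "planqa_empty_mask")
  }
  bg <- mean(pet$uptake[background_region$occupancy])
  structure_mask("BTV", pet$geometry, pet$uptake >= tbr_threshold * bg, "derived")
}

#' Contour-perturbation profile
#'
#' Stochastic model of inter-center delineation variability: a random rigid
#' translation per structure (per-axis SD in mm) plus boundary noise — a
#' smooth random field added to the signed distance function before
#' re-thresholding, which perturbs the contour surface by roughly
#' `boundary_sd` mm while preserving topology. Per-structure overrides can
#' change either magnitude or add a systematic margin error (`dilate_mm`,
#' negative to shrink), e.g. an edema-inclusion error as a large GTV
#' dilation. The zero profile is the identity.
#'
#' @param translation_sd Per-axis translation SD, mm, >= 0.
#' @param boundary_sd Boundary-noise amplitude, mm, >= 0.
#' @param boundary_smoothness Correlation length of the boundary field, in
#'   voxels.
#' @param overrides Named list: structure -> list(translation_sd=, boundary_sd=,
#'   dilate_mm=).
#' @return A `perturbation_profile` list.
#' @export
perturbation_profile <- function(translation_sd = 2, boundary_sd = 1.5,
                                 boundary_smoothness = 3, overrides = list()) {
  if (translation_sd < 0 || boundary_sd < 0) {
    abort("perturbation magnitudes must be >= 0", class = "planqa_parameter_error")
  }
  structure(
    list(translation_sd = translation_sd, boundary_sd = boundary_sd,
         boundary_smoothness = boundary_smoothness, overrides = overrides),
    class = "perturbation_profile"
  )
}

# Smooth unit-variance Gaussian random field via separable kernel smoothing
# of white noise (circular convolution; edge wrap is irrelevant for noise).
smooth_noise_field <- function(shape, sigma_vox) {
  x <- array(rnorm(prod(shape)), dim = shape)
  if (sigma_vox > 0) {
    r <- max(1L, ceiling(3 * sigma_vox))
    k <- exp(-((-r):r)^2 / (2 * sigma_vox^2))
    k <- k / sum(k)
    for (ax in 1:3) {
      perm <- c(ax, setdiff(1:3, ax))
      y <- aperm(x, perm)
      dm <- dim(y)
      m <- matrix(y, nrow = dm[1])
      m <- stats::filter(m, k, sides = 2, circular = TRUE)
      x <- aperm(array(as.numeric(m), dim = dm), order(perm))
    }
    x <- x / stats::sd(x)
  }
  x
}

shift_occ <- function(occ, offset_vox) {
  dm <- dim(occ)
  out <- array(FALSE, dim = dm)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    o <- offset_vox[ax]
    if (abs(o) >= dm[ax]) return(out)
    if (o >= 0) { dst[[ax]] <- (1 + o):dm[ax]; src[[ax]] <- 1:(dm[ax] - o) }
    else { dst[[ax]] <- 1:(dm[ax] + o); src[[ax]] <- (1 - o):dm[ax] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- occ[src[[1]], src[[2]], src[[3]]]
  out
}

perturb_mask <- function(mask, translation_sd, boundary_sd, dilate_mm, smoothness) {
  geom <- mask$geometry
  occ <- mask$occupancy
  n0 <- sum(occ)
  if (translation_sd > 0) {
    off <- round(rnorm(3, 0, translation_sd) / geom$spacing)
    occ <- shift_occ(occ, off)
    if (sum(occ) < n0) {
      abort(paste0("perturbation pushed structure '", mask$name, "' off the grid"),
            class = "planqa_parameter_error")
    }
  }
  if (boundary_sd > 0 && any(occ) && !all(occ)) {
    d_out <- sqrt(edt_sq(!occ, geom))
    d_in <- sqrt(edt_sq(occ, geom))
    sdf <- ifelse(occ, d_out, -d_in)
    occ <- (sdf + boundary_sd * smooth_noise_field(geom$shape, smoothness)) > 0
  }
  m <- structure_mask(mask$name, geom, occ, mask$role)
  if (dilate_mm > 0) m <- dilate_mask(m, dilate_mm, name = mask$name)
  if (dilate_mm < 0) m <- erode_mask(m, -dilate_mm, name = mask$name)
  m$role <- mask$role
  m
}

#' Simulate one center's submission
#'
#' Emulates an independently contoured and planned submission: the primitive
#' structures (GTV, BTV, OARs — not the brain, whose registration is assumed
#' sound) are each perturbed per the profile, the derived target hierarchy
#' (GTVu and the PTVs) is rebuilt from the perturbed primitives with the
#' protocol margin recipe, and the dose is re-simulated on the perturbed
#' targets. Fully reproducible under `(profile, seed)`.
#'
#' @param reference A reference [plan_bundle()] (typically from
#'   [simulate_reference_bundle()], which attaches its configs).
#' @param profile A [perturbation_profile()].
#' @param seed Integer seed.
#' @param phantom Phantom config supplying the margin recipe; defaults to the
#'   one attached to `reference`.
#' @param dose_config Dose model; defaults to the one attached to `reference`.
#' @param center_label Label for the new bundle.
#' @return A [plan_bundle()].
#' @export
generate_center_submission <- function(reference, profile, seed = 1L,
                                       phantom = attr(reference, "phantom_config"),
                                       dose_config = attr(reference, "dose_config"),
                                       center_label = paste0("center_seed", seed)) {
  if (is.null(phantom)) phantom <- phantom_config()
  if (is.null(dose_config)) dose_config <- dose_model_config()
  ref_set <- reference$structures
  geom <- ref_set$geometry
  primitive <- setdiff(names(ref_set$masks),
                       c("GTVu", "PTV75", "PTV60ex", "PTV60", "Brain"))
  withr::with_seed(seed, {
    masks <- list(get_structure(ref_set, "Brain"))
    for (nm in primitive) {
      ov <- profile$overrides[[nm]] %||% list()
      masks <- c(masks, list(perturb_mask(
        get_structure(ref_set, nm),
        translation_sd = ov$translation_sd %||% profile$translation_sd,
        boundary_sd = ov$boundary_sd %||% profile$boundary_sd,
        dilate_mm = ov$dilate_mm %||% 0,
        smoothness = profile$boundary_smoothness
      )))
    }
    set <- structure_set(geom, masks)
    gtvu <- mask_union(get_structure(set, "GTV"), get_structure(set, "BTV"), "GTVu")
    ptv75 <- dilate_mask(gtvu, phantom$gtv_to_ptv75, "PTV75")
    ptv60ex <- dilate_mask(ptv75, phantom$ptv75_to_ptv60, "PTV60ex")
    ptv60 <- dilate_mask(gtvu, phantom$gtvu_to_ptv60, "PTV60")
    for (m in list(gtvu, ptv75, ptv60ex, ptv60)) set <- add_structure(set, m)
    dose <- simulate_dose(set, dose_config, plan = reference$dose$plan_label,
                          seed = seed + 1L)
    out <- plan_bundle(set, dose, reference$prescription, center_label)
    attr(out, "phantom_config") <- phantom
    attr(out, "dose_config") <- dose_config
    out
  })
}

#' Simulate the reference plan bundle
#'
#' Convenience wrapper: phantom structures + simulated dose + prescription in
#' one bundle, with the configs attached for downstream perturbation.
#'
#' @param phantom A [phantom_config()].
#' @param dose_config A [dose_model_config()].
#' @param plan `"standard"` or `"experimental"`.
#' @param seed Integer seed for the dose noise.
#' @param center_label Bundle label.
#' @return A [plan_bundle()].
#' @export
simulate_reference_bundle <- function(phantom = phantom_config(),
                                      dose_config = dose_model_config(),
                                      plan = c("standard", "experimental"),
                                      seed = 1L, center_label = "reference") {
  plan <- match.arg(plan)
  set <- generate_phantom(phantom)
  dose <- simulate_dose(set, dose_config, plan = plan, seed = seed)
  rx <- if (plan == "standard") dose_config$standard_rx else dose_config$experimental_rx
  out <- plan_bundle(set, dose, rx, center_label)
  attr(out, "phantom_config") <- phantom
  attr(out, "dose_config") <- dose_config
  out
}
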