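#' Voxel-lattice geometry
#'
#' Defines the shared voxel grid every structure mask and dose grid lives on:
#' the physical position (mm) of the first voxel center, the voxel spacing
#' (mm), and the number of voxels along each axis. The physical coordinate of
#' voxel `(i, j, k)` (0-based) is `origin + c(i, j, k) * spacing`
#' (voxel-center convention).
#'
#' @param origin Numeric length-3, mm position of the first voxel center.
#' @param spacing Numeric length-3, mm voxel spacing, all > 0.
#' @param shape Integer length-3, voxel counts per axis, all >= 1.
#' @param axes Axis-order convention label (informational), default `"LPS"`.
#'
#' @return A `grid_geometry` object.
#' @export
#' @examples
#' geom <- grid_geometry(spacing = c(2, 2, 2), shape = c(64, 64, 64))
#' voxel_volume_cc(geom)
grid_geometry <- function(origin = c(0, 0, 0), spacing = c(1, 1, 1), shape,
                          axes = "LPS") {
  origin <- as.numeric(origin)
  spacing <- as.numeric(spacing)
  shape <- as.integer(shape)
  stopifnot(length(origin) == 3, length(spacing) == 3, length(shape) == 3)
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("all `spacing` components must be finite and > 0", class = "planqa_parameter_error")
  }
  if (any(shape < 1L)) {
    abort("all `shape` components must be >= 1", class = "planqa_parameter_error")
  }
  structure(
    list(origin = origin, spacing = spacing, shape = shape, axes = axes),
    class = "grid_geometry"
  )
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat("<grid_geometry> ", paste(x$shape, collapse = " x "),
      " voxels @ ", paste(x$spacing, collapse = " x "), " mm (", x$axes, ")\n",
      sep = "")
  invisible(x)
}

#' @rdname grid_geometry
#' @param geometry A `grid_geometry`.
#' @export
voxel_volume_cc <- function(geometry) {
  prod(geometry$spacing) / 1000
}

same_geometry <- function(a, b, tol = 1e-6) {
  all(a$shape == b$shape) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

check_same_geometry <- function(a, b, what = "objects") {
  if (!same_geometry(a, b)) {
    abort(paste0("incompatible grids: ", what, " are not on the same voxel lattice"),
          class = "planqa_incompatible_grids")
  }
  invisible(TRUE)
}

geometry_of <- function(x) {
  if (inherits(x, "grid_geometry")) x else x$geometry
}

#' Binary structure mask on a voxel grid
#'
#' @param name Structure label (TG-263 style, e.g. `"Brainstem"`).
#' @param geometry A [grid_geometry()].
#' @param occupancy Logical 3D array matching `geometry$shape`, or a logical
#'   vector of the right length (reshaped).
#' @param role One of `"target"`, `"oar"`, `"derived"`.
#'
#' @return A `structure_mask` object.
#' @export
structure_mask <- function(name, geometry, occupancy, role = c("target", "oar", "derived")) {
  role <- match.arg(role)
  stopifnot(inherits(geometry, "grid_geometry"))
  occupancy <- array(as.logical(occupancy), dim = geometry$shape)
  if (anyNA(occupancy)) abort("mask occupancy must not contain NA", class = "planqa_parameter_error")
  structure(
    list(name = name, geometry = geometry, occupancy = occupancy, role = role),
    class = "structure_mask"
  )
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask> %s [%s]: %d voxels, %.2f cc\n",
              x$name, x$role, sum(x$occupancy), volume_cc(x)))
  invisible(x)
}

#' Structure volume in cc
#'
#' Volume is the count of occupied voxels times the voxel volume; there is no
#' fractional (partial-volume) occupancy.
#'
#' @param mask A [structure_mask()].
#' @return Volume in cubic centimeters.
#' @export
volume_cc <- function(mask) {
  sum(mask$occupancy) * voxel_volume_cc(mask$geometry)
}

#' Voxelwise boolean algebra on masks
#'
#' Union, intersection and difference of two masks sharing one grid. The
#' result carries the `"derived"` role. Used e.g. to build the unified gross
#' tumor volume GTVu = GTV ∪ BTV.
#'
#' @param a,b [structure_mask()] objects on the same geometry.
#' @param name Name for the result (defaults to an algebraic label).
#' @return A derived [structure_mask()].
#' @export
mask_union <- function(a, b, name = paste0(a$name, "+", b$name)) {
  check_same_geometry(a$geometry, b$geometry, "masks")
  structure_mask(name, a$geometry, a$occupancy | b$occupancy, role = "derived")
}

#' @rdname mask_union
#' @export
mask_intersection <- function(a, b, name = paste0(a$name, "&", b$name)) {
  check_same_geometry(a$geometry, b$geometry, "masks")
  structure_mask(name, a$geometry, a$occupancy & b$occupancy, role = "derived")
}

#' @rdname mask_union
#' @export
mask_difference <- function(a, b, name = paste0(a$name, "-", b$name)) {
  check_same_geometry(a$geometry, b$geometry, "masks")
  structure_mask(name, a$geometry, a$occupancy & !b$occupancy, role = "derived")
}

# Squared distance (mm^2) from every voxel center to the nearest TRUE voxel
# center of `occ`. All-FALSE input gives +Inf everywhere.
edt_sq <- function(occ, geometry) {
  d <- edt_squared(as.logical(occ), geometry$shape, geometry$spacing)
  d[d > 1e200] <- Inf
  array(d, dim = geometry$shape)
}

#' Distance-transform mask morphology
#'
#' `erode_mask()` keeps the voxels whose Euclidean distance to the mask
#' exterior exceeds `margin`; `dilate_mask()` adds all voxels within `margin`
#' of the mask. Both honor anisotropic spacing (mm-true margins), matching the
#' "inner margin" construction used for structures such as the brainstem core
#' (brainstem minus a 3 mm inner margin). `margin = 0` is the identity.
#'
#' @param mask A [structure_mask()].
#' @param margin Margin in mm, >= 0.
#' @param name Name for the result.
#' @return A derived [structure_mask()].
#' @export
erode_mask <- function(mask, margin, name = paste0(a_name(mask), "_erode", margin)) {
  if (!is.finite(margin) || margin < 0) {
    abort("`margin` must be >= 0", class = "planqa_parameter_error")
  }
  if (margin == 0) return(structure_mask(name, mask$geometry, mask$occupancy, "derived"))
  d_out <- edt_sq(!mask$occupancy, mask$geometry)
  structure_mask(name, mask$geometry, mask$occupancy & d_out > margin^2, "derived")
}

#' @rdname erode_mask
#' @export
dilate_mask <- function(mask, margin, name = paste0(a_name(mask), "_dilate", margin)) {
  if (!is.finite(margin) || margin < 0) {
    abort("`margin` must be >= 0", class = "planqa_parameter_error")
  }
  if (margin == 0) return(structure_mask(name, mask$geometry, mask$occupancy, "derived"))
  d_in <- edt_sq(mask$occupancy, mask$geometry)
  structure_mask(name, mask$geometry, mask$occupancy | d_in <= margin^2, "derived")
}

a_name <- function(mask) mask$name

#' Named collection of masks on one grid
#'
#' @param geometry A [grid_geometry()].
#' @param masks List of [structure_mask()] objects; names are taken from the
#'   masks and must be unique.
#' @return A `structure_set` object.
#' @export
structure_set <- function(geometry, masks = list()) {
  stopifnot(inherits(geometry, "grid_geometry"))
  nm <- vapply(masks, function(m) m$name, character(1))
  if (anyDuplicated(nm)) abort("structure names must be unique within a set",
                               class = "planqa_parameter_error")
  for (m in masks) check_same_geometry(geometry, m$geometry, "set and member mask")
  structure(list(geometry = geometry, masks = setNames(masks, nm)),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat("<structure_set> ", length(x$masks), " structures: ",
      paste(names(x$masks), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @rdname structure_set
#' @param set A `structure_set`.
#' @param name Structure name (case-insensitive match).
#' @export
get_structure <- function(set, name) {
  hit <- which(tolower(names(set$masks)) == tolower(name))
  if (length(hit) == 0) {
    abort(paste0("structure '", name, "' not found in set"), class = "planqa_missing_structure")
  }
  set$masks[[hit[1]]]
}

has_structure <- function(set, name) {
  any(tolower(names(set$masks)) == tolower(name))
}

add_structure <- function(set, mask) {
  check_same_geometry(set$geometry, mask$geometry, "set and new mask")
  set$masks[[mask$name]] <- mask
  set
}

#' Per-voxel dose distribution in Gy
#'
#' @param geometry A [grid_geometry()].
#' @param dose Numeric 3D array (Gy) matching the geometry, all finite, >= 0.
#' @param n_fractions Number of delivered fractions (30 for both trial plans).
#' @param plan_label `"standard"` or `"experimental"`.
#' @return A `dose_grid` object.
#' @export
dose_grid <- function(geometry, dose, n_fractions = 30L,
                      plan_label = c("standard", "experimental")) {
  plan_label <- match.arg(plan_label)
  stopifnot(inherits(geometry, "grid_geometry"))
  dose <- array(as.numeric(dose), dim = geometry$shape)
  if (any(!is.finite(dose)) || any(dose < 0)) {
    abort("all dose values must be finite and >= 0", class = "planqa_parameter_error")
  }
  if (n_fractions < 1) abort("`n_fractions` must be >= 1", class = "planqa_parameter_error")
  structure(
    list(geometry = geometry, dose = dose, n_fractions = as.integer(n_fractions),
         plan_label = plan_label),
    class = "dose_grid"
  )
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %s plan, %d fractions, dose range %.1f-%.1f Gy\n",
              x$plan_label, x$n_fractions, min(x$dose), max(x$dose)))
  invisible(x)
}

#' One plan submission: structures + dose + prescription
#'
#' @param structures A [structure_set()].
#' @param dose A [dose_grid()] on the same geometry.
#' @param prescription Named numeric vector, target name -> prescribed Gy;
#'   every name must resolve to a mask in `structures`.
#' @param center_label Free-text identifier of the submitting center.
#' @return A `plan_bundle` object.
#' @export
plan_bundle <- function(structures, dose, prescription, center_label = "reference") {
  check_same_geometry(structures$geometry, dose$geometry, "structure set and dose grid")
  prescription <- unlist(prescription)
  for (nm in names(prescription)) {
    if (!has_structure(structures, nm)) {
      abort(paste0("prescription target '", nm, "' has no mask in the structure set"),
            class = "planqa_missing_structure")
    }
  }
  structure(
    list(structures = structures, dose = dose,
         prescription = prescription, center_label = center_label),
    class = "plan_bundle"
  )
}

#' @export
print.plan_bundle <- function(x, ...) {
  cat(sprintf("<plan_bundle> center '%s', %s plan; targets: %s\n",
              x$center_label, x$dose$plan_label,
              paste(sprintf("%s=%g Gy", names(x$prescription), x$prescription),
                    collapse = ", ")))
  invisible(x)
}

#' Brain structure for NTCP evaluation
#'
#' Builds the normal-brain structure the radionecrosis NTCP model is evaluated
#' on: the brain minus the union of a list of exclusion structures (in the
#' trial: cavernous sinuses, brainstem, optic chiasm, optic nerves, pituitary,
#' mammillary bodies, Meckel's caves, and the unified GTV). Exclusion names
#' missing from the set are reported and skipped, since a minimal phantom need
#' not define every OAR in the clinical list; the same helper serves plain
#' "Brain-GTV" style structures.
#'
#' @param structures A [structure_set()] containing a brain mask.
#' @param exclusion_names Character vector of structure names to subtract.
#' @param brain_name Name of the brain mask, default `"Brain"`.
#' @param name Name of the derived mask.
#' @return A derived [structure_mask()], always a subset of the brain mask.
#' @export
derive_ntcp_brain_structure <- function(structures,
                                        exclusion_names = c("Brainstem", "OpticChiasm",
                                                            "OpticNrv_L", "OpticNrv_R",
                                                            "Pituitary", "GTVu"),
                                        brain_name = "Brain",
                                        name = "Brain_NTCP") {
  if (!has_structure(structures, brain_name)) {
    abort(paste0("brain mask '", brain_name, "' not found in structure set"),
          class = "planqa_missing_structure")
  }
  brain <- get_structure(structures, brain_name)
  occ <- brain$occupancy
  missing <- character(0)
  for (nm in exclusion_names) {
    if (has_structure(structures, nm)) {
      occ <- occ & !get_structure(structures, nm)$occupancy
    } else {
      missing <- c(missing, nm)
    }
  }
  if (length(missing) > 0) {
    inform(paste0("derive_ntcp_brain_structure: skipping absent exclusion structure(s): ",
                  paste(missing, collapse = ", ")))
  }
  structure_mask(name, brain$geometry, occ, role = "derived")
}

# Logical array marking mask voxels with at least one face-adjacent exterior
# neighbor (voxels on the grid border count as surface).
surface_occupancy <- function(occ) {
  dm <- dim(occ)
  interior <- array(TRUE, dim = dm)
  shift_and <- function(int, ax, dir) {
    idx <- lapply(dm, seq_len)
    src <- idx
    if (dir > 0) { idx[[ax]] <- seq_len(dm[ax] - 1); src[[ax]] <- 2:dm[ax] }
    else { idx[[ax]] <- 2:dm[ax]; src[[ax]] <- seq_len(dm[ax] - 1) }
    nb <- array(FALSE, dim = dm)  # out-of-grid neighbor treated as exterior
    nb[idx[[1]], idx[[2]], idx[[3]]] <- occ[src[[1]], src[[2]], src[[3]]]
    int & nb
  }
  for (ax in 1:3) for (dir in c(-1, 1)) interior <- shift_and(interior, ax, dir)
  occ & !interior
}

#' Boundary voxel centers of a mask
#'
#' Returns the physical coordinates (mm) of mask voxels having at least one
#' face-adjacent exterior neighbor — the discrete "outer surface points" the
#' Hausdorff-distance metrics are computed between.
#'
#' @param mask A non-empty [structure_mask()].
#' @return A numeric matrix with columns `x`, `y`, `z` (mm), one row per
#'   surface voxel.
#' @export
surface_voxels <- function(mask) {
  if (!any(mask$occupancy)) {
    abort("surface of an empty mask is undefined", class = "planqa_empty_mask")
  }
  surf <- surface_occupancy(mask$occupancy)
  idx <- which(surf, arr.ind = TRUE)
  g <- mask$geometry
  coords <- sweep(sweep(idx - 1, 2, g$spacing, `*`), 2, g$origin, `+`)
  colnames(coords) <- c("x", "y", "z")
  coords
}
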