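BUNDLE_FORMAT_VERSION <- "1.0"

safe_file_name <- function(name) gsub("[^A-Za-z0-9_.-]", "_", name)

#' Write / read a plan bundle on disk
#'
#' The on-disk bundle is a directory holding one NIfTI volume per structure
#' mask (8-bit), the dose grid (floating point, Gy) and a JSON manifest
#' (format version, geometry, structure roles, prescription, fraction count,
#' center label, optional seed provenance). The manifest's geometry is
#' authoritative; write-then-read reproduces masks and dose bit-exactly. On
#' read, a missing file is reported by name and a volume whose shape differs
#' from the manifest geometry raises an incompatible-grids error.
#'
#' @param bundle A [plan_bundle()].
#' @param path Bundle directory (created if needed).
#' @param seed_provenance Optional seed/config note stored in the manifest.
#' @return `write_bundle()` returns `path` invisibly; `read_bundle()` returns
#'   a [plan_bundle()].
#' @export
write_bundle <- function(bundle, path, seed_provenance = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  geom <- bundle$structures$geometry
  structures <- purrr::imap(bundle$structures$masks, function(m, nm) {
    file <- paste0(safe_file_name(nm), ".nii.gz")
    RNifti::writeNifti(
      RNifti::asNifti(array(as.integer(m$occupancy), dim = geom$shape),
                      datatype = "uint8"),
      file.path(path, file))
    list(file = file, role = m$role)
  })
  RNifti::writeNifti(
    RNifti::asNifti(bundle$dose$dose, datatype = "double"),
    file.path(path, "dose.nii.gz"))
  manifest <- list(
    format_version = BUNDLE_FORMAT_VERSION,
    geometry = list(origin = geom$origin, spacing = geom$spacing,
                    shape = geom$shape, axes = geom$axes),
    structures = structures,
    dose_file = "dose.nii.gz",
    n_fractions = bundle$dose$n_fractions,
    plan_label = bundle$dose$plan_label,
    prescription = as.list(bundle$prescription),
    center_label = bundle$center_label,
    seed_provenance = seed_provenance
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) {
    abort(paste0("no manifest.json in bundle directory: ", path), class = "planqa_io_error")
  }
  mf <- jsonlite::fromJSON(mf_path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(mf$format_version, BUNDLE_FORMAT_VERSION)) {
    abort(paste0("unknown bundle format version: ", mf$format_version),
          class = "planqa_io_error")
  }
  geom <- grid_geometry(origin = mf$geometry$origin, spacing = mf$geometry$spacing,
                        shape = mf$geometry$shape, axes = mf$geometry$axes)
  read_vol <- function(file) {
    fp <- file.path(path, file)
    if (!file.exists(fp)) {
      abort(paste0("bundle file missing: ", file), class = "planqa_io_error")
    }
    v <- as.array(RNifti::readNifti(fp))
    if (length(dim(v)) != 3 || !all(dim(v) == geom$shape)) {
      abort(paste0("incompatible grids: '", file, "' does not match the manifest geometry"),
            class = "planqa_incompatible_grids")
    }
    v
  }
  masks <- purrr::imap(mf$structures, function(s, nm) {
    structure_mask(nm, geom, read_vol(s$file) > 0, role = s$role)
  })
  set <- structure_set(geom, unname(masks))
  dose <- dose_grid(geom, read_vol(mf$dose_file), n_fractions = mf$n_fractions,
                    plan_label = mf$plan_label)
  plan_bundle(set, dose, unlist(mf$prescription), mf$center_label)
}

#' Rasterize planar contour polygons to a mask
#'
#' Converts per-slice closed contour polygons (the shape RT-STRUCT exports
#' take) to a voxel mask by voxel-center point-in-polygon testing with the
#' even-odd rule; multiple rings on one slice are XOR-combined, which
#' supports holes. Every contour's slice position must coincide with a grid
#' plane within half the slice spacing.
#'
#' @param contours Data frame with columns `z` (mm slice position), `ring`
#'   (ring id within slice), `x`, `y` (mm vertex coordinates, in order,
#'   closed implicitly).
#' @param geometry Target [grid_geometry()].
#' @param name,role Passed to [structure_mask()].
#' @return A [structure_mask()].
#' @export
rasterize_contours <- function(contours, geometry, name = "ROI", role = "derived") {
  stopifnot(all(c("z", "ring", "x", "y") %in% names(contours)))
  occ <- array(FALSE, dim = geometry$shape)
  co <- axis_coords(geometry)
  for (zv in unique(contours$z)) {
    k <- round((zv - geometry$origin[3]) / geometry$spacing[3]) + 1
    if (k < 1 || k > geometry$shape[3] ||
        abs(co[[3]][max(1, min(k, geometry$shape[3]))] - zv) > geometry$spacing[3] / 2 + 1e-9) {
      abort(sprintf("contour slice z = %g mm is not aligned to a grid plane", zv),
            class = "planqa_parameter_error")
    }
    slice <- contours[contours$z == zv, , drop = FALSE]
    fill <- matrix(FALSE, geometry$shape[1], geometry$shape[2])
    for (rid in unique(slice$ring)) {
      ring <- slice[slice$ring == rid, , drop = FALSE]
      if (nrow(ring) < 3) {
        abort("contour rings need at least 3 vertices", class = "planqa_parameter_error")
      }
      fill <- xor(fill, point_in_polygon_grid(co[[1]], co[[2]], ring$x, ring$y))
    }
    occ[, , k] <- occ[, , k] | fill
  }
  structure_mask(name, geometry, occ, role)
}

# Even-odd (ray casting) point-in-polygon for all grid points (px x py).
point_in_polygon_grid <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- matrix(FALSE, length(px), length(py))
  j <- n
  for (i in seq_len(n)) {
    # edge from vertex j to i; crossing test per grid row y
    yi <- vy[i]; yj <- vy[j]
    if (yi != yj) {
      rows <- which((py < yi) != (py < yj))
      if (length(rows) > 0) {
        x_cross <- vx[i] + (py[rows] - yi) / (yj - yi) * (vx[j] - vx[i])
        inside[, rows] <- xor(inside[, rows],
                              outer(px, x_cross, `<`))
      }
    }
    j <- i
  }
  inside
}

#' Export a DVH curve to CSV
#'
#' Columns `dose_gy`, `volume_cc`, `volume_pct`, one file per structure.
#'
#' @param dvh A [cumulative_dvh()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_dvh_csv <- function(dvh, path) {
  df <- tidy(dvh)
  write.csv(df[, c("dose_gy", "volume_cc", "volume_pct")], path, row.names = FALSE)
  invisible(path)
}

#' Export a report table to CSV or JSON
#'
#' Works for any of the package's report objects (risk report, similarity
#' report, scorecard) or a plain data frame, via `tidy()`.
#'
#' @param x Report object or data frame.
#' @param path Output path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
export_report <- function(x, path) {
  df <- if (is.data.frame(x)) x else tidy(x)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
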