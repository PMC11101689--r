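# Shared fixtures and independent brute-force oracles. The oracles
# deliberately avoid the package's own code paths (no distance transform, no
# binned DVH): plain loops and sorts only.

small_geom <- function(n = 12, spacing = c(1, 1, 1)) {
  grid_geometry(spacing = spacing, shape = rep(n, 3))
}

mask_from_occ <- function(occ, geom, name = "M", role = "oar") {
  structure_mask(name, geom, occ, role)
}

# digitized sphere by direct voxel-center test
sphere_mask <- function(geom, center, radius, name = "Sphere") {
  co <- lapply(1:3, function(ax) geom$origin[ax] + (seq_len(geom$shape[ax]) - 1) * geom$spacing[ax])
  occ <- outer(outer((co[[1]] - center[1])^2, (co[[2]] - center[2])^2, `+`),
               (co[[3]] - center[3])^2, `+`) <= radius^2
  structure_mask(name, geom, occ, "oar")
}

random_mask <- function(geom, p = 0.2, name = "R") {
  occ <- array(runif(prod(geom$shape)) < p, dim = geom$shape)
  structure_mask(name, geom, occ, "oar")
}

# random connected-ish blob: a few overlapping random balls
random_blob_mask <- function(geom, n_balls = 3, name = "B") {
  occ <- array(FALSE, dim = geom$shape)
  extent <- (geom$shape - 1) * geom$spacing
  for (i in seq_len(n_balls)) {
    c0 <- geom$origin + runif(3, 0.25, 0.75) * extent
    r <- runif(1, 0.1, 0.25) * min(extent)
    occ <- occ | sphere_mask(geom, c0, r)$occupancy
  }
  structure_mask(name, geom, occ, "oar")
}

# brute-force surface scan: in-mask voxels with a face-adjacent exterior
# neighbor (grid border counts as exterior); returns mm coordinate matrix
brute_surface <- function(mask) {
  occ <- mask$occupancy
  g <- mask$geometry
  dm <- dim(occ)
  rows <- list()
  for (i in 1:dm[1]) for (j in 1:dm[2]) for (k in 1:dm[3]) {
    if (!occ[i, j, k]) next
    nb <- c(
      i == 1 || !occ[i - 1, j, k], i == dm[1] || !occ[i + 1, j, k],
      j == 1 || !occ[i, j - 1, k], j == dm[2] || !occ[i, j + 1, k],
      k == 1 || !occ[i, j, k - 1], k == dm[3] || !occ[i, j, k + 1]
    )
    if (any(nb)) rows[[length(rows) + 1]] <- g$origin + (c(i, j, k) - 1) * g$spacing
  }
  do.call(rbind, rows)
}

# all-pairs directed distances between two surface point sets
brute_directed <- function(pa, pb) {
  apply(pa, 1, function(p) sqrt(min(colSums((t(pb) - p)^2))))
}

brute_hd <- function(a, b) {
  pa <- brute_surface(a); pb <- brute_surface(b)
  max(max(brute_directed(pa, pb)), max(brute_directed(pb, pa)))
}

brute_hd95 <- function(a, b, p = 95) {
  pa <- brute_surface(a); pb <- brute_surface(b)
  max(quantile(brute_directed(pa, pb), p / 100, names = FALSE, type = 7),
      quantile(brute_directed(pb, pa), p / 100, names = FALSE, type = 7))
}

brute_dice <- function(a, b) {
  2 * sum(a$occupancy & b$occupancy) / (sum(a$occupancy) + sum(b$occupancy))
}

# sort-based DVH metric oracle straight from the voxel doses (no bins):
# dose covering at least k voxels is the k-th hottest voxel dose
oracle_d_relative <- function(doses, percent) {
  n <- length(doses)
  desc <- sort(doses, decreasing = TRUE)
  k <- min(n, max(1, ceiling(percent / 100 * n - 1e-9)))
  desc[k]
}

oracle_d_absolute <- function(doses, cc, voxel_cc) {
  oracle_d_relative(doses, 100 * cc / (length(doses) * voxel_cc))
}

uniform_dose_bundle <- function(level_gy, geom = small_geom(8),
                                plan = "standard", brain_name = "Brain_NTCP") {
  m <- structure_mask(brain_name, geom, array(TRUE, geom$shape), "derived")
  set <- structure_set(geom, list(m))
  d <- dose_grid(geom, array(level_gy, geom$shape), plan_label = plan)
  plan_bundle(set, d, setNames(numeric(0), character(0)), "fixture")
}

# small, fast phantom for Monte-Carlo style tests
test_phantom_config <- function() {
  phantom_config(spacing = c(4, 4, 4), shape = c(48, 48, 48))
}

test_dose_config <- function() dose_model_config(noise_sd = 0.2)
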