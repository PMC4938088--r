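# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

with_cache <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# all-ECM block
ecm_block <- function(dims = c(16L, 16L, 16L), voxel = 0.4) {
  wallperm:::new_voxel_microstructure(array(0L, dims), voxel)
}

# a study-scale generated block (48^3 @ 0.4 um), cached per seed
fixture_block <- function(seed = 1L) {
  with_cache(paste0("block", seed), generate_medial_block(
    microstructure_params(grid_shape = c(48L, 48L, 48L), seed = seed)))
}

# a small, quick block for cheap tests (phi target 0.2 packs easily)
small_block <- function(seed = 1L) {
  with_cache(paste0("small", seed), generate_medial_block(
    microstructure_params(grid_shape = c(24L, 24L, 24L),
                          target_phi_smc = 0.2, seed = seed)))
}

# the printed aortic parameter set of the constitutive law
printed_constitutive <- function() {
  constitutive_params(k0 = 5.51, p1 = 0.52, p2 = 0.52, p3 = 0.95,
                      p4 = 55.12, m = 0.2, phi_s_ref = 0.6)
}

# laminate permeability field: two equal slabs stacked along `axis`
laminate_field <- function(k1, k2, axis, dims = c(16L, 16L, 16L),
                           voxel = 0.4) {
  kf <- array(k1, dims)
  idx <- rep(list(quote(expr = )), 3)
  idx[[axis]] <- (dims[axis] / 2 + 1):dims[axis]
  kf <- do.call(`[<-`, c(list(kf), idx, list(k2)))
  attr(kf, "voxel_size") <- voxel
  kf
}

effective_k <- function(field, axis) {
  -field$mean_velocity[axis] * field$mu / field$mean_pressure_gradient[axis]
}
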