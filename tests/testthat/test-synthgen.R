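test_that("parameter validation rejects impossible geometries", {
  expect_error(microstructure_params(grid_shape = c(4, 64, 64)), "grid_shape")
  expect_error(microstructure_params(voxel_size = 0), "voxel_size")
  expect_error(microstructure_params(target_phi_smc = 0.95), "target_phi_smc")
  expect_error(microstructure_params(min_ecm_gap = 0.1), "min_ecm_gap")
  expect_error(optics_params(attenuation_length = -1), "attenuation_length")
  expect_error(optics_params(smc_intensity = 2000), "smc_intensity")
})

test_that("zero target gives an all-ECM block", {
  b <- generate_medial_block(microstructure_params(
    grid_shape = c(8, 8, 8), target_phi_smc = 0))
  expect_true(all(b$labels == 0L))
  vf <- volume_fractions(b)
  expect_equal(vf$phi_smc, 0)
  expect_equal(vf$phi_ecm, 1)
})

test_that("generated blocks hit the physiological SMC fraction and stay percolating", {
  b <- fixture_block(1)
  phi <- mean(b$labels == 1L)
  expect_gte(phi, 0.31)
  expect_lte(phi, 0.37)
  # ECM must form a single connected component spanning the grid
  comp <- label_components(b$labels == 0L)
  expect_identical(max(comp), 1L)
  # cells occupy every radial layer: long axes lie in transverse planes
  expect_true(all(b$cells$a2 > b$cells$a1))
  expect_true(all(b$cells$a3 > b$cells$a1))
})

test_that("block generation is deterministic under a fixed seed", {
  p <- microstructure_params(grid_shape = c(24, 24, 24),
                             target_phi_smc = 0.2, seed = 7)
  b1 <- generate_medial_block(p)
  b2 <- generate_medial_block(p)
  expect_identical(b1$labels, b2$labels)
  expect_equal(b1$cells, b2$cells)
})

test_that("packing failure names the achieved fraction", {
  # a gap this large cannot reach 34 percent
  expect_error(
    generate_medial_block(microstructure_params(
      grid_shape = c(24, 24, 24), voxel_size = 0.4, min_ecm_gap = 3)),
    "achieved phi_SMC")
})

test_that("compaction preserves SMC voxels and rescales the fraction as 1/J", {
  b <- fixture_block(1)
  expect_identical(apply_compaction(b, 1), b)
  bc <- apply_compaction(b, 0.86)
  # incompressible cells: voxel count conserved within 2 percent
  expect_lt(abs(sum(bc$labels) / sum(b$labels) - 1), 0.02)
  # total volume scales by J (up to radial-extent rounding)
  expect_lt(abs(prod(dim(bc$labels)) / prod(dim(b$labels)) - 0.86), 0.02)
  # phi_SMC rises as 1/J
  ratio <- mean(bc$labels == 1L) / mean(b$labels == 1L)
  expect_lt(abs(ratio * 0.86 - 1), 0.03)
  # ECM gaps shrink
  expect_lt(radial_metrics(bc)$ecm_radial_thickness,
            radial_metrics(b)$ecm_radial_thickness)
})

test_that("over-compaction of incompressible cells errors", {
  b <- small_block(1)
  expect_error(apply_compaction(b, 0.4), "overlap")
  expect_error(apply_compaction(b, 1.2), "j_target")
})

test_that("fluorescence rendering is a labeled two-level image in the noiseless limit", {
  b <- small_block(1)
  o <- optics_params(attenuation_length = 1e9, noise_sd = 0,
                     ecm_intensity = 800, smc_intensity = 40)
  st <- generate_fluorescence_stack(b, o)
  expect_equal(sort(unique(as.vector(signif(st$intensities, 6)))),
               c(40, 800), tolerance = 1e-6)
  expect_true(all((st$intensities < 100) == (b$labels == 1L)))
})

test_that("depth attenuation follows the exponential definition", {
  b <- ecm_block(c(32, 8, 8), voxel = 1)   # 32 planes of pure ECM, 1 um apart
  att_len <- 15.5                          # depth of plane 16 centre
  o <- optics_params(attenuation_length = att_len, noise_sd = 0,
                     ecm_intensity = 1000, smc_intensity = 0)
  st <- generate_fluorescence_stack(b, o)
  # at depth == attenuation_length the ECM mean is ecm_intensity / e
  expect_equal(mean(st$intensities[16, , ]), 1000 / exp(1), tolerance = 1e-8)
})

test_that("stack generation is reproducible under a fixed seed", {
  b <- small_block(1)
  o <- optics_params(noise_sd = 0.1, seed = 11)
  expect_identical(generate_fluorescence_stack(b, o)$intensities,
                   generate_fluorescence_stack(b, o)$intensities)
})

test_that("bubble traces invert the conductance relation", {
  # Lp = 2.078e-12 m/s/Pa across A = 1e-4 m^2 at 100 mmHg in a 460 um
  # capillary advances the bubble at 1.667e-5 m/s
  tr <- generate_bubble_trace(true_lp = 2.078e-12, surface_area = 1e-4,
                              capillary_diameter = 460e-6, delta_p = 13332,
                              noise_sd = 0)
  slope <- coef(lm(displacement ~ time, tr))[[2]]
  expect_equal(slope, 1.667e-5, tolerance = 1e-3)
  # noiseless trace is perfectly linear
  expect_lt(max(abs(residuals(lm(displacement ~ time, tr)))),
            1e-12 * max(tr$displacement))
  # a zero-conductance wall leaves the bubble stationary
  tr0 <- generate_bubble_trace(true_lp = 0, surface_area = 1e-4, noise_sd = 0)
  expect_true(all(tr0$displacement == 0))
})

test_that("constitutive datasets evaluate the law and honour the closure bound", {
  pars <- printed_constitutive()
  d <- generate_constitutive_dataset(pars, j_grid = 1, noise_sd = 0)
  expect_equal(d$k, pars$k0, tolerance = 1e-12)  # f(1) = 1 by construction
  expect_error(
    generate_constitutive_dataset(pars, j_grid = c(0.5, 1), noise_sd = 0),
    "phi_s_ref")
  d1 <- generate_constitutive_dataset(pars, seq(0.65, 1, 0.05), 0.05, seed = 3)
  d2 <- generate_constitutive_dataset(pars, seq(0.65, 1, 0.05), 0.05, seed = 3)
  expect_identical(d1, d2)
})
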