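test_that("attenuation correction recovers the true decay length on clean stacks", {
  b <- fixture_block(1)
  o <- optics_params(attenuation_length = 80, noise_sd = 0,
                     smc_intensity = 0)
  st <- generate_fluorescence_stack(b, o)
  cor <- correct_attenuation(st)
  expect_lt(abs(cor$meta$fitted_attenuation_length / 80 - 1), 0.02)
  # corrected ECM plane means are flat across depth (<= 5 percent)
  planes <- apply(cor$intensities, 1, function(p) mean(p[p > 100]))
  expect_lt(diff(range(planes)) / mean(planes), 0.05)
})

test_that("a decay-free stack passes through unchanged", {
  b <- small_block(1)
  o <- optics_params(attenuation_length = 1e12, noise_sd = 0)
  st <- generate_fluorescence_stack(b, o)
  cor <- suppressWarnings(correct_attenuation(st))
  expect_equal(cor$intensities, st$intensities, tolerance = 1e-6)
})

test_that("degenerate attenuation fits warn and fall back to identity", {
  img <- array(rep(seq(100, 400, length.out = 8), times = 16), c(8, 4, 4))
  st <- wallperm:::new_image_stack(img, rep(1, 3))  # intensity RISES with depth
  expect_warning(cor <- correct_attenuation(st), "no depth decay")
  expect_identical(cor$intensities, img)
  expect_identical(cor$meta$fitted_attenuation_length, Inf)
  zero <- wallperm:::new_image_stack(array(0, c(8, 4, 4)), rep(1, 3))
  expect_error(correct_attenuation(zero), "all-zero")
  thin <- wallperm:::new_image_stack(array(1, c(3, 4, 4)), rep(1, 3))
  expect_error(correct_attenuation(thin), "4 depth planes")
})

test_that("axis alignment behaves as a rotation group", {
  set.seed(5)
  img <- array(runif(6 * 8 * 10), c(6, 8, 10))
  st <- wallperm:::new_image_stack(img, c(0.4, 0.5, 0.6))
  # identity
  expect_identical(align_axes(st, list())$intensities, img)
  expect_identical(align_axes(st, list(c(2, 0)))$intensities, img)
  # two quarter turns equal one half turn
  two <- align_axes(st, list(c(1, 1), c(1, 1)))
  one <- align_axes(st, list(c(1, 2)))
  expect_identical(two$intensities, one$intensities)
  expect_identical(two$voxel_size, one$voxel_size)
  # rotate then inverse-rotate restores the stack and its voxel sizes
  for (axis in 1:3) {
    back <- align_axes(st, list(c(axis, 1), c(axis, 3)))
    expect_identical(back$intensities, img)
    expect_identical(back$voxel_size, st$voxel_size)
    expect_identical(back$imaging_axis, st$imaging_axis)
    # a quarter turn permutes the two other voxel sizes
    quarter <- align_axes(st, list(c(axis, 1)))
    expect_setequal(quarter$voxel_size, st$voxel_size)
  }
  # four quarter turns are the identity
  expect_identical(align_axes(st, list(c(3, 4)))$intensities, img)
})

test_that("segmentation inverts the noiseless renderer exactly", {
  b <- fixture_block(1)
  o <- optics_params(attenuation_length = 120, noise_sd = 0)
  seg <- segment_smc(correct_attenuation(generate_fluorescence_stack(b, o)))
  expect_identical(seg$labels, b$labels)
  # manual threshold at the intensity floor labels everything ECM
  st <- generate_fluorescence_stack(b, o)
  seg0 <- segment_smc(st, method = "manual",
                      manual_threshold = min(st$intensities))
  expect_true(all(seg0$labels == 0L))
})

test_that("threshold perturbations of 3 percent move phi_SMC by under ~2 points", {
  b <- fixture_block(1)
  o <- optics_params(attenuation_length = 120, noise_sd = 0.05, seed = 2)
  cor <- correct_attenuation(generate_fluorescence_stack(b, o))
  thr <- attr(segment_smc(cor), "threshold")
  rng <- diff(range(cor$intensities))
  phi <- vapply(c(-0.03, 0, 0.03), function(d) {
    volume_fractions(segment_smc(cor, method = "manual",
                                 manual_threshold = thr + d * rng))$phi_smc
  }, numeric(1))
  expect_lt(max(abs(phi - phi[2])), 0.025)
})

test_that("a flat histogram triggers the unimodality warning", {
  img <- array(500 + rnorm(8^3, 0, 5), c(8, 8, 8))
  img[img < 0] <- 0
  st <- wallperm:::new_image_stack(img, rep(0.4, 3))
  expect_warning(segment_smc(st), "separation|unimodal")
})

test_that("volume fractions count voxels and always sum to one", {
  chk <- array(0L, c(8, 8, 8))
  chk[(slice.index(chk, 1) + slice.index(chk, 2) + slice.index(chk, 3)) %% 2 == 0] <- 1L
  cb <- wallperm:::new_voxel_microstructure(chk, 0.4)
  vf <- volume_fractions(cb)
  expect_equal(vf$phi_smc, 0.5)
  expect_equal(vf$phi_smc + vf$phi_ecm, 1)
  for (s in 1:3) {
    vf <- volume_fractions(small_block(s))
    expect_identical(vf$phi_smc + vf$phi_ecm, 1)
  }
})

test_that("radial metrics read off slab geometry exactly", {
  lab <- array(0L, c(20, 6, 6))
  lab[6:10, , ] <- 1L  # one slab, 5 voxels = 2 um wide at 0.4 um
  b <- wallperm:::new_voxel_microstructure(lab, 0.4)
  m <- radial_metrics(b)
  expect_equal(m$n_smc_layers_radial, 1)
  expect_equal(m$mean_smc_radial_width, 2)
  expect_equal(m$ecm_radial_thickness, 15 * 0.4)
  # compaction against a reference reports the imposed ECM loss
  ref <- fixture_block(1)
  cmp <- apply_compaction(ref, 0.86)
  m2 <- radial_metrics(cmp, reference = ref)
  # all volume loss is radial ECM: expected loss fraction of ECM thickness
  ecm_ref <- radial_metrics(ref)$ecm_radial_thickness
  expected <- 100 * (dim(ref$labels)[1] * 0.14 * 0.4) / ecm_ref
  expect_lt(abs(m2$ecm_compression_pct - expected), 2.5)
})

test_that("radial metrics are invariant to transverse translation", {
  b <- small_block(2)
  rolled <- b
  rolled$labels <- b$labels[, c(13:24, 1:12), c(20:24, 1:19)]
  expect_equal(radial_metrics(rolled), radial_metrics(b))
})

test_that("degenerate blocks are flagged", {
  expect_warning(m <- radial_metrics(ecm_block(c(8, 4, 4))), "no SMC")
  expect_equal(m$n_smc_layers_radial, 0)
  expect_true(is.na(m$mean_smc_radial_width))
  thin <- wallperm:::new_voxel_microstructure(array(0L, c(3, 8, 8)), 0.4)
  expect_error(radial_metrics(thin), "thinner")
})
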