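test_that("conductance is recovered from bubble kinematics", {
  # slope 1.667e-5 m/s in a 460 um capillary, A = 1e-4 m^2, 100 mmHg
  tr <- tibble::tibble(time = seq(0, 1500, length.out = 50))
  tr$displacement <- 1.667e-5 * tr$time
  attr(tr, "capillary_diameter") <- 460e-6
  attr(tr, "surface_area") <- 1e-4
  attr(tr, "delta_p") <- 13332
  out <- lp_from_trace(tr)
  expect_equal(out$lp, 2.078e-12, tolerance = 1e-3)
  expect_equal(out$r_wall, 1 / out$lp)
  # synthetic round trip at zero noise is exact
  tr2 <- generate_bubble_trace(true_lp = 3.2e-12, surface_area = 2e-4,
                               delta_p = mmHg_to_Pa(80), noise_sd = 0)
  expect_equal(lp_from_trace(tr2)$lp, 3.2e-12, tolerance = 1e-10)
})

test_that("stalled and reversed bubbles are flagged", {
  tr <- generate_bubble_trace(true_lp = 0, surface_area = 1e-4, noise_sd = 0)
  expect_warning(out <- lp_from_trace(tr), "zero slope")
  expect_identical(out$lp, 0)
  expect_identical(out$r_wall, Inf)
  bad <- tr
  bad$displacement <- -seq_len(nrow(bad)) * 1e-5
  expect_error(lp_from_trace(bad), "backwards")
})

test_that("medial thickness is an area-weighted mean", {
  expect_equal(weighted_medial_thickness(c(30, 30), c(0.5, 0.5)), 30)
  expect_equal(weighted_medial_thickness(c(25, 40), c(1, 0)), 25)
  # aorta 44.5 um over 46.2 percent of the area, iliacs 30 um over 53.8
  # percent reproduce the bifurcation mean 36.7 um
  expect_equal(weighted_medial_thickness(c(44.5, 30), c(0.462, 0.538)),
               36.7, tolerance = 1e-3)
  expect_error(weighted_medial_thickness(c(30, 40), c(0.6, 0.6)), "sum to 1")
})

test_that("the medial slab resistance follows mu T / k", {
  # the aortic numbers: k_ECM, T = 36.7 um, water at 37 C
  expect_equal(medial_resistance(1.32e-18, 36.7e-6, 6.9e-4), 1.918e10,
               tolerance = 1e-3)
  expect_equal(medial_resistance(1e-18, 2 * 36.7e-6),
               2 * medial_resistance(1e-18, 36.7e-6))
  expect_lt(medial_resistance(1, 36.7e-6), 1e-6)  # k -> inf: vanishing
  expect_error(medial_resistance(-1, 1e-6), "positive")
})

test_that("intimal resistance is the series remainder", {
  expect_equal(intimal_resistance(5e13, 0)$r_int, 5e13)
  expect_equal(intimal_resistance(5e13, 5e13)$r_int, 0)
  # a 40 percent medial share leaves 60 percent intimal
  out <- intimal_resistance(5e13, 0.4 * 5e13)
  expect_equal(out$r_int, 0.6 * 5e13)
  expect_false(out$inconsistent)
  # medial estimate above the measured wall: flagged, not an error
  bad <- intimal_resistance(5e13, 6e13)
  expect_true(bad$inconsistent)
  expect_lt(bad$r_int, 0)
})

test_that("crossover detection brackets constructed roots", {
  r_med <- function(p) 2e13 + 1e11 * (p - 40)
  r_int <- function(p) r_med(93) + 1e11 * (93 - p)  # crosses at exactly 93
  cross <- crossover_pressure(r_med, r_int)
  expect_equal(cross$crossover_mmHg, 93, tolerance = 1e-4)
  # parallel curves never cross
  none <- crossover_pressure(function(p) 2e13 + 0 * p,
                             function(p) 3e13 + 0 * p)
  expect_identical(nrow(none), 0L)
  # tangency is reported with a warning
  expect_warning(
    tang <- crossover_pressure(function(p) (p - 80)^2, function(p) 0 * p,
                               n_grid = 2001L),
    "tangency")
  expect_true(80 %in% round(tang$crossover_mmHg))
})

test_that("a constructed decomposition recovers its crossover within 1 mmHg", {
  mu <- 6.9e-4
  lp_fn <- function(p) (0.9 + 1.2 / (1 + exp((65 - p) / 8))) * 1e-12
  k_fn <- function(p) (0.45 + 0.65 / (1 + exp((p - 85) / 10))) * 1e-19
  # choose the thickness so R_MED(93) = R_WALL(93) / 2, i.e. crossover at 93
  thickness <- (1 / lp_fn(93) / 2) * k_fn(93) / mu
  pg <- seq(40, 120, by = 10)
  lp_data <- tibble::tibble(
    pressure = pg,
    lp = vapply(pg, function(p) {
      tr <- generate_bubble_trace(lp_fn(p), surface_area = 1e-4,
                                  delta_p = mmHg_to_Pa(p), noise_sd = 0)
      lp_from_trace(tr)$lp
    }, numeric(1)))
  k_data <- tibble::tibble(pressure = pg, k = k_fn(pg))
  prof <- resistance_profile(lp_data, k_data,
                             thickness_um = thickness * 1e6)
  cross <- attr(prof, "crossover")
  expect_identical(nrow(cross), 1L)
  expect_lt(abs(cross$crossover_mmHg - 93), 1)
  # series identity holds exactly at every pressure
  expect_equal(prof$r_wall, prof$r_med + prof$r_int)
  # bands bracket the central estimates
  expect_true(all(prof$r_med_lo <= prof$r_med & prof$r_med <= prof$r_med_hi))
  expect_true(all(prof$r_int_lo <= prof$r_int & prof$r_int <= prof$r_int_hi))
})

test_that("ECM-permeability bands rescale reciprocally and collapse at zero", {
  r <- tibble::tibble(pressure = c(80, 100), r_wall = c(5e13, 5e13),
                      r_med = c(2e13, 3e13))
  prof <- structure(
    dplyr::mutate(r, r_int = r_wall - r_med,
                  r_med_lo = r_med / 1.2, r_med_hi = r_med / 0.8,
                  r_int_lo = r_wall - r_med / 0.8,
                  r_int_hi = r_wall - r_med / 1.2,
                  inconsistent = FALSE),
    class = c("resistance_profile", class(r)))
  attr(prof, "kecm_band") <- 0.2
  collapsed <- kecm_uncertainty_band(prof, 0)
  expect_equal(collapsed$r_med_lo, collapsed$r_med)
  expect_equal(collapsed$r_med_hi, collapsed$r_med)
  again <- kecm_uncertainty_band(prof, 0.2)
  expect_equal(again$r_med_hi, prof$r_med / 0.8)
  expect_equal(again$r_med_lo, prof$r_med / 1.2)
  # subtraction preserves the band width
  expect_equal(again$r_int_hi - again$r_int_lo,
               again$r_med_hi - again$r_med_lo)
})
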