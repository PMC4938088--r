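test_that("the permeability law honours its reference state and closure bound", {
  pars <- printed_constitutive()
  # reference state: k(1) = k0 exactly
  expect_equal(constitutive_eval(1, pars), pars$k0, tolerance = 1e-12)
  # pore closure: k -> 0 as J -> phi_s_ref from above
  expect_lt(constitutive_eval(pars$phi_s_ref + 1e-9, pars), 1e-3)
  expect_error(constitutive_eval(0.6, pars), "no transmural flow")
  # multiplicative in k0
  pars2 <- constitutive_params(k0 = 2 * pars$k0, p1 = pars$p1, p2 = pars$p2,
                               p3 = pars$p3, p4 = pars$p4)
  J <- seq(0.65, 1, length.out = 50)
  expect_equal(constitutive_eval(J, pars2), 2 * constitutive_eval(J, pars),
               tolerance = 1e-12)
  # continuous and non-negative on (phi_s_ref, 1]
  Jfine <- seq(pars$phi_s_ref + 1e-6, 1, length.out = 2000)
  k <- constitutive_eval(Jfine, pars)
  expect_true(all(is.finite(k)) && all(k >= 0))
  expect_lt(max(abs(diff(k))), 0.05)  # no jumps on a fine grid
})

test_that("noiseless constitutive data are recovered exactly", {
  pars <- printed_constitutive()
  d <- generate_constitutive_dataset(pars, seq(0.65, 1, length.out = 60),
                                     noise_sd = 0)
  fit <- fit_constitutive(d, n_starts = 10, seed = 2)
  expect_lt(fit$rss, 1e-10)
  est <- tidy(fit)$estimate
  truth <- c(pars$k0, pars$p1, pars$p2, pars$p3, pars$p4)
  expect_equal(est, truth, tolerance = 1e-3)
})

test_that("noisy constitutive recovery stays within the protocol tolerances", {
  pars <- printed_constitutive()
  d <- generate_constitutive_dataset(
    pars, seq(pars$phi_s_ref + 0.05, 1, length.out = 200),
    noise_sd = 0.01, seed = 42)
  fit <- fit_constitutive(d, n_starts = 20, seed = 42)
  est <- setNames(tidy(fit)$estimate, tidy(fit)$term)
  expect_lt(abs(est[["k0"]] / pars$k0 - 1), 0.02)
  expect_lt(abs(est[["p1"]] / pars$p1 - 1), 0.05)
  expect_lt(abs(est[["p2"]] / pars$p2 - 1), 0.05)
  expect_lt(abs(est[["p3"]] / pars$p3 - 1), 0.05)
  expect_lt(abs(est[["p4"]] / pars$p4 - 1), 0.10)
  # the refit reproduces its training data to within the injected noise
  pred <- constitutive_eval(d$J, fit$params)
  rmse <- sqrt(mean((log(pred) - log(d$k))^2))
  expect_lt(rmse, 1.5 * 0.01)
})

test_that("data confined above the elbow leave the steep mode unidentified", {
  pars <- printed_constitutive()
  d <- generate_constitutive_dataset(pars, seq(0.97, 1, length.out = 30),
                                     noise_sd = 0.01, seed = 1)
  expect_warning(fit_constitutive(d, n_starts = 5, seed = 1),
                 "poorly identified")
})

test_that("sigmoid fits recover generating parameters from lightly noisy data", {
  set.seed(3)
  truth <- c(lower = 1, upper = 3, midpoint = 60, scale = 9)
  x <- seq(20, 120, length.out = 40)
  y <- truth[1] + (truth[2] - truth[1]) / (1 + exp((truth[3] - x) / truth[4]))
  d <- tibble::tibble(x = x, y = y * (1 + rnorm(40, 0, 0.01)))
  fit <- fit_sigmoid(d, x, y, seed = 5)
  est <- setNames(tidy(fit)$estimate, tidy(fit)$term)
  expect_true(all(abs(est / truth - 1) < 0.05))
  # fitted function agrees with predict()
  expect_equal(predict(fit, tibble::tibble(x = c(40, 90))),
               fit$fn(c(40, 90)))
})

test_that("degenerate and step-like inputs are handled", {
  d <- tibble::tibble(x = 1:10, y = rep(2, 10))
  expect_warning(fit <- fit_sigmoid(d, x, y), "degenerate")
  expect_true(fit$degenerate)
  # step data: midpoint lands between the plateaus
  ds <- tibble::tibble(x = c(1:5, 6:10), y = c(rep(0, 5), rep(1, 5)))
  fs <- fit_sigmoid(ds, x, y, seed = 2)
  expect_gt(fs$params[["midpoint"]], 5)
  expect_lt(fs$params[["midpoint"]], 6)
})

test_that("AICc penalizes parameters and reduces to AIC at large n", {
  # equal RSS: fewer parameters always preferred
  tab <- aicc_compare(tibble::tibble(model = c("small", "big"),
                                     rss = c(1, 1), n = c(20, 20),
                                     n_params = c(2, 4)))
  expect_identical(tab$model[1], "small")
  # correction term vanishes as n grows
  n <- 1e4
  aic <- n * log(1 / n) + 2 * 3
  expect_lt(abs(aicc(1, n, 3) - aic), 0.01)
  expect_error(aicc(1, 4, 4), "n > n_params")
})

test_that("model selection prefers the sigmoid on sigmoid-generated data", {
  set.seed(8)
  x <- seq(40, 120, length.out = 30)
  y <- 1 + 2 / (1 + exp((70 - x) / 6)) + rnorm(30, 0, 0.05)
  d <- tibble::tibble(x = x, y = y)
  fits <- list(sigmoid = fit_sigmoid(d, x, y, seed = 1),
               linear = polynomial_fit(d, x, y, 1),
               quadratic = polynomial_fit(d, x, y, 2),
               cubic = polynomial_fit(d, x, y, 3))
  tab <- aicc_compare(fits)
  expect_identical(tab$model[1], "sigmoid")
  expect_identical(tab$delta_aicc[1], 0)
  expect_true(all(diff(tab$aicc) >= 0))
})
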