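test_that("all three fitters recover noiseless truth to machine precision", {
  fx <- generate_fixture("tuning", list(A = 30, sigma = 15, B = 2))
  f <- fit_gaussian_tuning(fx$data)
  expect_equal(f$amplitude, 30, tolerance = 1e-6)
  expect_equal(f$sigma, 15, tolerance = 1e-6)
  expect_equal(f$offset, 2, tolerance = 1e-6)

  fx <- generate_fixture("crf", list(R_max = 40, C50 = 20, n = 3))
  f <- fit_hratio(fx$data)
  expect_equal(f$R_max, 40, tolerance = 1e-6)
  expect_equal(f$C50, 20, tolerance = 1e-6)
  expect_equal(f$n_exp, 3, tolerance = 1e-6)
  expect_true(f$good)

  fx <- generate_fixture("fi", list(g = 5, beta = 2, Ic = 1))
  f <- fit_powerlaw(fx$data)
  expect_equal(f$gain, 5, tolerance = 1e-6)
  expect_equal(f$beta, 2, tolerance = 1e-6)
  expect_equal(f$threshold, 1, tolerance = 1e-6)
})

test_that("tuning fit is equivariant under rotation of the data", {
  fx <- generate_fixture("tuning", list(A = 25, sigma = 12, B = 1, center = 0),
                         noise_sd = 0.5, seed = 3)
  f0 <- fit_gaussian_tuning(fx$data)
  rot <- fx$data
  rot$theta <- ((rot$theta + 30 + 90) %% 180) - 90
  f1 <- fit_gaussian_tuning(rot)
  expect_equal(f1$sigma, f0$sigma, tolerance = 1e-6)
  expect_equal(((f1$center - f0$center + 90) %% 180) - 90, 30, tolerance = 1e-6)
})

test_that("Monte-Carlo width recovery stays within a few percent under noise", {
  errs <- vapply(1:60, function(k) {
    fx <- generate_fixture("tuning", list(A = 30, sigma = 15, B = 2),
                           noise_sd = 0.05 * 30, seed = 1000 + k)
    f <- fit_gaussian_tuning(fx$data)
    abs(f$sigma - 15) / 15
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("Monte-Carlo H-ratio recovery is unbiased within tolerance", {
  est <- t(vapply(1:60, function(k) {
    fx <- generate_fixture("crf", list(R_max = 40, C50 = 20, n = 3),
                           noise_sd = 1.5, seed = 2000 + k)
    f <- suppressWarnings(fit_hratio(fx$data))
    c(f$C50, f$n_exp)
  }, numeric(2)))
  expect_equal(median(est[, 1]), 20, tolerance = 0.1)
  expect_equal(median(est[, 2]), 3, tolerance = 0.15)
})

test_that("strictly linear contrast data give a not-good fit with C50 out of range", {
  d <- data.frame(contrast = crf_contrast_grid(), response = 0.3 * crf_contrast_grid())
  f <- suppressWarnings(fit_hratio(d))
  expect_gt(f$C50, 90)
  expect_false(f$good)
  expect_gt(f$rel_error[["C50"]], 0.15)
})

test_that("bootstrap and curvature standard errors agree within a factor of two", {
  fx <- generate_fixture("crf", list(R_max = 40, C50 = 20, n = 3),
                         noise_sd = 1.5, seed = 7)
  f <- suppressWarnings(fit_hratio(fx$data))
  set.seed(8)
  bs <- suppressWarnings(bootstrap_hratio_se(fx$data, n_boot = 150))
  for (p in c("R_max", "C50", "n_exp")) {
    ratio <- bs[[p]] / f$se[[p]]
    expect_gt(ratio, 0.5)
    expect_lt(ratio, 2)
  }
})

test_that("flat tuning input is a degenerate-fit error and stays not-good with noise", {
  flat <- data.frame(theta = seq(-90, 85, by = 5), rate = 5)
  expect_error(fit_gaussian_tuning(flat), class = "ringcrf_degenerate_fit")
  # noise on a flat CRF never turns the fit good
  set.seed(5)
  ok <- vapply(1:20, function(k) {
    d <- data.frame(contrast = crf_contrast_grid(),
                    response = abs(rnorm(12, 5, 1)))
    suppressWarnings(fit_hratio(d))$good
  }, logical(1))
  expect_false(any(ok))
})

test_that("power-law fit restricted to a response range uses only that range", {
  x <- seq(0, 5, by = 0.25)
  y <- 4 * pmax(x - 1, 0)^1.5
  y[y > 20] <- 20 + 5 * (y[y > 20] - 20) # distort above the cap
  f <- fit_powerlaw(data.frame(I = x, rate = y), response_range = c(0, 20))
  expect_equal(f$beta, 1.5, tolerance = 1e-6)
  expect_error(fit_powerlaw(data.frame(I = 1:4, rate = 1:4)),
               class = "ringcrf_fit_error")
})
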