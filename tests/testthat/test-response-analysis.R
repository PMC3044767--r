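test_that("saturation classes follow the closed-form H-ratio evaluation", {
  grid <- crf_contrast_grid()
  mk <- function(C50, n, Rmax = 40) {
    data.frame(contrast = grid, response = Rmax * grid^n / (grid^n + C50^n))
  }
  d <- mk(10, 4)
  f <- fit_hratio(d)
  expect_equal(classify_saturation(f), "saturating")
  d <- mk(60, 1)
  f <- suppressWarnings(fit_hratio(d))
  expect_equal(classify_saturation(f), "non_saturating")
  # interior maximum 20% above the high-contrast response
  d <- mk(10, 4)
  d$response[6] <- 1.2 * d$response[nrow(d)]
  f <- suppressWarnings(fit_hratio(d))
  expect_equal(classify_saturation(f), "supersaturating")
})

test_that("saturation classification is scale invariant", {
  grid <- crf_contrast_grid()
  d <- data.frame(contrast = grid, response = 30 * grid^3 / (grid^3 + 18^3))
  for (k in c(0.1, 1, 50)) {
    ds <- transform(d, response = response * k)
    f <- fit_hratio(ds)
    expect_equal(classify_saturation(f), "saturating")
  }
})

test_that("invariance metric is exact on hand-computable cases", {
  expect_equal(invariance_metric(data.frame(contrast = c(2, 10), width = c(12, 12))), 0)
  expect_equal(invariance_metric(data.frame(contrast = c(2, 10), width = c(10, 11))), 0.1)
  d <- data.frame(contrast = c(2, 8, 30), width = c(10, 12, 9))
  expect_equal(invariance_metric(d), 0.2)
  expect_equal(invariance_metric(transform(d, width = width * 7)), 0.2)
  expect_error(invariance_metric(data.frame(contrast = 2, width = 10)),
               class = "ringcrf_parameter_error")
})

test_that("correlations are exact on deterministic data and need 10 points", {
  x <- 1:20
  d <- data.frame(R_max = x, C50 = 2 * x, n_exp = 21 - x, good = TRUE)
  cc <- correlate_params(d)
  expect_equal(cc$r[cc$pair == "R_max-C50"], 1, tolerance = 1e-12)
  expect_equal(cc$rho[cc$pair == "R_max-C50"], 1, tolerance = 1e-12)
  expect_equal(cc$r[cc$pair == "C50-n_exp"], -1, tolerance = 1e-12)
  expect_error(correlate_params(d[1:5, ]), class = "ringcrf_insufficient_data")
})

test_that("independent samples give small correlations at n = 400", {
  set.seed(11)
  over <- vapply(1:30, function(k) {
    d <- data.frame(R_max = rnorm(400), C50 = rnorm(400), n_exp = rnorm(400),
                    good = TRUE)
    max(abs(correlate_params(d)$r))
  }, numeric(1))
  expect_gt(mean(over < 0.15), 0.9)
})

test_that("a true correlation of 0.5 is recovered at n = 300", {
  set.seed(12)
  hit <- vapply(1:30, function(k) {
    z <- rnorm(300)
    x <- z + rnorm(300)
    y <- z + rnorm(300)
    d <- data.frame(R_max = rnorm(300), C50 = x, n_exp = y, good = TRUE)
    r <- correlate_params(d)$r[3]
    r > 0.4 && r < 0.6
  }, logical(1))
  expect_gt(mean(hit), 0.9)
})
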