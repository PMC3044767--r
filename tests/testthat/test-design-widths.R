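test_that("equal inputs and exponents give four equal widths with the closed form", {
  for (sigma in c(18, 25)) for (beta in c(1.5, 2, 3)) {
    w <- design_widths(sigma, sigma, beta, beta)
    expect_equal(as.vector(w), rep(sigma * sqrt(1 - 1 / beta), 4), tolerance = 1e-12)
  }
})

test_that("infinitely sharp outputs make projection widths equal the input widths", {
  w <- design_widths(20, 26, 1e9, 1e9)
  expect_equal(w["E", "E"], 20, tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(w["E", "I"], 20, tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(w["I", "E"], 26, tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(w["I", "I"], 26, tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("a sharper inhibitory transfer makes inhibitory projections broader", {
  w <- design_widths(22, 22, 1.5, 2.8)
  expect_gt(w["E", "I"], w["E", "E"])
  expect_gt(w["I", "I"], w["I", "E"])
})

test_that("infeasible conditions raise an explicit error naming the entry", {
  expect_error(design_widths(10, 30, 2, 1.05), class = "ringcrf_infeasible_widths")
  expect_error(design_widths(10, 30, 2, 1.05), regexp = "sigma_EI")
})

test_that("the condition checker is zero exactly at the designed widths", {
  m <- default_rate_model()
  res <- check_width_conditions(m$conn, m$drive, m$pops)
  expect_equal(res$residual, rep(0, 4), tolerance = 1e-12)
  # and non-zero when a width is perturbed
  m$conn$widths["I", "E"] <- m$conn$widths["I", "E"] / 2
  res2 <- check_width_conditions(m$conn, m$drive, m$pops)
  expect_gt(max(abs(res2$residual)), 1e-3)
})

test_that("simulated output width follows the sharpening law under the conditions", {
  # uncoupled: width = sigma_lgn / sqrt(beta) by the power-law sharpening
  m <- default_rate_model()
  m$conn$strengths[, ] <- 0
  tr <- integrate_ring(m$pops, m$conn, m$drive, I0 = 2, T = 300)
  f <- fit_gaussian_tuning(data.frame(theta = tr$theta$E, rate = tr$rates$E),
                           fix_offset = TRUE)
  expect_equal(f$sigma, ringcrf:::rad2deg(m$drive$sigma[["E"]]) / sqrt(m$pops$E$beta),
               tolerance = 1e-3)
})
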