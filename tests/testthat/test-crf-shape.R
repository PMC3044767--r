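test_that("no inhibition onto E gives a non-saturating curve", {
  m <- default_rate_model()
  m$conn$strengths["E", "I"] <- 0
  cs <- classify_crf_shape(m$pops, m$conn, m$drive, I0_max = 40)
  expect_equal(cs$class, "non_saturating")
  expect_lt(cs$margin, 0)
})

test_that("strong and weak inhibitory self-coupling give the two extreme regimes", {
  # weak I-to-I coupling: inhibition onto E wins at large input
  m_super <- default_rate_model(J_II = 3)
  cs <- classify_crf_shape(m_super$pops, m_super$conn, m_super$drive, I0_max = 60)
  expect_equal(cs$class, "supersaturating")
  expect_gt(cs$margin, 0)
  expect_true(cs$agreement)
  # strong I-to-I coupling: both populations grow monotonically
  m_non <- default_rate_model(J_II = 6)
  cs2 <- classify_crf_shape(m_non$pops, m_non$conn, m_non$drive, I0_max = 60)
  expect_equal(cs2$class, "non_saturating")
  expect_lt(cs2$margin, 0)
  expect_true(cs2$agreement)
})

test_that("numeric classification agrees with the closed-form criterion on a 2-D sweep", {
  for (J_II in c(2.5, 3.8, 5.2, 6.5)) {
    for (J_EI in c(4, 5.6, 7)) {
      m <- default_rate_model(J_II = J_II)
      m$conn$strengths["E", "I"] <- J_EI
      cs <- classify_crf_shape(m$pops, m$conn, m$drive, I0_max = 80)
      expect_true(cs$agreement,
                  label = sprintf("agreement at J_II=%.1f J_EI=%.1f (%s, margin %.3f)",
                                  J_II, J_EI, cs$class, cs$margin))
    }
  }
})

test_that("the rate-model CRF is well fitted by the H-ratio function", {
  m <- default_rate_model()
  crf <- rate_crf(m$pops, m$conn, m$drive, crf_contrast_grid())
  dE <- crf[crf$pop == "E", c("contrast", "rate")]
  names(dE) <- c("contrast", "response")
  f <- fit_hratio(dE)
  expect_true(is.finite(f$R_max))
  # relative residual over the full range is small (a good fit)
  expect_lt(sqrt(f$rss / sum(dE$response^2)), 0.1)
  # at small inputs the excitatory response grows as input^beta_E (the
  # feedback corrections vanish to leading order)
  I0s <- c(0.02, 0.04, 0.08, 0.16)
  nuE <- vapply(I0s, function(i0)
    solve_selfconsistent(m$pops, m$conn, m$drive, i0)$nu_E0, numeric(1))
  sl <- coef(lm(log(nuE) ~ log(I0s)))[2]
  expect_equal(unname(sl), m$pops$E$beta, tolerance = 0.1)
})

test_that("contrast 1% gives zero response through the logarithmic map", {
  m <- default_rate_model()
  crf <- rate_crf(m$pops, m$conn, m$drive, c(1, 2))
  expect_equal(crf$rate[crf$contrast == 1], c(0, 0))
  expect_error(rate_crf(m$pops, m$conn, m$drive, c(-2, 5)),
               class = "ringcrf_parameter_error")
})
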