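test_that("transfer function handles threshold and simple closed forms", {
  expect_equal(transfer(-1, population_params("E", gain = 2, beta = 1)), 0)
  expect_equal(transfer(0, population_params("E", gain = 2, beta = 1)), 0)
  expect_equal(transfer(3, population_params("E", gain = 2, beta = 1)), 6)
  expect_equal(transfer(0.5, population_params("E", gain = 1, beta = 2)), 0.25)
  p <- population_params("I", gain = 1.3, beta = 2.5, threshold = 1)
  expect_equal(transfer(1, p), 0)
  expect_true(all(diff(transfer(seq(1, 5, 0.1), p)) > 0))
})

test_that("LGN input peaks at the stimulus, vanishes at 1% and separates", {
  drv <- lgn_drive(sigma_E = 20, sigma_I = 25, nu0 = 2)
  th <- seq(-pi / 2, pi / 2, length.out = 51)
  stim <- 0.3
  inp <- lgn_input(th, stim, 40, drv, "E")
  expect_equal(th[which.max(inp)], stim, tolerance = pi / 50)
  expect_equal(lgn_input(stim, stim, 40, drv, "E"), lgn_peak_input(40, drv),
               tolerance = 1e-9)
  expect_equal(lgn_input(th, stim, 1, drv, "E"), rep(0, length(th)))
  r <- lgn_input(th, stim, 60, drv, "I") / lgn_input(th, stim, 10, drv, "I")
  expect_equal(r, rep(r[1], length(r)), tolerance = 1e-12)
  expect_error(lgn_input(0, 0, -5, drv), class = "ringcrf_parameter_error")
})

test_that("uncoupled network reduces to the pointwise transfer of the input", {
  m <- default_rate_model()
  m$conn$strengths[, ] <- 0
  ss <- solve_selfconsistent(m$pops, m$conn, m$drive, 2)
  expect_equal(ss$nu_E0, m$pops$E$gain * 2^m$pops$E$beta, tolerance = 1e-8)
  expect_equal(ss$nu_I0, m$pops$I$gain * 2^m$pops$I$beta, tolerance = 1e-8)
  expect_equal(solve_selfconsistent(m$pops, m$conn, m$drive, 0)$nu_E0, 0)

  tr <- integrate_ring(m$pops, m$conn, m$drive, theta_stim = 0, I0 = 2, T = 300)
  target <- transfer(2 * periodic_gaussian(ringcrf:::ring_grid(m$pops$E$N),
                                           m$drive$sigma[["E"]]), m$pops$E)
  expect_equal(as.vector(tr$rates$E), as.vector(target), tolerance = 1e-6)
})

test_that("self-consistency solver matches the ODE integration oracle", {
  m <- default_rate_model()
  for (I0 in c(1, 3, 6)) {
    ss <- solve_selfconsistent(m$pops, m$conn, m$drive, I0)
    expect_true(ss$converged)
    tr <- integrate_ring(m$pops, m$conn, m$drive, I0 = I0, T = 600)
    expect_false(tr$diverged)
    expect_equal(ss$nu_E0, max(tr$rates$E), tolerance = 0.01)
    expect_equal(ss$nu_I0, max(tr$rates$I), tolerance = 0.01)
    fE <- fit_gaussian_tuning(data.frame(theta = tr$theta$E, rate = tr$rates$E),
                              fix_offset = TRUE)
    expect_equal(fE$sigma, ss$sigma_E, tolerance = 0.01)
  }
})

test_that("suppression regime returns an exactly zero excitatory rate", {
  m <- default_rate_model(J_II = 0.8)
  # strong inhibition onto E at large input suppresses the E population
  ss_hi <- solve_selfconsistent(m$pops, m$conn, m$drive, 40)
  expect_true(ss_hi$converged)
  expect_identical(ss_hi$nu_E0, 0)
  expect_gt(ss_hi$nu_I0, 0)
})

test_that("rotating the stimulus rotates the steady profile", {
  m <- default_rate_model()
  N <- m$pops$E$N
  shift_idx <- 10 # rotate by 10 grid steps = 18 degrees
  tr0 <- integrate_ring(m$pops, m$conn, m$drive, theta_stim = 0, I0 = 3, T = 400)
  tr1 <- integrate_ring(m$pops, m$conn, m$drive, theta_stim = shift_idx * 180 / N,
                        I0 = 3, T = 400)
  rotated <- tr0$rates$E[((seq_len(N) - 1 - shift_idx) %% N) + 1]
  expect_equal(as.vector(tr1$rates$E), rotated, tolerance = 1e-9)
})

test_that("with design widths the normalized profiles are contrast invariant", {
  m <- default_rate_model()
  tr1 <- integrate_ring(m$pops, m$conn, m$drive, contrast = 3, T = 800)
  tr2 <- integrate_ring(m$pops, m$conn, m$drive, contrast = 90, T = 800)
  for (p in c("E", "I")) {
    p1 <- tr1$rates[[p]] / max(tr1$rates[[p]])
    p2 <- tr2$rates[[p]] / max(tr2$rates[[p]])
    expect_lt(max(abs(p1 - p2)), 1e-4)
  }
})

test_that("divergence is diagnosed, not fatal", {
  m <- default_rate_model(J_II = 4)
  m$conn$strengths["E", "E"] <- 40 # runaway recurrent excitation
  tr <- integrate_ring(m$pops, m$conn, m$drive, I0 = 10, T = 400, rate_cap = 1e4)
  expect_true(tr$diverged)
})
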