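test_that("ring weights are homogeneous and rotation symmetric", {
  net <- build_network(40, 40)
  W <- net$W
  isE <- net$pop == "E"
  # row sums independent of the target neuron within a population
  for (blk in list(W[isE, isE], W[isE, !isE], W[!isE, isE], W[!isE, !isE])) {
    rs <- rowSums(blk)
    expect_lt(diff(range(rs)), 1e-10)
  }
  # joint index rotation leaves the E-E block invariant
  WE <- W[isE, isE]
  k <- 7
  idx <- ((seq_len(40) - 1 + k) %% 40) + 1
  expect_equal(WE[idx, idx], WE, tolerance = 1e-12)
})

test_that("total inhibitory weight onto an E cell exceeds the E-to-E weight", {
  net <- small_network()
  isE <- net$pop == "E"
  wEI <- sum(net$W[which(isE)[1], !isE])
  wEE <- sum(net$W[which(isE)[1], isE])
  expect_gt(wEI, wEE)
})

test_that("trials are deterministic under a fixed seed", {
  net <- small_network()
  drv <- cbm_lgn_drive()
  t1 <- run_trial(net, drv, 0, 25, T = 300, transient = 100, seed = 5,
                  return_spikes = TRUE)
  t2 <- run_trial(net, drv, 0, 25, T = 300, transient = 100, seed = 5,
                  return_spikes = TRUE)
  expect_identical(t1$rate, t2$rate)
  expect_identical(attr(t1, "raster"), attr(t2, "raster"))
})

test_that("no contrast and no noise means no spikes; conductances stay positive", {
  net <- small_network()
  drv <- cbm_lgn_drive(I_base_E = 0, I_base_I = 0)
  tr <- run_trial(net, drv, 0, 1e-6 + 1, 0, T = 300, transient = 100, seed = 1)
  expect_equal(sum(tr$rate), 0)
  tr2 <- small_trial()
  expect_true(all(tr2$g_E >= 0))
  expect_true(all(tr2$g_I >= 0))
  expect_true(all(tr2$rate >= 0))
})

test_that("with synapses off, network rates match the single-neuron prediction", {
  syn0 <- synapse_params(strengths = matrix(0, 2, 2))
  net <- build_network(24, 24, syn0)
  drv <- cbm_lgn_drive()
  tr <- run_trial(net, drv, 0, 36, T = 1500, transient = 300, seed = 9)
  # compare the peak-orientation neurons with an isolated neuron at the
  # same LGN current, same noise level
  iE <- which(net$pop == "E")[which.min(abs(net$theta[net$pop == "E"]))]
  I_in <- ringcrf:::lgn_currents(net, drv, 0, 36)[iE]
  rates <- vapply(1:6, function(k) {
    set.seed(200 + k)
    simulate_neuron(channel_set("E"), I_in, cbm_default_noise(),
                    T = 1800, transient = 300)$rate
  }, numeric(1))
  expect_lt(abs(tr$rate[iE] - mean(rates)),
            3 * (sd(rates) + 1))
})

test_that("rotating the stimulus shifts the response profile", {
  net <- small_network()
  drv <- cbm_lgn_drive()
  t0 <- network_experiment(net, drv, 25, trials = 2, theta_stim = 0,
                           T = 500, transient = 200, seed = 21)
  t1 <- network_experiment(net, drv, 25, trials = 2, theta_stim = 45,
                           T = 500, transient = 200, seed = 21)
  f0 <- fit_gaussian_tuning(t0[t0$pop == "E", ], "theta", "rate")
  f1 <- fit_gaussian_tuning(t1[t1$pop == "E", ], "theta", "rate")
  expect_lt(abs(f0$center), 6)
  expect_lt(abs(f1$center - 45), 6)
  expect_equal(f0$sigma, f1$sigma, tolerance = 0.25)
})

test_that("voltage tuning is broader than spike tuning at a fixed contrast", {
  tr <- small_trial()
  d <- tr[tr$pop == "E", ]
  fr <- fit_gaussian_tuning(d, "theta", "rate")
  fv <- fit_gaussian_tuning(d, "theta", "V_clip")
  expect_gt(fv$sigma, fr$sigma)
})

test_that("effective rate prediction matches the simulated widths more closely than peaks", {
  net <- small_network()
  drv <- cbm_lgn_drive()
  pred <- effective_rate_prediction(net, drv, 25)
  expect_true(attr(pred, "converged"))
  sim <- small_trial()
  fp <- fit_gaussian_tuning(pred[pred$pop == "E", ], "theta", "rate")
  fs <- fit_gaussian_tuning(sim[sim$pop == "E", ], "theta", "rate")
  expect_equal(fp$sigma, fs$sigma, tolerance = 0.35)
  # zero coupling: prediction equals the fitted transfer of the LGN current
  syn0 <- synapse_params(strengths = matrix(0, 2, 2))
  net0 <- build_network(24, 24, syn0)
  p0 <- effective_rate_prediction(net0, drv, 25)
  fits <- cbm_default_fits()
  I_in <- ringcrf:::lgn_currents(net0, drv, 0, 25)
  manual <- ifelse(net0$pop == "E",
                   fits$E$gain * pmax(I_in - fits$E$threshold, 0)^fits$E$beta,
                   fits$I$gain * pmax(I_in - fits$I$threshold, 0)^fits$I$beta)
  expect_equal(p0$rate, manual, tolerance = 1e-6)
})
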