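test_that("a quiet neuron settles to rest and stays subthreshold", {
  for (p in c("E", "I")) {
    ch <- channel_set(p)
    sim <- simulate_neuron(ch, 0, 0, T = 800, transient = 300, record_V = 1)
    expect_length(sim$spikes, 0)
    v_late <- tail(sim$V$V, 100)
    expect_lt(diff(range(v_late)), 1e-6) # settled
    expect_lt(max(v_late), -55)
  }
})

test_that("suprathreshold firing is periodic and the two rate estimators agree", {
  ch <- channel_set("I")
  sim <- simulate_neuron(ch, 16, 0, T = 1700, transient = 200)
  isi <- diff(sim$spikes[sim$spikes > 700]) # after adaptation settles
  expect_lt(sd(isi) / mean(isi), 0.01)
  expect_lt(abs(1000 / mean(isi) - sim$rate), 1.5) # within one spike of the count
})

test_that("noise-free f-I is reproducible bit-for-bit and dt-convergent", {
  ch <- channel_set("E")
  a <- characterize(ch, c(7, 9), 0, T = 800, reps = 1, transient = 300)
  b <- characterize(ch, c(7, 9), 0, T = 800, reps = 1, transient = 300)
  expect_identical(a$rate, b$rate)
  fine <- characterize(ch, c(7, 9), 0, T = 800, reps = 1, transient = 300, dt = 0.025)
  expect_equal(a$rate, fine$rate, tolerance = 0.01)
})

test_that("fixed seed makes noisy simulations deterministic", {
  ch <- channel_set("E")
  s1 <- simulate_neuron(ch, 4, 2.4, T = 500, seed = 99, record_V = 1)
  s2 <- simulate_neuron(ch, 4, 2.4, T = 500, seed = 99, record_V = 1)
  expect_identical(s1$V$V, s2$V$V)
  expect_identical(s1$spikes, s2$spikes)
})

test_that("excitatory profile has lower rheobase, lower gain and stronger adaptation", {
  rhE <- find_rheobase(channel_set("E"), c(0, 16), T = 1200, transient = 300, tol = 0.05)
  rhI <- find_rheobase(channel_set("I"), c(0, 16), T = 1200, transient = 300, tol = 0.05)
  expect_lt(rhE, rhI)
  # high-input gain: rate change per unit current well above threshold
  gE <- diff(characterize(channel_set("E"), rhE + c(2, 3), 0, T = 1500, reps = 1)$rate)
  gI <- diff(characterize(channel_set("I"), rhI + c(2, 3), 0, T = 1500, reps = 1)$rate)
  expect_lt(gE, gI)
  # adaptation: late-to-early rate ratio lower for E (window-based, robust
  # to the doublet firing patterns near threshold)
  adapt <- function(ch, rh) {
    sim <- simulate_neuron(ch, rh + 4, 0, T = 1500, transient = 0)
    sum(sim$spikes > 1200) / max(sum(sim$spikes <= 300), 1)
  }
  aE <- adapt(channel_set("E"), rhE)
  aI <- adapt(channel_set("I"), rhI)
  expect_lt(aE, aI)
  expect_lt(aE, 1)
})

test_that("excitatory noise-free onset is continuous (type I)", {
  ch <- channel_set("E")
  rh <- find_rheobase(ch, c(0, 16), T = 6000, transient = 1000, tol = 5e-4)
  just_above <- simulate_neuron(ch, rh + 0.01, 0, T = 12000, transient = 1000)
  expect_lt(just_above$rate, 2) # no jump > 2 Hz across rheobase
  expect_gt(just_above$rate, 0)
})

test_that("voltage-SD calibration brackets are monotone and reproducible", {
  ch <- channel_set("E")
  sds <- vapply(c(0.8, 1.6, 3.2), function(s) {
    set.seed(31)
    simulate_neuron(ch, 0, s, T = 1500, transient = 300)$sd_V
  }, numeric(1))
  expect_true(all(diff(sds) > 0))
  set.seed(32)
  sd0 <- simulate_neuron(ch, 0, 0, T = 1200, transient = 300)$sd_V
  expect_lt(sd0, 0.1)
  # the packaged default reproduces the 3-4 mV target under a fresh seed
  set.seed(77)
  sd_cal <- simulate_neuron(ch, 0, cbm_default_noise(), T = 3500, transient = 500)$sd_V
  expect_gt(sd_cal, 2.5)
  expect_lt(sd_cal, 4.5)
})

test_that("effective transfer reduces to the fitted law and shifts subtractively", {
  fit <- structure(list(gain = 5, beta = 1.5, threshold = 2, offset = 0,
                        has_offset = FALSE), class = "powerlaw_fit")
  I <- seq(0, 8, by = 0.5)
  expect_equal(effective_transfer(I, 0, fit, 15), predict(fit, I))
  r1 <- effective_transfer(I, 0.1, fit, 15)
  r2 <- effective_transfer(I, 0.2, fit, 15)
  expect_true(all(r2 <= r1))
})

test_that("blow-up inputs raise an integration error naming dt", {
  ch <- channel_set("E")
  expect_error(simulate_neuron(ch, 1e5, 0, T = 50),
               regexp = "dt")
  expect_error(simulate_neuron(ch, 2, 0, T = 100, dt = 0.2))
})
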