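# Shared fixtures for the test suite. Heavy simulations are computed lazily
# and cached so several test files can reuse the same run.

.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .cache)) {
    assign(name, force(expr), envir = .cache)
  }
  get(name, envir = .cache)
}

# A small spiking hypercolumn and a short trial at mid contrast.
small_network <- function() cached("small_net", build_network(80, 80))

small_trial <- function() cached("small_trial", {
  run_trial(small_network(), cbm_lgn_drive(), theta_stim = 0, contrast = 25,
            T = 600, transient = 300, seed = 42)
})

# Reduced-scale tuning/CRF experiment shared by the acceptance blocks on
# contrast invariance, CRF ordering and effective conductance.
acceptance_network_run <- function() cached("acc_net_run", {
  net <- build_network(192, 192)
  drv <- cbm_lgn_drive()
  contrasts <- c(1, 2, 3, 4.5, 6.5, 9, 13, 18, 25, 36, 50, 64)
  resp <- network_experiment(net, drv, contrasts, trials = 2,
                             T = 1200, transient = 400, seed = 11)
  measure_responses(resp, window_deg = 8)
})

acceptance_fi_E <- function() cached("acc_fi_E",
  fi_protocol(channel_set("E"), seed = 1, reps = 10))

acceptance_fi_I <- function() cached("acc_fi_I",
  fi_protocol(channel_set("I"), seed = 2, reps = 10))
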