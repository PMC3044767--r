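#' Calibrated single-neuron transfer constants
#'
#' The threshold power-law constants fitted to the noisy f-I curves of the
#' two channel profiles with the package pipeline ([characterize()] +
#' [fit_powerlaw()] at the calibrated noise level), together with the
#' leak-shift slope `V_c` from [gl_shift_experiment()]. These feed the
#' projection-width conditions and the effective rate model; tests recompute
#' them from scratch at reduced resolution.
#'
#' @return A list with elements `E` and `I` (each `gain`, `beta`,
#'   `threshold`) and `V_c_E`, `V_c_I` (mV).
#' @export
cbm_default_fits <- function() {
  list(E = list(gain = 6.0, beta = 1.47, threshold = 2.65),
       I = list(gain = 5.9, beta = 2.2, threshold = 8.8),
       V_c_E = 15.2, V_c_I = 18.7)
}

#' Synaptic parameters of the spiking hypercolumn
#'
#' Ring-weighted conductance synapses: the integrated conductance of a
#' single synapse from population B onto population A is `strengths[A, B] /
#' N_B` (mS ms/cm^2) times the pi-periodic Gaussian of the preferred-
#' orientation difference; each presynaptic spike injects that integral
#' through a difference-of-exponentials kernel.
#'
#' @param strengths 2x2 matrix of integrated conductance densities
#'   (mS ms/cm^2), target rows `E`/`I`, source columns.
#' @param widths 2x2 matrix of projection widths in degrees; defaults to the
#'   contrast-invariance conditions ([design_widths()]) evaluated at the
#'   fitted single-neuron exponents and the default LGN tuning widths.
#' @param V_rev_E,V_rev_I Synaptic reversal potentials, mV.
#' @param tau_rise,tau_decay Kernel time constants, ms.
#' @return A `synapse_params` object (widths stored in radians).
#' @export
synapse_params <- function(strengths = NULL, widths = NULL,
                           V_rev_E = 0, V_rev_I = -80,
                           tau_rise = 1, tau_decay = 3) {
  dn <- list(c("E", "I"), c("E", "I"))
  if (is.null(strengths)) {
    strengths <- matrix(c(1, 1, 4, 2.6), 2, 2, dimnames = dn)
  }
  if (is.null(widths)) {
    fits <- cbm_default_fits()
    drv <- cbm_lgn_drive()
    widths <- design_widths(rad2deg(drv$sigma[["E"]]), rad2deg(drv$sigma[["I"]]),
                            fits$E$beta, fits$I$beta)
  }
  if (tau_decay <= tau_rise || tau_rise <= 0) {
    abort("Need tau_decay > tau_rise > 0.", class = "ringcrf_parameter_error")
  }
  if (any(strengths < 0)) abort("Synaptic strengths must be >= 0.", class = "ringcrf_parameter_error")
  widths <- as.matrix(widths)
  widths_rad <- deg2rad(widths)
  dimnames(strengths) <- dn
  dimnames(widths_rad) <- dn
  structure(list(strengths = strengths, widths = widths_rad,
                 V_rev_E = V_rev_E, V_rev_I = V_rev_I,
                 tau_rise = tau_rise, tau_decay = tau_decay),
            class = "synapse_params")
}

#' LGN drive for the conductance-based network
#'
#' Feedforward current onto each neuron: an untuned, contrast-independent
#' baseline holding each population near its (noise-smoothed) current
#' threshold, plus an orientation-tuned modulation whose amplitude follows
#' a hyperbolic-ratio contrast dependence:
#' \deqn{I(\theta, C) = I_{base} + \nu_{max}\,\frac{C^n}{C^n + C_{50}^n}\, G(\theta - \theta_s;\sigma).}
#' The baseline stands for the background (spontaneous) thalamocortical
#' drive; it sits below the noise-free rheobase, so without noise and at
#' vanishing contrast the network is silent, while with the calibrated
#' noise it produces a low spontaneous rate and keeps the contrast
#' modulation inside the power-law region of the transfer function.
#'
#' @param nu_max Peak drive onto the excitatory population at saturating
#'   contrast, uA/cm^2.
#' @param C50_input Semi-saturation contrast of the LGN input, percent.
#' @param n_input Steepness exponent of the LGN input.
#' @param sigma_E,sigma_I Input tuning widths, degrees.
#' @param I_ratio Ratio of the peak modulation amplitude onto the
#'   inhibitory population to that onto the excitatory one (the inhibitory
#'   cells' higher current threshold and gain require a stronger
#'   feedforward drive for them to track the LGN contrast dependence).
#' @param I_base_E,I_base_I Untuned baseline currents per population,
#'   uA/cm^2.
#' @return A `cbm_lgn_drive` object (widths in radians).
#' @export
cbm_lgn_drive <- function(nu_max = 7, C50_input = 17.2, n_input = 1.4,
                          sigma_E = 22, sigma_I = 24, I_ratio = 1.7,
                          I_base_E = 3.4, I_base_I = 9.6) {
  if (nu_max < 0 || C50_input <= 0 || n_input <= 0 || I_ratio <= 0) {
    abort("Invalid LGN drive parameters.", class = "ringcrf_parameter_error")
  }
  structure(list(nu_max = nu_max, C50 = C50_input, n = n_input,
                 sigma = c(E = deg2rad(sigma_E), I = deg2rad(sigma_I)),
                 I_ratio = I_ratio,
                 I_base = c(E = I_base_E, I = I_base_I)),
            class = "cbm_lgn_drive")
}

#' Peak LGN current at a contrast
#' @param contrast Contrast in percent.
#' @param drive A [cbm_lgn_drive()].
#' @param nu_max,C50,n Optional per-neuron overrides.
#' @export
cbm_lgn_peak <- function(contrast, drive, nu_max = drive$nu_max,
                         C50 = drive$C50, n = drive$n) {
  nu_max * contrast^n / (contrast^n + C50^n)
}

#' Build the spiking hypercolumn
#'
#' Deterministic all-to-all ring weights
#' `w_AB(i, j) = (G_AB / N_B) G(theta_i - theta_j; sigma_AB)` with preferred
#' orientations uniform on the half-circle. Per-neuron heterogeneity in the
#' adaptation conductance, leak reversal and LGN parameters is attached via
#' `het` (one row per neuron, as produced by [sample_population()]).
#'
#' @param N_E,N_I Population sizes.
#' @param syn A [synapse_params()].
#' @param channels_E,channels_I Channel profiles.
#' @param het Optional heterogeneity table with columns `pop`, `idx` and any
#'   of `g_Ks`, `E_L`, `C50`, `n_exp`, `nu_max`.
#' @return A `cbm_network` object.
#' @export
build_network <- function(N_E = 400, N_I = 400, syn = synapse_params(),
                          channels_E = channel_set("E"),
                          channels_I = channel_set("I"), het = NULL) {
  theta <- c(ring_grid(N_E), ring_grid(N_I))
  pop <- rep(c("E", "I"), c(N_E, N_I))
  N <- N_E + N_I
  pars <- rbind(
    matrix(channel_vector(channels_E), N_E, 9, byrow = TRUE),
    matrix(channel_vector(channels_I), N_I, 9, byrow = TRUE))
  lgn <- tibble(C50 = rep(NA_real_, N), n_exp = NA_real_, nu_max = NA_real_)
  if (!is.null(het)) {
    idx <- ifelse(het$pop == "E", het$idx, N_E + het$idx)
    if ("g_Ks" %in% names(het)) pars[idx, 9] <- het$g_Ks
    if ("E_L" %in% names(het)) pars[idx, 2] <- het$E_L
    for (cl in c("C50", "n_exp", "nu_max")) {
      if (cl %in% names(het)) lgn[[cl]][idx] <- het[[cl]]
    }
  }
  # ring weight matrix: column j holds the outgoing weights of neuron j
  W <- matrix(0, N, N)
  Nsrc <- c(E = N_E, I = N_I)
  for (A in c("E", "I")) for (B in c("E", "I")) {
    ti <- theta[pop == A]; tj <- theta[pop == B]
    d <- outer(ti, tj, "-")
    blk <- syn$strengths[A, B] / Nsrc[[B]] *
      matrix(periodic_gaussian(as.vector(d), syn$widths[A, B]), length(ti))
    W[pop == A, pop == B] <- blk
  }
  structure(list(N_E = N_E, N_I = N_I, theta = theta, pop = pop,
                 pars = pars, W = W, syn = syn, lgn_het = lgn,
                 channels = list(E = channels_E, I = channels_I)),
            class = "cbm_network")
}

#' @export
print.cbm_network <- function(x, ...) {
  cat(sprintf("Spiking hypercolumn: %d E + %d I neurons; widths (deg): EE %.1f EI %.1f IE %.1f II %.1f\n",
              x$N_E, x$N_I,
              rad2deg(x$syn$widths["E", "E"]), rad2deg(x$syn$widths["E", "I"]),
              rad2deg(x$syn$widths["I", "E"]), rad2deg(x$syn$widths["I", "I"])))
  invisible(x)
}

# Per-neuron LGN current for a stimulus (theta_stim in radians)
lgn_currents <- function(network, drive, theta_stim, contrast) {
  n <- length(network$theta)
  C50 <- ifelse(is.na(network$lgn_het$C50), drive$C50, network$lgn_het$C50)
  nexp <- ifelse(is.na(network$lgn_het$n_exp), drive$n, network$lgn_het$n_exp)
  numax <- ifelse(is.na(network$lgn_het$nu_max), drive$nu_max, network$lgn_het$nu_max)
  ratio <- if (is.null(drive$I_ratio)) 1 else drive$I_ratio
  numax <- numax * ifelse(network$pop == "I", ratio, 1)
  peak <- numax * contrast^nexp / (contrast^nexp + C50^nexp)
  sig <- ifelse(network$pop == "E", drive$sigma[["E"]], drive$sigma[["I"]])
  base <- if (is.null(drive$I_base)) 0 else
    unname(drive$I_base[ifelse(network$pop == "E", "E", "I")])
  tune <- numeric(n)
  for (s in unique(sig)) {
    sel <- sig == s
    tune[sel] <- periodic_gaussian(network$theta[sel] - theta_stim, s)
  }
  base + peak * tune
}

#' Run one trial of the spiking hypercolumn
#'
#' Integrates all neurons with the double-exponential conductance synapses,
#' constant orientation-tuned LGN currents and per-neuron white noise, and
#' returns window-averaged statistics per neuron.
#'
#' @param network A [build_network()] object.
#' @param drive A [cbm_lgn_drive()].
#' @param theta_stim Stimulus orientation, degrees.
#' @param contrast Contrast in percent, in (0, 100].
#' @param sigma_noise White-noise amplitude.
#' @param T Analysis window, ms.
#' @param transient Discarded initial interval, ms.
#' @param dt Time step, ms.
#' @param seed RNG seed (two runs with the same seed give identical rasters).
#' @param return_spikes Attach the spike raster (`neuron`, `time_ms`).
#' @param clip Voltage clipping level, mV.
#' @return A tibble with one row per neuron: `neuron`, `pop`, `theta`
#'   (degrees), `rate` (Hz), `V_clip` (mV), `g_E`, `g_I`, `g_tot`
#'   (time-averaged synaptic conductances, mS/cm^2). The raster, when
#'   requested, is in `attr(, "raster")`.
#' @export
run_trial <- function(network, drive, theta_stim = 0, contrast,
                      sigma_noise = cbm_default_noise(), T = 1500,
                      transient = 500, dt = 0.05, seed = 1,
                      return_spikes = FALSE, clip = -50) {
  if (contrast <= 0 || contrast > 100) {
    abort("`contrast` must be in (0, 100].", class = "ringcrf_parameter_error")
  }
  I_lgn <- lgn_currents(network, drive, deg2rad(theta_stim), contrast)
  set.seed(seed)
  res <- cbm_network_run(network$pars, as.integer(network$pop == "E"),
                         network$W, network$syn$V_rev_E, network$syn$V_rev_I,
                         network$syn$tau_rise, network$syn$tau_decay,
                         I_lgn, sigma_noise, transient + T, dt, transient,
                         clip, return_spikes)
  out <- tibble(neuron = seq_along(network$theta), pop = network$pop,
                theta = rad2deg(network$theta), rate = res$rate,
                V_clip = res$mean_V_clipped, sd_V = res$sd_V,
                g_E = res$mean_gE, g_I = res$mean_gI,
                g_tot = res$mean_gE + res$mean_gI)
  if (return_spikes) attr(out, "raster") <- as_tibble(res$raster)
  out
}

#' Measure network responses over a contrast grid
#'
#' Runs `trials` noise realizations per contrast (single stimulus
#' orientation; the ring read-out yields the full tuning curve) and averages
#' the per-neuron statistics.
#'
#' @inheritParams run_trial
#' @param contrasts Contrast grid, percent.
#' @param trials Trials per contrast.
#' @param seed Base seed; trial `k` at contrast index `j` uses
#'   `seed + 1000 * j + k`.
#' @return A `network_responses` tibble: per-neuron rows with `contrast`
#'   column added, averaged over trials.
#' @export
network_experiment <- function(network, drive, contrasts, trials = 3,
                               theta_stim = 0,
                               sigma_noise = cbm_default_noise(), T = 1500,
                               transient = 500, dt = 0.05, seed = 1) {
  rows <- list()
  for (j in seq_along(contrasts)) {
    acc <- NULL
    for (k in seq_len(trials)) {
      tr <- run_trial(network, drive, theta_stim, contrasts[j], sigma_noise,
                      T, transient, dt, seed = seed + 1000 * j + k)
      if (is.null(acc)) {
        acc <- tr
      } else {
        for (cl in c("rate", "V_clip", "g_E", "g_I", "g_tot")) {
          acc[[cl]] <- acc[[cl]] + tr[[cl]]
        }
      }
    }
    for (cl in c("rate", "V_clip", "g_E", "g_I", "g_tot")) {
      acc[[cl]] <- acc[[cl]] / trials
    }
    acc$contrast <- contrasts[j]
    rows[[j]] <- acc
  }
  out <- bind_rows(rows)
  attr(out, "theta_stim") <- theta_stim
  attr(out, "trials") <- trials
  class(out) <- c("network_responses", class(out))
  out
}

#' Tuning-curve and CRF measurements from network responses
#'
#' Fits pi-periodic Gaussians (free offset) to the spike-rate and clipped-
#' voltage tuning curves at every contrast, assembles the population CRFs
#' from the fitted amplitudes and fits the hyperbolic-ratio function to
#' them, and reports the mean total synaptic conductance of neurons at the
#' stimulated orientation per contrast.
#'
#' @param resp A [network_experiment()] result.
#' @param window_deg Half-width of the orientation window (degrees) for the
#'   conductance read-out at the stimulated orientation.
#' @return A list: `tuning` (per pop x contrast: amplitude, width, offset,
#'   voltage width; the width is `NA` where the fitted amplitude does not
#'   exceed twice its standard error), `crf` (per pop: [fit_hratio()]
#'   object), `crf_data`,
#'   `conductance` (per pop x contrast mean `g_tot`), `invariance` (per
#'   pop: max fractional width deviation).
#' @export
measure_responses <- function(resp, window_deg = 10) {
  th0 <- attr(resp, "theta_stim")
  if (is.null(th0)) th0 <- 0
  tuning <- list()
  cond <- list()
  for (p in c("E", "I")) {
    for (C in unique(resp$contrast)) {
      d <- resp[resp$pop == p & resp$contrast == C, ]
      f <- try(fit_gaussian_tuning(d, "theta", "rate"), silent = TRUE)
      fv <- try(fit_gaussian_tuning(d, "theta", "V_clip"), silent = TRUE)
      dth <- (d$theta - th0 + 90) %% 180 - 90
      sel <- abs(dth) <= window_deg
      # a width is only reported when the tuned modulation is detectable:
      # the fitted amplitude must exceed twice its standard error
      ok <- !inherits(f, "try-error") &&
        is.finite(f$se[["amplitude"]]) &&
        f$amplitude > 2 * f$se[["amplitude"]]
      tuning[[length(tuning) + 1L]] <- tibble(
        pop = p, contrast = C,
        amplitude = if (inherits(f, "try-error")) NA_real_ else f$amplitude,
        width = if (ok) f$sigma else NA_real_,
        offset = if (inherits(f, "try-error")) NA_real_ else f$offset,
        v_width = if (inherits(fv, "try-error")) NA_real_ else fv$sigma,
        peak_rate = mean(d$rate[sel]))
      cond[[length(cond) + 1L]] <- tibble(pop = p, contrast = C,
                                          g_tot = mean(d$g_tot[sel]),
                                          g_E = mean(d$g_E[sel]),
                                          g_I = mean(d$g_I[sel]))
    }
  }
  tuning <- bind_rows(tuning)
  cond <- bind_rows(cond)
  crf <- list(); crf_data <- list()
  for (p in c("E", "I")) {
    d <- tuning[tuning$pop == p & is.finite(tuning$amplitude), ]
    cd <- tibble(contrast = d$contrast, response = d$amplitude)
    crf_data[[p]] <- cd
    crf[[p]] <- if (nrow(cd) >= 5) suppressWarnings(fit_hratio(cd)) else NULL
  }
  invariance <- vapply(c("E", "I"), function(p) {
    d <- tuning[tuning$pop == p & is.finite(tuning$width), ]
    if (nrow(d) < 2) return(NA_real_)
    invariance_metric(d, "contrast", "width")
  }, numeric(1))
  list(tuning = tuning, crf = crf, crf_data = crf_data,
       conductance = cond, invariance = invariance)
}

#' Effective rate-model prediction of the network steady state
#'
#' Solves, on the ring, the self-consistent effective rate equations in
#' which each population's spiking nonlinearity is its fitted threshold
#' power law, the synaptic conductance load enters as a leak-proportional
#' threshold shift `V_c * dG`, and the synaptic current is evaluated at the
#' resting potential:
#' \deqn{\nu_A(\theta) = g_A\lfloor I_{lgn} + \sum_B \Delta G_{AB}(V_{rev,B} - V_{rest}) - I_c - V_c \Delta G_A\rfloor_+^{\beta_A}}
#' with \eqn{\Delta G_{AB}} the ring convolution of the presynaptic rates
#' with the synaptic weights (conductance per spike times rate).
#'
#' @param network A [build_network()] object.
#' @param drive A [cbm_lgn_drive()].
#' @param contrast Contrast, percent.
#' @param theta_stim Stimulus orientation, degrees.
#' @param fits Single-neuron constants, as from [cbm_default_fits()].
#' @param damping Fixed-point damping factor.
#' @param tol Convergence tolerance on rates, Hz.
#' @param max_iter Iteration cap.
#' @return A tibble per neuron: `pop`, `theta`, `rate` (Hz), `dG`
#'   (mS/cm^2), plus convergence attributes.
#' @export
effective_rate_prediction <- function(network, drive, contrast,
                                      theta_stim = 0,
                                      fits = cbm_default_fits(),
                                      damping = 0.3, tol = 1e-8,
                                      max_iter = 5000) {
  I_lgn <- lgn_currents(network, drive, deg2rad(theta_stim), contrast)
  isE <- network$pop == "E"
  Vrest <- c(E = cbm_resting_V(channel_vector(network$channels$E), 500, 0.05),
             I = cbm_resting_V(channel_vector(network$channels$I), 500, 0.05))
  g <- ifelse(isE, fits$E$gain, fits$I$gain)
  beta <- ifelse(isE, fits$E$beta, fits$I$beta)
  Ic <- ifelse(isE, fits$E$threshold, fits$I$threshold)
  Vc <- ifelse(isE, fits$V_c_E, fits$V_c_I)
  Vr <- ifelse(isE, Vrest[["E"]], Vrest[["I"]])
  WE <- network$W[, isE, drop = FALSE]
  WI <- network$W[, !isE, drop = FALSE]
  nu <- rep(0, length(I_lgn))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # rates in spikes/ms so that (weight * rate) is a conductance in mS/cm^2
    dGE <- as.vector(WE %*% (nu[isE] / 1000))
    dGI <- as.vector(WI %*% (nu[!isE] / 1000))
    dG <- dGE + dGI
    I_net <- I_lgn + dGE * (network$syn$V_rev_E - Vr) +
      dGI * (network$syn$V_rev_I - Vr)
    target <- g * pmax(I_net - Ic - Vc * dG, 0)^beta
    nu_new <- (1 - damping) * nu + damping * target
    if (anyNA(nu_new) || max(nu_new) > 1e4) {
      break
    }
    if (max(abs(nu_new - nu)) < tol) {
      nu <- nu_new
      converged <- TRUE
      break
    }
    nu <- nu_new
  }
  dGE <- as.vector(WE %*% (nu[isE] / 1000))
  dGI <- as.vector(WI %*% (nu[!isE] / 1000))
  out <- tibble(neuron = seq_along(nu), pop = network$pop,
                theta = rad2deg(network$theta), rate = nu, dG = dGE + dGI)
  attr(out, "converged") <- converged
  out
}
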