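#' Ionic channel profile of a conductance-based neuron
#'
#' Maximal conductance densities (mS/cm^2) and reversal potentials (mV) for
#' the leak, transient sodium, persistent sodium, delayed-rectifier
#' potassium, A-type potassium and slow (adaptation) potassium currents.
#' The excitatory profile has a lower spike threshold and much stronger
#' adaptation (`g_Ks`) than the inhibitory one; the two profiles differ only
#' in these densities.
#'
#' @param profile `"E"` (regular-spiking excitatory) or `"I"`
#'   (fast-spiking inhibitory).
#' @param g_Ks,E_L Optional overrides of the adaptation conductance and leak
#'   reversal (used by the heterogeneity experiments).
#' @return A `channel_set` object.
#' @export
channel_set <- function(profile = c("E", "I"), g_Ks = NULL, E_L = NULL) {
  profile <- match.arg(profile)
  base <- if (profile == "E") {
    list(gL = 0.2, EL = -70, gNa = 35, ENa = 55, gNaP = 0.12,
         gK = 15, EK = -90, gA = 2.5, gKs = 2.5)
  } else {
    list(gL = 0.2, EL = -70, gNa = 35, ENa = 55, gNaP = 0.08,
         gK = 7.5, EK = -90, gA = 7.5, gKs = 0.25)
  }
  if (!is.null(g_Ks)) base$gKs <- g_Ks
  if (!is.null(E_L)) base$EL <- E_L
  if (any(unlist(base[c("gL", "gNa", "gNaP", "gK", "gA", "gKs")]) < 0)) {
    abort("Conductance densities must be >= 0.", class = "ringcrf_parameter_error")
  }
  structure(c(base, list(label = profile)), class = "channel_set")
}

channel_vector <- function(ch) {
  c(ch$gL, ch$EL, ch$gNa, ch$ENa, ch$gNaP, ch$gK, ch$EK, ch$gA, ch$gKs)
}

#' Default white-noise amplitude
#'
#' The noise current amplitude (uA/cm^2 * sqrt(ms)) used throughout the
#' conductance-based experiments, calibrated with [calibrate_noise()] so the
#' subthreshold membrane-potential SD lies in the 3-4 mV range reported for
#' V1 neurons in vivo.
#'
#' @export
cbm_default_noise <- function() 2.45

#' Simulate a single conductance-based neuron
#'
#' Second-order integration of the full current-balance equation with an
#' optional added leak conductance and Gaussian white-noise current (added
#' with 1/sqrt(dt) scaling inside the step). Spikes are upward crossings of
#' -20 mV with a 2 ms lockout.
#'
#' @param channels A [channel_set()].
#' @param I_ext Constant external current density, uA/cm^2.
#' @param sigma_noise White-noise amplitude (0 = deterministic).
#' @param T Total simulated time, ms.
#' @param dt Time step, ms (must be <= 0.1).
#' @param extra_gL Added leak conductance, mS/cm^2.
#' @param transient Initial interval excluded from the window statistics, ms.
#' @param clip Spike-clipping level for the mean-voltage statistic, mV.
#' @param record_V Record the voltage trace every `record_V` ms (0 = none).
#' @param seed Optional RNG seed (uses R's RNG).
#' @return A list: `spikes` (times, ms), `rate` (Hz over the analysis
#'   window), `mean_V_clipped`, `sd_V`, and a `V` tibble when recorded.
#' @export
simulate_neuron <- function(channels, I_ext = 0, sigma_noise = 0, T = 1700,
                            dt = 0.05, extra_gL = 0, transient = 200,
                            clip = -50, record_V = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stride <- if (record_V > 0) max(1L, round(record_V / dt)) else 0L
  res <- cbm_neuron_run(channel_vector(channels), I_ext, sigma_noise, T, dt,
                        extra_gL, transient, clip, stride, channels$EL)
  out <- list(spikes = res$spikes, rate = res$rate,
              mean_V_clipped = res$mean_V_clipped, sd_V = res$sd_V,
              mean_V = res$mean_V)
  if (stride > 0) out$V <- tibble(time = res$t, V = res$V)
  out
}

#' f-I and V-I characterization of a conductance-based neuron
#'
#' Mean firing rate and mean subthreshold voltage (samples above the
#' clipping level replaced by it) per injected current, averaged over
#' repetitions, with the standard error over repetitions. The initial
#' transient is discarded before averaging.
#'
#' @param channels A [channel_set()].
#' @param I_grid Current densities to test, uA/cm^2.
#' @param sigma_noise White-noise amplitude.
#' @param T Analysis window per repetition, ms.
#' @param reps Repetitions per current.
#' @param dt,transient,clip,extra_gL As in [simulate_neuron()].
#' @param seed RNG seed.
#' @return A tibble with columns `I`, `rate`, `rate_sem`, `V`, `V_sem`.
#' @export
characterize <- function(channels, I_grid, sigma_noise = cbm_default_noise(),
                         T = 1500, reps = 10, dt = 0.05, transient = 200,
                         clip = -50, extra_gL = 0, seed = 1) {
  if (reps < 1) abort("`reps` must be >= 1.", class = "ringcrf_parameter_error")
  set.seed(seed)
  rows <- lapply(I_grid, function(I) {
    r <- v <- numeric(reps)
    for (k in seq_len(reps)) {
      sim <- simulate_neuron(channels, I, sigma_noise, T = transient + T,
                             dt = dt, extra_gL = extra_gL,
                             transient = transient, clip = clip)
      r[k] <- sim$rate
      v[k] <- sim$mean_V_clipped
    }
    tibble(I = I, rate = mean(r), rate_sem = sd(r) / sqrt(reps),
           V = mean(v), V_sem = sd(v) / sqrt(reps))
  })
  bind_rows(rows)
}

#' Rheobase of a conductance-based neuron
#'
#' Bisection on the constant current for the onset of repetitive (noise-free)
#' firing.
#'
#' @param channels A [channel_set()].
#' @param bracket Initial current bracket, uA/cm^2.
#' @param T,dt,transient As in [simulate_neuron()].
#' @param tol Bisection tolerance on the current.
#' @param extra_gL Added leak conductance.
#' @return Rheobase current density, uA/cm^2.
#' @export
find_rheobase <- function(channels, bracket = c(0, 6), T = 2000, dt = 0.05,
                          transient = 400, tol = 1e-3, extra_gL = 0) {
  fires <- function(I) {
    sim <- simulate_neuron(channels, I, 0, T = T, dt = dt,
                           extra_gL = extra_gL, transient = transient)
    sum(sim$spikes > transient) >= 2
  }
  lo <- bracket[1]; hi <- bracket[2]
  if (fires(lo)) abort("Lower bracket already fires.", class = "ringcrf_parameter_error")
  # scan upward for the first firing current (large currents may sit in
  # depolarization block, so expanding the upper bracket blindly is unsafe)
  if (!fires(hi)) {
    found <- FALSE
    step <- max(hi - lo, 1)
    while (hi <= 100) {
      cand <- hi + step
      if (fires(cand)) {
        lo <- hi; hi <- cand; found <- TRUE; break
      }
      hi <- cand
    }
    if (!found) abort("No firing up to 100 uA/cm^2.", class = "ringcrf_parameter_error")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Calibrate the white-noise amplitude to a target voltage SD
#'
#' Bisection on the noise amplitude until the standard deviation of the
#' subthreshold membrane potential, measured at rest (zero holding current),
#' lies in the target range. Calibrating at rest rather than just below
#' rheobase avoids the persistent-sodium amplification region, where the
#' effective membrane conductance is much smaller and the same voltage SD
#' would imply a far weaker noise current.
#'
#' @param channels A [channel_set()].
#' @param target_sd Target range for the voltage SD, mV.
#' @param bracket Initial bracket on the noise amplitude.
#' @param T Measurement window, ms.
#' @param dt Time step, ms.
#' @param seed RNG seed.
#' @return A list: `sigma` (calibrated amplitude), `sd_V` (achieved SD),
#'   `hold_I` (holding current), `rheobase`.
#' @export
calibrate_noise <- function(channels, target_sd = c(3, 4), bracket = c(0.01, 20),
                            T = 3000, dt = 0.05, seed = 1) {
  rhb <- find_rheobase(channels, dt = dt)
  hold <- 0
  measure <- function(sigma, s = seed) {
    set.seed(s)
    sim <- simulate_neuron(channels, hold, sigma, T = 500 + T, dt = dt,
                           transient = 500)
    sim$sd_V
  }
  lo <- bracket[1]; hi <- bracket[2]
  mid_target <- mean(target_sd)
  if (measure(lo) > target_sd[2] || measure(hi) < target_sd[1]) {
    abort("Target voltage SD unreachable within the noise bracket.",
          class = "ringcrf_calibration_error")
  }
  for (it in 1:30) {
    mid <- sqrt(lo * hi)
    s <- measure(mid)
    if (s >= target_sd[1] && s <= target_sd[2]) {
      return(list(sigma = mid, sd_V = s, hold_I = hold, rheobase = rhb))
    }
    if (s < mid_target) lo <- mid else hi <- mid
  }
  abort("Noise calibration did not converge.", class = "ringcrf_calibration_error")
}

#' Leak-conductance shift experiment
#'
#' Measures noisy f-I curves for a set of added leak conductances and
#' quantifies how the added leak acts on the fitted threshold power law. In
#' the effective rate description an extra leak `dG` behaves as a
#' subtractive current `V_c * dG`; the slope `V_c` comes from regressing
#' the per-condition fitted threshold on `dG`.
#'
#' Because the three power-law parameters trade off strongly against each
#' other on noisy curves, the per-condition threshold is fitted with the
#' gain and exponent pinned to the baseline fit (one-parameter fit), and
#' the sensitivity of the gain and of the exponent to `dG` is measured by
#' profile refits in which only that parameter (plus the threshold) is
#' free. A superposition metric (maximum vertical deviation between the
#' baseline curve and each threshold-shifted curve, as a fraction of the
#' peak rate in the fit range) is also reported.
#'
#' @param channels A [channel_set()].
#' @param delta_gL Added leak conductances (mS/cm^2), including 0; the
#'   largest value should keep the effective leak at most twice baseline.
#' @param I_grid Optional current span override (only its range is used).
#' @param rate_range Output range (Hz) over which the power laws are
#'   fitted.
#' @param sigma_noise,T,reps,dt,seed As in [characterize()].
#' @param shift_grid Anchor each condition's current grid at its own
#'   rheobase (keeps comparable coverage of the fitted rate range).
#' @return A `gl_shift` object: per-condition tibble `fits` (`delta_gL`,
#'   `gain`, `beta`, `threshold`), `V_c` (slope, mV), `r_squared`,
#'   `gain_variation`, `beta_variation`, `superposition_error`, and the
#'   raw `curves`.
#' @export
gl_shift_experiment <- function(channels, delta_gL = c(0, 0.05, 0.1, 0.15, 0.2),
                                I_grid = NULL, rate_range = c(0, 30),
                                sigma_noise = cbm_default_noise(), T = 1500,
                                reps = 10, dt = 0.05, seed = 1,
                                shift_grid = TRUE) {
  if (min(delta_gL) < 0) abort("`delta_gL` must be >= 0.", class = "ringcrf_parameter_error")
  if (max(delta_gL) > channels$gL) {
    abort("Largest `delta_gL` exceeds the baseline leak (beyond the doubling range).",
          class = "ringcrf_parameter_error")
  }
  rhb0 <- find_rheobase(channels, c(0, 16), dt = dt)
  span <- if (is.null(I_grid)) 3.5 else diff(range(I_grid))
  curves <- vector("list", length(delta_gL))
  for (i in seq_along(delta_gL)) {
    dg <- delta_gL[i]
    rhb <- if (dg == 0 || !shift_grid) rhb0 else
      find_rheobase(channels, c(0, 20), dt = dt, extra_gL = dg)
    grid_i <- sort(unique(c(seq(0, rhb + span, length.out = 8),
                            seq(max(0, rhb - 4), rhb + span, length.out = 12))))
    cv <- characterize(channels, grid_i, sigma_noise, T = T, reps = reps,
                       dt = dt, extra_gL = dg, seed = seed + i)
    curves[[i]] <- mutate(cv, delta_gL = dg)
  }
  base <- fit_powerlaw(curves[[1]], "I", "rate", response_range = rate_range)
  g0 <- base$gain; b0 <- base$beta

  sub_fit <- function(cv, fix_beta = NULL, fix_gain = NULL) {
    d <- cv[cv$rate >= rate_range[1] & cv$rate <= rate_range[2], ]
    I <- d$I; y <- d$rate
    if (!is.null(fix_beta)) {
      # threshold (+ profiled gain) with the exponent pinned
      obj <- function(Ic) {
        x <- pmax(I - Ic, 0)^fix_beta
        den <- sum(x^2)
        if (den <= 0) return(1e12)
        g <- sum(x * y) / den
        sum((y - g * x)^2)
      }
      o <- stats::optimize(obj, range(I) + c(-2, 0))
      x <- pmax(I - o$minimum, 0)^fix_beta
      c(threshold = o$minimum, gain = sum(x * y) / sum(x^2), beta = fix_beta)
    } else {
      # threshold + exponent with the gain pinned
      obj <- function(p) {
        bet <- exp(p[2])
        if (bet < 0.1 || bet > 10) return(1e12)
        sum((y - fix_gain * pmax(I - p[1], 0)^bet)^2)
      }
      o <- optim(c(min(I), log(b0)), obj, method = "Nelder-Mead",
                 control = list(maxit = 1000, reltol = 1e-10))
      c(threshold = o$par[1], gain = fix_gain, beta = exp(o$par[2]))
    }
  }

  fits <- list()
  sup_err <- numeric(0)
  for (i in seq_along(delta_gL)) {
    fa <- sub_fit(curves[[i]], fix_beta = b0)
    fb <- sub_fit(curves[[i]], fix_gain = g0)
    fits[[i]] <- tibble(delta_gL = delta_gL[i],
                        threshold = unname(fa[["threshold"]]),
                        gain = unname(fa[["gain"]]),
                        beta = unname(fb[["beta"]]))
    # superposition: compare the curve, shifted back by its threshold
    # offset, against the baseline fit
    d <- curves[[i]]
    d <- d[d$rate >= rate_range[1] & d$rate <= rate_range[2], ]
    pred <- g0 * pmax(d$I - fa[["threshold"]], 0)^b0
    sup_err[i] <- max(abs(d$rate - pred)) / rate_range[2]
  }
  fits <- bind_rows(fits)
  lmfit <- stats::lm(threshold ~ delta_gL, data = fits)
  structure(list(
    fits = fits,
    baseline = base,
    curves = bind_rows(curves),
    V_c = unname(coef(lmfit)[2]),
    r_squared = summary(lmfit)$r.squared,
    gain_variation = max(abs(fits$gain / fits$gain[1] - 1)),
    beta_variation = max(abs(fits$beta / fits$beta[1] - 1)),
    superposition_error = max(sup_err)),
    class = "gl_shift")
}

#' Effective transfer function with a leak-proportional threshold shift
#'
#' The effective rate description of a conductance-based neuron under a
#' synaptic conductance load `delta_gL`:
#' \deqn{\nu = g \lfloor I_{net} - I_c - V_c\,\Delta G\rfloor_+^\beta.}
#'
#' @param I_net Net input current, uA/cm^2.
#' @param delta_gL Conductance load, mS/cm^2.
#' @param fit A [fit_powerlaw()] result for the baseline f-I curve.
#' @param V_c Threshold-shift slope from [gl_shift_experiment()], mV.
#' @return Firing rate(s), Hz.
#' @export
effective_transfer <- function(I_net, delta_gL, fit, V_c) {
  fit$gain * pmax(I_net - fit$threshold - V_c * delta_gL, 0)^fit$beta
}

#' Standard f-I / V-I measurement and power-law fit for a channel profile
#'
#' The package's canonical single-neuron characterization: locates the
#' rheobase, builds a current grid spanning zero to the current at which the
#' noisy rate reaches `rate_cap` (with extra resolution around the
#' threshold region, where the noise-smoothed foot of the curve lives),
#' measures the noisy f-I and V-I curves, and fits threshold power laws --
#' the f-I fit restricted to rates in `[0, rate_cap]`, the V-I fit (with a
#' free offset) over the same currents.
#'
#' @param channels A [channel_set()].
#' @param rate_cap Upper rate bound of the fit range, Hz (30 for the
#'   excitatory profile, 60 for the inhibitory one, following the
#'   convention that the fit covers each cell type's physiological range).
#' @param sigma_noise,T,reps,dt,seed As in [characterize()].
#' @param n_coarse,n_fine Grid sizes for the full span and the threshold
#'   region.
#' @return A list: `fi` ([fit_powerlaw()] of the rates), `vi` (power law of
#'   the clipped voltage), `curve` (the measured tibble), `rheobase`.
#' @export
fi_protocol <- function(channels, rate_cap = if (channels$label == "E") 30 else 60,
                        sigma_noise = cbm_default_noise(), T = 1500,
                        reps = 12, dt = 0.05, seed = 1,
                        n_coarse = 10, n_fine = 12) {
  rhb <- find_rheobase(channels, c(0, 14), dt = dt)
  Ihi <- rhb + 0.5
  repeat {
    set.seed(seed)
    r <- simulate_neuron(channels, Ihi, sigma_noise, T = 900, dt = dt,
                         transient = 300)$rate
    if (r >= rate_cap || Ihi > 4 * rhb + 4) break
    Ihi <- rhb + (Ihi - rhb) * 1.5
  }
  grid <- sort(unique(c(seq(0, Ihi, length.out = n_coarse),
                        seq(max(0, rhb - 4), Ihi, length.out = n_fine))))
  cv <- characterize(channels, grid, sigma_noise, T = T, reps = reps,
                     dt = dt, seed = seed)
  fi <- fit_powerlaw(cv, "I", "rate", response_range = c(0, rate_cap))
  fi_span <- range(cv$I[cv$rate <= rate_cap])
  vi <- fit_powerlaw(cv, "I", "V", offset = TRUE, input_range = fi_span,
                     beta_starts = c(0.3, 0.5, 0.8, 1),
                     beta_bounds = c(0.2, 1.5))
  list(fi = fi, vi = vi, curve = cv, rheobase = rhb)
}

#' @export
print.gl_shift <- function(x, ...) {
  cat(sprintf("Leak-shift experiment: V_c = %.3g mV (R^2 = %.4f); gain var %.1f%%, beta var %.1f%%\n",
              x$V_c, x$r_squared, 100 * x$gain_variation, 100 * x$beta_variation))
  invisible(x)
}
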