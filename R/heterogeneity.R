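#' Heterogeneity specification for the diversity experiments
#'
#' Two sources of contrast-response diversity, mixed by a single parameter
#' `P`: LGN-input heterogeneity (per-neuron semi-saturation contrast,
#' steepness exponent and peak drive of the feedforward input) and intrinsic
#' heterogeneity (per-neuron adaptation conductance and leak reversal). The
#' uniform sampling ranges are scaled about their fixed midpoints by `P`
#' (LGN ranges) and `1 - P` (intrinsic ranges): at `P = 1` only the LGN
#' input is heterogeneous, at `P = 0` only the intrinsic properties are.
#'
#' @param P Mixing parameter in [0, 1].
#' @param lgn_C50,lgn_n,lgn_nu_max Full-width LGN ranges (`nu_max` in the
#'   dimensionless drive units of the experiments; converted to current
#'   density by the network drive scale).
#' @param gKs_E,gKs_I,E_L Full-width intrinsic ranges (mS/cm^2, mS/cm^2,
#'   mV).
#' @return A `heterogeneity_spec` object.
#' @export
heterogeneity_spec <- function(P, lgn_C50 = c(8, 28), lgn_n = c(1, 1.8),
                               lgn_nu_max = c(3.5, 4.5),
                               gKs_E = c(0.5, 6.5), gKs_I = c(0.1, 1.1),
                               E_L = c(-77.5, -67.5)) {
  if (P < 0 || P > 1) abort("`P` must be in [0, 1].", class = "ringcrf_parameter_error")
  structure(list(P = P, lgn_C50 = lgn_C50, lgn_n = lgn_n,
                 lgn_nu_max = lgn_nu_max, gKs_E = gKs_E, gKs_I = gKs_I,
                 E_L = E_L),
            class = "heterogeneity_spec")
}

scale_range <- function(rng, f) {
  mid <- mean(rng)
  mid + f * (rng - mid)
}

runif_range <- function(n, rng) {
  if (diff(rng) <= 0) rep(mean(rng), n) else runif(n, rng[1], rng[2])
}

#' Sample per-neuron parameters from a heterogeneity specification
#'
#' Independent uniform draws from the `P`-scaled ranges; collapsed ranges
#' yield the midpoints exactly.
#'
#' @param spec A [heterogeneity_spec()].
#' @param N_E,N_I Population sizes.
#' @param seed RNG seed.
#' @return A tibble, one row per neuron: `pop`, `idx`, `C50`, `n_exp`,
#'   `nu_max` (drive units), `g_Ks`, `E_L`.
#' @export
sample_population <- function(spec, N_E = 400, N_I = 400, seed = 1) {
  set.seed(seed)
  P <- spec$P
  pop <- rep(c("E", "I"), c(N_E, N_I))
  n <- N_E + N_I
  tibble(
    pop = pop,
    idx = c(seq_len(N_E), seq_len(N_I)),
    C50 = runif_range(n, scale_range(spec$lgn_C50, P)),
    n_exp = runif_range(n, scale_range(spec$lgn_n, P)),
    nu_max = runif_range(n, scale_range(spec$lgn_nu_max, P)),
    g_Ks = ifelse(pop == "E",
                  runif_range(n, scale_range(spec$gKs_E, 1 - P)),
                  runif_range(n, scale_range(spec$gKs_I, 1 - P))),
    E_L = runif_range(n, scale_range(spec$E_L, 1 - P)))
}

#' Run a heterogeneous-network diversity experiment
#'
#' Simulates the spiking hypercolumn with per-neuron sampled parameters
#' across a contrast grid, reads out each neuron's contrast-response
#' function at (approximately) its preferred orientation, fits the
#' hyperbolic-ratio function per neuron, classifies saturation, and
#' computes the pairwise parameter correlations on the good-fit subset.
#'
#' Because orientation tuning is contrast invariant, a stimulus offset from
#' a neuron's preferred orientation scales its CRF by a contrast-independent
#' factor, which leaves `C50` and the exponent (and hence the correlation
#' structure) unchanged; the stimulus set therefore uses `n_orientations`
#' evenly spaced orientations and each neuron is read out at the nearest
#' one.
#'
#' @param spec A [heterogeneity_spec()].
#' @param N_E,N_I Population sizes.
#' @param drive A [cbm_lgn_drive()]; the sampled `nu_max` (drive units,
#'   midpoint 4) is converted to current density by `drive$nu_max / 4`.
#' @param syn A [synapse_params()].
#' @param contrasts Contrast grid, percent.
#' @param trials Trials per (orientation, contrast).
#' @param n_orientations Number of stimulus orientations.
#' @param T,transient,dt,sigma_noise As in [run_trial()].
#' @param seed Base seed (controls both sampling and simulation noise).
#' @param min_rate Neurons whose maximum CRF response is below this rate
#'   (Hz) are excluded from fitting (they are silent at all contrasts).
#' @return A `heterogeneity_result` list: `fits` (per-neuron tibble with
#'   the sampled parameters as `lgn_C50`, `lgn_n`, `lgn_nu_max`, `g_Ks`,
#'   `E_L` and the fitted H-ratio parameters `R_max`, `C50`, `n_exp` with
#'   relative errors, `good`, `class`), `correlations` ([correlate_params()] output per
#'   population), `good_fraction` (overall and per population), `P`,
#'   `n_fitted`.
#' @export
run_heterogeneity_experiment <- function(spec, N_E = 400, N_I = 400,
                                         drive = cbm_lgn_drive(),
                                         syn = synapse_params(),
                                         contrasts = crf_contrast_grid(10),
                                         trials = 3, n_orientations = 5,
                                         T = 1500, transient = 500, dt = 0.05,
                                         sigma_noise = cbm_default_noise(),
                                         seed = 1, min_rate = 2) {
  het <- sample_population(spec, N_E, N_I, seed = seed)
  het_net <- het
  het_net$nu_max <- het$nu_max * drive$nu_max / 4
  net <- build_network(N_E, N_I, syn, het = het_net)
  orientations <- seq(-90, 90 - 180 / n_orientations,
                      length.out = n_orientations)
  # per-neuron read-out orientation: the nearest stimulated one
  th_deg <- rad2deg(net$theta)
  d <- abs(outer(th_deg, orientations, function(a, b) (a - b + 90) %% 180 - 90))
  nearest <- apply(d, 1, which.min)

  n <- N_E + N_I
  rates <- matrix(0, n, length(contrasts))
  for (oi in seq_along(orientations)) {
    sel <- nearest == oi
    if (!any(sel)) next
    for (j in seq_along(contrasts)) {
      acc <- numeric(n)
      for (k in seq_len(trials)) {
        tr <- run_trial(net, drive, orientations[oi], contrasts[j],
                        sigma_noise, T, transient, dt,
                        seed = seed + 17 * oi + 1000 * j + k)
        acc <- acc + tr$rate
      }
      rates[sel, j] <- acc[sel] / trials
    }
  }

  fit_one <- function(i) {
    cd <- tibble(contrast = contrasts, response = rates[i, ])
    if (max(cd$response) < min_rate) {
      return(tibble(R_max = NA_real_, C50 = NA_real_, n_exp = NA_real_,
                    rel_R_max = Inf, rel_C50 = Inf, rel_n = Inf,
                    good = FALSE, class = NA_character_))
    }
    f <- try(suppressWarnings(fit_hratio(cd)), silent = TRUE)
    if (inherits(f, "try-error") || !is.finite(f$R_max)) {
      return(tibble(R_max = NA_real_, C50 = NA_real_, n_exp = NA_real_,
                    rel_R_max = Inf, rel_C50 = Inf, rel_n = Inf,
                    good = FALSE, class = NA_character_))
    }
    tibble(R_max = f$R_max, C50 = f$C50, n_exp = f$n_exp,
           rel_R_max = f$rel_error[["R_max"]],
           rel_C50 = f$rel_error[["C50"]],
           rel_n = f$rel_error[["n_exp"]],
           good = f$good,
           class = classify_saturation(f))
  }
  fits <- bind_rows(lapply(seq_len(n), fit_one))
  sampled <- het
  names(sampled)[match(c("C50", "n_exp", "nu_max"), names(sampled))] <-
    c("lgn_C50", "lgn_n", "lgn_nu_max")
  fits <- dplyr::bind_cols(sampled, fits)
  fitted_ok <- is.finite(fits$R_max)
  if (mean(fitted_ok) < 0.5) {
    abort("More than 50% of neurons failed to fit: aborting the experiment.",
          class = "ringcrf_experiment_error")
  }
  good_fraction <- c(
    overall = mean(fits$good),
    E = mean(fits$good[fits$pop == "E"]),
    I = mean(fits$good[fits$pop == "I"]))
  correlations <- try(correlate_params(fits), silent = TRUE)
  if (inherits(correlations, "try-error")) correlations <- NULL
  structure(list(fits = fits, correlations = correlations,
                 good_fraction = good_fraction, P = spec$P,
                 n_fitted = sum(fitted_ok), contrasts = contrasts,
                 rates = rates),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("Heterogeneity experiment (P = %.2f): %d neurons fitted; good-fit fraction %.1f%% (E %.1f%%, I %.1f%%)\n",
              x$P, x$n_fitted, 100 * x$good_fraction[["overall"]],
              100 * x$good_fraction[["E"]], 100 * x$good_fraction[["I"]]))
  if (!is.null(x$correlations)) {
    cc <- x$correlations[x$correlations$pair == "C50-n_exp", ]
    for (i in seq_len(nrow(cc))) {
      cat(sprintf("  %s: r(C50, n) = %+.3f (Fisher p = %.3g)\n",
                  cc$pop[i], cc$r[i], cc$p_fisher[i]))
    }
  }
  invisible(x)
}

#' Correlation-versus-mixing sweep
#'
#' Repeats the heterogeneity experiment across a grid of mixing parameters
#' and collects the pairwise parameter correlations; the zero crossing of
#' the excitatory C50-exponent correlation is located by linear
#' interpolation.
#'
#' @param P_grid Mixing parameters (at least 3).
#' @param ... Arguments passed to [run_heterogeneity_experiment()].
#' @return A list: `correlations` (tibble with `P` column), `results`
#'   (per-P experiment objects), `zero_crossing_E` (interpolated P where
#'   the excitatory C50-n correlation changes sign, NA if none).
#' @export
correlation_vs_P <- function(P_grid = c(0, 0.5, 1), ...) {
  if (length(P_grid) < 3) abort("Need at least 3 P values.", class = "ringcrf_parameter_error")
  results <- lapply(P_grid, function(P) {
    run_heterogeneity_experiment(heterogeneity_spec(P), ...)
  })
  cors <- bind_rows(lapply(seq_along(P_grid), function(i) {
    cc <- results[[i]]$correlations
    if (is.null(cc)) return(NULL)
    cc$P <- P_grid[i]
    cc
  }))
  ce <- cors[cors$pair == "C50-n_exp" & cors$pop == "E", ]
  zc <- NA_real_
  if (nrow(ce) >= 2) {
    ce <- ce[order(ce$P), ]
    sgn <- sign(ce$r)
    flip <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    if (length(flip)) {
      i <- flip[1]
      zc <- ce$P[i] + (0 - ce$r[i]) * (ce$P[i + 1] - ce$P[i]) /
        (ce$r[i + 1] - ce$r[i])
    }
  }
  list(correlations = cors, results = results, zero_crossing_E = zc)
}
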