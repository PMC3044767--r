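# Ring grids and discretized connectivity ------------------------------------

ring_grid <- function(N) seq(-pi / 2, pi / 2 - pi / N, length.out = N)

# Block weight matrix W[[A]][[B]] (N_A x N_B) carrying sign, strength and the
# 1/N_B density factor of the discretized ring convolution.
ring_weights <- function(pops, conn) {
  sgn <- c(E = 1, I = -1)
  th <- list(E = ring_grid(pops$E$N), I = ring_grid(pops$I$N))
  W <- list()
  for (A in c("E", "I")) {
    W[[A]] <- list()
    for (B in c("E", "I")) {
      d <- outer(th[[A]], th[[B]], "-")
      W[[A]][[B]] <- sgn[[B]] * conn$strengths[A, B] / pops[[B]]$N *
        periodic_gaussian(as.vector(d), conn$widths[A, B]) |> matrix(pops[[A]]$N)
    }
  }
  W
}

#' Integrate the ring rate dynamics
#'
#' Explicit second-order (Heun) integration of
#' \deqn{\tau_A \dot\nu_A(\theta) = -\nu_A(\theta) + g_A\lfloor I_A(\theta)\rfloor_+^{\beta_A},}
#' where the input combines the orientation-tuned LGN drive and the ring
#' feedback, discretized with the 1/N density factor.
#'
#' @inheritParams check_width_conditions
#' @param theta_stim Stimulus orientation, degrees.
#' @param contrast Contrast in percent (mapped through `I0 = nu0 log C`), or
#'   `NULL` if `I0` is given directly.
#' @param I0 Peak LGN input, overrides `contrast` when non-`NULL`.
#' @param T Integration time, ms.
#' @param dt Time step, ms; must satisfy `dt <= min(tau)/5`.
#' @param init Optional list with numeric vectors `E` and `I` of initial
#'   rates (defaults to zero).
#' @param record_every Sampling interval for the returned trajectory, ms
#'   (`Inf` records only the final state).
#' @param rate_cap Divergence guard: if any rate exceeds this cap the
#'   integration stops and the result is flagged `diverged`.
#' @return A `ring_trajectory` object: `theta` grids (degrees), final
#'   `rates` (list `E`, `I`), a tibble `trajectory` of sampled states, and
#'   flags.
#' @export
integrate_ring <- function(pops, conn, drive, theta_stim = 0, contrast = NULL,
                           I0 = NULL, T = 500, dt = 1, init = NULL,
                           record_every = Inf, rate_cap = 1e4) {
  if (dt > min(pops$E$tau, pops$I$tau) / 5) {
    abort("`dt` must be <= min(tau_E, tau_I) / 5.", class = "ringcrf_parameter_error")
  }
  if (is.null(I0)) {
    if (is.null(contrast)) abort("Give either `contrast` or `I0`.", class = "ringcrf_parameter_error")
    I0 <- lgn_peak_input(contrast, drive)
  }
  I0 <- if (length(I0) == 1L) c(E = unname(I0), I = unname(I0)) else I0[c("E", "I")]
  ths <- deg2rad(theta_stim)
  th <- list(E = ring_grid(pops$E$N), I = ring_grid(pops$I$N))
  W <- ring_weights(pops, conn)
  ff <- list(
    E = I0[["E"]] * periodic_gaussian(th$E - ths, drive$sigma[["E"]]),
    I = I0[["I"]] * periodic_gaussian(th$I - ths, drive$sigma[["I"]])
  )
  nu <- list(E = if (is.null(init)) numeric(pops$E$N) else init$E,
             I = if (is.null(init)) numeric(pops$I$N) else init$I)

  deriv <- function(nu) {
    list(E = (-nu$E + transfer(ff$E + W$E$E %*% nu$E + W$E$I %*% nu$I, pops$E)) / pops$E$tau,
         I = (-nu$I + transfer(ff$I + W$I$E %*% nu$E + W$I$I %*% nu$I, pops$I)) / pops$I$tau)
  }

  n_steps <- ceiling(T / dt)
  rec_step <- if (is.finite(record_every)) max(1L, round(record_every / dt)) else n_steps + 1L
  traj <- list()
  diverged <- FALSE
  for (s in seq_len(n_steps)) {
    k1 <- deriv(nu)
    k2 <- deriv(list(E = nu$E + dt * k1$E, I = nu$I + dt * k1$I))
    nu$E <- as.vector(nu$E + dt / 2 * (k1$E + k2$E))
    nu$I <- as.vector(nu$I + dt / 2 * (k1$I + k2$I))
    if (max(nu$E, nu$I) > rate_cap || anyNA(nu$E) || anyNA(nu$I)) {
      diverged <- TRUE
      break
    }
    if (s %% rec_step == 0) {
      traj[[length(traj) + 1L]] <- tibble(
        time = s * dt,
        pop = rep(c("E", "I"), c(pops$E$N, pops$I$N)),
        theta = rad2deg(c(th$E, th$I)),
        rate = c(nu$E, nu$I))
    }
  }
  structure(list(theta = list(E = rad2deg(th$E), I = rad2deg(th$I)),
                 rates = nu,
                 trajectory = if (length(traj)) bind_rows(traj) else NULL,
                 diverged = diverged, T = T, dt = dt,
                 theta_stim = theta_stim, I0 = I0),
            class = "ring_trajectory")
}

#' Tidy the final state of a ring integration
#' @param x A `ring_trajectory` object.
#' @param ... Unused.
#' @export
tidy.ring_trajectory <- function(x, ...) {
  tibble(pop = rep(c("E", "I"), c(length(x$theta$E), length(x$theta$I))),
         theta = c(x$theta$E, x$theta$I),
         rate = c(x$rates$E, x$rates$I))
}

# Peak rate and periodic-Gaussian-fitted width of a final ring profile.
profile_summary <- function(theta_deg, rate) {
  if (max(rate) <= 0) return(c(peak = 0, width = NA_real_))
  fit <- try(fit_gaussian_tuning(tibble(theta = theta_deg, rate = rate),
                                 fix_offset = TRUE), silent = TRUE)
  if (inherits(fit, "try-error")) return(c(peak = max(rate), width = NA_real_))
  c(peak = fit$amplitude, width = fit$sigma)
}

#' Closed-form criterion for CRF supersaturation
#'
#' At large LGN input the inhibitory peak rate grows as
#' \eqn{\nu_{I0} \to I_0/\tilde J_{II}}, so (with equal drive to both
#' populations) the net input to the excitatory population grows as
#' \eqn{I_0 (1 - \tilde J_{EI}/\tilde J_{II})}: the excitatory activity is
#' eventually suppressed -- the CRF supersaturates -- if and only if
#' \eqn{\tilde J_{EI} > \tilde J_{II}} in terms of the effective peak
#' couplings.
#'
#' @inheritParams check_width_conditions
#' @return The margin `Jt_EI - Jt_II`; positive values predict
#'   supersaturation.
#' @export
supersaturation_margin <- function(pops, conn, drive) {
  Jt <- effective_couplings(pops, conn, drive)
  unname(Jt["E", "I"] - Jt["I", "I"])
}

#' Classify the shape of the excitatory rate-vs-input curve
#'
#' Evaluates `nu_E0(I0)` on a log-spaced input grid via
#' [solve_selfconsistent()] and labels the curve `supersaturating` (interior
#' maximum, final value < 0.95 of the maximum), `saturating` (monotone
#' increasing but with decreasing slope after an inflexion) or
#' `non_saturating` (slope non-decreasing throughout; runaway solutions are
#' treated as non-saturating growth). Also evaluates the closed-form
#' criterion [supersaturation_margin()] and reports agreement of the two
#' routes.
#'
#' @inheritParams check_width_conditions
#' @param I0_max Largest LGN input of the sweep.
#' @param I0_min Smallest (positive) LGN input of the sweep.
#' @param n_grid Number of grid points.
#' @return A `crf_shape` object with elements `class`, `margin`,
#'   `criterion_class`, `agreement` and the diagnostic `curve` tibble.
#' @export
classify_crf_shape <- function(pops, conn, drive, I0_max = 50, I0_min = 0.05,
                               n_grid = 80) {
  I0s <- exp(seq(log(I0_min), log(I0_max), length.out = n_grid))
  sols <- lapply(I0s, function(i0) solve_selfconsistent(pops, conn, drive, i0))
  nuE <- vapply(sols, `[[`, numeric(1), "nu_E0")
  nuI <- vapply(sols, `[[`, numeric(1), "nu_I0")
  div <- vapply(sols, `[[`, logical(1), "diverged")
  bad <- vapply(sols, function(s) !s$converged && !s$diverged, logical(1))
  if (mean(bad) > 0.1) {
    abort("Self-consistency solver failed on more than 10% of the input grid.",
          class = "ringcrf_classification_error")
  }
  keep <- !bad
  if (any(div)) keep <- keep & (seq_along(I0s) < which(div)[1] | div)
  curve <- tibble(I0 = I0s, nu_E0 = nuE, nu_I0 = nuI, diverged = div)[keep, ]
  x <- curve$I0[!curve$diverged]
  y <- curve$nu_E0[!curve$diverged]

  cls <- if (any(curve$diverged)) {
    "non_saturating"
  } else {
    imax <- which.max(y)
    if (imax < length(y) && y[length(y)] < 0.95 * y[imax]) {
      "supersaturating"
    } else {
      slopes <- diff(y) / diff(x)
      smax <- which.max(slopes)
      if (smax < length(slopes) &&
          slopes[length(slopes)] < 0.95 * slopes[smax]) "saturating" else "non_saturating"
    }
  }
  margin <- supersaturation_margin(pops, conn, drive)
  criterion_class <- if (margin > 0) "supersaturating" else "non_saturating"
  agreement <- if (cls == "saturating") margin > 0 else
    (cls == "supersaturating") == (margin > 0)
  structure(list(class = cls, margin = margin,
                 criterion_class = criterion_class, agreement = agreement,
                 curve = curve),
            class = "crf_shape")
}

#' @export
print.crf_shape <- function(x, ...) {
  cat(sprintf("CRF shape: %s (criterion margin %.4g -> %s; agreement: %s)\n",
              x$class, x$margin, x$criterion_class, x$agreement))
  invisible(x)
}

#' Contrast-response curves of the ring rate model
#'
#' Maps contrasts through `I0 = nu0 log(C)` and [solve_selfconsistent()];
#' returns peak-rate-vs-contrast curves ready for hyperbolic-ratio fitting.
#'
#' @inheritParams check_width_conditions
#' @param contrasts Contrasts in percent, each in (0, 100].
#' @return A tibble with columns `contrast`, `I0`, `pop`, `rate`,
#'   `width_deg`, `converged`.
#' @export
rate_crf <- function(pops, conn, drive, contrasts = crf_contrast_grid()) {
  if (any(contrasts <= 0) || any(contrasts > 100)) {
    abort("`contrasts` must lie in (0, 100].", class = "ringcrf_parameter_error")
  }
  rows <- lapply(contrasts, function(C) {
    ss <- solve_selfconsistent(pops, conn, drive, lgn_peak_input(C, drive))
    tibble(contrast = C, I0 = lgn_peak_input(C, drive), pop = c("E", "I"),
           rate = c(ss$nu_E0, ss$nu_I0),
           width_deg = c(ss$sigma_E, ss$sigma_I),
           converged = ss$converged)
  })
  bind_rows(rows)
}

#' Linear stability of the ring steady state
#'
#' Linearizes the ring dynamics about the steady state on the orientation
#' grid and returns the spectrum of the resulting 2N x 2N operator. The
#' least-stable eigenmode is compared with the amplitude mode (a pure
#' rescaling of the steady profile). A bisection over the time-constant
#' ratio `tau_I/tau_E` locates the critical ratio at which the largest real
#' part crosses zero.
#'
#' @inheritParams check_width_conditions
#' @param ss A converged [solve_selfconsistent()] result.
#' @param find_critical_ratio If `TRUE`, bisect over `tau_I/tau_E`.
#' @param max_ratio Upper bound of the bisection bracket.
#' @return A `stability_result` object: sorted `eigenvalues`, `max_real`,
#'   `amplitude_mode_overlap` (|cosine| between the least-stable mode and
#'   the steady profile) and `critical_tau_ratio` (NA if stable throughout).
#' @export
stability_spectrum <- function(pops, conn, drive, ss,
                               find_critical_ratio = FALSE, max_ratio = 200) {
  if (!isTRUE(ss$converged)) {
    abort("`ss` must be a converged steady state.", class = "ringcrf_precondition_error")
  }
  th <- list(E = ring_grid(pops$E$N), I = ring_grid(pops$I$N))
  # total input profile under the ansatz: peak (nu_A0/g_A)^(1/beta_A), shape
  # given by the LGN tuning width
  inp <- list(
    E = (ss$nu_E0 / pops$E$gain)^(1 / pops$E$beta) *
      periodic_gaussian(th$E, drive$sigma[["E"]]),
    I = (ss$nu_I0 / pops$I$gain)^(1 / pops$I$beta) *
      periodic_gaussian(th$I, drive$sigma[["I"]])
  )
  gain_prime <- function(pop, I) pop$gain * pop$beta * pmax(I - pop$threshold, 0)^(pop$beta - 1)
  W <- ring_weights(pops, conn)

  jacobian <- function(tauE, tauI) {
    phiE <- gain_prime(pops$E, inp$E)
    phiI <- gain_prime(pops$I, inp$I)
    NE <- pops$E$N; NI <- pops$I$N
    J <- rbind(
      cbind(diag(-1, NE) + phiE * W$E$E, phiE * W$E$I),
      cbind(phiI * W$I$E, diag(-1, NI) + phiI * W$I$I))
    J / rep(c(tauE, tauI), c(NE, NI))
  }
  max_real_at <- function(ratio) {
    max(Re(eigen(jacobian(pops$E$tau, pops$E$tau * ratio), only.values = TRUE)$values))
  }

  ev <- eigen(jacobian(pops$E$tau, pops$I$tau))
  ord <- order(Re(ev$values), decreasing = TRUE)
  vals <- ev$values[ord]
  lead <- Re(ev$vectors[, ord[1]])
  # amplitude mode: each population's component of the mode rescales that
  # population's steady profile without changing its shape
  NE <- pops$E$N
  profE <- transfer(inp$E, pops$E)
  profI <- transfer(inp$I, pops$I)
  cosE <- abs(sum(lead[1:NE] * profE)) /
    sqrt(sum(lead[1:NE]^2) * sum(profE^2))
  cosI <- abs(sum(lead[-(1:NE)] * profI)) /
    sqrt(sum(lead[-(1:NE)]^2) * sum(profI^2))
  overlap <- min(cosE, cosI)

  critical <- NA_real_
  if (find_critical_ratio) {
    r0 <- pops$I$tau / pops$E$tau
    if (max_real_at(r0) >= 0) {
      critical <- r0
    } else if (max_real_at(max_ratio) > 0) {
      critical <- uniroot(max_real_at, c(r0, max_ratio), tol = 1e-3)$root
    }
  }
  structure(list(eigenvalues = vals, max_real = Re(vals[1]),
                 amplitude_mode_overlap = overlap,
                 critical_tau_ratio = critical),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("Stability: max Re(lambda) = %.5g /ms; amplitude-mode overlap %.3f\n",
              x$max_real, x$amplitude_mode_overlap))
  if (!is.na(x$critical_tau_ratio))
    cat(sprintf("  critical tau_I/tau_E = %.3g\n", x$critical_tau_ratio))
  invisible(x)
}

#' Default rate-model parameter set
#'
#' A convenience bundle used by examples and experiments: exponents and
#' relative coupling magnitudes chosen so the inhibitory peak rates are
#' several times the excitatory ones, output widths are about 15 degrees,
#' and the default CRF sits near the boundary between saturating and
#' supersaturating behaviour (the inhibitory self-coupling `J_II` moves it
#' across the three regimes). Projection widths come from [design_widths()].
#'
#' @param beta_E,beta_I Transfer exponents.
#' @param J_II Inhibitory self-coupling strength; the default sits just on
#'   the supersaturating side of the shape boundary (a flat-topped CRF),
#'   and lowering/raising it crosses into the clearly supersaturating /
#'   non-saturating regimes.
#' @param sigma_lgn_E,sigma_lgn_I LGN tuning widths, degrees.
#' @param nu0 Contrast coefficient of the logarithmic contrast map.
#' @return A list with elements `pops`, `conn`, `drive`.
#' @export
default_rate_model <- function(beta_E = 1.5, beta_I = 2.2, J_II = 4.3,
                               sigma_lgn_E = 15 * sqrt(beta_E),
                               sigma_lgn_I = 15 * sqrt(beta_I),
                               nu0 = 1.5) {
  pops <- list(E = population_params("E", tau = 10, gain = 1, beta = beta_E),
               I = population_params("I", tau = 10, gain = 3, beta = beta_I))
  widths <- design_widths(sigma_lgn_E, sigma_lgn_I, beta_E, beta_I)
  strengths <- matrix(c(5, 3, 5.6, J_II), 2, 2,
                      dimnames = list(c("E", "I"), c("E", "I")))
  conn <- ring_connectivity(strengths, widths)
  drive <- lgn_drive(sigma_E = sigma_lgn_E, sigma_I = sigma_lgn_I, nu0 = nu0)
  list(pops = pops, conn = conn, drive = drive)
}
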