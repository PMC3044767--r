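#' Population parameters for the ring rate model
#'
#' One excitatory (`"E"`) or inhibitory (`"I"`) population of rate units with
#' a threshold power-law transfer function
#' \eqn{\nu = g \lfloor I - I_\theta \rfloor_+^\beta}.
#'
#' @param label `"E"` or `"I"`.
#' @param N Number of units on the ring (default 100).
#' @param tau Membrane time constant in ms.
#' @param gain Scale `g` of the transfer function.
#' @param beta Power-law exponent (dimensionless, > 0).
#' @param threshold Input offset below which the output is zero (default 0).
#' @return A `population_params` object.
#' @export
population_params <- function(label, N = 100, tau = 10, gain = 1, beta = 2,
                              threshold = 0) {
  label <- match.arg(label, c("E", "I"))
  if (tau <= 0) abort("`tau` must be > 0.", class = "ringcrf_parameter_error")
  if (gain <= 0) abort("`gain` must be > 0.", class = "ringcrf_parameter_error")
  if (beta <= 0) abort("`beta` must be > 0.", class = "ringcrf_parameter_error")
  if (N < 2) abort("`N` must be >= 2.", class = "ringcrf_parameter_error")
  structure(list(label = label, N = as.integer(N), tau = tau, gain = gain,
                 beta = beta, threshold = threshold),
            class = "population_params")
}

#' Ring connectivity: coupling strengths and projection widths
#'
#' Pairwise coupling between the E and I populations on the orientation ring.
#' `strengths[A, B]` is the non-negative magnitude `J_AB` of the projection
#' from population B onto population A; inputs from I enter the dynamics with
#' a minus sign. `widths[A, B]` is the width (degrees) of the pi-periodic
#' Gaussian projection profile.
#'
#' @param strengths 2x2 numeric matrix with dimnames `E`/`I` (target rows,
#'   source columns), all entries >= 0.
#' @param widths 2x2 numeric matrix of projection widths in degrees, all in
#'   (0, 90).
#' @return A `ring_connectivity` object (widths stored in radians).
#' @export
ring_connectivity <- function(strengths, widths) {
  strengths <- as.matrix(strengths)
  widths <- as.matrix(widths)
  dn <- list(c("E", "I"), c("E", "I"))
  if (!all(dim(strengths) == c(2, 2)) || !all(dim(widths) == c(2, 2))) {
    abort("`strengths` and `widths` must be 2x2 matrices.", class = "ringcrf_parameter_error")
  }
  dimnames(strengths) <- dn
  if (any(strengths < 0)) abort("All coupling strengths must be >= 0.", class = "ringcrf_parameter_error")
  if (any(widths <= 0) || any(widths >= 90)) {
    abort("All projection widths must be in (0, 90) degrees.", class = "ringcrf_parameter_error")
  }
  widths <- deg2rad(widths)
  dimnames(widths) <- dn
  structure(list(strengths = strengths, widths = widths),
            class = "ring_connectivity")
}

#' Orientation-tuned LGN drive for the rate model
#'
#' Feedforward input \eqn{I_A(\theta) = I_0(C)\, G(\theta - \theta_s; \sigma_A)}
#' whose peak varies logarithmically with contrast,
#' \eqn{I_0(C) = \max(0, \nu_0 \ln C)} with C in percent. The input tuning
#' width does not depend on contrast.
#'
#' @param sigma_E,sigma_I Input tuning widths in degrees.
#' @param nu0 Contrast coefficient: peak input at contrast C is
#'   `nu0 * log(C)` (clamped at 0; contrasts below 1\% give no input).
#' @return An `lgn_drive` object (widths stored in radians).
#' @export
lgn_drive <- function(sigma_E = 18.4, sigma_I = 22.2, nu0 = 1.5) {
  if (sigma_E <= 0 || sigma_I <= 0) abort("Input widths must be > 0.", class = "ringcrf_parameter_error")
  structure(list(sigma = c(E = deg2rad(sigma_E), I = deg2rad(sigma_I)), nu0 = nu0),
            class = "lgn_drive")
}

#' Peak LGN input at a given contrast
#' @param contrast Contrast in percent, in (0, 100].
#' @param drive An [lgn_drive()] object.
#' @return Peak input `max(0, nu0 * log(contrast))`.
#' @export
lgn_peak_input <- function(contrast, drive) {
  if (any(contrast <= 0) || any(contrast > 100)) {
    abort("`contrast` must be in (0, 100] percent.", class = "ringcrf_parameter_error")
  }
  pmax(0, drive$nu0 * log(contrast))
}

#' LGN input profile
#'
#' @param theta_pref Preferred orientation(s), radians.
#' @param theta_stim Stimulus orientation, radians.
#' @param contrast Contrast in percent, in (0, 100].
#' @param drive An [lgn_drive()] object.
#' @param pop `"E"` or `"I"` (selects the input tuning width).
#' @return Input values at `theta_pref`.
#' @export
lgn_input <- function(theta_pref, theta_stim, contrast, drive, pop = "E") {
  pop <- match.arg(pop, c("E", "I"))
  lgn_peak_input(contrast, drive) *
    periodic_gaussian(theta_pref - theta_stim, drive$sigma[[pop]])
}

#' Threshold power-law transfer function
#'
#' \eqn{\nu = g \lfloor I - I_\theta \rfloor_+^\beta}: zero at or below
#' threshold, strictly increasing above it.
#'
#' @param input Net input (any units).
#' @param pop A [population_params()] object.
#' @return Firing rate(s).
#' @export
transfer <- function(input, pop) {
  pop$gain * pmax(input - pop$threshold, 0)^pop$beta
}

# Output tuning widths under the Gaussian ansatz: sigma_A,out = sigma_A,lgn / sqrt(beta_A)
output_widths <- function(pops, drive) {
  c(E = drive$sigma[["E"]] / sqrt(pops$E$beta),
    I = drive$sigma[["I"]] / sqrt(pops$I$beta))
}

# Effective peak couplings Jt_AB: the ring convolution of the projection
# profile with a Gaussian activity profile of width sigma_B,out reduces, at
# the profile peak, to Jt_AB * nu_B0.
effective_couplings <- function(pops, conn, drive) {
  sw <- output_widths(pops, drive)
  Jt <- conn$strengths
  for (A in c("E", "I")) for (B in c("E", "I")) {
    Jt[A, B] <- conn$strengths[A, B] * conv_peak_factor(conn$widths[A, B], sw[[B]])
  }
  Jt
}

#' Projection widths enforcing exact contrast invariance
#'
#' Under the Gaussian ansatz the recurrent input to population A is a
#' periodic Gaussian of width \eqn{\sqrt{\sigma_{AB}^2 + \sigma_{B,lgn}^2/\beta_B}}
#' (variance additivity of the Gaussian convolution, with output widths
#' \eqn{\sigma_{B,lgn}/\sqrt{\beta_B}}). The total input keeps a single
#' Gaussian shape -- and the output width stays exactly contrast invariant --
#' only when every feedback profile matches the LGN input width of its
#' target:
#' \deqn{\sigma_{AB}^2 = \sigma_{A,lgn}^2 - \sigma_{B,lgn}^2/\beta_B.}
#'
#' @param sigma_lgn_E,sigma_lgn_I LGN input tuning widths, degrees.
#' @param beta_E,beta_I Transfer-function exponents of the source populations.
#' @return 2x2 matrix of projection widths in degrees (target rows A, source
#'   columns B).
#' @seealso [check_width_conditions()] for the per-entry residuals of
#'   arbitrary widths.
#' @export
design_widths <- function(sigma_lgn_E, sigma_lgn_I, beta_E, beta_I) {
  sl <- c(E = deg2rad(sigma_lgn_E), I = deg2rad(sigma_lgn_I))
  beta <- c(E = beta_E, I = beta_I)
  w <- matrix(NA_real_, 2, 2, dimnames = list(c("E", "I"), c("E", "I")))
  for (A in c("E", "I")) for (B in c("E", "I")) {
    v <- sl[[A]]^2 - sl[[B]]^2 / beta[[B]]
    if (v <= 0) {
      abort(sprintf(
        "Width condition infeasible for entry sigma_%s%s: required variance %.4g <= 0.",
        A, B, v), class = "ringcrf_infeasible_widths")
    }
    w[A, B] <- sqrt(v)
  }
  rad2deg(w)
}

#' Residuals of the contrast-invariance width conditions
#'
#' For arbitrary projection widths, returns the per-entry defect
#' \eqn{\sigma_{AB}^2 + \sigma_{B,lgn}^2/\beta_B - \sigma_{A,lgn}^2}
#' (in radians squared); all zeros means the feedback preserves the Gaussian
#' shape of the total input exactly.
#'
#' @param conn A [ring_connectivity()] object.
#' @param drive An [lgn_drive()] object.
#' @param pops Named list with [population_params()] entries `E` and `I`.
#' @return A tibble with columns `target`, `source`, `residual`.
#' @export
check_width_conditions <- function(conn, drive, pops) {
  out <- expand.grid(target = c("E", "I"), source = c("E", "I"),
                     stringsAsFactors = FALSE)
  out$residual <- mapply(function(A, B) {
    conn$widths[A, B]^2 + drive$sigma[[B]]^2 / pops[[B]]$beta - drive$sigma[[A]]^2
  }, out$target, out$source)
  as_tibble(out)
}

# Unique solution of nu = g * max(c - Jt_II * nu, 0)^beta (monotone crossing).
solve_inhibitory_branch <- function(c_I, g, beta, JtII, tol = 1e-12) {
  if (c_I <= 0) return(0)
  f <- function(nu) nu - g * pmax(c_I - JtII * nu, 0)^beta
  hi <- g * c_I^beta
  if (f(hi) <= 0) return(hi)
  uniroot(f, c(0, hi), tol = tol * max(1, hi))$root
}

#' Solve the self-consistency equations for the ring steady state
#'
#' Under the Gaussian ansatz (projection widths close to the
#' [design_widths()] conditions), the steady state reduces to two coupled
#' scalar equations for the peak rates:
#' \deqn{\nu_{E0} = g_E \lfloor I_{0E} + \tilde J_{EE}\nu_{E0} - \tilde J_{EI}\nu_{I0} \rfloor_+^{\beta_E}}
#' \deqn{\nu_{I0} = g_I \lfloor I_{0I} + \tilde J_{IE}\nu_{E0} - \tilde J_{II}\nu_{I0} \rfloor_+^{\beta_I}}
#' with output widths fixed at \eqn{\sigma_{A,lgn}/\sqrt{\beta_A}}. A damped
#' fixed-point iteration is tried first; on failure the solver falls back to
#' bracketed root-finding that scans for the lowest fixed point reachable
#' from rest, which also captures the suppression branch (`nu_E0 = 0`
#' exactly) at large input. If the width conditions are violated beyond
#' `width_tol` the ansatz is still applied and a warning flag is set.
#'
#' @inheritParams check_width_conditions
#' @param I0 Peak LGN input; a scalar (same drive to both populations) or a
#'   named vector `c(E =, I =)`.
#' @param damping Damping factor of the fixed-point iteration.
#' @param tol Absolute tolerance on the self-consistency defect.
#' @param max_iter Maximum fixed-point iterations before the fallback.
#' @param width_tol Tolerance (radians squared) on the width-condition
#'   residuals before `width_warning` is set.
#' @return A `steady_state` object: peak rates `nu_E0`, `nu_I0`, output
#'   widths `sigma_E`, `sigma_I` (degrees), `residual`, `converged`,
#'   `diverged`, `width_warning`.
#' @export
solve_selfconsistent <- function(pops, conn, drive, I0, damping = 0.5,
                                 tol = 1e-10, max_iter = 3000, width_tol = 1e-4) {
  I0 <- if (length(I0) == 1L) c(E = unname(I0), I = unname(I0)) else I0[c("E", "I")]
  Jt <- effective_couplings(pops, conn, drive)
  sw <- output_widths(pops, drive)
  width_warning <- any(abs(check_width_conditions(conn, drive, pops)$residual) > width_tol)

  gE <- pops$E$gain; bE <- pops$E$beta; thE <- pops$E$threshold
  gI <- pops$I$gain; bI <- pops$I$beta; thI <- pops$I$threshold
  fE <- function(nuE, nuI) gE * pmax(I0[["E"]] + Jt["E", "E"] * nuE - Jt["E", "I"] * nuI - thE, 0)^bE
  fI <- function(nuE, nuI) gI * pmax(I0[["I"]] + Jt["I", "E"] * nuE - Jt["I", "I"] * nuI - thI, 0)^bI
  cap <- 1e4

  result <- function(nuE, nuI, converged, diverged = FALSE) {
    res <- max(abs(nuE - fE(nuE, nuI)), abs(nuI - fI(nuE, nuI)))
    structure(list(nu_E0 = nuE, nu_I0 = nuI,
                   sigma_E = rad2deg(sw[["E"]]), sigma_I = rad2deg(sw[["I"]]),
                   residual = res, converged = converged && res <= sqrt(tol),
                   diverged = diverged, width_warning = width_warning,
                   effective_couplings = Jt, I0 = I0),
              class = "steady_state")
  }

  if (all(I0 <= 0) && thE >= 0 && thI >= 0) return(result(0, 0, TRUE))

  # fast path: damped fixed-point iteration
  nuE <- fE(0, 0); nuI <- fI(0, 0)
  ok <- FALSE
  for (it in seq_len(max_iter)) {
    nE <- (1 - damping) * nuE + damping * fE(nuE, nuI)
    nI <- (1 - damping) * nuI + damping * fI(nuE, nuI)
    if (!is.finite(nE) || !is.finite(nI) || nE > cap || nI > cap) break
    if (abs(nE - nuE) < tol && abs(nI - nuI) < tol) { nuE <- nE; nuI <- nI; ok <- TRUE; break }
    nuE <- nE; nuI <- nI
  }
  if (ok) return(result(nuE, nuI, TRUE))

  # fallback: bracketed root-finding on the excitatory branch, with the
  # inhibitory rate eliminated through its own (monotone) equation
  nuI_of <- function(nuE) solve_inhibitory_branch(I0[["I"]] + Jt["I", "E"] * nuE - thI,
                                                  gI, bI, Jt["I", "I"])
  FE <- function(nuE) nuE - fE(nuE, nuI_of(nuE))
  grid <- c(0, 10^seq(-6, log10(cap), length.out = 300))
  vals <- vapply(grid, FE, numeric(1))
  if (vals[1] == 0 && vals[2] > 0) return(result(0, nuI_of(0), TRUE))
  idx <- which(vals[-length(vals)] <= 0 & vals[-1] > 0)
  if (length(idx) == 0) {
    # no fixed point reachable from rest: runaway regime
    return(result(cap, nuI_of(cap), FALSE, diverged = TRUE))
  }
  i <- idx[1]
  root <- if (vals[i] == 0) grid[i] else
    uniroot(FE, c(grid[i], grid[i + 1]), tol = tol)$root
  result(root, nuI_of(root), TRUE)
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("Ring steady state: nu_E0 = %.4g, nu_I0 = %.4g (sigma_E = %.3g deg, sigma_I = %.3g deg)\n",
              x$nu_E0, x$nu_I0, x$sigma_E, x$sigma_I))
  cat(sprintf("  residual %.3g, converged %s%s%s\n", x$residual, x$converged,
              if (x$diverged) ", DIVERGED (runaway)" else "",
              if (x$width_warning) ", width conditions violated" else ""))
  invisible(x)
}

#' @export
tidy.steady_state <- function(x, ...) {
  tibble(pop = c("E", "I"), peak_rate = c(x$nu_E0, x$nu_I0),
         width_deg = c(x$sigma_E, x$sigma_I))
}

#' @export
glance.steady_state <- function(x, ...) {
  tibble(residual = x$residual, converged = x$converged, diverged = x$diverged,
         width_warning = x$width_warning)
}
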