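# Shared nonlinear least-squares helpers --------------------------------------

# Curvature-based covariance of a least-squares fit: sigma^2 * (J'J)^-1 with
# J the Jacobian of predictions w.r.t. parameters at the optimum.
lsq_se <- function(jac, resid, n_par) {
  n <- length(resid)
  dof <- max(n - n_par, 1)
  s2 <- sum(resid^2) / dof
  JtJ <- crossprod(jac)
  cov <- try(s2 * solve(JtJ), silent = TRUE)
  if (inherits(cov, "try-error") || any(!is.finite(diag(cov))) || any(diag(cov) < 0)) {
    return(rep(Inf, n_par))
  }
  sqrt(diag(cov))
}

num_jacobian <- function(fn, par, eps = 1e-6) {
  f0 <- fn(par)
  J <- matrix(NA_real_, length(f0), length(par))
  for (j in seq_along(par)) {
    h <- eps * max(abs(par[j]), 1)
    pp <- par; pp[j] <- pp[j] + h
    pm <- par; pm[j] <- pm[j] - h
    J[, j] <- (fn(pp) - fn(pm)) / (2 * h)
  }
  J
}

#' The 12-level geometric contrast grid
#'
#' Contrast levels increasing geometrically, mirroring the standard
#' experimental protocol for contrast-response measurements.
#'
#' @param n Number of levels.
#' @param from,to Lowest and highest contrast in percent.
#' @return Numeric vector of contrasts.
#' @export
crf_contrast_grid <- function(n = 12, from = 2, to = 90) {
  exp(seq(log(from), log(to), length.out = n))
}

# Threshold power law ----------------------------------------------------------

#' Fit a threshold power law to an f-I or V-I curve
#'
#' Least-squares fit of \eqn{y = g\lfloor I - I_c\rfloor_+^\beta} (plus an
#' additive offset for V-I curves when `offset = TRUE`), optionally
#' restricted to a response range (e.g. rates in [0, 30] Hz). The gain (and
#' offset) are profiled linearly; the threshold and exponent are optimized
#' by Nelder-Mead with multi-start over `beta_starts`. Standard errors come
#' from the local quadratic (Gauss-Newton) approximation of the objective.
#'
#' @param data Data frame with the input and response columns.
#' @param input,response Column names (strings).
#' @param response_range Optional `c(lo, hi)`: only points with responses in
#'   this range enter the fit.
#' @param input_range Optional `c(lo, hi)` restriction on the input.
#' @param offset If `TRUE`, fit `y = y0 + g floor(I - Ic)^beta` (for V-I
#'   curves).
#' @param beta_starts Multi-start grid for the exponent.
#' @param beta_bounds Allowed exponent range (guards against the
#'   logarithmic degeneracy of the power law as the exponent approaches 0).
#' @return A `powerlaw_fit` object with elements `gain`, `beta`,
#'   `threshold`, `offset`, `se` (per-parameter standard errors), `rss`,
#'   `n`, `fit_range`, `degenerate`.
#' @export
fit_powerlaw <- function(data, input = "I", response = "rate",
                         response_range = NULL, input_range = NULL,
                         offset = FALSE, beta_starts = c(0.5, 1, 2, 3, 4),
                         beta_bounds = c(0.05, 12)) {
  I <- data[[input]]; y <- data[[response]]
  keep <- is.finite(I) & is.finite(y)
  if (!is.null(response_range)) keep <- keep & y >= response_range[1] & y <= response_range[2]
  if (!is.null(input_range)) keep <- keep & I >= input_range[1] & I <= input_range[2]
  I <- I[keep]; y <- y[keep]
  if (length(I) < 6) abort("Need at least 6 points in the fit range.",
                           class = "ringcrf_fit_error")
  o <- order(I); I <- I[o]; y <- y[o]
  span <- diff(range(I))

  # linear profile of g (and offset) given (Ic, beta)
  profile <- function(Ic, beta) {
    x <- pmax(I - Ic, 0)^beta
    if (offset) {
      X <- cbind(1, x)
      cf <- try(qr.coef(qr(X), y), silent = TRUE)
      if (inherits(cf, "try-error") || anyNA(cf)) return(NULL)
      list(g = cf[2], y0 = cf[1], pred = X %*% cf)
    } else {
      denom <- sum(x^2)
      if (denom <= 0) return(NULL)
      g <- sum(x * y) / denom
      list(g = g, y0 = 0, pred = g * x)
    }
  }
  obj <- function(p) {
    Ic <- p[1]; beta <- exp(p[2])
    if (beta < beta_bounds[1] || beta > beta_bounds[2]) return(1e12)
    pr <- profile(Ic, beta)
    if (is.null(pr) || pr$g <= 0) return(1e12)
    sum((y - pr$pred)^2)
  }
  # threshold start: last input with (near-)zero response, else min input
  base <- if (offset) min(y) else 0
  i0 <- which(y <= base + 0.02 * (max(y) - base))
  Ic_starts <- unique(c(if (length(i0)) I[max(i0)], min(I) - 0.05 * span, min(I)))
  best <- NULL
  for (b in beta_starts) for (Ic in Ic_starts) {
    fit <- optim(c(Ic, log(b)), obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  Ic <- best$par[1]; beta <- exp(best$par[2])
  pr <- profile(Ic, beta)
  par <- c(gain = unname(pr$g), threshold = unname(Ic), beta = unname(beta))
  if (offset) par <- c(par, offset = unname(pr$y0))
  pred_fn <- function(p) {
    x <- pmax(I - p[["threshold"]], 0)^p[["beta"]]
    p[["gain"]] * x + if (offset) p[["offset"]] else 0
  }
  resid <- y - pred_fn(par)
  J <- num_jacobian(pred_fn, par)
  se <- lsq_se(J, resid, length(par))
  names(se) <- names(par)
  structure(list(gain = unname(par[["gain"]]), beta = unname(par[["beta"]]),
                 threshold = unname(par[["threshold"]]),
                 offset = if (offset) unname(par[["offset"]]) else 0,
                 has_offset = offset,
                 se = se, rss = sum(resid^2), n = length(I),
                 fit_range = range(I), response_range = response_range,
                 degenerate = any(!is.finite(se)),
                 data = tibble(I = I, y = y, fitted = y - resid)),
            class = "powerlaw_fit")
}

#' Evaluate a fitted threshold power law
#' @param object A `powerlaw_fit`.
#' @param I Input values.
#' @param ... Unused.
#' @export
predict.powerlaw_fit <- function(object, I, ...) {
  object$offset + object$gain * pmax(I - object$threshold, 0)^object$beta
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("Threshold power law: g = %.4g, beta = %.3f, Ic = %.4g (n = %d, rss = %.3g)%s\n",
              x$gain, x$beta, x$threshold, x$n, x$rss,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' @export
tidy.powerlaw_fit <- function(x, ...) {
  nm <- c("gain", "threshold", "beta", if (x$has_offset) "offset")
  est <- c(x$gain, x$threshold, x$beta, if (x$has_offset) x$offset)
  tibble(term = nm, estimate = est, std.error = unname(x$se[nm]))
}

#' @export
glance.powerlaw_fit <- function(x, ...) {
  tibble(rss = x$rss, n = x$n, degenerate = x$degenerate)
}

# Hyperbolic-ratio (Naka-Rushton) CRF ------------------------------------------

#' Fit a hyperbolic-ratio contrast-response function
#'
#' Least-squares fit of the H-ratio (Naka-Rushton) function
#' \deqn{R(C) = R_{max}\, C^n / (C^n + C_{50}^n)}
#' with multi-start over the exponent. Per-parameter relative errors are the
#' curvature-based standard deviations divided by the estimates; the fit is
#' flagged `good` when all three relative errors are below 0.15.
#'
#' @param data Data frame of contrast/response pairs.
#' @param contrast,response Column names (strings).
#' @param n_starts Multi-start grid for the exponent.
#' @return An `hratio_fit` object with `R_max`, `C50`, `n_exp`, `se`,
#'   `rel_error`, `good`, `rss`.
#' @export
fit_hratio <- function(data, contrast = "contrast", response = "response",
                       n_starts = c(1, 2, 4, 6)) {
  C <- data[[contrast]]; y <- data[[response]]
  keep <- is.finite(C) & is.finite(y) & C > 0
  C <- C[keep]; y <- y[keep]
  failed <- function() structure(
    list(R_max = NA_real_, C50 = NA_real_, n_exp = NA_real_,
         se = c(R_max = Inf, C50 = Inf, n_exp = Inf),
         rel_error = c(R_max = Inf, C50 = Inf, n_exp = Inf),
         good = FALSE, rss = NA_real_, n = length(C),
         data = tibble(contrast = C, response = y, fitted = NA_real_)),
    class = "hratio_fit")
  if (length(C) < 5 || max(y) <= 0) {
    if (length(C) < 5) abort("Need at least 5 contrast levels.", class = "ringcrf_fit_error")
    return(failed())
  }
  half <- max(y) / 2
  if (!any(y < half) || !any(y > half)) {
    warn("CRF does not straddle its apparent half-response; fit may be poorly constrained.")
  }
  profile <- function(c50, n) {
    x <- C^n / (C^n + c50^n)
    denom <- sum(x^2)
    if (denom <= 0) return(NULL)
    g <- sum(x * y) / denom
    list(R = g, pred = g * x)
  }
  obj <- function(p) {
    pr <- profile(exp(p[1]), exp(p[2]))
    if (is.null(pr) || pr$R <= 0) return(1e12)
    sum((y - pr$pred)^2)
  }
  c50_starts <- c(stats::median(C), max(C))
  best <- NULL
  for (n0 in n_starts) for (c0 in c50_starts) {
    fit <- optim(log(c(c0, n0)), obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  c50 <- exp(best$par[1]); n_exp <- exp(best$par[2])
  pr <- profile(c50, n_exp)
  if (is.null(pr)) return(failed())
  par <- c(R_max = unname(pr$R), C50 = unname(c50), n_exp = unname(n_exp))
  pred_fn <- function(p) p[["R_max"]] * C^p[["n_exp"]] / (C^p[["n_exp"]] + p[["C50"]]^p[["n_exp"]])
  resid <- y - pred_fn(par)
  J <- num_jacobian(pred_fn, par)
  se <- lsq_se(J, resid, 3)
  names(se) <- names(par)
  rel <- se / abs(par)
  structure(list(R_max = unname(par[["R_max"]]), C50 = unname(par[["C50"]]),
                 n_exp = unname(par[["n_exp"]]),
                 se = se, rel_error = rel,
                 good = all(is.finite(rel)) && all(rel < 0.15),
                 rss = sum(resid^2), n = length(C),
                 data = tibble(contrast = C, response = y, fitted = y - resid)),
            class = "hratio_fit")
}

#' Evaluate a fitted H-ratio function
#' @param object An `hratio_fit`.
#' @param contrast Contrasts in percent.
#' @param ... Unused.
#' @export
predict.hratio_fit <- function(object, contrast, ...) {
  object$R_max * contrast^object$n_exp /
    (contrast^object$n_exp + object$C50^object$n_exp)
}

#' @export
print.hratio_fit <- function(x, ...) {
  cat(sprintf("H-ratio fit: R_max = %.4g, C50 = %.3g%%, n = %.3g (good: %s)\n",
              x$R_max, x$C50, x$n_exp, x$good))
  invisible(x)
}

#' @export
tidy.hratio_fit <- function(x, ...) {
  tibble(term = c("R_max", "C50", "n_exp"),
         estimate = c(x$R_max, x$C50, x$n_exp),
         std.error = unname(x$se),
         rel.error = unname(x$rel_error))
}

#' @export
glance.hratio_fit <- function(x, ...) {
  tibble(rss = x$rss, n = x$n, good = x$good)
}

#' Bootstrap standard errors of an H-ratio fit
#'
#' Case resampling of the contrast/response pairs; a cross-check for the
#' curvature-based standard errors.
#'
#' @param data,contrast,response As in [fit_hratio()].
#' @param n_boot Number of resamples.
#' @return Named vector of bootstrap parameter SDs.
#' @export
bootstrap_hratio_se <- function(data, contrast = "contrast",
                                response = "response", n_boot = 200) {
  n <- nrow(data)
  est <- matrix(NA_real_, n_boot, 3)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(data[[contrast]][idx])) < 5) next
    f <- try(suppressWarnings(fit_hratio(data[idx, ], contrast, response)), silent = TRUE)
    if (!inherits(f, "try-error") && is.finite(f$R_max)) {
      est[b, ] <- c(f$R_max, f$C50, f$n_exp)
    }
  }
  apply(est, 2, sd, na.rm = TRUE) |> stats::setNames(c("R_max", "C50", "n_exp"))
}

# Periodic-Gaussian tuning curve ----------------------------------------------

#' Fit a periodic Gaussian to an orientation tuning curve
#'
#' Least-squares fit of \eqn{R(\theta) = A\,G(\theta - \theta_0; \sigma) + B}
#' with the pi-periodic Gaussian; the amplitude and offset are profiled
#' linearly, the center and width optimized by Nelder-Mead with multi-start
#' over the width. The offset is fixed at zero with `fix_offset = TRUE`
#' (rate-model profiles have no baseline activity).
#'
#' @param data Data frame with orientation (degrees) and response columns.
#' @param theta,response Column names (strings).
#' @param fix_offset Fix the offset `B` at 0.
#' @param sigma_starts Multi-start width grid, degrees.
#' @return A `gaussian_fit` object with `amplitude`, `sigma` (degrees),
#'   `center` (degrees), `offset`, `se`, `rss`.
#' @export
fit_gaussian_tuning <- function(data, theta = "theta", response = "rate",
                                fix_offset = FALSE,
                                sigma_starts = c(5, 10, 20, 40)) {
  th <- deg2rad(data[[theta]]); y <- data[[response]]
  keep <- is.finite(th) & is.finite(y)
  th <- th[keep]; y <- y[keep]
  if (length(th) < 5) abort("Need at least 5 points.", class = "ringcrf_fit_error")
  if (max(y) - min(y) < 1e-6 * max(abs(max(y)), 1e-12)) {
    abort("Tuning curve is flat: degenerate fit.", class = "ringcrf_degenerate_fit")
  }
  profile <- function(th0, sigma) {
    x <- periodic_gaussian(th - th0, sigma)
    if (fix_offset) {
      denom <- sum(x^2)
      if (denom <= 0) return(NULL)
      A <- sum(x * y) / denom
      list(A = A, B = 0, pred = A * x)
    } else {
      X <- cbind(1, x)
      cf <- try(qr.coef(qr(X), y), silent = TRUE)
      if (inherits(cf, "try-error") || anyNA(cf)) return(NULL)
      list(A = cf[2], B = cf[1], pred = X %*% cf)
    }
  }
  obj <- function(p) {
    pr <- profile(p[1], exp(p[2]))
    if (is.null(pr) || pr$A <= 0) return(1e12)
    sum((y - pr$pred)^2)
  }
  th0_start <- th[which.max(y)]
  best <- NULL
  for (s0 in sigma_starts) {
    fit <- optim(c(th0_start, log(deg2rad(s0))), obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  th0 <- best$par[1]; sigma <- exp(best$par[2])
  # wrap the center back to [-90, 90)
  th0 <- (th0 + pi / 2) %% pi - pi / 2
  pr <- profile(th0, sigma)
  par <- c(amplitude = unname(pr$A), center = unname(th0), sigma = unname(sigma))
  if (!fix_offset) par <- c(par, offset = unname(pr$B))
  pred_fn <- function(p) {
    x <- periodic_gaussian(th - p[["center"]], p[["sigma"]])
    p[["amplitude"]] * x + if (fix_offset) 0 else p[["offset"]]
  }
  resid <- y - pred_fn(par)
  J <- num_jacobian(pred_fn, par)
  se <- lsq_se(J, resid, length(par))
  names(se) <- names(par)
  se[c("center", "sigma")] <- rad2deg(se[c("center", "sigma")])
  structure(list(amplitude = unname(par[["amplitude"]]),
                 sigma = rad2deg(sigma), center = rad2deg(th0),
                 offset = if (fix_offset) 0 else unname(par[["offset"]]),
                 fix_offset = fix_offset,
                 se = se, rss = sum(resid^2), n = length(th)),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("Periodic-Gaussian tuning fit: A = %.4g, sigma = %.3g deg, center = %.3g deg, B = %.3g\n",
              x$amplitude, x$sigma, x$center, x$offset))
  invisible(x)
}

#' @export
tidy.gaussian_fit <- function(x, ...) {
  nm <- c("amplitude", "center", "sigma", if (!x$fix_offset) "offset")
  est <- c(x$amplitude, x$center, x$sigma, if (!x$fix_offset) x$offset)
  tibble(term = nm, estimate = est, std.error = unname(x$se[nm]))
}

#' @export
glance.gaussian_fit <- function(x, ...) {
  tibble(rss = x$rss, n = x$n)
}
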