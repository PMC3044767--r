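#' Classify a contrast-response function as saturating, non-saturating or
#' supersaturating
#'
#' The fitted H-ratio curve is extrapolated to 100\% contrast (the reference
#' response). The CRF is `supersaturating` when at least one measured
#' response at a contrast below 90\% exceeds 1.05 times the reference,
#' `non_saturating` when the reference is below 0.95 of the fitted
#' \eqn{R_{max}}, and `saturating` otherwise. The classification is
#' invariant under a common rescaling of the responses.
#'
#' @param fit An [fit_hratio()] result.
#' @param data Optional data frame of the measured CRF (defaults to the data
#'   stored in the fit).
#' @param contrast,response Column names in `data`.
#' @return One of `"saturating"`, `"non_saturating"`, `"supersaturating"`
#'   (NA for failed fits).
#' @export
classify_saturation <- function(fit, data = NULL, contrast = "contrast",
                                response = "response") {
  if (!is.finite(fit$R_max)) return(NA_character_)
  if (is.null(data)) {
    C <- fit$data$contrast; y <- fit$data$response
  } else {
    C <- data[[contrast]]; y <- data[[response]]
  }
  ref <- predict(fit, 100)
  if (any(y[C < 90] > 1.05 * ref)) return("supersaturating")
  if (ref < 0.95 * fit$R_max) return("non_saturating")
  "saturating"
}

#' Maximum fractional deviation of tuning width across contrasts
#'
#' Contrast invariance metric: the maximum over contrasts of
#' \eqn{|\sigma(C) - \sigma(C_{ref})| / \sigma(C_{ref})}, with the lowest
#' contrast as reference.
#'
#' @param data Data frame of per-contrast fitted widths.
#' @param contrast,width Column names (strings).
#' @return The maximum fractional deviation (0 for identical widths).
#' @export
invariance_metric <- function(data, contrast = "contrast", width = "width") {
  C <- data[[contrast]]; w <- data[[width]]
  keep <- is.finite(C) & is.finite(w)
  C <- C[keep]; w <- w[keep]
  if (length(C) < 2) abort("Need widths at >= 2 contrasts.", class = "ringcrf_parameter_error")
  ref <- w[which.min(C)]
  max(abs(w - ref) / ref)
}

#' Pairwise correlations between CRF fit parameters
#'
#' For the good-fit subset, computes the Pearson correlation with the
#' Fisher z-transform p-value and the Spearman rank correlation with its
#' p-value, for the pairs (R_max, C50), (R_max, n) and (C50, n).
#'
#' @param fits Data frame with one row per neuron and columns `R_max`,
#'   `C50`, `n_exp` and logical `good` (rows with `good = FALSE` are
#'   excluded). Optionally a `pop` column for per-population results.
#' @param by_pop Split by the `pop` column when present.
#' @return A tibble with columns `pop` (if requested), `pair`, `r`,
#'   `p_fisher`, `rho`, `p_spearman`, `n`.
#' @export
correlate_params <- function(fits, by_pop = "pop" %in% names(fits)) {
  one_group <- function(df, popname = NA_character_) {
    df <- df[df$good & is.finite(df$R_max) & is.finite(df$C50) & is.finite(df$n_exp), ]
    if (nrow(df) < 10) {
      abort("Fewer than 10 good-fit neurons: insufficient data for correlations.",
            class = "ringcrf_insufficient_data")
    }
    pairs <- list(c("R_max", "C50"), c("R_max", "n_exp"), c("C50", "n_exp"))
    rows <- lapply(pairs, function(p) {
      x <- df[[p[1]]]; y <- df[[p[2]]]
      r <- cor(x, y)
      # Fisher z: atanh(r) * sqrt(n - 3) is standard normal under the null
      z <- atanh(min(max(r, -1 + 1e-12), 1 - 1e-12)) * sqrt(length(x) - 3)
      p_f <- 2 * pnorm(-abs(z))
      sp <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
      tibble(pop = popname, pair = paste(p, collapse = "-"),
             r = r, p_fisher = p_f,
             rho = unname(sp$estimate), p_spearman = sp$p.value,
             n = length(x))
    })
    bind_rows(rows)
  }
  if (by_pop) {
    out <- bind_rows(lapply(split(fits, fits$pop), function(d) one_group(d, d$pop[1])))
  } else {
    out <- one_group(fits)
    out$pop <- NULL
  }
  out
}
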