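#' Load and validate a run configuration
#'
#' YAML configuration with sections `model` (`rate` or `cbm`), `populations`,
#' `connectivity`, `drive`, `solver` and `seeds`. Missing values are filled
#' from the package defaults and every filled default is recorded in the
#' `defaults_filled` attribute so that runs never silently rely on values
#' the user did not set.
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config` list with attribute `defaults_filled`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path),
                                class = "ringcrf_config_error")
  raw <- yaml::read_yaml(path)
  defaults <- list(
    model = "rate",
    populations = list(
      E = list(N = 100, tau = 10, gain = 1, beta = 1.5),
      I = list(N = 100, tau = 10, gain = 3, beta = 2.2)),
    connectivity = list(J_EE = 1, J_EI = 4, J_IE = 1, J_II = 3,
                        widths = "design"),
    drive = list(sigma_E = 15 * sqrt(1.5), sigma_I = 15 * sqrt(2.2),
                 nu0 = 1.5, nu_max = 6, C50_input = 17.2, n_input = 1.4),
    solver = list(dt = 1, tol = 1e-10, damping = 0.5, rate_cap = 1e4),
    seeds = list(master = 1))
  known <- names(defaults)
  unknown <- setdiff(names(raw), known)
  violations <- character()
  if (length(unknown)) {
    violations <- c(violations, sprintf("unknown section(s): %s",
                                        paste(unknown, collapse = ", ")))
  }
  filled <- character()
  cfg <- defaults
  for (sec in intersect(names(raw), known)) {
    if (is.list(defaults[[sec]]) && is.list(raw[[sec]])) {
      bad <- setdiff(names(raw[[sec]]), c(names(defaults[[sec]]), "E", "I"))
      if (length(bad)) {
        violations <- c(violations, sprintf("unknown key(s) in %s: %s", sec,
                                            paste(bad, collapse = ", ")))
      }
      cfg[[sec]] <- utils::modifyList(defaults[[sec]], raw[[sec]])
    } else {
      cfg[[sec]] <- raw[[sec]]
    }
  }
  for (sec in known) {
    if (!sec %in% names(raw)) filled <- c(filled, sec)
  }
  # range validation
  if (!cfg$model %in% c("rate", "cbm")) {
    violations <- c(violations, "model must be 'rate' or 'cbm'")
  }
  for (p in c("E", "I")) {
    pp <- cfg$populations[[p]]
    if (!is.null(pp)) {
      if (pp$tau <= 0) violations <- c(violations, sprintf("populations$%s$tau must be > 0", p))
      if (pp$beta <= 0) violations <- c(violations, sprintf("populations$%s$beta must be > 0", p))
      if (pp$gain <= 0) violations <- c(violations, sprintf("populations$%s$gain must be > 0", p))
    }
  }
  for (k in c("J_EE", "J_EI", "J_IE", "J_II")) {
    if (cfg$connectivity[[k]] < 0) violations <- c(violations, sprintf("connectivity$%s must be >= 0", k))
  }
  if (!identical(cfg$connectivity$widths, "design")) {
    w <- unlist(cfg$connectivity$widths)
    if (any(w <= 0) || any(w >= 90)) {
      violations <- c(violations, "connectivity$widths must be in (0, 90) degrees")
    }
  }
  if (cfg$drive$sigma_E <= 0 || cfg$drive$sigma_I <= 0) {
    violations <- c(violations, "drive widths must be > 0")
  }
  if (length(violations)) {
    abort(paste0("Invalid configuration:\n- ",
                 paste(violations, collapse = "\n- ")),
          class = "ringcrf_config_error")
  }
  attr(cfg, "defaults_filled") <- filled
  class(cfg) <- "run_config"
  cfg
}

#' Write a configuration back to YAML
#'
#' `load_config(write_config(cfg, f))` reproduces `cfg` (lossless
#' round-trip).
#'
#' @param cfg A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  x <- unclass(cfg)
  attr(x, "defaults_filled") <- NULL
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Assemble rate-model objects from a configuration
#'
#' @param cfg A `run_config` (model `rate`).
#' @return A list with `pops`, `conn`, `drive`.
#' @export
rate_model_from_config <- function(cfg) {
  pops <- list(
    E = population_params("E", N = cfg$populations$E$N, tau = cfg$populations$E$tau,
                          gain = cfg$populations$E$gain, beta = cfg$populations$E$beta),
    I = population_params("I", N = cfg$populations$I$N, tau = cfg$populations$I$tau,
                          gain = cfg$populations$I$gain, beta = cfg$populations$I$beta))
  if (identical(cfg$connectivity$widths, "design")) {
    widths <- design_widths(cfg$drive$sigma_E, cfg$drive$sigma_I,
                            pops$E$beta, pops$I$beta)
  } else {
    widths <- matrix(unlist(cfg$connectivity$widths), 2, 2, byrow = TRUE)
  }
  strengths <- matrix(c(cfg$connectivity$J_EE, cfg$connectivity$J_IE,
                        cfg$connectivity$J_EI, cfg$connectivity$J_II), 2, 2,
                      dimnames = list(c("E", "I"), c("E", "I")))
  conn <- ring_connectivity(strengths, widths)
  drive <- lgn_drive(cfg$drive$sigma_E, cfg$drive$sigma_I, cfg$drive$nu0)
  list(pops = pops, conn = conn, drive = drive)
}

#' Generate synthetic fixtures with known ground truth
#'
#' Exact model families (pi-periodic Gaussian tuning curve, hyperbolic-ratio
#' CRF, threshold power law) with optional additive Gaussian noise, for
#' fitter recovery tests.
#'
#' @param kind `"tuning"`, `"crf"` or `"fi"`.
#' @param truth Named list of true parameters: tuning `A`, `sigma`
#'   (degrees), `B`, `center`; crf `R_max`, `C50`, `n`; fi `g`, `beta`,
#'   `Ic`.
#' @param noise_sd Additive noise SD (response units).
#' @param seed RNG seed.
#' @param x Optional sampling grid (degrees, percent contrast, or current).
#' @return A list: `data` (tibble) and `truth`.
#' @export
generate_fixture <- function(kind = c("tuning", "crf", "fi"), truth = list(),
                             noise_sd = 0, seed = 1, x = NULL) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (kind == "tuning") {
    tr <- utils::modifyList(list(A = 30, sigma = 15, B = 2, center = 0), truth)
    if (is.null(x)) x <- seq(-90, 85, by = 5)
    y <- tr$A * periodic_gaussian(deg2rad(x - tr$center), deg2rad(tr$sigma)) + tr$B
    data <- tibble(theta = x, rate = y + rnorm(length(y), 0, noise_sd))
  } else if (kind == "crf") {
    tr <- utils::modifyList(list(R_max = 40, C50 = 20, n = 3), truth)
    if (is.null(x)) x <- crf_contrast_grid()
    y <- tr$R_max * x^tr$n / (x^tr$n + tr$C50^tr$n)
    data <- tibble(contrast = x, response = y + rnorm(length(y), 0, noise_sd))
  } else {
    tr <- utils::modifyList(list(g = 5, beta = 2, Ic = 1), truth)
    if (is.null(x)) x <- seq(0, 4, by = 0.25)
    y <- tr$g * pmax(x - tr$Ic, 0)^tr$beta
    data <- tibble(I = x, rate = y + rnorm(length(y), 0, noise_sd))
  }
  list(data = data, truth = tr, kind = kind)
}

#' Write a run record
#'
#' JSON snapshot of a finished run: configuration, package version, timing,
#' warnings (e.g. width-condition residuals or defaulted parameters). The
#' record is written atomically (temp file + rename).
#'
#' @param path Output path (JSON).
#' @param config The configuration used (list).
#' @param timings Named numeric vector of per-stage timings, seconds.
#' @param warnings Character vector of warnings and fallback notes.
#' @param extra Optional named list merged into the record.
#' @return `path`, invisibly.
#' @export
write_run_record <- function(path, config = NULL, timings = NULL,
                             warnings = character(), extra = list()) {
  rec <- c(list(
    package = "ringcrf",
    version = as.character(utils::packageVersion("ringcrf")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    timings = as.list(timings),
    warnings = warnings), extra)
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(rec, tmp, auto_unbox = TRUE, digits = NA, null = "null")
  file.rename(tmp, path)
  invisible(path)
}
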