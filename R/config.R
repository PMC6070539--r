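#' Simulation run configuration
#'
#' Assembles and validates the full parameter set of a diversification run.
#' Defaults follow the study conditions: a 3 x 3 gradient landscape with
#' optimum spacing `delta_x = 1`, `K_star = 150`, `sigma_K = 1`,
#' `sigma_C = 0.4`, barrier rates `f = 1e-3` and `c = 5e-5` (pace 4.76e-5,
#' isolation 95\%), no catastrophes, `GIT = 15`, `AMT = 0.01`, 16 loci per
#' trait, mate-search cap 50, incompatibility mutation rate `mu_n = 1e-3`,
#' horizon 100,000 generations sampled every 100 generations, and 150
#' founders per site.
#'
#' Unknown argument names are errors, so typos in sweep scripts fail loudly
#' rather than silently running defaults.
#'
#' @param ... Named overrides of any default listed by
#'   `names(clade_config())`.
#' @return A validated list of class `"clade_config"`.
#' @examples
#' cfg <- clade_config(K_star = 75, horizon = 2e4)
#' cfg$K_star
#' @export
clade_config <- function(...) {
  defaults <- list(
    # landscape
    n = 3L, landscape = "gradient", delta_x = 1.0, random_width = 4.0,
    f = 1e-3, c = 5e-5, cr = 0.0, borders_closed = FALSE,
    # ecology
    r = 1.0, K_star = 150, sigma_K = 1.0, sigma_C = 0.4, m = 1.0,
    dispersal = "island",
    # genetics
    L_x = 16L, L_a = 16L, mu_k = 1e-3, s_x = 0.1, s_a = 0.2,
    mu_n = 1e-3, init_sd = 0.1,
    # mating; c_am calibrated so that homogamy (a > 0) evolves, see the
    # methods vignette
    c_am = 0.2, AMT = 0.01, GIT = 15, max_tries = 50L,
    # run control
    horizon = 100000, snap_interval = 100, init_per_site = 150L,
    record_vitals = FALSE, check_propensities = FALSE,
    # measurement
    gap_threshold = NA_real_  # subpopulation clustering gap; NA -> sigma_C / 2
  )
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("all configuration overrides must be named")
    unknown <- setdiff(names(over), names(defaults))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    defaults[names(over)] <- over
  }
  cfg <- defaults
  validate_config(cfg)
  if (is.na(cfg$gap_threshold)) cfg$gap_threshold <- cfg$sigma_C / 2
  structure(cfg, class = "clade_config")
}

validate_config <- function(cfg) {
  problems <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  chk(is.numeric(cfg$n) && cfg$n >= 1, "'n' must be a positive integer")
  chk(cfg$landscape %in% c("gradient", "random"),
      "'landscape' must be 'gradient' or 'random'")
  chk(cfg$delta_x > 0, "'delta_x' must be > 0")
  chk(cfg$random_width >= 0, "'random_width' must be >= 0")
  chk(all(c(cfg$f, cfg$c, cfg$cr) >= 0), "rates f, c, cr must be >= 0")
  chk(cfg$r > 0, "'r' must be > 0")
  chk(cfg$K_star > 0, "'K_star' must be > 0")
  chk(cfg$sigma_K > cfg$sigma_C, "'sigma_K' must exceed 'sigma_C'")
  chk(cfg$sigma_C > 0, "'sigma_C' must be > 0")
  chk(cfg$m >= 0 && cfg$m <= 1, "'m' must be in [0, 1]")
  chk(cfg$dispersal %in% c("island", "stay_move"),
      "'dispersal' must be 'island' or 'stay_move'")
  chk(cfg$L_x >= 1 && cfg$L_a >= 1, "locus numbers must be >= 1")
  chk(cfg$mu_k >= 0 && cfg$mu_k <= 1, "'mu_k' must be a probability")
  chk(cfg$mu_n >= 0 && cfg$mu_n <= 1, "'mu_n' must be a probability")
  chk(cfg$s_x >= 0 && cfg$s_a >= 0, "mutational s.d. must be >= 0")
  chk(cfg$init_sd >= 0, "'init_sd' must be >= 0")
  chk(cfg$c_am > 0, "'c_am' must be > 0")
  chk(cfg$AMT > 0 && cfg$AMT < 1, "'AMT' must be in (0, 1)")
  chk(cfg$GIT >= 1, "'GIT' must be >= 1")
  chk(cfg$max_tries >= 1, "'max_tries' must be >= 1")
  chk(cfg$horizon > 0, "'horizon' must be > 0")
  chk(cfg$snap_interval > 0 && cfg$snap_interval <= cfg$horizon,
      "'snap_interval' must be in (0, horizon]")
  chk(cfg$init_per_site >= 1, "'init_per_site' must be >= 1")
  if (length(problems))
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  invisible(cfg)
}

#' @export
print.clade_config <- function(x, ...) {
  cat("<clade_config>\n")
  for (k in names(x)) cat(sprintf("  %-18s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Read a run configuration from a YAML file
#'
#' The file must contain only known configuration keys (see
#' [clade_config()]); unknown keys are itemized validation errors.
#'
#' @param path Path to a YAML file of configuration keys.
#' @return A `"clade_config"`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) stop("configuration file must be a YAML mapping")
  # YAML 1.1 parses a bare `n` key as the boolean FALSE; map it back to the
  # grid-side key
  names(vals)[names(vals) %in% c("FALSE", "false")] <- "n"
  do.call(clade_config, vals)
}

#' Write a run configuration to YAML
#'
#' @param config A `"clade_config"`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "clade_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
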