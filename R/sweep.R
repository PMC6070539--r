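#' Macroevolutionary summary of one run
#'
#' The four headline quantities of a diversification run: the stage-1
#' diversification rate (`(n_optima - 1) / stage-1 duration`, species per
#' generation), the stage-2 diversification rate (initial slope of the von
#' Bertalanffy fit started at the end of stage 1), the stationary turnover
#' rate, and the stationary species diversity (median diversity over the
#' stationary window).
#'
#' @param sim A `"clade_sim"`.
#' @param history Optional pre-computed `"lineage_history"` (computed if
#'   missing).
#' @param n_optima Number of environmental optima.
#' @return One-row data.frame with `stage1_rate`, `stage2_rate`, `turnover`,
#'   `stationary_N`, `stage1_end`, `stage2_end`, `extinct`.
#' @export
run_summary <- function(sim, history = NULL, n_optima = sim$config$n^2) {
  if (is.null(history)) history <- track_lineages(sim)
  div <- history$diversity
  stages <- detect_stages(div, max_range_path(history), n_optima)
  stat <- stationary_window(div)
  stage1_rate <- if (!is.na(stages$stage1_end) && stages$stage1_end > 0)
    (n_optima - 1) / stages$stage1_end else NA_real_
  stage2_rate <- NA_real_
  if (!is.na(stages$stage1_end)) {
    tail_div <- div[div$gen >= stages$stage1_end, , drop = FALSE]
    if (nrow(tail_div) >= 3) {
      fit <- fit_von_bertalanffy(tail_div$gen, tail_div$N, N0 = n_optima)
      if (fit$converged) stage2_rate <- fit$initial_slope
    }
  }
  data.frame(stage1_rate = stage1_rate,
             stage2_rate = stage2_rate,
             turnover = turnover_rate(history, stat$from, stat$to),
             stationary_N = stats::median(div$N[div$gen >= stat$from]),
             stage1_end = stages$stage1_end,
             stage2_end = stages$stage2_end,
             extinct = sim$extinct)
}

#' Factor sweep over replicates
#'
#' Reruns the simulator over a set of values of one biotic or abiotic
#' factor, holding everything else at the base configuration, and summarizes
#' each run with [run_summary()]. The landscape-dynamics factors adjust the
#' barrier rates so that varying the pace holds the isolation time constant
#' and vice versa. The factor axis is also reported rescaled to `[0, 1]`
#' (0 = smallest value used, 1 = largest).
#'
#' @param base A [clade_config()].
#' @param factor One of `"GIT"`, `"sigma_ratio"` (`sigma_C / sigma_K`),
#'   `"K_star"`, `"pace"`, `"isolation"`, `"cr"`.
#' @param values Numeric vector of factor values.
#' @param replicates Replicates per value.
#' @param seed Base seed; replicate `j` of value `i` runs with
#'   `seed + 1000 * (i - 1) + j`.
#' @return data.frame of class `"factor_sweep"`: one row per replicate with
#'   the factor value, its `[0, 1]` rescaling, the replicate seed and the
#'   [run_summary()] columns.
#' @export
sweep_factor <- function(base, factor, values, replicates = 50L, seed = 1L) {
  stopifnot(inherits(base, "clade_config"))
  factor <- match.arg(factor, c("GIT", "sigma_ratio", "K_star", "pace",
                                "isolation", "cr"))
  scaled <- if (length(values) > 1)
    (values - min(values)) / (max(values) - min(values)) else rep(0, length(values))
  rows <- list()
  for (i in seq_along(values)) {
    v <- values[i]
    cfg <- switch(factor,
      GIT = clade_config_update(base, GIT = v),
      sigma_ratio = clade_config_update(base, sigma_C = v * base$sigma_K,
                                        gap_threshold = v * base$sigma_K / 2),
      K_star = clade_config_update(base, K_star = v),
      pace = {
        iso <- isolation_fraction(base$f, base$c)
        rt <- barrier_rates(v, iso)
        clade_config_update(base, f = rt$f, c = rt$c)
      },
      isolation = {
        pace <- landscape_pace(base$f, base$c)
        rt <- barrier_rates(pace, v)
        clade_config_update(base, f = rt$f, c = rt$c)
      },
      cr = clade_config_update(base, cr = v))
    for (j in seq_len(replicates)) {
      s <- seed + 1000L * (i - 1L) + j
      sim <- simulate_clade(cfg, seed = s)
      sm <- run_summary(sim)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(factor = factor, value = v, value_scaled = scaled[i],
                         seed = s), sm)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("factor_sweep", "data.frame")
  out
}

# rebuild a config with overrides, revalidating
clade_config_update <- function(base, ...) {
  vals <- unclass(base)
  over <- list(...)
  vals[names(over)] <- over
  do.call(clade_config, vals)
}

#' Per-value medians and intervals of a sweep
#'
#' @param sweep A `"factor_sweep"` result.
#' @param probs Quantiles reported around the median (default the 50\% and
#'   95\% intervals).
#' @return data.frame with one row per factor value and per summary
#'   statistic: median and the requested quantiles.
#' @export
summarize_sweep <- function(sweep, probs = c(0.025, 0.25, 0.75, 0.975)) {
  stats_cols <- c("stage1_rate", "stage2_rate", "turnover", "stationary_N")
  out <- list()
  for (v in unique(sweep$value)) {
    sub <- sweep[sweep$value == v, , drop = FALSE]
    for (sc in stats_cols) {
      x <- sub[[sc]]
      qs <- stats::quantile(x, probs, na.rm = TRUE, names = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        factor = sub$factor[1], value = v,
        value_scaled = sub$value_scaled[1], statistic = sc,
        median = stats::median(x, na.rm = TRUE),
        q2.5 = qs[1], q25 = qs[2], q75 = qs[3], q97.5 = qs[4])
    }
  }
  do.call(rbind, out)
}
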