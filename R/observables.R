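#' Speciation and extinction rates as a function of diversity
#'
#' Estimates per-species macroevolutionary rates from the waiting times
#' between events: for each diversity level `N`, the per-species rate is the
#' number of events that occurred while the clade held `N` species divided
#' by `N` times the total time spent at `N`. The diversity trajectory is
#' treated as piecewise-constant between its sampling times; an event is
#' attributed to the diversity in effect immediately before it. Replicates
#' are aggregated by pooling events and occupancy times.
#'
#' @param events A data.frame with columns `time` and `event`
#'   (`"speciation"` / `"extinction"`), or a list of such data.frames (one
#'   per replicate).
#' @param diversity A data.frame with columns `gen` (or `time`) and `N`, or
#'   a list of such data.frames matching `events`.
#' @return A data.frame of class `"rate_curve"`: `N`, `time_at_N`,
#'   `n_speciation`, `n_extinction`, `speciation_rate`, `extinction_rate`
#'   (per species per generation). Diversity levels never visited are
#'   absent; levels with zero occupancy are dropped (rates undefined there).
#' @export
rates_vs_diversity <- function(events, diversity) {
  if (is.data.frame(events)) events <- list(events)
  if (is.data.frame(diversity)) diversity <- list(diversity)
  stopifnot(length(events) == length(diversity))
  occ_e <- new.env(); sp_e <- new.env(); ex_e <- new.env()
  bump <- function(env, N, val) {
    key <- as.character(N)
    cur <- if (is.null(env[[key]])) 0 else env[[key]]
    assign(key, cur + val, envir = env)
  }
  for (rep in seq_along(events)) {
    path <- diversity[[rep]]
    tcol <- if ("gen" %in% names(path)) "gen" else "time"
    tt <- path[[tcol]]
    NN <- path$N
    if (is.unsorted(tt)) stop("diversity path times must be increasing")
    seg <- diff(tt)
    for (i in seq_along(seg)) bump(occ_e, NN[i], seg[i])
    ev <- events[[rep]]
    if (nrow(ev)) {
      if (max(ev$time) > max(tt) || min(ev$time) < min(tt))
        stop("event log extends beyond the diversity path: inconsistent inputs")
      idx <- pmax(1L, findInterval(ev$time, tt, left.open = TRUE))
      for (j in seq_len(nrow(ev))) {
        if (ev$event[j] == "speciation") bump(sp_e, NN[idx[j]], 1)
        else if (ev$event[j] == "extinction") bump(ex_e, NN[idx[j]], 1)
      }
    }
  }
  levels <- sort(as.integer(ls(occ_e)))
  out <- data.frame(
    N = levels,
    time_at_N = vapply(as.character(levels), get, numeric(1), envir = occ_e),
    n_speciation = vapply(as.character(levels), function(k)
      if (exists(k, sp_e)) get(k, sp_e) else 0, numeric(1)),
    n_extinction = vapply(as.character(levels), function(k)
      if (exists(k, ex_e)) get(k, ex_e) else 0, numeric(1)))
  out <- out[out$time_at_N > 0 & out$N > 0, , drop = FALSE]
  out$speciation_rate <- out$n_speciation / (out$N * out$time_at_N)
  out$extinction_rate <- out$n_extinction / (out$N * out$time_at_N)
  rownames(out) <- NULL
  class(out) <- c("rate_curve", "data.frame")
  out
}

#' Fit a von Bertalanffy growth curve to species diversity
#'
#' Least-squares fit of `N(t) = a (1 - b exp(-c t))^3` to a diversity
#' trajectory, with `b` constrained by the anchor `N(0) = N0` (so
#' `b = 1 - (N0 / a)^(1/3)`; time is measured from the start of the supplied
#' series, conventionally the beginning of the second diversification
#' stage at `N0 = 9`). Returns the stationary diversity `a`, the rate
#' parameter `c`, and the curve's initial slope `3 a b c (1 - b)^2`, which
#' operationalizes the stage-2 diversification rate.
#'
#' @param times Sampling times (generations); internally shifted to start at 0.
#' @param diversity Species counts at `times` (at least 3 points).
#' @param N0 Anchored starting diversity (default 9, the number of
#'   environmental optima of the default landscape).
#' @return A list of class `"vb_fit"`: `a`, `b`, `c`, `initial_slope`,
#'   `fitted`, `converged`, and `fit` (the underlying `nls` object, or
#'   `NULL` for the degenerate constant series).
#' @export
fit_von_bertalanffy <- function(times, diversity, N0 = 9) {
  stopifnot(length(times) == length(diversity), length(times) >= 3)
  if (diversity[1] < N0 * 0.5)
    warning("series starts well below the anchor N0; fit may be poor")
  tt <- times - times[1]
  if (stats::sd(diversity) == 0) {
    a <- diversity[1]
    return(structure(list(a = a, b = 1 - (N0 / a)^(1 / 3), c = 0,
                          initial_slope = 0, fitted = rep(a, length(tt)),
                          converged = TRUE, fit = NULL),
                     class = "vb_fit"))
  }
  vb <- function(a, cc, t) a * (1 - (1 - (N0 / a)^(1 / 3)) * exp(-cc * t))^3
  start <- list(a = max(max(diversity), N0 + 1), cc = 2 / max(tt))
  fit <- try(minpack.lm::nlsLM(
    diversity ~ vb(a, cc, tt),
    start = start, lower = c(a = N0, cc = 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
  if (inherits(fit, "try-error"))
    return(structure(list(a = NA_real_, b = NA_real_, c = NA_real_,
                          initial_slope = NA_real_, fitted = NULL,
                          converged = FALSE, fit = attr(fit, "condition")),
                     class = "vb_fit"))
  cf <- stats::coef(fit)
  a <- unname(cf["a"]); cc <- unname(cf["cc"])
  b <- 1 - (N0 / a)^(1 / 3)
  structure(list(a = a, b = b, c = cc,
                 initial_slope = 3 * a * b * cc * (1 - b)^2,
                 fitted = vb(a, cc, tt), converged = TRUE, fit = fit),
            class = "vb_fit")
}

#' @export
print.vb_fit <- function(x, ...) {
  cat(sprintf(
    "<vb_fit> a (stationary diversity) = %.3f, c = %.3g, initial slope = %.3g %s\n",
    x$a, x$c, x$initial_slope,
    if (x$converged) "" else "[NOT CONVERGED]"))
  invisible(x)
}

#' Monitored ecological and genetic variables per species
#'
#' Computes, for every species present in one snapshot: the intensity of
#' interspecific competition (average over the species' individuals of
#' `(1/K*) * sum_j C(z_i, z_j)` over co-resident heterospecifics), the
#' phenotypic distance to the parent species (Euclidean distance between
#' mean phenotypes; `NA` if the parent is absent from the snapshot), the
#' mean choosiness trait, maladaptation (mean squared distance between the
#' local optimum and individual phenotypes, averaged over the species'
#' populations), geographic range (number of occupied sites), mean abundance
#' per occupied site, and the hybridization risk (maximum subpopulation-level
#' mating probability `Q` against heterospecific subpopulations that are not
#' postzygotically isolated, i.e. with incompatibility distance at most
#' `GIT`).
#'
#' @param sim A `"clade_sim"`.
#' @param history The matching `"lineage_history"`.
#' @param snap Snapshot index.
#' @return data.frame, one row per species.
#' @export
species_variables <- function(sim, history, snap) {
  s <- sim$snapshots[[snap]]
  del <- history$delims[[snap]]
  lab <- history$assignments[[snap]]
  if (is.null(del) || length(lab) == 0L) return(NULL)
  cfg <- sim$config
  opt <- sim$landscape$sites
  sp_ids <- sort(unique(lab))
  # persistent species id per subpopulation
  sub_species <- vapply(seq_len(nrow(del$subpops)), function(sb)
    lab[which(del$ind_subpop == sb)[1]], integer(1))

  # mean phenotype of each species at this snapshot (for parent distance)
  mean_z <- t(vapply(sp_ids, function(z)
    c(mean(s$x1[lab == z]), mean(s$x2[lab == z])), numeric(2)))
  rownames(mean_z) <- sp_ids

  out <- lapply(sp_ids, function(z) {
    rows <- which(lab == z)
    sites <- unique(s$site[rows])
    # interspecific competition, within-site, scaled by K*
    comp <- vapply(rows, function(i) {
      co <- which(s$site == s$site[i] & lab != z)
      if (!length(co)) return(0)
      d2 <- (s$x1[co] - s$x1[i])^2 + (s$x2[co] - s$x2[i])^2
      sum(exp(-d2 / (2 * cfg$sigma_C^2))) / cfg$K_star
    }, numeric(1))
    # maladaptation averaged over the species' populations (site groups)
    mal <- vapply(sites, function(st) {
      ii <- rows[s$site[rows] == st]
      o <- c(opt$x1_opt[opt$site == st], opt$x2_opt[opt$site == st])
      mean((s$x1[ii] - o[1])^2 + (s$x2[ii] - o[2])^2)
    }, numeric(1))
    # hybridization risk via subpopulation-level Q and D matrices
    own_subs <- which(sub_species == z)
    het_subs <- which(sub_species != z)
    hyb <- 0
    if (length(het_subs)) {
      qd <- del$Q[own_subs, het_subs, drop = FALSE]
      dd <- del$D[own_subs, het_subs, drop = FALSE]
      qd[dd > mating_params(cfg$c_am, cfg$AMT, cfg$GIT)$GIT] <- NA
      if (any(!is.na(qd))) hyb <- max(qd, na.rm = TRUE)
    }
    parent <- history$records$parent[history$records$species == z]
    pdist <- if (length(parent) == 1L && !is.na(parent) &&
                 as.character(parent) %in% rownames(mean_z))
      sqrt(sum((mean_z[as.character(z), ] - mean_z[as.character(parent), ])^2))
    else NA_real_
    data.frame(gen = s$gen, species = z, n = length(rows),
               interspecific_competition = mean(comp),
               parent_distance = pdist,
               mean_a = mean(s$a[rows]),
               maladaptation = mean(mal),
               range_sites = length(sites),
               abundance_per_site = length(rows) / length(sites),
               hybridization_risk = hyb)
  })
  do.call(rbind, out)
}

#' Classify the fate of each extant species
#'
#' At time `t`, each extant species is labeled `"speciating"` if it splits
#' (is the parent of a speciation event) within the next 200 generations,
#' `"going_extinct"` if it goes extinct within the next 200 generations,
#' `"static"` if it neither speciates nor goes extinct within the next 2000
#' generations, and `"other"` if its next event falls between those two
#' windows. Species whose records do not extend 2000 generations past `t`
#' and have no event in that span are `"censored"`.
#'
#' @param history A `"lineage_history"`.
#' @param t Reference time (generations).
#' @param near,far Window lengths (defaults 200 and 2000 generations).
#' @return data.frame with `species` and `fate`.
#' @export
classify_fates <- function(history, t, near = 200, far = 2000) {
  rec <- history$records
  ev <- history$events
  extant <- rec$species[rec$birth <= t & (is.na(rec$death) | rec$death > t)]
  fate <- vapply(extant, function(sp) {
    split_times <- ev$time[ev$event == "speciation" & !is.na(ev$parent) &
                             ev$parent == sp & ev$time > t]
    death <- rec$death[rec$species == sp]
    ext_time <- if (!is.na(death) && death > t) death else Inf
    nxt_split <- if (length(split_times)) min(split_times) else Inf
    if (nxt_split <= t + near) return("speciating")
    if (ext_time <= t + near) return("going_extinct")
    nxt <- min(nxt_split, ext_time)
    if (nxt <= t + far) return("other")
    if (history$horizon < t + far) return("censored")
    "static"
  }, character(1))
  data.frame(species = extant, fate = fate)
}

#' Detect the three stages of diversification
#'
#' The initial adaptive radiation (stage 1) ends when species diversity first
#' reaches the number of environmental optima. The niche self-structuring
#' phase (stage 2) ends — and the final phase begins — when every species is
#' confined to at most two sites, sustained for `window` generations to
#' avoid boundary flicker.
#'
#' @param diversity data.frame with `gen` and `N`.
#' @param range_path data.frame with `gen` and `max_range` (largest species
#'   range in sites at each sampling time); e.g. from
#'   [max_range_path()].
#' @param n_optima Number of environmental optima (9 for the default
#'   3 x 3 gradient landscape).
#' @param window Persistence window for the stage-3 onset (generations).
#' @return List with `stage1_end` and `stage2_end` (generations; `NA` when a
#'   boundary is never reached, leaving the corresponding stage open-ended).
#' @export
detect_stages <- function(diversity, range_path = NULL, n_optima = 9,
                          window = 1000) {
  i1 <- which(diversity$N >= n_optima)
  stage1_end <- if (length(i1)) diversity$gen[i1[1]] else NA_real_
  stage2_end <- NA_real_
  if (!is.null(range_path) && !is.na(stage1_end)) {
    ok <- range_path$max_range <= 2 & range_path$gen >= stage1_end
    # first time the <=2-site condition holds and persists for `window`
    for (i in which(ok)) {
      span <- range_path$gen >= range_path$gen[i] &
        range_path$gen <= range_path$gen[i] + window
      if (all(range_path$max_range[span] <= 2)) {
        stage2_end <- range_path$gen[i]
        break
      }
    }
  }
  list(stage1_end = stage1_end, stage2_end = stage2_end)
}

#' Largest species range through time
#'
#' @param history A `"lineage_history"`.
#' @return data.frame with `gen` and `max_range` (sites).
#' @export
max_range_path <- function(history) {
  sm <- history$species_means
  agg <- stats::aggregate(range_sites ~ gen, data = sm, FUN = max)
  names(agg) <- c("gen", "max_range")
  agg[order(agg$gen), ]
}

#' Diversity plateau at the end of the initial radiation
#'
#' Locates the terminal plateau of a radiation-phase diversity trajectory:
#' the time the running maximum of diversity last increased, required to lie
#' at least `stall` generations before the end of the series (so a pause
#' during the rise is not mistaken for the plateau), and the modal diversity
#' over the terminal window. The detection uses only the shape of the
#' trajectory — no reference to the number of environmental optima.
#'
#' @param diversity data.frame with `gen` and `N`, covering the radiation
#'   phase (pass a truncated series if the trajectory extends deep into
#'   later diversification stages).
#' @param stall Minimum length of the terminal stalled window (generations).
#' @return List with `gen` (plateau onset: the time the maximum was first
#'   reached) and `N` (modal diversity over the terminal window), or `NULL`
#'   if the trajectory is still rising near its end (no stall of length
#'   `stall`) or never left one species.
#' @export
radiation_plateau <- function(diversity, stall = 2000) {
  gen <- diversity$gen
  N <- diversity$N
  # a running median suppresses one-sample spikes and dips so that a brief
  # overshoot near the end is not mistaken for a still-rising trajectory
  Ns <- if (length(N) >= 5) as.integer(stats::runmed(N, 5)) else N
  top <- max(Ns)
  if (top < 2) return(NULL)  # still monomorphic: no radiation to end
  onset <- gen[which(Ns == top)[1]]
  if (max(gen) - onset < stall) return(NULL)  # still rising near the end
  win <- which(gen >= onset)
  tab <- table(N[win])
  list(gen = onset,
       N = as.integer(names(tab)[which.max(tab)]))
}

#' Identify the stationary window of a trajectory
#'
#' Takes the trailing fraction of the horizon and checks stationarity of
#' diversity by rank correlation with time (no significant monotone trend).
#'
#' @param diversity data.frame with `gen` and `N`.
#' @param frac Trailing fraction used as the candidate window (default 0.25).
#' @param p_cut Significance level of the Spearman trend test.
#' @return List with `from`, `to` (generations), `stationary` (logical) and
#'   `p_trend`.
#' @export
stationary_window <- function(diversity, frac = 0.25, p_cut = 0.05) {
  gen <- diversity$gen
  from <- max(gen) - frac * (max(gen) - min(gen))
  win <- diversity[gen >= from, , drop = FALSE]
  p <- if (nrow(win) >= 5 && stats::sd(win$N) > 0)
    suppressWarnings(stats::cor.test(win$gen, win$N, method = "spearman"))$p.value
  else 1
  list(from = from, to = max(gen), stationary = p > p_cut, p_trend = p)
}

#' Species turnover rate in a time window
#'
#' Per-species event rate over the window: `(speciations + extinctions) /
#' (2 * mean diversity * duration)`. At stationarity the speciation and
#' extinction rates are equal and this is either one.
#'
#' @param history A `"lineage_history"`.
#' @param from,to Window bounds (generations); default the full record.
#' @return Turnover rate (per species per generation).
#' @export
turnover_rate <- function(history, from = -Inf, to = Inf) {
  ev <- history$events
  ev <- ev[ev$time > from & ev$time <= to, , drop = FALSE]
  div <- history$diversity
  win <- div[div$gen >= max(from, min(div$gen)) &
               div$gen <= min(to, max(div$gen)), , drop = FALSE]
  dur <- max(win$gen) - min(win$gen)
  if (dur <= 0 || mean(win$N) == 0) return(0)
  nrow(ev) / (2 * mean(win$N) * dur)
}

#' Macroecological summaries of a run
#'
#' Metacommunity size through time, species rank-abundance distributions at
#' three reference times (end of stage 1, mid-stage 2, and the stationary
#' state), and the stationary turnover rate.
#'
#' @param sim A `"clade_sim"`.
#' @param history The matching `"lineage_history"`.
#' @param n_optima Number of environmental optima (stage detection).
#' @return List with `metacommunity` (data.frame `gen`, `metacommunity_size`),
#'   `rank_abundance` (named list of decreasing abundance vectors per stage),
#'   `stationary` (the [stationary_window()] result) and `turnover`
#'   (per-species rate in the stationary window).
#' @export
macroecology <- function(sim, history, n_optima = sim$config$n^2) {
  meta <- abundance_path(sim)
  div <- history$diversity
  stages <- detect_stages(div, max_range_path(history), n_optima)
  stat <- stationary_window(div)
  rank_at <- function(gen_target) {
    i <- which.min(abs(div$gen - gen_target))
    lab <- history$assignments[[i]]
    if (!length(lab)) return(numeric(0))
    sort(as.integer(table(lab)), decreasing = TRUE)
  }
  picks <- list(
    stage1_end = if (!is.na(stages$stage1_end)) stages$stage1_end else NA,
    mid_stage2 = if (!is.na(stages$stage1_end))
      (stages$stage1_end +
         ifelse(is.na(stages$stage2_end), stat$from, stages$stage2_end)) / 2
    else NA,
    stationary = (stat$from + stat$to) / 2)
  ra <- lapply(picks, function(g) if (is.na(g)) numeric(0) else rank_at(g))
  list(metacommunity = meta, rank_abundance = ra, stages = stages,
       stationary = stat,
       turnover = turnover_rate(history, stat$from, stat$to))
}
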