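#' Two phenotypic clusters in one site
#'
#' Deterministic hand-checkable community: two clusters of individuals with
#' zero within-cluster phenotypic variance, separated by `gap` trait units
#' along `x1`. Useful as a fixture for subpopulation clustering.
#'
#' @param gap Separation between cluster centers (trait units, `>= 0`).
#' @param sizes Length-2 integer vector of cluster sizes.
#' @param site Site index assigned to all individuals.
#' @return data.frame with columns `id`, `site`, `x1`, `x2`, `a`.
#' @export
make_two_cluster_site <- function(gap, sizes = c(10L, 10L), site = 1L) {
  stopifnot(gap >= 0, length(sizes) == 2, all(sizes >= 0))
  n <- sum(sizes)
  data.frame(id = seq_len(n), site = site,
             x1 = rep(c(0, gap), sizes), x2 = 0, a = 0)
}

#' Simulate a constant-rate linear birth-death event series
#'
#' Exact realization of a linear birth-death process: each of the `N`
#' current species speciates at rate `lambda` and goes extinct at rate `mu`
#' (per species per generation). Returns the event log with exact times and
#' the piecewise-constant diversity path. Serves as the known-rates oracle
#' for the diversity-dependent rate estimator.
#'
#' @param lambda,mu Per-species speciation and extinction rates.
#' @param horizon End time (generations).
#' @param N0 Starting diversity.
#' @return List with `events` (data.frame `time`, `event`) and `diversity`
#'   (data.frame `gen`, `N`; starts at time 0 and ends with a closing row at
#'   `horizon` so occupancy times cover the whole window).
#' @export
make_bd_eventlog <- function(lambda, mu, horizon, N0 = 5L) {
  stopifnot(lambda >= 0, mu >= 0, horizon > 0, N0 >= 0)
  t <- 0; N <- as.integer(N0)
  cap <- 1024L
  ev_t <- numeric(cap); ev_sp <- logical(cap)
  k <- 0L
  repeat {
    rate <- N * (lambda + mu)
    if (rate == 0) break
    t <- t + stats::rexp(1, rate)
    if (t >= horizon) break
    k <- k + 1L
    if (k > cap) {  # grow geometrically
      cap <- 2L * cap
      length(ev_t) <- cap
      length(ev_sp) <- cap
    }
    ev_t[k] <- t
    ev_sp[k] <- stats::runif(1) < lambda / (lambda + mu)
    N <- N + if (ev_sp[k]) 1L else -1L
  }
  ev_t <- ev_t[seq_len(k)]
  ev_sp <- ev_sp[seq_len(k)]
  path_N <- as.integer(N0 + cumsum(c(0L, ifelse(ev_sp, 1L, -1L))))
  list(events = data.frame(time = ev_t,
                           event = if (k) ifelse(ev_sp, "speciation", "extinction")
                                   else character(0)),
       diversity = data.frame(gen = c(0, ev_t, horizon),
                              N = c(path_N, path_N[length(path_N)])))
}

#' Generate a von Bertalanffy diversity curve
#'
#' `N(t) = a (1 - b exp(-c t))^3` with `b` anchored by `N(0) = 9`,
#' optionally with Poisson sampling noise (each point replaced by a
#' Poisson draw with the curve value as mean).
#'
#' @param a Asymptotic (stationary) diversity; must be `>= 9` for the anchor
#'   to be feasible.
#' @param c Rate parameter (per generation).
#' @param times Sampling times.
#' @param noise `"none"` or `"poisson"`.
#' @return data.frame with `gen` and `N`.
#' @export
make_vb_curve <- function(a, c, times = seq(0, 60000, by = 100),
                          noise = c("none", "poisson")) {
  noise <- match.arg(noise)
  if (a < 9) stop("'a' must be >= 9 (anchor N(0) = 9 infeasible otherwise)")
  b <- 1 - (9 / a)^(1 / 3)
  N <- a * (1 - b * exp(-c * times))^3
  if (noise == "poisson") N <- stats::rpois(length(N), N)
  data.frame(gen = times, N = N)
}

#' Regenerate all serialized test fixtures
#'
#' Writes the deterministic fixture tables used by the test-suite to `dir`
#' as TSV files, under fixed seeds. The serialized copies exist only to
#' detect generator drift; tests rebuild fixtures in code.
#'
#' @param dir Output directory.
#' @param seed RNG seed.
#' @return Invisibly, the written file paths.
#' @export
regenerate_fixtures <- function(dir = ".", seed = 42L) {
  set.seed(seed)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(make_two_cluster_site(2.0, c(10L, 8L)), "two_cluster_site.tsv")
  bd <- make_bd_eventlog(0.01, 0.005, 600, N0 = 5L)
  wr(bd$events, "bd_events.tsv")
  wr(bd$diversity, "bd_diversity.tsv")
  wr(make_vb_curve(45, 5e-5), "vb_curve_a45.tsv")
  invisible(paths)
}
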