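# shared fixtures, built in code; the heavier simulation is memoised so several
# test files can reuse one realization

make_homozygous_parents <- function(params, vals_m = 0.3, vals_f = -0.1) {
  al <- function(v) lapply(params$L, function(L) matrix(v, L, 2))
  mother <- individual(setNames(al(vals_m), names(params$L)), sex = "F")
  father <- individual(setNames(al(vals_f), names(params$L)), sex = "M")
  list(mother = mother, father = father)
}

# a hand-built minimal snapshot list understood by delimit_species /
# track_lineages: `groups` is a list of lists with fields n, x1, site, muts
# (shared by all members of the group), anc (vector of ancestor ids)
fake_snapshot <- function(gen, groups, start_id = 1000L) {
  id <- integer(0); site <- integer(0); x1 <- numeric(0); anc <- integer(0)
  muts <- list()
  nxt <- start_id
  for (g in groups) {
    for (k in seq_len(g$n)) {
      id <- c(id, nxt)
      site <- c(site, g$site)
      x1 <- c(x1, g$x1)
      anc <- c(anc, if (is.null(g$anc)) nxt else g$anc[((k - 1) %% length(g$anc)) + 1])
      muts[[length(muts) + 1]] <- as.integer(g$muts)
      nxt <- nxt + 1L
    }
  }
  list(gen = gen, id = id, site = site, sex = rep(0L, length(id)),
       snap_anc = anc, x1 = x1, x2 = rep(0, length(id)),
       a = rep(0, length(id)), muts = muts)
}

fake_sim <- function(snapshots, cfg = clade_config()) {
  structure(list(snapshots = snapshots, config = cfg,
                 events = data.frame(), extinct = FALSE),
            class = "clade_sim")
}

# small diversifying run shared across test files: 2x2 landscape, permissive
# incompatibility threshold and elevated mutation supply so speciation and
# extinction both occur within a short horizon
shared_sim_env <- new.env()
shared_diversifying_run <- function() {
  if (!is.null(shared_sim_env$sim)) {
    return(list(sim = shared_sim_env$sim, history = shared_sim_env$history))
  }
  cfg <- clade_config(n = 2, K_star = 50, init_per_site = 50, horizon = 4000,
                      GIT = 4, mu_n = 5e-3)
  sim <- simulate_clade(cfg, seed = 7)
  history <- track_lineages(sim)
  shared_sim_env$sim <- sim
  shared_sim_env$history <- history
  list(sim = sim, history = history)
}
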