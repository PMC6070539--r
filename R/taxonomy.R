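#' Cluster one site's individuals into subpopulations
#'
#' Groups of phenotypically similar individuals inhabiting the same
#' geographical site form subpopulations. Clustering is single-linkage in
#' `(x1, x2)` space with a gap rule: two individuals belong to the same
#' subpopulation exactly when they are connected by a chain of
#' nearest-neighbor links no longer than `gap`. This is implemented as the
#' connected components of the threshold graph (edges where the Euclidean
#' phenotype distance is `<= gap`), which is order-independent; cluster
#' labels are canonicalized by the smallest member id.
#'
#' @param site_df data.frame of one site's individuals with columns `id`,
#'   `x1`, `x2`, `a` (e.g. a subset of [snapshot_table()]).
#' @param gap Gap threshold in trait units; the default used throughout the
#'   package is `sigma_C / 2`.
#' @return Integer vector of subpopulation labels (1, 2, ...) aligned with
#'   the rows of `site_df`, with labels ordered by smallest member id.
#' @export
cluster_subpopulations <- function(site_df, gap) {
  n <- nrow(site_df)
  if (n == 0L) stop("site must be non-empty")
  if (n == 1L) return(1L)
  comp <- .cluster_threshold(as.numeric(site_df$x1), as.numeric(site_df$x2),
                             gap)
  # canonical labels: order clusters by their smallest member id
  first_id <- tapply(site_df$id, comp, min)
  as.integer(match(comp, names(sort(first_id))))
}

#' Delimit species in one snapshot
#'
#' Applies the biological species concept at the subpopulation level: sites
#' are clustered into subpopulations ([cluster_subpopulations()]); a graph is
#' drawn over all subpopulations of all sites with an edge whenever the pair
#' is neither prezygotically isolated (average cross-breeding probability on
#' subpopulation mean traits at least `AMT`) nor postzygotically isolated
#' (frequency-weighted incompatibility distance at most `GIT`); species are
#' the connected components of this interbreeding graph.
#'
#' @param snap A snapshot: either an element of `sim$snapshots` or a
#'   [snapshot_table()] data.frame with the `"muts"` attribute.
#' @param gap Subpopulation gap threshold (trait units).
#' @param params A [mating_params()] object.
#' @return List with `subpops` (data.frame: `subpop`, `site`, `n`,
#'   `mean_x1`, `mean_x2`, `mean_a`, `species`), `ind_subpop` and
#'   `ind_species` (per-individual labels aligned with the snapshot rows),
#'   `Q` (pairwise mean-trait mating probabilities between subpopulations)
#'   and `D` (pairwise incompatibility distances).
#' @export
delimit_species <- function(snap, gap, params = mating_params()) {
  if (is.data.frame(snap)) {
    df <- snap
    muts <- attr(snap, "muts")
  } else {
    df <- data.frame(id = snap$id, site = snap$site, x1 = snap$x1,
                     x2 = snap$x2, a = snap$a)
    muts <- snap$muts
  }
  n <- nrow(df)
  if (n == 0L) stop("empty snapshot")
  ind_subpop <- integer(n)
  sub_site <- integer(0)
  next_label <- 0L
  for (s in sort(unique(df$site))) {
    rows <- which(df$site == s)
    lab <- cluster_subpopulations(df[rows, , drop = FALSE], gap)
    ind_subpop[rows] <- lab + next_label
    k <- max(lab)
    sub_site <- c(sub_site, rep.int(s, k))
    next_label <- next_label + k
  }
  ns <- next_label
  mean_x1 <- as.numeric(tapply(df$x1, ind_subpop, mean))
  mean_x2 <- as.numeric(tapply(df$x2, ind_subpop, mean))
  mean_a  <- as.numeric(tapply(df$a, ind_subpop, mean))
  sizes   <- as.integer(tabulate(ind_subpop, ns))

  # carrier-frequency matrix over all mutation ids present in the snapshot
  flat <- unlist(muts, use.names = FALSE)
  all_ids <- sort(unique(flat))
  D <- matrix(0, ns, ns)
  if (length(all_ids)) {
    counts <- lengths(muts)
    owner <- rep.int(ind_subpop, counts)
    midx <- match(flat, all_ids)
    freq <- matrix(0, ns, length(all_ids))
    tab <- table(factor(owner, levels = seq_len(ns)),
                 factor(midx, levels = seq_along(all_ids)))
    freq[] <- as.numeric(tab)
    freq <- freq / sizes
    # distances are capped just above the postzygotic threshold: the
    # delimitation gate and the hybridization-risk filter only compare
    # against GIT (use incompat_distance_subpops() for exact distances)
    D <- .manhattan_cap(freq, cap = params$GIT + 1)
  }

  # pairwise mating probability on subpopulation mean traits, vectorized over
  # all pairs; the choosier subpopulation's mean a applies
  d2 <- outer(mean_x1, mean_x1, "-")^2 + outer(mean_x2, mean_x2, "-")^2
  ai <- matrix(mean_a, ns, ns)
  aj <- t(ai)
  a_use <- ifelse(abs(ai) > abs(aj), ai, ifelse(abs(aj) > abs(ai), aj,
                                                pmax(ai, aj)))
  qpos <- (1 - 0.5 * exp(-a_use^2)) *
    exp(-d2 / (2 / (a_use^2 * params$c_am))^2)
  Q <- ifelse(a_use == 0, 0.5, ifelse(a_use > 0, qpos, 1 - qpos))
  diag(Q) <- 1

  compatible <- (Q >= params$AMT) & (D <= params$GIT)
  diag(compatible) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(compatible, mode = "undirected")
  sp <- igraph::components(g)$membership
  subpops <- data.frame(subpop = seq_len(ns), site = sub_site, n = sizes,
                        mean_x1 = mean_x1, mean_x2 = mean_x2, mean_a = mean_a,
                        species = as.integer(sp))
  list(subpops = subpops, ind_subpop = ind_subpop,
       ind_species = as.integer(sp[ind_subpop]), Q = Q, D = D)
}

#' Delimit species in every snapshot and track lineages through time
#'
#' Runs [delimit_species()] on each stored snapshot, then stitches species
#' identities across consecutive sampling times by maximal descendant
#' overlap: each species at time `t + 100` is assigned to the species at
#' time `t` from which the largest fraction of its members descend. When one
#' species has several descendant groups, a speciation event is recorded at
#' the later sampling time — the most abundant group keeps the maternal id
#' (ties go to the group with the older members) and every other group
#' receives a fresh id with the maternal species as parent. A species with
#' no surviving descendants is recorded as extinct. Event times therefore
#' have the resolution of the sampling interval, mirroring how the
#' trajectory itself is observed.
#'
#' @param sim A `"clade_sim"` object.
#' @param gap Subpopulation gap threshold; defaults to the configuration's
#'   (`sigma_C / 2` unless overridden).
#' @param params A [mating_params()]; defaults to the simulation's
#'   configuration.
#' @return An object of class `"lineage_history"`: list with `events`
#'   (data.frame `time`, `event`, `species`, `parent`), `records`
#'   (data.frame `species`, `parent`, `birth`, `death` — `NA` death means
#'   extant at the end), `diversity` (data.frame `gen`, `N`),
#'   `assignments` (per-snapshot integer vectors of persistent species ids),
#'   `species_means` (per-snapshot data.frame of species mean phenotypes,
#'   abundances and range sizes), and `delims` (the raw per-snapshot
#'   delimitations).
#' @export
track_lineages <- function(sim, gap = NULL, params = NULL) {
  stopifnot(inherits(sim, "clade_sim"))
  cfg <- sim$config
  if (is.null(gap)) gap <- cfg$gap_threshold
  if (is.null(params))
    params <- mating_params(cfg$c_am, cfg$AMT, cfg$GIT, cfg$max_tries)
  snaps <- sim$snapshots
  nsnap <- length(snaps)
  gens <- vapply(snaps, `[[`, numeric(1), "gen")

  records <- data.frame(species = integer(), parent = integer(),
                        birth = numeric(), death = numeric())
  events <- data.frame(time = numeric(), event = character(),
                       species = integer(), parent = integer())
  assignments <- vector("list", nsnap)
  delims <- vector("list", nsnap)
  species_means <- vector("list", nsnap)
  diversity <- data.frame(gen = gens, N = NA_integer_)

  next_id <- 0L
  prev_ids <- NULL       # individual ids at previous snapshot
  prev_species <- NULL   # persistent species per individual, previous snapshot

  for (i in seq_len(nsnap)) {
    s <- snaps[[i]]
    if (length(s$id) == 0L) {
      # clade extinct: every previously extant species dies here
      alive <- records$species[is.na(records$death)]
      for (spid in alive) {
        records$death[records$species == spid] <- gens[i]
        events <- rbind(events, data.frame(time = gens[i], event = "extinction",
                                           species = spid, parent = NA_integer_))
      }
      assignments[[i]] <- integer(0)
      diversity$N[i] <- 0L
      delims[[i]] <- NULL
      species_means[[i]] <- NULL
      prev_ids <- integer(0)
      prev_species <- integer(0)
      next
    }
    del <- delimit_species(s, gap, params)
    delims[[i]] <- del
    raw <- del$ind_species                 # snapshot-local labels 1..k
    k <- max(raw)
    if (i == 1L) {
      if (k != 1L)
        warning("initial snapshot contains ", k, " species; founding each")
      persistent <- integer(k)
      for (r in seq_len(k)) {
        next_id <- next_id + 1L
        persistent[r] <- next_id
        records <- rbind(records, data.frame(species = next_id,
                                             parent = NA_integer_,
                                             birth = gens[i],
                                             death = NA_real_))
      }
      lab <- persistent[raw]
    } else {
      if (is.null(prev_ids)) stop("missing ancestry bookkeeping")
      anc_pos <- match(s$snap_anc, prev_ids)
      if (anyNA(anc_pos))
        stop("snapshot ", i, ": ancestor ids missing from previous snapshot")
      anc_species <- prev_species[anc_pos]
      # parent of each raw cluster: the previous species contributing most members
      parent_of <- integer(k)
      for (r in seq_len(k)) {
        tab <- table(anc_species[raw == r])
        parent_of[r] <- as.integer(names(tab)[which.max(tab)])
      }
      # assign persistent ids parent by parent
      persistent <- rep(NA_integer_, k)
      for (p in unique(parent_of)) {
        group <- which(parent_of == p)
        if (length(group) == 1L) {
          persistent[group] <- p
        } else {
          sizes <- vapply(group, function(r) sum(raw == r), integer(1))
          # most abundant keeps the maternal id; tie -> older members (smaller
          # mean individual id, ids increase with birth order)
          mean_id <- vapply(group, function(r) mean(s$id[raw == r]), numeric(1))
          keeper <- group[order(-sizes, mean_id)][1]
          persistent[keeper] <- p
          for (r in setdiff(group, keeper)) {
            next_id <- next_id + 1L
            persistent[r] <- next_id
            records <- rbind(records,
                             data.frame(species = next_id, parent = p,
                                        birth = gens[i], death = NA_real_))
            events <- rbind(events,
                            data.frame(time = gens[i], event = "speciation",
                                       species = next_id, parent = p))
          }
        }
      }
      # previous species with no descendants die at this sampling time
      gone <- setdiff(prev_species, parent_of)
      for (spid in sort(unique(gone))) {
        if (is.na(records$death[records$species == spid])) {
          records$death[records$species == spid] <- gens[i]
          events <- rbind(events,
                          data.frame(time = gens[i], event = "extinction",
                                     species = spid, parent = NA_integer_))
        }
      }
      lab <- persistent[raw]
    }
    assignments[[i]] <- lab
    diversity$N[i] <- length(unique(lab))
    sp_ids <- sort(unique(lab))
    species_means[[i]] <- data.frame(
      gen = gens[i], species = sp_ids,
      n = vapply(sp_ids, function(z) sum(lab == z), integer(1)),
      mean_x1 = vapply(sp_ids, function(z) mean(s$x1[lab == z]), numeric(1)),
      mean_x2 = vapply(sp_ids, function(z) mean(s$x2[lab == z]), numeric(1)),
      mean_a  = vapply(sp_ids, function(z) mean(s$a[lab == z]), numeric(1)),
      range_sites = vapply(sp_ids,
                           function(z) length(unique(s$site[lab == z])),
                           integer(1)))
    prev_ids <- s$id
    prev_species <- lab
  }
  structure(list(events = events, records = records, diversity = diversity,
                 assignments = assignments,
                 species_means = do.call(rbind, species_means),
                 delims = delims,
                 horizon = gens[nsnap], snap_interval = cfg$snap_interval),
            class = "lineage_history")
}

#' @export
print.lineage_history <- function(x, ...) {
  cat(sprintf("<lineage_history> %d species total, %d extant at generation %g\n",
              nrow(x$records), sum(is.na(x$records$death)), x$horizon))
  cat(sprintf("  %d speciation and %d extinction events\n",
              sum(x$events$event == "speciation"),
              sum(x$events$event == "extinction")))
  invisible(x)
}

#' Build the phylogeny of extant and extinct species
#'
#' Converts the species records (budding speciation: a daughter species
#' branches off its mother, which keeps its identity) into a rooted
#' `ape::phylo` tree with branch lengths in generations. Extinct tips
#' terminate at their death time; extant tips extend to the end of the run.
#' Tip labels are `sp<id>`. The founder's stem — the segment from its birth
#' to the first speciation — is kept as the tree's `root.edge`, so the total
#' species-lifetime in the records equals `sum(tree$edge.length)` plus the
#' root edge.
#'
#' @param records The `records` data.frame of a `"lineage_history"` (columns
#'   `species`, `parent`, `birth`, `death`), or a `"lineage_history"` itself.
#' @param horizon End time (generations); defaults to the history's horizon
#'   or `max(death, birth)`.
#' @return An `ape::phylo`; the per-species data are attached as attribute
#'   `"species_data"`.
#' @export
build_phylogeny <- function(records, horizon = NULL) {
  if (inherits(records, "lineage_history")) {
    if (is.null(horizon)) horizon <- records$horizon
    records <- records$records
  }
  stopifnot(all(c("species", "parent", "birth", "death") %in% names(records)))
  if (is.null(horizon)) horizon <- max(c(records$death, records$birth), na.rm = TRUE)
  orphan <- !is.na(records$parent) & !(records$parent %in% records$species)
  if (any(orphan)) stop("orphan parent reference(s): species ",
                        paste(records$species[orphan], collapse = ", "))
  death <- ifelse(is.na(records$death), horizon, records$death)
  kids <- split(records[!is.na(records$parent), c("species", "birth")],
                records$parent[!is.na(records$parent)])
  kids <- lapply(kids, function(k) k[order(k$birth, k$species), , drop = FALSE])
  # budding speciation: each daughter inserts a node on the mother's lineage;
  # walk each species' children in birth order so recursion always advances
  lineage <- function(sp, from, child_idx) {
    row <- which(records$species == sp)
    k <- kids[[as.character(sp)]]
    if (!is.null(k))
      k <- k[seq_len(nrow(k)) >= child_idx & k$birth <= death[row], , drop = FALSE]
    if (is.null(k) || nrow(k) == 0L)
      return(sprintf("sp%d:%.10g", sp, death[row] - from))
    t1 <- k$birth[1]
    sprintf("(%s,%s):%.10g",
            lineage(sp, t1, child_idx + 1L),
            lineage(k$species[1], t1, 1L), t1 - from)
  }
  roots <- records$species[is.na(records$parent)]
  if (length(roots) != 1L) stop("records must contain exactly one founder species")
  nwk <- lineage(roots, records$birth[records$species == roots], 1L)
  if (!grepl("(", nwk, fixed = TRUE)) nwk <- sprintf("(%s);", nwk)
  else nwk <- paste0(nwk, ";")
  tree <- ape::read.tree(text = nwk)
  attr(tree, "species_data") <- records
  tree
}

#' Write a phylogeny to a Newick file
#'
#' Standard Newick with branch lengths in generations; extinct tips are
#' included. The output round-trips through `ape::read.tree`.
#'
#' @param tree An `ape::phylo`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}
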