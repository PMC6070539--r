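test_that("subpopulation clustering follows the single-linkage gap rule", {
  sC <- 0.4
  two <- make_two_cluster_site(gap = 5 * sC, sizes = c(10L, 8L))
  lab <- cluster_subpopulations(two, gap = sC / 2)
  expect_equal(max(lab), 2)
  expect_equal(as.integer(table(lab)), c(10L, 8L))
  one <- make_two_cluster_site(gap = 0, sizes = c(10L, 8L))
  expect_equal(max(cluster_subpopulations(one, gap = sC / 2)), 1)
  empty_second <- make_two_cluster_site(gap = 3, sizes = c(10L, 0L))
  expect_equal(max(cluster_subpopulations(empty_second, gap = sC / 2)), 1)
  # chaining: points spaced just under the gap form one cluster
  chain <- data.frame(id = 1:6, site = 1, x1 = (0:5) * 0.19, x2 = 0, a = 0)
  expect_equal(max(cluster_subpopulations(chain, gap = 0.2)), 1)
  chain$x1 <- (0:5) * 0.21
  expect_equal(max(cluster_subpopulations(chain, gap = 0.2)), 6)
  # order-independence up to canonical relabeling
  set.seed(71)
  pts <- data.frame(id = 1:40, site = 1, x1 = runif(40, 0, 3), x2 = runif(40, 0, 3),
                    a = 0)
  ref <- cluster_subpopulations(pts, gap = 0.35)
  perm <- sample(40)
  shuffled <- cluster_subpopulations(pts[perm, ], gap = 0.35)
  expect_equal(shuffled[order(perm)], ref)
})

test_that("species are connected components of the interbreeding graph", {
  mp <- mating_params(c_am = 1)
  # postzygotic split: monomorphic incompatibility distance 20 > GIT = 15
  snap <- fake_snapshot(0, list(
    list(n = 5, x1 = 0, site = 1, muts = integer(0)),
    list(n = 5, x1 = 0, site = 2, muts = 1:20)))
  del <- delimit_species(snap, gap = 0.2, mp)
  expect_equal(nrow(del$subpops), 2)
  expect_equal(max(del$subpops$species), 2)
  expect_equal(del$D[1, 2], 16)  # capped just above GIT, still > 15
  # same pair below the threshold: one species
  snap2 <- fake_snapshot(0, list(
    list(n = 5, x1 = 0, site = 1, muts = integer(0)),
    list(n = 5, x1 = 0, site = 2, muts = 1:14)))
  expect_equal(max(delimit_species(snap2, gap = 0.2, mp)$subpops$species), 1)
  # chain connectivity: A-B and B-C compatible, A-C prezygotically isolated,
  # still one species (components, not cliques); strong homogamy a = 3
  chain <- fake_snapshot(0, list(
    list(n = 4, x1 = 0.0, site = 1, muts = integer(0)),
    list(n = 4, x1 = 0.4, site = 1, muts = integer(0)),
    list(n = 4, x1 = 0.8, site = 1, muts = integer(0))))
  chain$a <- rep(3, 12)
  qAB <- mating_probability(c(0, 0), 3, c(0.4, 0), 3, 1)
  qAC <- mating_probability(c(0, 0), 3, c(0.8, 0), 3, 1)
  expect_gt(qAB, mp$AMT)
  expect_lt(qAC, mp$AMT)
  delc <- delimit_species(chain, gap = 0.2, mp)
  expect_equal(nrow(delc$subpops), 3)
  expect_equal(max(delc$subpops$species), 1)
  # all mutually compatible: one species
  expect_equal(max(delimit_species(fake_snapshot(0, list(
    list(n = 6, x1 = 0, site = 1, muts = integer(0)),
    list(n = 6, x1 = 0, site = 5, muts = integer(0)))),
    gap = 0.2, mp)$subpops$species), 1)
})

test_that("delimitation is idempotent and partitions every subpopulation", {
  run <- shared_diversifying_run()
  i <- length(run$sim$snapshots)
  s <- run$sim$snapshots[[i]]
  d1 <- delimit_species(s, gap = 0.2)
  d2 <- delimit_species(s, gap = 0.2)
  expect_identical(d1$subpops$species, d2$subpops$species)
  expect_false(anyNA(d1$ind_species))
  expect_equal(length(d1$ind_species), length(s$id))
  # every subpopulation in exactly one species
  expect_false(anyNA(d1$subpops$species))
  # symmetric edge predicate
  expect_equal(d1$Q, t(d1$Q))
  expect_equal(d1$D, t(d1$D))
})

test_that("lineage tracking dates splits and extinctions at snapshot resolution", {
  cfg <- clade_config(n = 1, K_star = 30, init_per_site = 10, horizon = 300)
  # snapshot 1-2: one species of 10; snapshot 3: a GIT-isolated group of 4
  # splits off; snapshot 4: that group leaves no descendants
  g0 <- list(n = 10, x1 = 0, site = 1, muts = integer(0))
  s1 <- fake_snapshot(100, list(g0), start_id = 1L)
  s2 <- fake_snapshot(200, list(list(n = 6, x1 = 0, site = 1, muts = integer(0),
                                     anc = 1:6),
                                list(n = 4, x1 = 3, site = 1, muts = 1:20,
                                     anc = 7:10)), start_id = 101L)
  s3 <- fake_snapshot(300, list(list(n = 8, x1 = 0, site = 1, muts = integer(0),
                                     anc = 101:106)), start_id = 201L)
  sim <- fake_sim(list(fake_snapshot(0, list(g0), start_id = 1L), s1, s2, s3), cfg)
  h <- track_lineages(sim)
  expect_equal(nrow(h$records), 2)
  expect_equal(h$events$event, c("speciation", "extinction"))
  expect_equal(h$events$time, c(200, 300))          # dated at the later snapshot
  expect_equal(h$events$parent[1], 1L)              # mother keeps her id
  expect_equal(h$records$birth, c(0, 200))
  expect_equal(h$records$death, c(NA, 300))
  expect_equal(h$diversity$N, c(1L, 1L, 2L, 1L))
  # the larger fragment kept the maternal id
  expect_equal(sum(h$assignments[[3]] == 1L), 6)
})

test_that("a constant one-species series produces no events", {
  cfg <- clade_config(n = 1, K_star = 30, init_per_site = 8, horizon = 300)
  g <- list(n = 8, x1 = 0, site = 1, muts = integer(0))
  snaps <- list(fake_snapshot(0, list(g), start_id = 1L))
  for (k in 1:3) {
    prev <- snaps[[k]]
    snaps[[k + 1]] <- fake_snapshot(k * 100,
      list(c(g, list(anc = prev$id))), start_id = 1L + 100L * k)
  }
  h <- track_lineages(fake_sim(snaps, cfg))
  expect_equal(nrow(h$events), 0)
  expect_true(all(h$diversity$N == 1))
})

test_that("phylogenies mirror the species records", {
  # hand-drawn history: founder 1 splits at t=200 (daughter 2) and t=400
  # (daughter 3); species 2 dies at t=500; horizon 1000
  rec <- data.frame(species = 1:3, parent = c(NA, 1L, 1L),
                    birth = c(0, 200, 400), death = c(NA, 500, NA))
  tr <- build_phylogeny(rec, horizon = 1000)
  expect_s3_class(tr, "phylo")
  expect_equal(ape::Ntip(tr), 3)
  expect_setequal(tr$tip.label, c("sp1", "sp2", "sp3"))
  # branch lengths plus the founder stem (root edge) equal total lifetime
  expect_equal(tr$root.edge, 200)
  expect_equal(sum(tr$edge.length) + tr$root.edge,
               (1000 - 0) + (500 - 200) + (1000 - 400))
  # tip times (stem + depth): extinct tip ends at 500, extant tips at 1000
  depths <- ape::node.depth.edgelength(tr)[1:3] + tr$root.edge
  names(depths) <- tr$tip.label
  expect_equal(unname(depths["sp2"]), 500)
  expect_equal(unname(depths["sp1"]), 1000)
  expect_equal(unname(depths["sp3"]), 1000)
  # patristic distances pin the hand-drawn topology and node times
  coph <- ape::cophenetic.phylo(tr)
  expect_equal(coph["sp1", "sp2"], (500 - 200) + (1000 - 200))
  expect_equal(coph["sp1", "sp3"], 2 * (1000 - 400))
  expect_equal(coph["sp2", "sp3"], (500 - 200) + (400 - 200) + (1000 - 400))
  # single species: one tip of length horizon
  one <- build_phylogeny(data.frame(species = 1L, parent = NA_integer_,
                                    birth = 0, death = NA), horizon = 500)
  expect_equal(ape::Ntip(one), 1)
  expect_equal(sum(one$edge.length), 500)
  # orphan parent rejected
  expect_error(build_phylogeny(data.frame(species = 1:2, parent = c(NA, 9L),
                                          birth = c(0, 1), death = NA),
                               horizon = 10), "orphan")
})

test_that("newick export round-trips and includes extinct tips", {
  rec <- data.frame(species = 1:3, parent = c(NA, 1L, 1L),
                    birth = c(0, 200, 400), death = c(NA, 600, NA))
  tr <- build_phylogeny(rec, horizon = 1000)
  path <- tempfile(fileext = ".nwk")
  write_newick(tr, path)
  back <- ape::read.tree(path)
  expect_equal(ape::Ntip(back), 3)
  expect_true("sp2" %in% back$tip.label)  # extinct tip present
  expect_equal(sum(back$edge.length), sum(tr$edge.length))
  expect_equal(ape::cophenetic.phylo(back)[tr$tip.label, tr$tip.label],
               ape::cophenetic.phylo(tr)[tr$tip.label, tr$tip.label])
})

test_that("species accounting balances over a full diversifying run", {
  run <- shared_diversifying_run()
  h <- run$history
  n_speciation <- sum(h$events$event == "speciation")
  n_extinction <- sum(h$events$event == "extinction")
  n_extant <- sum(is.na(h$records$death))
  # extinctions + extant species = speciations + 1 (single founder)
  expect_equal(n_extinction + n_extant, n_speciation + 1)
  # phylogeny tips cover every species ever recorded
  tr <- build_phylogeny(h)
  expect_equal(ape::Ntip(tr), nrow(h$records))
  stem <- if (is.null(tr$root.edge)) 0 else tr$root.edge
  expect_equal(sum(tr$edge.length) + stem,
               sum(ifelse(is.na(h$records$death), h$horizon, h$records$death) -
                     h$records$birth))
})
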