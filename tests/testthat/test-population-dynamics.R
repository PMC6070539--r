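test_that("carrying capacity and competition kernel match their Gaussian forms", {
  expect_equal(carrying_capacity(c(0, 0), c(0, 0), K_star = 150), 150)
  expect_equal(carrying_capacity(c(1, 0), c(0, 0), K_star = 150, sigma_K = 1),
               150 * exp(-0.5))
  expect_lt(carrying_capacity(c(50, 50), c(0, 0)), 1e-10)
  expect_equal(competition_kernel(c(1, 1), c(1, 1)), 1)
  expect_equal(competition_kernel(c(0.4, 0), c(0, 0), sigma_C = 0.4), exp(-0.5))
  set.seed(61)
  for (i in 1:20) {
    zi <- runif(2, -2, 2); zj <- runif(2, -2, 2)
    expect_equal(competition_kernel(zi, zj), competition_kernel(zj, zi))
  }
})

test_that("death rate equals the brute-force double loop and its closed forms", {
  eco <- ecology_params(K_star = 150)
  # lone individual: empty competition sum
  expect_equal(death_rate(c(0.3, -0.2), matrix(numeric(0), 0, 2), c(0, 0), eco), 0)
  # n identical individuals at the optimum: each dies at r (n - 1) / K*
  n <- 40
  others <- matrix(0, n - 1, 2)
  expect_equal(death_rate(c(0, 0), others, c(0, 0), eco), eco$r * (n - 1) / 150)
  # random 30-individual site against an independent double-loop evaluation
  set.seed(62)
  for (rep in 1:10) {
    z <- matrix(runif(60, -2, 2), 30, 2)
    opt <- runif(2, -1, 1)
    i <- sample(30, 1)
    manual <- 0
    for (j in seq_len(30)) {
      if (j == i) next
      manual <- manual + exp(-sum((z[i, ] - z[j, ])^2) / (2 * eco$sigma_C^2))
    }
    manual <- eco$r * manual /
      (eco$K_star * exp(-sum((z[i, ] - opt)^2) / (2 * eco$sigma_K^2)))
    expect_equal(death_rate(z[i, ], z[-i, , drop = FALSE], opt, eco), manual)
  }
})

test_that("newborn dispersal follows the island and stay/move rules", {
  L <- gradient_landscape(3)
  Lclosed <- L; Lclosed$borders$closed <- TRUE
  set.seed(63)
  expect_true(all(vapply(1:50, function(i)
    disperse_newborn(5, Lclosed, m = 1), numeric(1)) == 5))
  expect_true(all(vapply(1:50, function(i)
    disperse_newborn(5, L, m = 0, mode = "stay_move"), numeric(1)) == 5))
  # stay_move with m = 1 and two open borders: each neighbor ~ 1/2
  L2 <- L; L2$borders$closed <- TRUE
  L2$borders$closed[L2$borders$site_a == 5 & L2$borders$site_b %in% c(6, 8) |
                      L2$borders$site_b == 5 & L2$borders$site_a %in% c(6, 8)] <- FALSE
  expect_setequal(open_neighbors(L2, 5), c(6, 8))
  draws <- vapply(1:4000, function(i)
    disperse_newborn(5, L2, m = 1, mode = "stay_move"), numeric(1))
  expect_setequal(unique(draws), c(6, 8))
  expect_equal(mean(draws == 6), 0.5, tolerance = 0.05)
  # island rule spreads uniformly over natal + open neighbors
  draws <- vapply(1:6000, function(i)
    disperse_newborn(5, L2, mode = "island"), numeric(1))
  expect_equal(as.numeric(table(draws) / 6000), rep(1 / 3, 3), tolerance = 0.12)
})

test_that("simulation starts from the configured founder community and is deterministic", {
  cfg <- clade_config(horizon = 100, K_star = 150)
  sim <- simulate_clade(cfg, seed = 5)
  expect_equal(length(sim$snapshots[[1]]$id), 1350)  # 150 founders x 9 sites
  expect_equal(sort(unique(sim$snapshots[[1]]$site)), 1:9)
  expect_equal(sim$snapshots[[1]]$gen, 0)
  # identical seed and configuration: bit-identical trajectories
  sim2 <- simulate_clade(cfg, seed = 5)
  expect_identical(sim$snapshots, sim2$snapshots)
  expect_identical(sim$events, sim2$events)
  sim3 <- simulate_clade(cfg, seed = 6)
  expect_false(identical(sim$snapshots, sim3$snapshots))
})

test_that("incremental death propensities track the from-scratch recomputation", {
  cfg <- clade_config(n = 2, K_star = 30, init_per_site = 30, horizon = 60,
                      snap_interval = 60, check_propensities = TRUE)
  sim <- simulate_clade(cfg, seed = 8)
  expect_lt(sim$max_propensity_error, 1e-9)
})

test_that("a monomorphic single-site population fluctuates near carrying capacity", {
  # no mutation, founders identical at the optimum: C = 1, K = K*, so the
  # birth-death balance sits at K* + 1
  K <- 60
  cfg <- clade_config(n = 1, K_star = K, init_per_site = K, horizon = 2000,
                      mu_k = 0, mu_n = 0, init_sd = 0)
  sim <- simulate_clade(cfg, seed = 9)
  ab <- abundance_path(sim)
  avg <- mean(ab$metacommunity_size[ab$gen >= 500])
  expect_lt(abs(avg - (K + 1)), 3 * sqrt(K))
})

test_that("catastrophes empty sites and the clade can go extinct before the horizon", {
  cfg <- clade_config(n = 1, K_star = 30, init_per_site = 30, horizon = 4000,
                      cr = 5e-3, mu_k = 0, mu_n = 0, init_sd = 0,
                      snap_interval = 50)
  sim <- simulate_clade(cfg, seed = 10)
  cats <- sim$events[sim$events$type == "catastrophe", ]
  expect_gt(nrow(cats), 0)
  expect_true(sim$extinct)  # single site: first catastrophe kills the clade
  sizes <- vapply(sim$snapshots, function(s) length(s$id), integer(1))
  expect_equal(sizes[length(sizes)], 0)
})

test_that("barrier events toggle border states at the configured rates", {
  cfg <- clade_config(n = 2, K_star = 20, init_per_site = 5, horizon = 5000,
                      f = 5e-3, c = 5e-3, mu_k = 0, mu_n = 0, init_sd = 0,
                      snap_interval = 500)
  sim <- simulate_clade(cfg, seed = 11)
  ev <- sim$events[sim$events$type %in% c("barrier_close", "barrier_open"), ]
  expect_gt(nrow(ev), 10)
  # every border is exactly one of open/closed: closes and opens alternate
  # per border pair
  key <- paste(ev$site_a, ev$site_b)
  for (k in unique(key)) {
    seq_types <- ev$type[key == k]
    expect_true(all(seq_types[c(TRUE, FALSE)] == "barrier_close"))
    expect_true(all(rle(seq_types)$lengths == 1))
  }
  # expected number of closes over the horizon ~ f * borders * time-open share
  expect_equal(sum(ev$type == "barrier_close"),
               sum(ev$type == "barrier_open"), tolerance = 5)
})
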