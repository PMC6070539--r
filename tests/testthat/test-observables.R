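test_that("rate estimation divides event counts by species-time", {
  # arithmetic oracle: 1000 generations at N = 5 with 2 speciations
  path <- data.frame(gen = c(0, 1000), N = c(5L, 5L))
  ev <- data.frame(time = c(300, 700), event = "speciation")
  rc <- rates_vs_diversity(ev, path)
  expect_equal(rc$speciation_rate[rc$N == 5], 2 / (5 * 1000))
  expect_equal(rc$extinction_rate[rc$N == 5], 0)
  # no events: all-zero rates
  rc0 <- rates_vs_diversity(data.frame(time = numeric(), event = character()),
                            path)
  expect_true(all(rc0$speciation_rate == 0) && all(rc0$extinction_rate == 0))
  # events outside the path are inconsistent
  expect_error(rates_vs_diversity(data.frame(time = 2000, event = "speciation"),
                                  path), "inconsistent")
})

test_that("the rate estimator is flat and unbiased on constant-rate birth-death logs", {
  set.seed(81)
  lambda <- 0.01; mu <- 0.005
  reps <- lapply(1:100, function(i) make_bd_eventlog(lambda, mu, 600, N0 = 5L))
  rc <- rates_vs_diversity(lapply(reps, `[[`, "events"),
                           lapply(reps, `[[`, "diversity"))
  # pooled estimates hit the true rates
  expect_equal(sum(rc$n_speciation) / sum(rc$N * rc$time_at_N), lambda,
               tolerance = 0.05)
  expect_equal(sum(rc$n_extinction) / sum(rc$N * rc$time_at_N), mu,
               tolerance = 0.08)
  # per-level estimates unbiased at well-sampled diversity levels
  well <- rc[rc$time_at_N * rc$N > 5000, ]
  expect_gt(nrow(well), 3)
  z_sp <- (well$speciation_rate - lambda) /
    sqrt(lambda / (well$N * well$time_at_N))
  z_ex <- (well$extinction_rate - mu) /
    sqrt(mu / (well$N * well$time_at_N))
  expect_lt(max(abs(z_sp)), 4)
  expect_lt(max(abs(z_ex)), 4)
  # flat in N: any fitted trend drifts the rate by well under 10% of the
  # truth across the whole observed diversity span (a magnitude bound; an
  # lm confidence interval overstates precision here because occupancy
  # times at neighboring levels come from the same trajectories)
  fit <- lm(speciation_rate ~ N, data = well, weights = well$N * well$time_at_N)
  expect_lt(abs(coef(fit)["N"]) * diff(range(well$N)), 0.1 * lambda)
})

test_that("birth-death fixture matches its analytic expectation", {
  set.seed(82)
  lambda <- 0.01; mu <- 0.004; T <- 300; N0 <- 5
  finals <- vapply(1:1000, function(i)
    make_bd_eventlog(lambda, mu, T, N0)$diversity$N |> tail(1), numeric(1))
  expect_equal(mean(finals), N0 * exp((lambda - mu) * T), tolerance = 0.05)
  # mu = 0: diversity non-decreasing
  d <- make_bd_eventlog(0.02, 0, 500, 3L)$diversity$N
  expect_true(all(diff(d) >= 0))
  # no rates: empty log
  expect_equal(nrow(make_bd_eventlog(0, 0, 100, 5L)$events), 0)
})

test_that("von Bertalanffy fits recover known parameters", {
  # noiseless recovery across the plausible range
  for (a in c(20, 45, 80)) for (cc in c(1e-5, 1e-4)) {
    curve <- make_vb_curve(a, cc, times = seq(0, 3 / cc, by = 1 / (50 * cc)))
    fit <- fit_von_bertalanffy(curve$gen, curve$N)
    expect_true(fit$converged)
    expect_equal(fit$a, a, tolerance = 0.05)
    expect_equal(fit$c, cc, tolerance = 0.05)
  }
  # the worked example: a = 45, c = 5e-5 recovered within 1%
  curve <- make_vb_curve(45, 5e-5)
  fit <- fit_von_bertalanffy(curve$gen, curve$N)
  expect_equal(fit$a, 45, tolerance = 0.01)
  # anchor: N(0) = 9 and the asymptote is a
  expect_equal(curve$N[1], 9)
  expect_equal(make_vb_curve(45, 5e-5, times = 1e7)$N, 45, tolerance = 1e-6)
  expect_error(make_vb_curve(5, 1e-4), ">= 9")
  # constant series: that constant, zero slope
  flat <- fit_von_bertalanffy(seq(0, 1000, 100), rep(9, 11))
  expect_equal(flat$a, 9)
  expect_equal(flat$initial_slope, 0)
  # initial slope formula 3 a b c (1 - b)^2 equals the numerical derivative
  b <- 1 - (9 / 45)^(1 / 3)
  num <- (make_vb_curve(45, 5e-5, times = 1e-3)$N - 9) / 1e-3
  expect_equal(3 * 45 * b * 5e-5 * (1 - b)^2, num, tolerance = 1e-4)
})

test_that("Poisson-noise fits are unbiased over replicate seeds", {
  set.seed(83)
  a_hat <- replicate(100, {
    curve <- make_vb_curve(45, 8e-5, times = seq(0, 50000, by = 500),
                           noise = "poisson")
    suppressWarnings(fit_von_bertalanffy(curve$gen, curve$N)$a)
  })
  expect_equal(mean(a_hat, na.rm = TRUE), 45, tolerance = 0.03)
})

test_that("fate classification applies the 200/2000-generation windows", {
  ev <- data.frame(time = c(1150, 1150, 1900, 3500),
                   event = c("speciation", "extinction", "extinction",
                             "speciation"),
                   species = c(5L, 2L, 4L, 6L), parent = c(1L, NA, NA, 3L))
  rec <- data.frame(species = 1:6, parent = c(NA, 1L, 1L, 1L, 1L, 3L),
                    birth = c(0, 100, 100, 100, 1150, 3500),
                    death = c(NA, 1150, NA, 1900, NA, NA))
  h <- structure(list(events = ev, records = rec, horizon = 10000),
                 class = "lineage_history")
  f <- classify_fates(h, t = 1000)
  fates <- setNames(f$fate, f$species)
  expect_equal(unname(fates["1"]), "speciating")     # splits at t + 150
  expect_equal(unname(fates["2"]), "going_extinct")  # dies at t + 150
  expect_equal(unname(fates["3"]), "static")         # next event at t + 2500
  expect_equal(unname(fates["4"]), "other")          # dies at t + 900
  expect_false("5" %in% names(fates))                # not yet born at t
  # near the horizon, event-free species are censored
  f2 <- classify_fates(h, t = 9500)
  expect_true(all(f2$fate == "censored"))
})

test_that("stage boundaries come from diversity and range criteria", {
  gens <- seq(0, 40000, by = 100)
  N <- pmin(9, 1 + floor(gens / 1000))          # reaches 9 at 8000
  div <- data.frame(gen = gens, N = N)
  rng <- data.frame(gen = gens,
                    max_range = ifelse(gens < 30000, 5, 2))
  st <- detect_stages(div, rng, n_optima = 9, window = 1000)
  expect_equal(st$stage1_end, 8000)
  expect_equal(st$stage2_end, 30000)
  # diversity never reaching 9: open-ended stage 1
  st2 <- detect_stages(data.frame(gen = gens, N = pmin(5, N)), rng, 9)
  expect_true(is.na(st2$stage1_end))
  # range condition must persist: a flickering dip does not end stage 2
  rng$max_range[rng$gen == 20000] <- 2
  st3 <- detect_stages(div, rng, 9, window = 1000)
  expect_equal(st3$stage2_end, 30000)
})

test_that("the radiation plateau is found from the trajectory shape alone", {
  gens <- seq(0, 20000, by = 100)
  N <- ifelse(gens < 5000, 1 + floor(gens / 625), 9)  # rise then plateau at 9
  pl <- radiation_plateau(data.frame(gen = gens, N = N), stall = 2000)
  expect_equal(pl$N, 9)
  expect_lte(pl$gen, 6000)
  # monotone unbounded growth: no plateau
  expect_null(radiation_plateau(
    data.frame(gen = gens, N = 1 + floor(gens / 500)), stall = 2000))
})

test_that("turnover is the per-species event rate over the window", {
  ev <- data.frame(time = c(seq(1000, 8500, length.out = 4),
                            seq(1200, 9000, length.out = 4)),
                   event = rep(c("speciation", "extinction"), each = 4),
                   species = 1:8, parent = NA)
  div <- data.frame(gen = seq(0, 10000, by = 500), N = 40L)
  h <- structure(list(events = ev, records = NULL, diversity = div,
                      horizon = 10000), class = "lineage_history")
  expect_equal(turnover_rate(h, 0, 10000), 8 / (2 * 40 * 10000))
  expect_equal(turnover_rate(h, 9500, 10000), 0)
})

test_that("per-species variables match closed-form cases", {
  # two species, same site, near-identical phenotypes, K* = 150
  cfg <- clade_config(K_star = 150, gap_threshold = 0.001)
  snap <- list(gen = 0, id = 1:2, site = c(1L, 1L), sex = c(0L, 1L),
               snap_anc = 1:2, x1 = c(0, 0.01), x2 = c(0, 0),
               a = c(0, 0), muts = list(integer(0), 1:20))
  sim <- fake_sim(list(snap), cfg)
  sim$landscape <- gradient_landscape(3)
  suppressWarnings(h <- track_lineages(sim, gap = 0.001))
  expect_equal(h$diversity$N[1], 2)
  sv <- species_variables(sim, h, 1)
  expect_equal(sv$interspecific_competition,
               rep(competition_kernel(c(0, 0), c(0.01, 0)) / 150, 2),
               tolerance = 1e-6)
  expect_equal(sv$range_sites, c(1L, 1L))
  expect_equal(sv$abundance_per_site, c(1, 1))
  # heterospecific pair is GIT-isolated (distance 20): no hybridization risk
  expect_equal(sv$hybridization_risk, c(0, 0))

  # a lone species sitting exactly on its optimum
  cfg1 <- clade_config()
  snap1 <- list(gen = 0, id = 1:4, site = rep(5L, 4), sex = c(0L, 1L, 0L, 1L),
                snap_anc = 1:4, x1 = rep(0, 4), x2 = rep(0, 4),
                a = rep(0, 4), muts = rep(list(integer(0)), 4))
  sim1 <- fake_sim(list(snap1), cfg1)
  sim1$landscape <- gradient_landscape(3)
  h1 <- track_lineages(sim1)
  sv1 <- species_variables(sim1, h1, 1)
  expect_equal(sv1$interspecific_competition, 0)
  expect_equal(sv1$maladaptation, 0)  # all individuals at the site optimum
  expect_equal(sv1$hybridization_risk, 0)
  expect_true(is.na(sv1$parent_distance))
})

test_that("macroecology summarizes ranked abundances and stationary turnover", {
  run <- shared_diversifying_run()
  mac <- macroecology(run$sim, run$history, n_optima = 4)
  expect_equal(mac$metacommunity$metacommunity_size[1], 200)  # 4 x 50 founders
  ra <- mac$rank_abundance$stationary
  expect_true(all(diff(ra) <= 0))                 # ranked decreasing
  expect_equal(sum(ra), mac$metacommunity$metacommunity_size[
    which.min(abs(mac$metacommunity$gen - (mac$stationary$from + mac$stationary$to) / 2))])
  expect_gte(mac$turnover, 0)
})
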