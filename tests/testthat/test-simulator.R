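test_that("payoff vector: direct sums within groups", {
  m <- payoff_matrix(1, 2, 3, 4)
  lone <- population_state(c(1, 0), 1:2, M = 2)
  expect_equal(payoff_vector(lone, m), c(0, 0))
  expect_equal(payoff_vector(lone, m, include_self = TRUE), c(1, 4))
  # A with 2 other A and 1 B in its group: 2a + b
  st <- population_state(c(1, 1, 1, 0), rep(1, 4), M = 1)
  expect_equal(payoff_vector(st, m)[1], 2 * 1 + 2)
  expect_equal(payoff_vector(st, m)[4], 3 * 3)  # the B: 3 A-partners
  allA <- population_state(rep(1, 6), rep(1, 6), M = 1)
  expect_equal(payoff_vector(allA, m), rep(5 * 1, 6))
})

test_that("forced step mechanics: offspring inherits strategy, shifts group", {
  p <- model_params(5, 4, 0.5, 0.5)
  cfg <- simulation_config(p, r = 1, generations = 10, burn_in = 0)
  st <- population_state(c(1, 0, 0, 1, 0), c(2, 2, 3, 4, 1), M = 4)
  out <- step_population(st, cfg, reproducer = 1, dier = 3,
                         mutate_to = NA, displacement = 1)
  expect_equal(out$offspring_strategy, 1)   # parent 1 plays A
  expect_equal(out$offspring_group, 3)      # group 2 shifted by +1
  expect_equal(out$state$strategies[3], 1)
  expect_equal(out$state$groups[3], 3)
  # wrap-around: parent in group M, displacement +1 lands in group 1
  out2 <- step_population(st, cfg, reproducer = 4, dier = 2,
                          mutate_to = NA, displacement = 1)
  expect_equal(out2$offspring_group, 1)
  # unreachable displacement is rejected under r = 1 (M = 4 reaches 1 and 3)
  expect_error(step_population(st, cfg, reproducer = 1, dier = 3,
                               mutate_to = NA, displacement = 2),
               "not reachable")
})

test_that("steps conserve N and keep labels valid", {
  set.seed(99)
  p <- model_params(12, 5, 0.3, 0.4)
  cfg <- simulation_config(p, r = 2, generations = 10, burn_in = 0)
  st <- population_state(sample(0:1, 12, TRUE), sample.int(5, 12, TRUE), 5)
  for (i in 1:300) {
    st <- step_population(st, cfg)$state
    expect_equal(st$N, 12)
    expect_true(all(st$strategies %in% c(0L, 1L)))
    expect_true(all(st$groups >= 1L & st$groups <= 5L))
  }
})

test_that("neutral reproduction is uniform over individuals", {
  set.seed(123)
  p <- model_params(10, 2, 0.1, 0.1)
  cfg <- simulation_config(p, r = 1, generations = 10, burn_in = 0)
  st <- population_state(rep(c(1L, 0L), 5), rep(1:2, 5), M = 2)
  reps <- integer(2e4)
  for (i in seq_along(reps)) reps[i] <- step_population(st, cfg)$reproducer
  tab <- tabulate(reps, 10)
  pval <- stats::chisq.test(tab)$p.value
  expect_gt(pval, 1e-3)
})

test_that("selection shifts reproduction toward high payoff", {
  set.seed(5)
  # one A alone earning nothing vs a B-rich group: with b >> others the
  # B-group members earn more, so they should reproduce more often
  p <- model_params(6, 2, 0.1, 0.1)
  cfg <- simulation_config(p, r = 1, payoff = payoff_matrix(0, 0, 0, 1),
                           w = 1, generations = 10, burn_in = 0)
  st <- population_state(c(1, 0, 0, 0, 0, 0), c(1, 2, 2, 2, 2, 2), M = 2)
  reps <- vapply(1:4000, function(i) step_population(st, cfg)$reproducer,
                 integer(1))
  # individual 1 has fitness 1, the five B's fitness 1 + 4: expected share
  # for the A is 1/26
  expect_lt(mean(reps == 1), 0.09)
  expect_gt(mean(reps == 1), 0.02)
})

test_that("negative fitness raises a configuration error", {
  p <- model_params(6, 2, 0.1, 0.1)
  cfg <- simulation_config(p, r = 1, payoff = payoff_matrix(-10, -10, 0, 0),
                           w = 1, generations = 10, burn_in = 0)
  st <- population_state(rep(1L, 6), rep(1L, 6), M = 2)
  expect_error(step_population(st, cfg), "negative fitness")
})

test_that("neutral sigma estimator is reproducible and rejects misuse", {
  p <- model_params(20, 5, 0.1, 0.1)
  cfg <- simulation_config(p, r = 1, generations = 2e5, seed = 31)
  e1 <- run_neutral_sigma(cfg)
  e2 <- run_neutral_sigma(cfg)
  expect_identical(e1$sigma_hat, e2$sigma_hat)
  expect_identical(e1$se, e2$se)
  expect_equal(e1$sigma_hat, e1$mean_iaa_nb / e1$mean_iab_nb)
  expect_gte(e1$se, 0)
  cfg_sel <- simulation_config(p, r = 1, w = 0.1, generations = 1e4)
  expect_error(run_neutral_sigma(cfg_sel), "neutrality")
  cfg_u0 <- simulation_config(model_params(20, 5, 0, 0.1), r = 1,
                              generations = 1e4)
  expect_error(run_neutral_sigma(cfg_u0), "0/0")
})

test_that("neutral estimates bracket the closed form on a (u, v) grid", {
  grid <- data.frame(u = c(0.1, 0.1, 0.3), v = c(0.05, 0.3, 0.1))
  for (i in seq_len(nrow(grid))) {
    p <- model_params(20, 5, grid$u[i], grid$v[i])
    cfg <- simulation_config(p, r = 1, generations = 1e6, seed = 1000 + i)
    est <- run_neutral_sigma(cfg)
    closed <- sigma_exact(p, range_pattern(5, 1), FALSE)$sigma
    expect_lt(abs(est$sigma_hat - closed), 3 * est$se)
    # the with-self estimator against the with-self closed form
    cfg_s <- simulation_config(p, r = 1, include_self = TRUE,
                               generations = 1e6, seed = 2000 + i)
    est_s <- run_neutral_sigma(cfg_s)
    closed_s <- sigma_exact(p, range_pattern(5, 1), TRUE)$sigma
    expect_lt(abs(est_s$sigma_hat - closed_s), 3 * est_s$se)
  }
})

test_that("v = 0 occupancy is absorbing into a single group", {
  p <- model_params(30, 5, 0.1, 0)
  cfg <- simulation_config(p, r = 1, generations = 3e5, seed = 17,
                           snapshot_times = c(1e3, 3e5))
  occ <- run_occupancy(cfg)
  expect_equal(unique(occ$generation), c(1e3, 3e5))
  totals <- tapply(occ$count_A + occ$count_B, occ$generation, sum)
  expect_true(all(totals == 30))  # conservation at every snapshot
  late <- occ[occ$generation == 3e5, ]
  expect_equal(sum((late$count_A + late$count_B) > 0), 1)
})

test_that("v = 1 occupancy fills all groups for N >> M", {
  p <- model_params(60, 5, 0.1, 1)
  cfg <- simulation_config(p, r = 2, generations = 1e5, seed = 19,
                           snapshot_times = 1e5)
  occ <- run_occupancy(cfg)
  expect_true(all(occ$count_A + occ$count_B > 0))
  expect_equal(sum(occ$count_A + occ$count_B), 60)
})

test_that("occupancy snapshots are written as TSV round-trip", {
  p <- model_params(12, 3, 0.2, 0.5)
  cfg <- simulation_config(p, r = 1, generations = 500, seed = 2,
                           snapshot_times = c(100, 500))
  occ <- run_occupancy(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_occupancy_tsv(occ, path)
  back <- utils::read.delim(path)
  expect_equal(back$count_A, occ$count_A)
  expect_equal(names(back), c("group", "count_A", "count_B", "generation"))
})
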