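test_that("triplet probabilities: monomorphic at u = 0, normalization, bounds", {
  pat <- range_pattern(9, 2)
  p0 <- model_params(50, 9, 0, 0.3)
  # without mutation a mixed triple is impossible
  expect_equal(triplet_probability(1, 1, 0, p0, pat), 0)
  expect_equal(triplet_probability(0, 0, 1, p0, pat), 0)
  for (u in c(0.05, 0.5, 1)) {
    for (v in c(0.05, 0.5, 1)) {
      p <- model_params(20, 9, u, v)
      probs <- vapply(0:7, function(k) {
        d <- as.integer(intToBits(k)[1:3])
        triplet_probability(d[1], d[2], d[3], p, pat)
      }, numeric(1))
      expect_true(all(probs >= 0 & probs <= 1))
      coloc <- mean(pair_kernels(pat$f, p)$Psi1)  # (1/M) * sum_x Psi1(f(x))
      expect_equal(sum(probs), coloc, tolerance = 1e-12)
    }
  }
})

test_that("sigma reduces to the well-mixed value (N-2)/N", {
  for (N in c(3, 10, 100, 1000)) {
    for (u in c(0.05, 0.5, 1)) {
      # M = 1: single group, f = 1
      p1 <- model_params(N, 1, u, 0)
      expect_equal(sigma_exact(p1, single_group_pattern(), FALSE)$sigma,
                   (N - 2) / N, tolerance = 1e-12)
      # v = 0 with many groups: same limit without self-interaction,
      # exactly 1 with self-interaction
      p0 <- model_params(N, 9, u, 0)
      pat <- range_pattern(9, 3)
      expect_equal(sigma_exact(p0, pat, FALSE)$sigma, (N - 2) / N,
                   tolerance = 1e-12)
      expect_equal(sigma_exact(p0, pat, TRUE)$sigma, 1, tolerance = 1e-12)
    }
  }
})

test_that("global closed form equals the exact form with the global pattern", {
  draws <- random_params(100)
  for (i in seq_len(nrow(draws))) {
    p <- model_params(draws$N[i], draws$M[i], draws$u[i], draws$v[i])
    ac <- sigma_global_closed(p)$sigma
    ex <- sigma_exact(p, global_pattern(p$M), include_self = TRUE)$sigma
    expect_equal(ac, ex, tolerance = 1e-12)
  }
  # v = 0: closed form gives exactly 1
  for (N in c(5, 100)) for (M in c(2, 9)) for (u in c(0.07, 0.9)) {
    expect_equal(sigma_global_closed(model_params(N, M, u, 0))$sigma, 1,
                 tolerance = 1e-12)
  }
})

test_that("sigma result bookkeeping: ratio, positive denominator", {
  p <- model_params(30, 4, 0.2, 0.3)
  res <- sigma_exact(p, range_pattern(4, 1), TRUE)
  expect_s3_class(res, "sigma_result")
  expect_equal(res$sigma, res$numerator / res$denominator)
  expect_gt(res$denominator, 0)
  expect_gt(res$sigma, 0)
  expect_true(res$include_self)
})

test_that("u = 0 is rejected as a 0/0 degeneracy", {
  p <- model_params(30, 4, 0, 0.3)
  pat <- range_pattern(4, 1)
  expect_error(sigma_exact(p, pat), "0/0")
  expect_error(sigma_global_closed(model_params(30, 4, 0, 0.3)), "0/0")
  expect_error(sigma_tilt(p, pat), "0/0")
})

test_that("mismatched pattern and parameters are rejected", {
  p <- model_params(30, 4, 0.1, 0.3)
  expect_error(sigma_exact(p, range_pattern(5, 1)), "disagree on M")
  expect_error(triplet_probability(0, 1, 1, p, range_pattern(5, 1)),
               "disagree on M")
})

test_that("approximate sigma: M = 1 limit and large-N agreement", {
  expect_equal(sigma_approx(model_params(100, 1, 0.3, 0.2)), 1)
  # large N, low rates: approximation within 1% of the accurate value
  p <- model_params(1000, 9, 0.001, 0.001)
  expect_lt(relative_difference(p), 0.01)
  # high migration at moderate N: visibly worse than the low-rate regime
  lo <- relative_difference(model_params(100, 19, 0.07, 0.001))
  hi <- relative_difference(model_params(100, 19, 0.07, 1))
  expect_gt(hi, lo)
})

test_that("relative difference shrinks with N and with fewer groups", {
  rd <- function(N, M) relative_difference(model_params(N, M, 0.1, 0.1))
  expect_lt(rd(1000, 9), rd(100, 9))
  expect_lt(rd(1000, 19), rd(100, 19))
  expect_lt(rd(100, 9), rd(100, 49))
  expect_lt(rd(1000, 9), rd(1000, 49))
})

test_that("tilt equals (sigma-1)/(sigma+1) and decreases with mutation", {
  draws <- random_params(30, seed = 7)
  for (i in seq_len(nrow(draws))) {
    p <- model_params(draws$N[i], draws$M[i], draws$u[i], draws$v[i])
    pat <- range_pattern(p$M, max(1, p$M %/% 3))
    s <- sigma_exact(p, pat, FALSE)$sigma
    expect_equal(sigma_tilt(p, pat), (s - 1) / (s + 1), tolerance = 1e-10)
  }
  # v = 0: sigma = (N-2)/N so the tilt is -1/(N-1)
  for (N in c(5, 50)) for (u in c(0.1, 0.8)) {
    p <- model_params(N, 6, u, 0)
    expect_equal(sigma_tilt(p, range_pattern(6, 2)), -1 / (N - 1),
                 tolerance = 1e-12)
  }
  # strict decrease in u
  pat <- range_pattern(9, 1)
  tilts <- vapply(seq(0.01, 0.99, by = 0.07), function(u)
    sigma_tilt(model_params(100, 9, u, 0.1), pat), numeric(1))
  expect_true(all(diff(tilts) < 0))
})

test_that("sigma decreases strictly with the mutation probability", {
  for (r in 1:4) {
    pat <- range_pattern(9, r)
    s <- vapply(seq(0.01, 0.99, by = 0.02), function(u)
      sigma_exact(model_params(100, 9, u, 0.1), pat, FALSE)$sigma, numeric(1))
    expect_true(all(diff(s) < 0))
  }
})

test_that("sigma(v) rises from (N-2)/N to an interior maximum then falls", {
  vgrid <- seq(0, 1, by = 0.01)
  for (r in 1:4) {
    pat <- range_pattern(9, r)
    s <- vapply(vgrid, function(v)
      sigma_exact(model_params(100, 9, 0.07, v), pat, FALSE)$sigma, numeric(1))
    expect_equal(s[1], 0.98, tolerance = 1e-12)
    imax <- which.max(s)
    expect_gt(imax, 1)
    expect_lt(imax, length(vgrid))
    expect_gt(s[imax], s[1])
  }
})

test_that("critical ratios and the abundance condition", {
  cr1 <- critical_ratios(1)
  expect_equal(cr1$pd_ratio, 0)
  expect_equal(cr1$sd_ratio, 2 / 3)
  big <- critical_ratios(1e9)
  expect_equal(big$pd_ratio, 1, tolerance = 1e-8)
  expect_equal(big$sd_ratio, 2, tolerance = 1e-8)
  s <- seq(0.2, 5, by = 0.2)
  crs <- critical_ratios(s)
  expect_true(all(diff(crs$pd_ratio) > 0))
  expect_true(all(diff(crs$sd_ratio) > 0))
  expect_error(critical_ratios(0), "positive")

  expect_false(favors_A(1, payoff_matrix(2, 3, 3, 2)))  # a=d, b=c boundary
  expect_true(favors_A(2, payoff_matrix(1, 0, 0, 0)))
  # PD with b = 3, c = 1: favored iff (sigma-1)/(sigma+1) > 1/3, i.e. sigma > 2
  pd <- pd_payoff(b = 3, cost = 1)
  expect_false(favors_A(1.99, pd))
  expect_true(favors_A(2.01, pd))
})

test_that("sweep grid emits deterministic rows and isolates failures", {
  sw <- sigma_sweep(N = 100, M = 9, u = 0.07, v = c(0.01, 1), r = 1:4)
  expect_equal(nrow(sw), 8)
  expect_true(all(is.na(sw$error)))
  sw2 <- sigma_sweep(N = 100, M = 9, u = 0.07, v = c(0.01, 1), r = 1:4)
  expect_identical(sw, sw2)
  # per-point failure recorded, run continues
  sw3 <- sigma_sweep(N = 100, M = 9, u = c(0, 0.07), v = 0.1, r = 1)
  expect_equal(sum(!is.na(sw3$error)), 1)
  expect_equal(sum(!is.na(sw3$sigma)), 1)
  expect_error(sigma_sweep(N = numeric(0), M = 9, u = 0.1, v = 0.1),
               "non-empty")
  # comparison columns
  sw4 <- sigma_sweep(N = 100, M = 19, u = 0.07, v = 0.3, r = "global",
                     include_self = TRUE, compare_approx = TRUE)
  expect_equal(sw4$sigma, sw4$sigma_ac, tolerance = 1e-12)
})
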