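test_that("the precomputation move maximizes shallow value, first wins ties", {
  expect_equal(precomputation_move(consideration_set(c(0.6, 0.5, 0.4),
                                                     c(0.5, 0.5, 0.5))),
               "m1")
  expect_equal(precomputation_move(consideration_set(c(0.5, 0.5),
                                                     c(0.1, 0.9))),
               "m1")
  withr::local_seed(42)
  for (i in 1:50) {
    cs <- random_cset()
    best <- precomputation_move(cs)
    expect_true(all(cs$shallow[cs$move_id == best] >= cs$shallow))
  }
})

test_that("benefit of computation matches its brute-force definition", {
  expect_equal(benefit_of_computation(consideration_set(c(0.6, 0.5),
                                                        c(0.40, 0.70))),
               0.30)
  # deep and shallow argmax agree: computation changes nothing
  expect_equal(benefit_of_computation(consideration_set(c(0.7, 0.2),
                                                        c(0.9, 0.1))),
               0)
  withr::local_seed(7)
  for (i in 1:200) {
    cs <- random_cset(k = sample(2:6, 1))
    duc <- benefit_of_computation(cs)
    oracle <- max(cs$deep) - cs$deep[which.max(cs$shallow)]
    expect_identical(duc, oracle)
    expect_gte(duc, 0)
    agree <- which.max(cs$deep) == which.max(cs$shallow)
    expect_identical(duc == 0, agree)
  }
})

test_that("expected max of Gaussians handles degenerate and closed-form cases", {
  expect_equal(expected_max_gaussians(0.3, 0.2), 0.3)
  expect_equal(expected_max_gaussians(c(0.1, 0.7, 0.4), c(0, 0, 0)), 0.7)
  expect_equal(expected_max_gaussians(c(0, 0), c(1, 1)), 1 / sqrt(pi),
               tolerance = 1e-6)
  # mixed point mass and Gaussian, against the two-component closed form
  expect_equal(expected_max_gaussians(c(0.5, 0.3), c(0, 0.2)),
               emax_two_gaussians(0.5, 0, 0.3, 0.2), tolerance = 1e-6)
  expect_error(expected_max_gaussians(c(0, 0), c(1, -1)), "non-negative")
})

test_that("expected max of Gaussians is monotone in means and spreads", {
  withr::local_seed(8)
  for (i in 1:40) {
    k <- sample(2:5, 1)
    mu <- runif(k)
    sig <- runif(k, 0, 0.3)
    base <- expected_max_gaussians(mu, sig)
    j <- sample(k, 1)
    mu2 <- mu; mu2[j] <- mu2[j] + runif(1, 0, 0.5)
    sig2 <- sig; sig2[j] <- sig2[j] + runif(1, 0, 0.5)
    expect_gte(expected_max_gaussians(mu2, sig) + 1e-9, base)
    expect_gte(expected_max_gaussians(mu, sig2) + 1e-9, base)
  }
})

test_that("expected benefit is zero without uncertainty, positive with overlap", {
  # shallow == deep everywhere: beliefs are point masses at the known answer
  expect_equal(expected_benefit_of_computation(
    consideration_set(c(0.6, 0.4), c(0.6, 0.4))), 0)
  fx <- make_fixture_positions()
  expect_equal(benefit_of_computation(fx$agreeing_argmax), 0)
  expect_gt(expected_benefit_of_computation(fx$agreeing_argmax), 0)
  expect_equal(benefit_of_computation(fx$degenerate), 0)
  expect_equal(expected_benefit_of_computation(fx$degenerate), 0)
})

test_that("quadrature agrees with the Monte-Carlo oracle on random sets", {
  withr::local_seed(9)
  for (i in 1:30) {
    cs <- random_cset()
    eb <- expected_benefit_of_computation(cs)
    mc <- mc_expected_benefit(cs, n_samples = 20000, seed = 100 + i)
    expect_lte(abs(eb - mc$estimate), 3 * mc$se + 1e-6)
  }
})

test_that("mc_expected_benefit is seed-stable and degenerate-safe", {
  cs <- make_fixture_positions()$agreeing_argmax
  a <- mc_expected_benefit(cs, n_samples = 5000, seed = 1)
  b <- mc_expected_benefit(cs, n_samples = 5000, seed = 1)
  expect_identical(a, b)
  deg <- mc_expected_benefit(make_fixture_positions()$degenerate,
                             n_samples = 5000, seed = 1)
  expect_equal(deg, list(estimate = 0, se = 0))
  expect_error(mc_expected_benefit(cs, n_samples = 10), ">= 1000")
})

test_that("scores are permutation-invariant away from ties", {
  withr::local_seed(10)
  for (i in 1:25) {
    cs <- random_cset(p_tie = 0, p_exact = 0)
    perm <- sample(nrow(cs))
    cs2 <- consideration_set(cs$shallow[perm], cs$deep[perm],
                             move_id = cs$move_id[perm])
    expect_equal(benefit_of_computation(cs2), benefit_of_computation(cs))
    expect_equal(expected_benefit_of_computation(cs2),
                 expected_benefit_of_computation(cs), tolerance = 1e-7)
  }
})

test_that("table-level scoring matches the per-set functions row by row", {
  withr::local_seed(11)
  tbl <- toy_move_table(n = 20, k = 4)
  sc <- quiet(score_moves(tbl, expected = TRUE))
  for (i in seq_len(nrow(tbl))) {
    cs <- consideration_set_from_record(tbl, i)
    expect_equal(sc$delta_uc[i], benefit_of_computation(cs))
    expect_equal(sc$e_delta_uc[i], expected_benefit_of_computation(cs),
                 tolerance = 1e-9)
    expect_equal(sc$u[i], cs$deep[which.max(cs$shallow)])
  }
  expect_equal(sc$move_time, rep(3, 20))
})
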