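test_that("a one-cell grid estimates V = 1 there and nothing elsewhere", {
  withr::local_seed(41)
  tbl <- toy_move_table(n = 10, k = 2, game_id = sprintf("g%03d", 1:10),
                        ply = rep(20L, 10))
  tbl$clock_before <- 100.5
  tbl$clock_after <- 98
  rec <- quiet(score_moves(tbl))
  rec$u <- 0.5
  g <- quiet(build_value_grid(rec, time_control(180, 0),
                              run_config(min_count = 5)))
  expect_equal(grid_cell <- g$wins[34, 17] / g$totals[34, 17], 1)
  expect_equal(sum(g$totals), 10)
  expect_equal(sum(g$totals >= g$min_count), 1)
})

test_that("grid tallies match an independent brute-force count", {
  withr::local_seed(42)
  n <- 400
  tbl <- toy_move_table(n = n, game_id = sprintf("g%04d", seq_len(n)),
                        ply = sample(15:75, n, replace = TRUE),
                        outcome = sample(c("win", "loss", "draw"), n,
                                         replace = TRUE))
  tbl$clock_before <- runif(n, 0, 180)
  tbl$clock_after <- pmax(tbl$clock_before - runif(n, 0, 5), 0)
  tbl$opp_clock <- runif(n, 40, 180)
  rec <- quiet(score_moves(tbl))
  rec$u <- runif(n)
  cfg <- run_config(min_count = 1)
  g <- quiet(build_value_grid(rec, time_control(180, 0), cfg))
  keep <- rec$opp_clock >= 60
  w_val <- c(win = 1, loss = 0, draw = 0.5)
  for (i in which(keep)) {
    ti <- floor(rec$clock_before[i] / 3) + 1
    ui <- floor(rec$u[i] / 0.03) + 1
    expect_gte(g$totals[ti, ui], 1)
  }
  wins_oracle <- matrix(0, nrow(g$wins), ncol(g$wins))
  totals_oracle <- matrix(0, nrow(g$wins), ncol(g$wins))
  for (i in which(keep)) {
    ti <- floor(rec$clock_before[i] / 3) + 1
    ui <- floor(rec$u[i] / 0.03) + 1
    totals_oracle[ti, ui] <- totals_oracle[ti, ui] + 1
    wins_oracle[ti, ui] <- wins_oracle[ti, ui] + w_val[[rec$outcome[i]]]
  }
  expect_equal(g$totals, totals_oracle, tolerance = 1e-12)
  expect_equal(g$wins, wins_oracle, tolerance = 1e-12)
})

test_that("time cost on an injected analytic grid equals the closed form", {
  f <- function(T, U) pmin(1, U * (1 - exp(-T / 100)))
  g <- value_grid_from_function(f, t_max = 300, time_control(300, 0))
  # bin midpoints: T = 100.5 -> cell value f(100.5, U_mid)
  u_mid <- 0.495
  expect_equal(time_cost(g, 100, 0.5, 0), 0)
  expect_equal(time_cost(g, 100, 0.5, 30),
               f(100.5, u_mid) - f(70.5, u_mid), tolerance = 1e-12)
  # monotone law: cost of spending time is non-negative everywhere estimable
  withr::local_seed(43)
  for (i in 1:25) {
    t0 <- runif(1, 40, 290)
    dt <- runif(1, 0, t0 - 10)
    expect_gte(time_cost(g, t0, runif(1), dt), 0)
  }
})

test_that("inestimable cells error with coordinates in strict mode", {
  wins <- matrix(0, 4, 4)
  totals <- matrix(0, 4, 4)
  totals[2, 2] <- 100
  wins[2, 2] <- 50
  g <- value_grid(wins, totals, time_control(60, 0))
  expect_error(time_cost(g, 4, 0.04, 3, strict = TRUE), "T bin 1")
  # non-strict lookups fall back along the T axis within the same row,
  # then to the nearest non-empty utility row
  expect_equal(time_cost(g, 10, 0.05, 6, strict = FALSE), 0)
  expect_equal(time_cost(g, 4, 0.10, 3, strict = FALSE), 0)
  empty <- value_grid(matrix(0, 2, 2), matrix(0, 2, 2), time_control(60, 0))
  expect_error(time_cost(empty, 4, 0.04, 3, strict = FALSE),
               "no estimable cell")
})

test_that("empirical stopping times solve the threshold inequality", {
  # linear-in-T law, fine utility bins so midpoint quantization is negligible
  f <- function(T, U) pmin(1, pmax(0, U + 0.001 * T))
  g <- value_grid_from_function(f, t_max = 300, time_control(300, 0),
                                utility_bin_width = 0.001)
  expect_true(abs(delta_t_max_empirical(g, 100, 0.4, 0.05) - 50) <= 3)
  # no benefit: never worth spending on a strictly increasing row
  expect_equal(delta_t_max_empirical(g, 100, 0.4, 0), 0)
  # weakly increasing in the offered benefit
  d <- vapply(c(0.01, 0.02, 0.05, 0.08, 0.12), function(duc) {
    delta_t_max_empirical(g, 150, 0.3, duc)
  }, numeric(1))
  expect_true(all(diff(d) >= 0))
})

test_that("analytic stopping times reproduce hand-solved values", {
  expect_equal(delta_t_max_analytic(cost_family("linear", rho = 0.01),
                                    delta_uc = 0.1), 10, tolerance = 1e-12)
  expect_equal(delta_t_max_analytic(cost_family("power", a = 1, b = 2),
                                    delta_uc = 0.25), 0.5, tolerance = 1e-12)
  expect_equal(delta_t_max_analytic(cost_family("power_timeleft", a = 1,
                                                b = 2),
                                    t = 100, delta_uc = 0.04), 20,
               tolerance = 1e-12)
  # degree-1 homogeneity in time left
  fam <- cost_family("power_timeleft", a = 0.7, b = 3)
  withr::local_seed(44)
  for (i in 1:10) {
    t0 <- runif(1, 1, 500); lam <- runif(1, 0.1, 5); duc <- runif(1, 0, 0.5)
    expect_equal(delta_t_max_analytic(fam, lam * t0, duc),
                 lam * delta_t_max_analytic(fam, t0, duc),
                 tolerance = 1e-12)
  }
  expect_error(cost_family("power", a = 1, b = 0.5), "exceed 1")
  expect_error(cost_family("linear", rho = -1), "rho")
})

test_that("implied mean move times average the policy's allocations", {
  cfg <- run_config(motor_time = 1)
  fam <- cost_family("linear", rho = 0.01) # dtmax = 100 * duc
  # all offers acceptable: mean = motor + mean(delta_tc) per bin
  offers <- tibble::tibble(t_left = 100, u = 0.5,
                           delta_tc = c(1, 2, 1.5, 0.5),
                           delta_uc = c(0.04, 0.05, 0.31, 0.32))
  out <- implied_mean_move_times(fam, offers, cfg)
  expect_equal(out$mean_time, c(1 + 1.5, 1 + 1))
  expect_equal(out$n, c(2L, 2L))
  # all offers declined: mean = motor exactly
  declined <- tibble::tibble(t_left = 100, u = 0.5,
                             delta_tc = c(10, 20), delta_uc = c(0.01, 0.02))
  expect_equal(implied_mean_move_times(fam, declined, cfg)$mean_time, 1)
  # mixed enumerated offers, hand-computed expectation
  mixed <- tibble::tibble(
    t_left = rep(100, 12), u = 0.5,
    delta_tc = c(1, 2, 3, 9, 1, 2, 30, 40, 2, 2, 2, 100),
    delta_uc = c(rep(0.02, 4), rep(0.32, 4), rep(0.62, 4)))
  # thresholds: 2, 32, 62 s -> accepted: (1,2), (1,2,30), (2,2,2)
  res <- implied_mean_move_times(fam, mixed, cfg)
  expect_equal(res$mean_time,
               c(1 + 3 / 4, 1 + 33 / 4, 1 + 6 / 4))
})
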