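test_that("move times follow the clock recurrence under both conventions", {
  expect_equal(compute_move_time(60, 57, 0), 3)
  expect_equal(compute_move_time(60, 57, 0, "subtract_increment"), 3)
  expect_equal(compute_move_time(60, 57, 2), 5)
  expect_equal(compute_move_time(60, 57, 2, "subtract_increment"), 1)
  expect_equal(compute_move_time(10, 10, 0), 0)
  # clamped at zero when the increment exceeds the clock drop
  expect_equal(quiet(compute_move_time(60, 59.5, 2, "subtract_increment")), 0)
  expect_equal(compute_move_time(c(60, 30), c(57, 29), 2), c(5, 3))
})

test_that("the ply window is inclusive on both edges", {
  tbl <- toy_move_table(n = 4, ply = c(14L, 15L, 75L, 76L))
  kept <- filter_ply_window(tbl)
  expect_equal(kept$ply, c(15L, 75L))
  expect_equal(nrow(filter_ply_window(tbl[0, ])), 0)
})

test_that("a noiseless linear system is interpolated exactly", {
  withr::local_seed(51)
  n <- 500
  rec <- tibble::tibble(
    delta_uc = runif(n, 0, 0.5),
    elo = runif(n, 1000, 2000),
    tc_start = 180, tc_inc = 0
  )
  rec$move_time <- 2 + 5 * sqrt(rec$delta_uc) + 0.001 * (rec$elo - 1500)
  fit <- fit_movetime_regression(rec, "delta_uc", transform = "sqrt")
  est <- setNames(fit$terms$estimate, fit$terms$term)
  expect_equal(unname(est["(Intercept)"]), 2, tolerance = 1e-8)
  expect_equal(unname(est["benefit"]), 5, tolerance = 1e-8)
  expect_equal(unname(est["elo_c"]), 0.001, tolerance = 1e-8)
  expect_equal(unname(est["benefit:elo_c"]), 0, tolerance = 1e-8)
  expect_equal(fit$n, n)
})

test_that("OLS matches the closed-form normal equations", {
  withr::local_seed(52)
  n <- 200
  rec <- tibble::tibble(
    delta_uc = runif(n, 0, 0.4),
    elo = rnorm(n, 1500, 200),
    move_time = rexp(n, 1 / 3)
  )
  fit <- fit_movetime_regression(rec, "delta_uc", transform = "identity")
  X <- cbind(1, rec$delta_uc, rec$elo - 1500,
             rec$delta_uc * (rec$elo - 1500))
  beta <- solve(crossprod(X), crossprod(X, rec$move_time))
  expect_equal(unname(fit$terms$estimate), drop(beta), tolerance = 1e-8)
})

test_that("a three-point hand system recovers slope one, intercept zero", {
  rec <- tibble::tibble(delta_uc = c(0, 1, 2), move_time = c(0, 1, 2))
  fit <- fit_movetime_regression(rec, "delta_uc", transform = "identity",
                                 include_elo = FALSE, min_rows_per_term = 1)
  expect_equal(unname(fit$terms$estimate), c(0, 1), tolerance = 1e-12)
  # default precondition would refuse so small a system
  expect_error(fit_movetime_regression(rec, "delta_uc",
                                       transform = "identity",
                                       include_elo = FALSE),
               "at least")
})

test_that("noisy benefit slopes are recovered within sampling error", {
  withr::local_seed(53)
  n <- 50000
  rec <- tibble::tibble(delta_uc = runif(n, 0, 0.5),
                        elo = rnorm(n, 1500, 200))
  rec$move_time <- 2 + 5 * rec$delta_uc + rnorm(n)
  fit <- fit_movetime_regression(rec, "delta_uc", transform = "identity",
                                 include_interaction = FALSE)
  b <- fit$terms[fit$terms$term == "benefit", ]
  expect_lt(abs(b$estimate - 5), 3 * b$std_error)
})

test_that("rank-deficient designs error with the collinear terms named", {
  rec <- tibble::tibble(delta_uc = runif(50, 0, 0.5), elo = 1500,
                        move_time = rnorm(50))
  expect_error(fit_movetime_regression(rec, "delta_uc", min_rows_per_term = 1),
               "collinear")
})

test_that("per-time-control and pooled designs expand as documented", {
  withr::local_seed(54)
  n <- 2000
  rec <- tibble::tibble(
    delta_uc = runif(n, 0, 0.5),
    elo = rnorm(n, 1500, 200),
    tc_start = sample(c(180, 600), n, replace = TRUE),
    tc_inc = sample(c(0, 2), n, replace = TRUE)
  )
  rec$move_time <- 1 + 4 * rec$delta_uc + 0.002 * rec$tc_start + rnorm(n)
  per <- fit_movetime_regression(rec, "delta_uc", transform = "identity",
                                 per_time_control = TRUE)
  expect_equal(per$k, 16) # 4 settings x (intercept, benefit, elo, interaction)
  pooled <- fit_movetime_regression(rec, "delta_uc", transform = "identity",
                                    pooled_time_control = TRUE)
  expect_setequal(
    pooled$terms$term,
    c("(Intercept)", "benefit", "elo_c", "tc_start", "tc_inc",
      "benefit:elo_c", "benefit:tc_start", "benefit:tc_inc"))
  ts <- pooled$terms[pooled$terms$term == "tc_start", ]
  expect_lt(abs(ts$estimate - 0.002), 4 * ts$std_error)
})

test_that("AIC comparison prefers the generative transform", {
  withr::local_seed(55)
  n <- 20000
  base <- tibble::tibble(delta_uc = runif(n, 0, 0.5),
                         elo = rnorm(n, 1500, 200))
  sq <- base
  sq$move_time <- 2 + 6 * sqrt(sq$delta_uc) + rnorm(n)
  f_sq_s <- fit_movetime_regression(sq, "delta_uc", "sqrt")
  f_sq_i <- fit_movetime_regression(sq, "delta_uc", "identity")
  cmp <- aic_compare(f_sq_s, f_sq_i)
  expect_equal(cmp$preferred, "a")
  expect_lt(cmp$delta_aic, 0)
  lin <- base
  lin$move_time <- 2 + 6 * lin$delta_uc + rnorm(n)
  f_li_s <- fit_movetime_regression(lin, "delta_uc", "sqrt")
  f_li_i <- fit_movetime_regression(lin, "delta_uc", "identity")
  expect_equal(aic_compare(f_li_s, f_li_i)$preferred, "b")
  # identical models tie; different row counts are refused
  expect_equal(aic_compare(f_sq_s, f_sq_s)$delta_aic, 0)
  small <- fit_movetime_regression(sq[1:10000, ], "delta_uc", "sqrt")
  expect_error(aic_compare(f_sq_s, small), "row counts")
})

test_that("per-player Spearman summaries behave at the extremes", {
  withr::local_seed(56)
  mk_records <- function(n_games, rho_fun, elo) {
    recs <- lapply(seq_len(n_games), function(g) {
      n <- 10
      duc <- runif(n, 0, 0.5)
      tibble::tibble(
        game_id = sprintf("g%05d", g), ply = seq(15L, 33L, by = 2L),
        elo = elo, move_time = rho_fun(duc), delta_uc = duc)
    })
    dplyr::bind_rows(recs)
  }
  # strictly increasing move times in benefit: rho = 1 in every bin
  mono <- mk_records(250, function(d) 1 + d^3, elo = 1510)
  out <- spearman_by_elo(mono, min_games = 200)
  expect_equal(out$elo_bin, 1500)
  expect_equal(out$mean_rho, 1)
  # independent move times: mean rho near 0
  null <- mk_records(600, function(d) runif(length(d)), elo = 1510)
  out0 <- spearman_by_elo(null, min_games = 200)
  expect_lt(abs(out0$mean_rho), 0.05)
  # bins under the game floor are dropped
  few <- mk_records(199, function(d) d, elo = 1510)
  expect_equal(nrow(spearman_by_elo(few, min_games = 200)), 0)
  # invariance to monotone transforms of move time
  trans <- mono
  trans$move_time <- exp(3 * trans$move_time)
  expect_equal(spearman_by_elo(trans, min_games = 200)$mean_rho,
               out$mean_rho)
})

test_that("binned move-time curves average within benefit bins", {
  rec1 <- tibble::tibble(tc_start = 180, tc_inc = 0, delta_uc = 0.05,
                         move_time = 4)
  out1 <- binned_movetime_curve(rec1)
  expect_equal(out1$mean_move_time, 4)
  expect_equal(out1$benefit_bin, 0.03)
  rec2 <- tibble::tibble(tc_start = 180, tc_inc = 0,
                         delta_uc = c(0.05, 0.055), move_time = c(2, 4))
  expect_equal(binned_movetime_curve(rec2)$mean_move_time, 3)
})

test_that("players in one game are split by ply parity", {
  rec <- tibble::tibble(
    game_id = "g1", ply = 15:26, elo = rep(c(1200, 1900), 6),
    delta_uc = runif(12, 0, 0.5))
  rec$move_time <- ifelse(rec$ply %% 2 == 1, 1 + rec$delta_uc,
                          2 - rec$delta_uc)
  out <- spearman_by_elo(rec, min_games = 1)
  expect_equal(nrow(out), 2)
  expect_equal(out$mean_rho[out$elo_bin == 1200], 1)
  expect_equal(out$mean_rho[out$elo_bin == 1900], -1)
})
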