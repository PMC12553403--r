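#' Simulation configuration
#'
#' Study conditions for the synthetic clocked-game generator: blitz-style
#' two-player games whose positions carry consideration sets of paired
#' shallow/deep evaluations, and whose players deliberate according to a
#' stopping policy plus noise. Defaults describe a 180+0 blitz population
#' with a power-law time cost; the methods vignette discusses each choice.
#'
#' @param n_games Number of games (>= 1).
#' @param time_control A [time_control()] (default 180+0).
#' @param elo_mean,elo_sd Rating distribution of players (default 1500, 300).
#' @param advantage_step_sd Innovation SD of the reflected random walk the
#'   position advantage follows across plies, utility units (default 0.03).
#' @param gap_mean Mean utility gap (exponential) between the best move and
#'   the alternatives in a consideration set (default 0.08).
#' @param shallow_noise_sd Scale of the shallow-deep evaluation discrepancy,
#'   utility units (default 0.1); per-move heteroscedastic multipliers are
#'   drawn uniformly on (0.5, 1.5).
#' @param consideration_size Moves per consideration set (default 5, >= 2).
#' @param policy_family `"linear"`, `"power"`, `"power_timeleft"` or
#'   `"empirical_grid"`.
#' @param policy_params For the analytic families, the [cost_family()]
#'   parameters as a list (default `list(a = 0.005, b = 2)`); for
#'   `"empirical_grid"`, `list(grid = <value_grid>)`.
#' @param motor_time Baseline non-deliberative seconds per move (default 2).
#' @param movetime_noise_cv Coefficient of variation of the multiplicative
#'   lognormal noise on deliberation time (default 0.25).
#' @param player_speed_sd Lognormal sdlog of a per-player deliberateness
#'   multiplier applied to all of that player's deliberation times within a
#'   game (default 0.4). Persistent speed differences are what make a low
#'   clock at mid-game predictive of losing on time, giving the empirical
#'   value function its dependence on time remaining.
#' @param offer_spread Lognormal sdlog of the offered-time multiplier around
#'   the policy threshold (default 0.75); offers are accepted when the
#'   multiplier is at most 1.
#' @param offer_coupling Spearman correlation between offered time and
#'   offered benefit in standalone [generate_offer()] draws (default 0.5).
#' @param offer_scale_s Scaling of raw offer times in [generate_offer()]
#'   (default 20000; raw draws are lognormal with median 1e-4 s, so the
#'   scaled median offer is 2 s).
#' @param draw_threshold Final advantage within `0.5 +/- draw_threshold` is
#'   scored a draw (default 0.05).
#' @param max_ply Truncation ply for unfinished games (default 140).
#' @param seed Optional integer seed; fixes the whole dataset.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_games = 200,
                       time_control = NULL,
                       elo_mean = 1500, elo_sd = 300,
                       advantage_step_sd = 0.03,
                       gap_mean = 0.08,
                       shallow_noise_sd = 0.1,
                       consideration_size = 5,
                       policy_family = c("power", "linear",
                                         "power_timeleft", "empirical_grid"),
                       policy_params = NULL,
                       motor_time = 2,
                       movetime_noise_cv = 0.25,
                       player_speed_sd = 0.4,
                       offer_spread = 0.75,
                       offer_coupling = 0.5,
                       offer_scale_s = 20000,
                       draw_threshold = 0.05,
                       max_ply = 140,
                       seed = NULL) {
  policy_family <- match.arg(policy_family)
  if (is.null(time_control)) time_control <- vocchess::time_control(180, 0)
  if (!inherits(time_control, "time_control")) {
    stop("`time_control` must be a time_control() object", call. = FALSE)
  }
  if (n_games < 1) stop("`n_games` must be >= 1", call. = FALSE)
  if (consideration_size < 2) {
    stop("`consideration_size` must be >= 2", call. = FALSE)
  }
  for (nm in c("elo_sd", "advantage_step_sd", "gap_mean", "shallow_noise_sd",
               "offer_spread", "offer_scale_s", "player_speed_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0) {
      stop(sprintf("`%s` must be non-negative", nm), call. = FALSE)
    }
  }
  if (motor_time < 0 || movetime_noise_cv < 0) {
    stop("`motor_time` and `movetime_noise_cv` must be non-negative ",
         "(negative move times are impossible)", call. = FALSE)
  }
  if (is.null(policy_params)) {
    policy_params <- switch(policy_family,
                            linear = list(rho = 0.01),
                            power = list(a = 0.005, b = 2),
                            power_timeleft = list(a = 0.5, b = 2),
                            empirical_grid = stop(
                              "`policy_params$grid` is required for the ",
                              "empirical_grid policy", call. = FALSE))
  }
  structure(
    list(n_games = as.integer(n_games), time_control = time_control,
         elo_mean = elo_mean, elo_sd = elo_sd,
         advantage_step_sd = advantage_step_sd, gap_mean = gap_mean,
         shallow_noise_sd = shallow_noise_sd,
         consideration_size = as.integer(consideration_size),
         policy_family = policy_family, policy_params = policy_params,
         motor_time = motor_time, movetime_noise_cv = movetime_noise_cv,
         player_speed_sd = player_speed_sd,
         offer_spread = offer_spread, offer_coupling = offer_coupling,
         offer_scale_s = offer_scale_s, draw_threshold = draw_threshold,
         max_ply = as.integer(max_ply), seed = seed),
    class = "sim_config"
  )
}

# Policy object from a sim_config.
sim_policy <- function(config) {
  p <- config$policy_params
  switch(config$policy_family,
         linear = cost_family("linear", rho = p$rho),
         power = cost_family("power", a = p$a, b = p$b),
         power_timeleft = cost_family("power_timeleft", a = p$a, b = p$b),
         empirical_grid = p$grid)
}

# Triangle-wave reflection of a random walk into [0, 1].
reflect01 <- function(x) {
  r <- x %% 2
  ifelse(r > 1, 2 - r, r)
}

#' Sample a consideration set
#'
#' Draws one consideration set: deep utilities uniform on \[0, 1\] (or spread
#' below a supplied anchor `u`, the in-game structure), shallow utilities
#' equal to the deep values plus heteroscedastic Gaussian noise
#' (`sd = shallow_noise_sd * eps_m`, `eps_m ~ U(0.5, 1.5)` per move) clamped
#' to \[0, 1\], and moves ordered by descending shallow value. Uses the
#' current RNG stream.
#'
#' @param config A [sim_config()].
#' @param u Optional anchor advantage: the best deep value is `u` and the
#'   others sit an exponential gap below it.
#' @return A [consideration_set()].
#' @export
sample_consideration_set <- function(config = sim_config(), u = NULL) {
  k <- config$consideration_size
  deep <- if (is.null(u)) {
    runif(k)
  } else {
    c(u, pmax(0, u - rexp(k - 1, rate = 1 / config$gap_mean)))
  }
  eps <- runif(k, 0.5, 1.5)
  shallow <- clamp01(deep + rnorm(k, 0, config$shallow_noise_sd * eps))
  ord <- order(shallow, decreasing = TRUE)
  consideration_set(shallow[ord], deep[ord],
                    move_id = paste0("m", seq_len(k))[ord])
}

#' Sample computation offers
#'
#' Draws `(delta_tc, delta_uc)` offer pairs for policy marginalization:
#' offered times are lognormal (median 1e-4 s) scaled by `offer_scale_s`
#' (mean offered time is exactly proportional to the scale), offered benefits
#' are Beta(1.2, 10) on \[0, 1\], and the two are positively coupled through
#' a Gaussian copula with Spearman correlation `offer_coupling`
#' (`coupling = 0` gives independence). Uses the current RNG stream.
#'
#' @param n Number of offers.
#' @param config A [sim_config()].
#' @param coupling Override the configured rank correlation.
#' @return A tibble with columns `delta_tc` (s) and `delta_uc` (utility).
#' @export
generate_offer <- function(n, config = sim_config(),
                           coupling = config$offer_coupling) {
  if (abs(coupling) >= 1) stop("`coupling` must be in (-1, 1)", call. = FALSE)
  rho <- 2 * sin(pi * coupling / 6) # Gaussian-copula Spearman inversion
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  tibble::tibble(
    delta_tc = config$offer_scale_s *
      qlnorm(pnorm(z1), meanlog = log(1e-4), sdlog = 1),
    delta_uc = qbeta(pnorm(z2), shape1 = 1.2, shape2 = 10)
  )
}

#' Generate a synthetic clocked-game dataset
#'
#' Simulates `n_games` two-player games under the configured time control.
#' The position advantage follows a reflected random walk on \[0, 1\]; at
#' each ply the mover receives a consideration set anchored on the current
#' advantage, an offered computation `(delta_tc, delta_uc)` whose time is the
#' policy threshold `delta_t_max` times an independent lognormal factor
#' (positions with zero true benefit get a baseline offer that is never
#' worthwhile), and accepts it exactly when `delta_tc <= delta_t_max`
#' (all-or-none computation). Deliberation time is multiplied by lognormal
#' noise with the configured CV; declining a positive-benefit offer forfeits
#' that benefit (the advantage drops by `delta_uc`). Clocks follow
#' `clock_after = clock_before - t + I`; a mover whose clock would reach 0
#' flags and loses (the flagging move is not emitted, as it never completes).
#' Games surviving to `max_ply` are scored by final advantage against a
#' symmetric draw band.
#'
#' @param config A [sim_config()].
#' @return A list of class `voc_sim` with `records` (a move table; one row
#'   per completed move), `truth` (aligned per-move ground truth: true
#'   benefit, offer, policy threshold, acceptance, deliberation and spent
#'   time), `games` (per game: winner 1/2/0-for-draw, end ply, flag
#'   indicator) and `config`.
#' @export
generate_dataset <- function(config = sim_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_games
  k <- config$consideration_size
  tc <- config$time_control
  policy <- sim_policy(config)
  noise_sdlog <- sqrt(log(1 + config$movetime_noise_cv^2))

  elo <- matrix(rnorm(2 * n, config$elo_mean, config$elo_sd), n, 2)
  speed <- matrix(rlnorm(2 * n, 0, config$player_speed_sd), n, 2)
  clocks <- matrix(tc$start_seconds, n, 2)
  u_white <- runif(n, 0.35, 0.65)
  alive <- rep(TRUE, n)
  winner <- rep(NA_integer_, n)
  end_ply <- rep(config$max_ply, n)
  flagged <- rep(FALSE, n)

  rec_chunks <- vector("list", config$max_ply)
  truth_chunks <- vector("list", config$max_ply)

  for (p in seq_len(config$max_ply)) {
    idx <- which(alive)
    if (length(idx) == 0) break
    m <- length(idx)
    mover <- if (p %% 2 == 1) 1L else 2L
    opp <- 3L - mover
    u_active <- if (mover == 1L) u_white[idx] else 1 - u_white[idx]

    # consideration sets anchored on the current advantage
    deep <- cbind(u_active,
                  matrix(pmax(0, u_active - matrix(
                    rexp(m * (k - 1), rate = 1 / config$gap_mean),
                    m, k - 1)), m, k - 1))
    eps <- matrix(runif(m * k, 0.5, 1.5), m, k)
    shallow <- clamp01(deep + matrix(rnorm(m * k), m, k) *
                         config$shallow_noise_sd * eps)
    ord <- t(apply(shallow, 1, order, decreasing = TRUE))
    rows <- seq_len(m)
    i_shallow <- max.col(shallow, ties.method = "first")
    duc <- u_active - deep[cbind(rows, i_shallow)]

    t_before <- clocks[cbind(idx, rep(mover, m))]
    dtmax <- policy_delta_t_max(policy, t_before, u_active, duc)
    offer_mult <- rlnorm(m, 0, config$offer_spread)
    delta_tc <- ifelse(dtmax > 0, dtmax * offer_mult,
                       rlnorm(m, log(2), config$offer_spread))
    accept <- dtmax > 0 & delta_tc <= dtmax
    noise <- if (config$movetime_noise_cv > 0) {
      rlnorm(m, -noise_sdlog^2 / 2, noise_sdlog)
    } else {
      rep(1, m)
    }
    think <- ifelse(accept, delta_tc * noise, 0) *
      speed[cbind(idx, rep(mover, m))]
    t_spent <- config$motor_time + think

    flags <- t_before - t_spent <= 0
    t_after <- t_before - t_spent + tc$increment_seconds

    # flagging games end here; their move is never completed or recorded
    fi <- idx[flags]
    if (length(fi) > 0) {
      alive[fi] <- FALSE
      winner[fi] <- opp
      end_ply[fi] <- p
      flagged[fi] <- TRUE
    }
    live <- !flags
    if (any(live)) {
      li <- idx[live]
      clocks[cbind(li, rep(mover, sum(live)))] <- t_after[live]
      ord_l <- ord[live, , drop = FALSE]
      lr <- seq_len(sum(live))
      sh_ord <- matrix(shallow[live, , drop = FALSE][
        cbind(rep(lr, k), as.vector(ord_l))], ncol = k)
      dp_ord <- matrix(deep[live, , drop = FALSE][
        cbind(rep(lr, k), as.vector(ord_l))], ncol = k)
      chunk <- tibble::tibble(
        game_id = sprintf("g%05d", li),
        ply = p,
        elo = elo[cbind(li, rep(mover, sum(live)))],
        opp_clock = clocks[cbind(li, rep(opp, sum(live)))],
        clock_before = t_before[live],
        clock_after = t_after[live],
        tc_start = tc$start_seconds,
        tc_inc = tc$increment_seconds,
        outcome = NA_character_
      )
      for (j in seq_len(k)) {
        chunk[[paste0("move_id_", j)]] <- paste0("m", ord_l[, j])
      }
      for (j in seq_len(k)) chunk[[paste0("shallow_", j)]] <- sh_ord[, j]
      for (j in seq_len(k)) chunk[[paste0("deep_", j)]] <- dp_ord[, j]
      chunk$observed_move_id <- ifelse(accept[live], "m1",
                                       paste0("m", i_shallow[live]))
      rec_chunks[[p]] <- chunk
      truth_chunks[[p]] <- tibble::tibble(
        game_id = sprintf("g%05d", li),
        ply = p,
        delta_uc_true = duc[live],
        delta_tc_offer = delta_tc[live],
        delta_t_max = dtmax[live],
        accepted = accept[live],
        think_time = think[live],
        t_spent = t_spent[live]
      )
      # declined positive-benefit offers forfeit the benefit
      u_active_new <- u_active[live] - ifelse(accept[live], 0, duc[live])
      u_w <- if (mover == 1L) u_active_new else 1 - u_active_new
      u_white[li] <- reflect01(
        u_w + rnorm(sum(live), 0, config$advantage_step_sd))
    }
  }

  # games surviving to max_ply: score by final advantage
  left <- which(alive)
  if (length(left) > 0) {
    winner[left] <- ifelse(
      u_white[left] > 0.5 + config$draw_threshold, 1L,
      ifelse(u_white[left] < 0.5 - config$draw_threshold, 2L, 0L))
  }

  records <- dplyr::bind_rows(rec_chunks)
  truth <- dplyr::bind_rows(truth_chunks)
  if (nrow(records) > 0) {
    gi <- as.integer(sub("^g", "", records$game_id))
    mover <- ifelse(records$ply %% 2 == 1, 1L, 2L)
    w <- winner[gi]
    records$outcome <- ifelse(w == 0L, "draw",
                              ifelse(w == mover, "win", "loss"))
    ordu <- order(records$game_id, records$ply)
    records <- records[ordu, ]
    truth <- truth[order(truth$game_id, truth$ply), ]
  } else {
    records <- empty_move_table(k)
  }
  games <- tibble::tibble(
    game_id = sprintf("g%05d", seq_len(n)),
    winner = winner, end_ply = end_ply, flagged = flagged,
    final_u_white = u_white
  )
  voc_log("generate_dataset",
          sprintf("%d games, %d move records, %d flagged", n,
                  nrow(records), sum(flagged)))
  structure(list(records = records, truth = truth, games = games,
                 config = config),
            class = "voc_sim")
}

#' @export
print.voc_sim <- function(x, ...) {
  cat(sprintf(
    "<voc_sim> %d games (%s), %d move records, %d flagged, policy %s\n",
    x$config$n_games, x$config$time_control$label, nrow(x$records),
    sum(x$games$flagged), x$config$policy_family))
  invisible(x)
}

#' Labelled fixture consideration sets
#'
#' Three hand-built positions exercising the score definitions:
#' \describe{
#'   \item{agreeing_argmax}{deep and shallow prefer the same move, so the
#'     true benefit is 0, but the beliefs overlap, so the expected benefit is
#'     strictly positive.}
#'   \item{disagreeing_argmax}{the deep search flips the preference; the true
#'     benefit is large.}
#'   \item{degenerate}{shallow equals deep for every move; both scores are
#'     exactly 0.}
#' }
#'
#' @return A named list of [consideration_set()] objects.
#' @export
make_fixture_positions <- function() {
  list(
    agreeing_argmax = consideration_set(
      shallow = c(0.55, 0.50, 0.45, 0.40),
      deep = c(0.60, 0.58, 0.30, 0.35)),
    disagreeing_argmax = consideration_set(
      shallow = c(0.60, 0.50),
      deep = c(0.40, 0.70)),
    degenerate = consideration_set(
      shallow = c(0.60, 0.40, 0.20),
      deep = c(0.60, 0.40, 0.20))
  )
}
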