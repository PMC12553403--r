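#' Empirical value grid constructor
#'
#' Low-level constructor for the binned empirical value function `V(T, U)`:
#' the probability that the active player goes on to win, given `T` seconds
#' remaining and position advantage `U`, estimated as the win proportion
#' (draws counting one half) in half-open bins `[lo, hi)` over both axes.
#' Cells with fewer than `min_count` moves are inestimable (`NA`). Usually
#' built from data with [build_value_grid()].
#'
#' @param wins,totals Numeric matrices (time bins x utility bins),
#'   `wins <= totals` cellwise.
#' @param time_control A [time_control()].
#' @param time_bin_seconds,utility_bin_width Bin widths; left edges at 0.
#' @param min_count Estimability threshold.
#' @return An object of class `value_grid`.
#' @export
value_grid <- function(wins, totals, time_control, time_bin_seconds = 3,
                       utility_bin_width = 0.03, min_count = 50) {
  stopifnot(is.matrix(wins), is.matrix(totals),
            all(dim(wins) == dim(totals)))
  if (any(wins > totals + 1e-9)) {
    stop("`wins` must not exceed `totals` in any cell", call. = FALSE)
  }
  structure(
    list(wins = wins, totals = totals, time_control = time_control,
         time_bin_seconds = time_bin_seconds,
         utility_bin_width = utility_bin_width,
         min_count = as.integer(min_count)),
    class = "value_grid"
  )
}

#' @export
print.value_grid <- function(x, ...) {
  est <- sum(x$totals >= x$min_count)
  cat(sprintf(
    "<value_grid> %s: %d x %d cells (%g s x %g utility), %d estimable, %s moves\n",
    x$time_control$label, nrow(x$wins), ncol(x$wins), x$time_bin_seconds,
    x$utility_bin_width, est, format(sum(x$totals))))
  invisible(x)
}

# Half-open [lo, hi) bin index with left edge at 0.
bin_index <- function(x, width) pmax(1L, floor(x / width) + 1L)

#' Estimate the empirical value function from scored records
#'
#' Bins moves of one time control by time remaining (`clock_before`, 3 s bins
#' by default) and position advantage `u` (0.03 utility bins), and computes
#' the proportion won by the active player per cell (draws count 0.5). To
#' isolate the effect of the player's own clock, only moves where the
#' opponent had at least 60 s remaining (30 s for the 60+0 control) are used,
#' and only moves inside the configured ply window. The advantage is the
#' computation-free advantage attached by [score_moves()] (column `u`).
#'
#' @param records A scored move table (needs columns `u`, `outcome`,
#'   `clock_before`, `opp_clock`, `ply`, `tc_start`, `tc_inc`).
#' @param time_control A [time_control()]; only matching records are used.
#' @param config A [run_config()] (bin widths, ply window, opponent-clock
#'   floor, `min_count`).
#' @return A [value_grid()].
#' @export
build_value_grid <- function(records, time_control, config = run_config()) {
  stopifnot("u" %in% names(records))
  floor_s <- opponent_clock_floor(config, time_control$label)
  keep <- records$tc_start == time_control$start_seconds &
    records$tc_inc == time_control$increment_seconds &
    records$opp_clock >= floor_s &
    records$ply >= config$ply_min & records$ply <= config$ply_max
  rec <- records[keep, , drop = FALSE]
  if (nrow(rec) == 0) {
    stop(sprintf(paste0(
      "no records survive the value-grid filters (time control %s, ",
      "opponent clock >= %g s, ply %d-%d)"), time_control$label, floor_s,
      config$ply_min, config$ply_max), call. = FALSE)
  }
  tw <- config$time_bin_seconds
  uw <- config$utility_bin_width
  n_t <- max(bin_index(rec$clock_before, tw))
  n_u <- max(bin_index(rec$u, uw), bin_index(1 - 1e-9, uw))
  ti <- pmin(bin_index(rec$clock_before, tw), n_t)
  ui <- pmin(bin_index(rec$u, uw), n_u)
  w <- ifelse(rec$outcome == "win", 1, ifelse(rec$outcome == "draw", 0.5, 0))
  idx <- (ui - 1L) * n_t + ti
  totals <- matrix(tabulate(idx, nbins = n_t * n_u), n_t, n_u)
  wins <- matrix(0, n_t, n_u)
  acc <- rowsum(w, idx)
  wins[as.integer(rownames(acc))] <- acc[, 1]
  voc_log("build_value_grid",
          sprintf("%s: %d moves into %d x %d cells", time_control$label,
                  nrow(rec), n_t, n_u))
  value_grid(wins, totals, time_control, tw, uw, config$min_count)
}

#' Build a value grid from an analytic law
#'
#' Fills every cell from a known function `V*(T, U)` evaluated at bin
#' midpoints, with a constant per-cell count, so that grid arithmetic can be
#' checked against closed forms and policies can be derived from smooth
#' synthetic laws.
#'
#' @param f A function of `(T, U)` returning values in \[0, 1\].
#' @param t_max Top of the time axis, seconds.
#' @param time_control A [time_control()].
#' @param n_per_cell Count assigned to every cell (default 1000).
#' @param time_bin_seconds,utility_bin_width,min_count As in [value_grid()].
#' @return A [value_grid()].
#' @export
value_grid_from_function <- function(f, t_max, time_control,
                                     n_per_cell = 1000,
                                     time_bin_seconds = 3,
                                     utility_bin_width = 0.03,
                                     min_count = 50) {
  t_mids <- seq(time_bin_seconds / 2, t_max, by = time_bin_seconds)
  u_mids <- seq(utility_bin_width / 2, 1, by = utility_bin_width)
  v <- outer(t_mids, u_mids, f)
  if (any(v < -1e-12 | v > 1 + 1e-12)) {
    stop("`f` must return values in [0, 1]", call. = FALSE)
  }
  v <- clamp01(v)
  totals <- matrix(n_per_cell, length(t_mids), length(u_mids))
  value_grid(v * n_per_cell, totals, time_control, time_bin_seconds,
             utility_bin_width, min_count)
}

# Cell lookup. Inestimable cells either error (strict) or fall back to the
# nearest estimable cell along the T axis within the same utility row,
# preserving the U-conditioning that drives the stopping inequality; a row
# with no estimable cell at all (utilities saturate near 0 and 1, where data
# thin out) falls back to the nearest non-empty row first. U above the top
# edge clamps to the top bin.
grid_value <- function(grid, t, u, strict = FALSE) {
  n_t <- nrow(grid$wins)
  n_u <- ncol(grid$wins)
  ti <- min(max(bin_index(t, grid$time_bin_seconds), 1L), n_t)
  ui <- min(max(bin_index(u, grid$utility_bin_width), 1L), n_u)
  est <- grid$totals >= grid$min_count
  if (est[ti, ui]) return(grid$wins[ti, ui] / grid$totals[ti, ui])
  if (strict) {
    stop(sprintf("value-grid cell (T bin %d, U bin %d) is inestimable ",
                 ti, ui),
         sprintf("(%d < %d moves)", grid$totals[ti, ui], grid$min_count),
         call. = FALSE)
  }
  if (!any(est[, ui])) {
    rows <- which(colSums(est) > 0)
    if (length(rows) == 0) {
      stop("the value grid has no estimable cell", call. = FALSE)
    }
    ui <- rows[which.min(abs(rows - ui))]
  }
  cand <- which(est[, ui])
  tj <- cand[which.min(abs(cand - ti))]
  grid$wins[tj, ui] / grid$totals[tj, ui]
}

#' Time cost of deliberation from the value grid
#'
#' The cost of spending `delta_t` seconds, in utility, is the drop in the
#' empirical value function as the clock is decremented:
#' `c(delta_t) = V(T, U) - V(T - delta_t, U)`.
#'
#' @param grid A [value_grid()].
#' @param t Time remaining, seconds.
#' @param u Position advantage.
#' @param delta_t Time spent, seconds.
#' @param strict Error on inestimable cells (default `TRUE`); otherwise fall
#'   back to the nearest estimable cell in the same utility row.
#' @return A utility cost (0 when both times fall in the same bin).
#' @export
time_cost <- function(grid, t, u, delta_t, strict = TRUE) {
  grid_value(grid, t, u, strict = strict) -
    grid_value(grid, t - delta_t, u, strict = strict)
}

#' Longest worthwhile deliberation from the empirical value grid
#'
#' Scans `delta_t` over time-bin multiples from 0 up to `t` and returns the
#' largest one for which computation is still worthwhile:
#' `V(t - delta_t, u + delta_uc) >= V(t, u)`. Returns 0 when no positive
#' expenditure qualifies. `u + delta_uc` above the top utility edge clamps to
#' the top bin. By default the largest satisfying multiple is returned even
#' if the satisfying set is broken up by sampling noise; `contiguous = TRUE`
#' stops at the first failure instead.
#'
#' @param grid A [value_grid()].
#' @param t Time remaining, seconds.
#' @param u Current position advantage.
#' @param delta_uc Offered utility benefit of computation.
#' @param strict Error on inestimable cells instead of falling back.
#' @param contiguous Require an unbroken run of satisfying `delta_t`.
#' @return The largest worthwhile expenditure, seconds.
#' @export
delta_t_max_empirical <- function(grid, t, u, delta_uc, strict = FALSE,
                                  contiguous = FALSE) {
  v0 <- grid_value(grid, t, u, strict = strict)
  u2 <- min(u + delta_uc, ncol(grid$wins) * grid$utility_bin_width - 1e-9)
  steps <- seq(0, t, by = grid$time_bin_seconds)
  ok <- vapply(steps, function(dt) {
    grid_value(grid, t - dt, u2, strict = strict) >= v0
  }, logical(1))
  if (!any(ok)) return(0)
  if (contiguous) {
    run <- which(!ok)
    last <- if (length(run) == 0) length(ok) else min(run) - 1L
    if (last < 1) return(0)
    return(steps[last])
  }
  steps[max(which(ok))]
}

## ---- Analytic cost families ----------------------------------------------

#' Analytic time-cost families
#'
#' Parametric cost structures for spending `delta_t` seconds of clock time:
#' `linear` (`c = rho * delta_t`, constant opportunity cost per second),
#' `power` (`c = a * delta_t^b`, `a > 0`, `b > 1`, accelerating cost), and
#' `power_timeleft` (`c = a * (delta_t / T)^b`, accelerating cost of the
#' *fraction* of remaining time spent).
#'
#' @param family One of `"linear"`, `"power"`, `"power_timeleft"`.
#' @param rho Opportunity cost, utility per second (linear family).
#' @param a Cost scale, utility (power families).
#' @param b Cost exponent, dimensionless > 1 (power families).
#' @return An object of class `cost_family`.
#' @examples
#' cost_family("power", a = 1, b = 2)
#' @export
cost_family <- function(family = c("linear", "power", "power_timeleft"),
                        rho = NULL, a = NULL, b = NULL) {
  family <- match.arg(family)
  if (family == "linear") {
    if (is.null(rho) || rho <= 0) {
      stop("`rho` must be positive for the linear family", call. = FALSE)
    }
  } else {
    if (is.null(a) || a <= 0) stop("`a` must be positive", call. = FALSE)
    if (is.null(b) || b <= 1) stop("`b` must exceed 1", call. = FALSE)
  }
  structure(list(family = family, rho = rho, a = a, b = b),
            class = "cost_family")
}

#' @export
print.cost_family <- function(x, ...) {
  desc <- switch(x$family,
                 linear = sprintf("c(dT) = %g * dT", x$rho),
                 power = sprintf("c(dT) = %g * dT^%g", x$a, x$b),
                 power_timeleft = sprintf("c(dT) = %g * (dT/T)^%g", x$a, x$b))
  cat("<cost_family>", desc, "\n")
  invisible(x)
}

#' Longest worthwhile deliberation under an analytic cost family
#'
#' Solves `c(delta_t) = delta_uc` for each family: `delta_uc / rho` (linear),
#' `(delta_uc / a)^(1/b)` (power) and `T * (delta_uc / a)^(1/b)`
#' (power-of-time-left; exactly homogeneous of degree 1 in `T`). Vectorized
#' over `delta_uc` and `t`.
#'
#' @param family A [cost_family()].
#' @param t Time remaining, seconds (required for `power_timeleft`).
#' @param delta_uc Offered benefit(s), utility.
#' @return Maximum worthwhile expenditure(s), seconds.
#' @examples
#' delta_t_max_analytic(cost_family("linear", rho = 0.01), delta_uc = 0.1)
#' @export
delta_t_max_analytic <- function(family, t = NULL, delta_uc) {
  stopifnot(inherits(family, "cost_family"))
  switch(family$family,
         linear = delta_uc / family$rho,
         power = (delta_uc / family$a)^(1 / family$b),
         power_timeleft = {
           if (is.null(t)) {
             stop("`t` is required for the power_timeleft family",
                  call. = FALSE)
           }
           t * (delta_uc / family$a)^(1 / family$b)
         })
}

# Policy dispatch shared by the simulator and the marginalization below.
policy_delta_t_max <- function(policy, t, u, delta_uc, ...) {
  if (inherits(policy, "cost_family")) {
    delta_t_max_analytic(policy, t = t, delta_uc = delta_uc)
  } else if (inherits(policy, "value_grid")) {
    mapply(function(ti, ui, di) {
      delta_t_max_empirical(policy, ti, ui, di, ...)
    }, t, u, delta_uc)
  } else {
    stop("`policy` must be a cost_family or a value_grid", call. = FALSE)
  }
}

#' Mean move times implied by a stopping policy
#'
#' Marginalizes a deliberation policy over a distribution of starting states
#' and computation offers: for each offer the policy spends
#' `motor_time + delta_tc` if `delta_tc <= delta_t_max(T, U, delta_uc)` and
#' `motor_time` otherwise, and allocations are averaged within benefit bins.
#' This is the summary that connects a measured cost structure back to the
#' observable move-time-versus-benefit curve.
#'
#' @param policy A [cost_family()] or [value_grid()].
#' @param offers A data frame with columns `t_left` (s), `u` (utility),
#'   `delta_tc` (offered computation time, s) and `delta_uc` (offered
#'   benefit, utility), e.g. [generate_offer()] draws paired with observed
#'   states.
#' @param config A [run_config()]; supplies the benefit bin width and
#'   `motor_time` (default 0: declined offers contribute no time).
#' @return A tibble with one row per benefit bin: `time_control` label (or
#'   `NA` for analytic policies), `delta_uc_bin` (left edge), `mean_time`,
#'   `n`.
#' @export
implied_mean_move_times <- function(policy, offers, config = run_config()) {
  stopifnot(all(c("t_left", "u", "delta_tc", "delta_uc") %in% names(offers)),
            nrow(offers) > 0)
  dtmax <- policy_delta_t_max(policy, offers$t_left, offers$u,
                              offers$delta_uc)
  alloc <- config$motor_time +
    ifelse(offers$delta_tc <= dtmax, offers$delta_tc, 0)
  uw <- config$utility_bin_width
  label <- if (inherits(policy, "value_grid")) {
    policy$time_control$label
  } else {
    NA_character_
  }
  tibble::tibble(
    delta_uc_bin = floor(offers$delta_uc / uw) * uw,
    alloc = alloc
  ) |>
    dplyr::group_by(.data$delta_uc_bin) |>
    dplyr::summarise(mean_time = mean(.data$alloc), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(time_control = label, .before = 1) |>
    dplyr::arrange(.data$delta_uc_bin)
}
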