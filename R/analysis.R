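#' Move time from successive clock readings
#'
#' Under the default `post_increment` convention recorded clocks obey the
#' recurrence `clock_after = clock_before - t + I`, so
#' `t = (clock_before - clock_after) + I`. The `subtract_increment` convention
#' instead subtracts the increment from the raw clock difference,
#' `t = (clock_before - clock_after) - I`, for exports that record clocks
#' before the increment is credited. Either way the result is clamped at 0
#' (clamps are logged).
#'
#' @param clock_before,clock_after Clock readings, seconds (vectorized).
#' @param increment Time-control increment, seconds.
#' @param convention `"post_increment"` (default) or `"subtract_increment"`.
#' @return Move times in seconds, >= 0.
#' @examples
#' compute_move_time(60, 57, 2) # 5 s
#' @export
compute_move_time <- function(clock_before, clock_after, increment = 0,
                              convention = c("post_increment",
                                             "subtract_increment")) {
  convention <- match.arg(convention)
  raw <- clock_before - clock_after
  t <- if (convention == "post_increment") raw + increment else raw - increment
  n_clamped <- sum(t < 0)
  if (n_clamped > 0) {
    voc_log("compute_move_time",
            sprintf("clamped %d negative move time(s) to 0", n_clamped))
  }
  pmax(t, 0)
}

#' Restrict records to the analysis ply window
#'
#' Keeps moves with `ply_min <= ply <= ply_max` (inclusive; defaults 15-75),
#' excluding preplanned openings and long endgames.
#'
#' @param records A move table.
#' @param ply_min,ply_max Inclusive bounds.
#' @return The filtered table.
#' @export
filter_ply_window <- function(records, ply_min = 15, ply_max = 75) {
  records[records$ply >= ply_min & records$ply <= ply_max, , drop = FALSE]
}

#' Move-time regression
#'
#' Ordinary least squares (QR decomposition via [stats::lm()]) predicting
#' move times from a benefit-of-computation column (optionally
#' square-root-transformed, the concave specification), centered Elo, and
#' their interaction. With `per_time_control = TRUE` every term (including
#' the intercept) is estimated separately per time-control setting; with
#' `pooled_time_control = TRUE` the time-control structure instead enters
#' through starting time and increment and their interactions with the
#' benefit.
#'
#' @param records A scored move table (needs `move_time`, the benefit column,
#'   `elo`, and `tc_start`/`tc_inc` for the time-control modes).
#' @param benefit_column `"delta_uc"` or `"e_delta_uc"`.
#' @param transform `"sqrt"` (default, the concave model) or `"identity"`.
#' @param per_time_control Separate coefficients per time-control setting.
#' @param pooled_time_control Pool settings; add `tc_start`, `tc_inc` and
#'   their benefit interactions as predictors.
#' @param elo_center Rating at which Elo is centered (default 1500).
#' @param include_elo,include_interaction Drop the Elo covariate and/or the
#'   benefit-by-Elo interaction (for reduced designs).
#' @param min_rows_per_term Required ratio of rows to coefficients
#'   (default 10).
#' @return An object of class `voc_regression`: a list with a `terms` tibble
#'   (term, estimate, std_error, t, p), `n`, `k`, `rss`, `sigma2` and `aic`
#'   (Gaussian convention `n * log(RSS / n) + 2k`, additive constants
#'   dropped; fixed across models so AIC differences are comparable).
#' @export
fit_movetime_regression <- function(records,
                                    benefit_column = c("delta_uc",
                                                       "e_delta_uc"),
                                    transform = c("sqrt", "identity"),
                                    per_time_control = FALSE,
                                    pooled_time_control = FALSE,
                                    elo_center = 1500,
                                    include_elo = TRUE,
                                    include_interaction = include_elo,
                                    min_rows_per_term = 10) {
  benefit_column <- match.arg(benefit_column)
  transform <- match.arg(transform)
  if (per_time_control && pooled_time_control) {
    stop("`per_time_control` and `pooled_time_control` are exclusive",
         call. = FALSE)
  }
  stopifnot(all(c("move_time", benefit_column) %in% names(records)))
  df <- data.frame(
    move_time = records$move_time,
    benefit = if (transform == "sqrt") sqrt(records[[benefit_column]])
              else records[[benefit_column]]
  )
  rhs <- "benefit"
  if (include_elo) {
    df$elo_c <- records$elo - elo_center
    rhs <- c(rhs, "elo_c")
    if (include_interaction) rhs <- c(rhs, "benefit:elo_c")
  }
  if (per_time_control) {
    df$tc <- factor(paste0(records$tc_start, "+", records$tc_inc))
    fml <- stats::as.formula(paste(
      "move_time ~ 0 + tc +",
      paste(paste0("tc:", rhs), collapse = " + ")))
  } else if (pooled_time_control) {
    df$tc_start <- records$tc_start
    df$tc_inc <- records$tc_inc
    fml <- stats::as.formula(paste(
      "move_time ~",
      paste(c(rhs, "tc_start", "tc_inc", "benefit:tc_start",
              "benefit:tc_inc"), collapse = " + ")))
  } else {
    fml <- stats::as.formula(paste("move_time ~",
                                   paste(rhs, collapse = " + ")))
  }
  mm <- stats::model.matrix(fml, df)
  if (nrow(df) < min_rows_per_term * ncol(mm)) {
    stop(sprintf(
      "need at least %d rows for %d terms (%d supplied)",
      min_rows_per_term * ncol(mm), ncol(mm), nrow(df)), call. = FALSE)
  }
  fit <- stats::lm(fml, data = df, singular.ok = TRUE)
  co <- coef(fit)
  if (anyNA(co)) {
    stop("design is rank deficient; collinear term(s): ",
         paste(names(co)[is.na(co)], collapse = ", "), call. = FALSE)
  }
  sm <- suppressWarnings(summary(fit)) # noiseless fixtures fit exactly
  n <- length(fit$residuals)
  k <- length(co)
  rss <- sum(fit$residuals^2)
  terms_tbl <- tibble::tibble(
    term = rownames(sm$coefficients),
    estimate = sm$coefficients[, 1],
    std_error = sm$coefficients[, 2],
    t = sm$coefficients[, 3],
    p = sm$coefficients[, 4]
  )
  structure(
    list(terms = terms_tbl, n = n, k = k, rss = rss,
         sigma2 = rss / n, aic = n * log(rss / n) + 2 * k,
         benefit_column = benefit_column, transform = transform,
         formula = fml),
    class = "voc_regression"
  )
}

#' @export
print.voc_regression <- function(x, ...) {
  cat(sprintf("<voc_regression> %s(%s), n = %d, AIC = %.2f\n",
              if (x$transform == "sqrt") "sqrt" else "", x$benefit_column,
              x$n, x$aic))
  print(as.data.frame(x$terms), digits = 4)
  invisible(x)
}

#' Compare two move-time regressions by AIC
#'
#' Both models must be fitted on identical row sets (checked via `n`);
#' `delta_aic = AIC(a) - AIC(b)` and the model with lower AIC is preferred.
#'
#' @param a,b `voc_regression` objects.
#' @return A list with `delta_aic` and `preferred` (`"a"` or `"b"`).
#' @export
aic_compare <- function(a, b) {
  stopifnot(inherits(a, "voc_regression"), inherits(b, "voc_regression"))
  if (a$n != b$n) {
    stop(sprintf("models were fitted on different row counts (%d vs %d)",
                 a$n, b$n), call. = FALSE)
  }
  delta <- a$aic - b$aic
  list(delta_aic = delta, preferred = if (delta <= 0) "a" else "b")
}

#' Per-player rank correlation of move time with benefit, by Elo bin
#'
#' Computes a Spearman correlation (average ranks for ties) between move
#' times and the benefit of computation separately for each player in each
#' game (players within a game are distinguished by ply parity), then
#' averages the correlations within Elo bins. Players contributing fewer
#' than 3 moves, or with a constant variable, are skipped; bins with fewer
#' than `min_games` correlations are dropped.
#'
#' @param records A scored move table.
#' @param elo_bin_width Bin width in rating points (default 100).
#' @param min_games Minimum (game, player) correlations per reported bin
#'   (default 200).
#' @param benefit_column Benefit column to correlate against.
#' @return A tibble with `elo_bin` (left edge), `mean_rho`, `n_games`.
#' @export
spearman_by_elo <- function(records, elo_bin_width = 100, min_games = 200,
                            benefit_column = "delta_uc") {
  stopifnot(all(c("move_time", benefit_column, "elo", "game_id", "ply")
                %in% names(records)))
  per_player <- records |>
    dplyr::mutate(player = .data$ply %% 2) |>
    dplyr::group_by(.data$game_id, .data$player) |>
    dplyr::summarise(
      rho = if (dplyr::n() >= 3 &&
                stats::sd(.data$move_time) > 0 &&
                stats::sd(.data[[benefit_column]]) > 0) {
        stats::cor(.data$move_time, .data[[benefit_column]],
                   method = "spearman")
      } else NA_real_,
      elo = .data$elo[1],
      .groups = "drop"
    ) |>
    dplyr::filter(!is.na(.data$rho))
  per_player |>
    dplyr::mutate(elo_bin = floor(.data$elo / elo_bin_width) *
                    elo_bin_width) |>
    dplyr::group_by(.data$elo_bin) |>
    dplyr::summarise(mean_rho = mean(.data$rho), n_games = dplyr::n(),
                     .groups = "drop") |>
    dplyr::filter(.data$n_games >= min_games) |>
    dplyr::arrange(.data$elo_bin)
}

#' Mean move time by benefit bin and time control
#'
#' The tabular analogue of the move-time-versus-benefit curves: mean move
#' time within each benefit bin (width `utility_bin_width`), separately per
#' time-control setting.
#'
#' @param records A scored move table.
#' @param benefit_column Benefit column to bin on.
#' @param config A [run_config()] (bin width).
#' @return A tibble with `time_control`, `benefit_bin` (left edge),
#'   `mean_move_time`, `n`.
#' @export
binned_movetime_curve <- function(records, benefit_column = "delta_uc",
                                  config = run_config()) {
  stopifnot(all(c("move_time", benefit_column) %in% names(records)))
  uw <- config$utility_bin_width
  records |>
    dplyr::mutate(
      time_control = paste0(.data$tc_start, "+", .data$tc_inc),
      benefit_bin = floor(.data[[benefit_column]] / uw) * uw
    ) |>
    dplyr::group_by(.data$time_control, .data$benefit_bin) |>
    dplyr::summarise(mean_move_time = mean(.data$move_time),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$time_control, .data$benefit_bin)
}

#' Recover the cost exponent from simulated move times
#'
#' Under a power-family stopping policy, accepted deliberations satisfy
#' `log(move_time - motor_time) = (1/b) log(delta_uc) + const + noise`, so an
#' OLS fit of log excess time on log benefit over accepted moves estimates
#' the reciprocal cost exponent `1/b`. Used for parameter-recovery checks
#' against the synthetic generator.
#'
#' @param records A scored move table from [generate_dataset()].
#' @param motor_time The generator's baseline move time, seconds.
#' @return A list with `slope` (the estimate of `1/b`), `se` and `n`.
#' @export
recover_cost_exponent <- function(records, motor_time) {
  excess <- records$move_time - motor_time
  keep <- excess > 1e-9 & records$delta_uc > 0
  if (sum(keep) < 100) {
    stop("too few accepted deliberations to recover the exponent",
         call. = FALSE)
  }
  fit <- stats::lm(log(excess[keep]) ~ log(records$delta_uc[keep]))
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]), se = sm$coefficients[2, 2],
       n = sum(keep))
}
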