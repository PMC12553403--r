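#' Elo expected score
#'
#' The expected score of a player against an opponent rated `delta_elo`
#' points lower: `1 / (1 + 10^(-delta_elo / 400))`. A player rated 100 points
#' above their opponent is expected to win 64% of the time (to two decimals).
#'
#' @param delta_elo Rating difference (player minus opponent), vectorized.
#' @return Expected score(s) in (0, 1).
#' @examples
#' round(elo_expected_score(100), 2) # 0.64
#' @export
elo_expected_score <- function(delta_elo) {
  1 / (1 + 10^(-delta_elo / 400))
}

#' Construct a utility map directly from coefficients
#'
#' A utility map converts raw engine-style evaluations — centipawns, or a
#' signed ply-distance to mate — to a time-agnostic win probability in (0, 1)
#' via one logistic model per channel. Normally produced by
#' [fit_utility_map()]; this constructor allows injecting known coefficients.
#'
#' @param cp_intercept,cp_slope Logistic coefficients on centipawns
#'   (`cp_slope > 0`), or `NULL` for an unfitted channel.
#' @param mate_intercept,mate_slope Coefficients on signed mate distance, or
#'   `NULL`.
#' @param n_fit Named integer vector of rows used per channel.
#' @param ridged Logical flags marking channels rescued by an L2 penalty.
#' @return An object of class `utility_map`.
#' @export
utility_map <- function(cp_intercept = NULL, cp_slope = NULL,
                        mate_intercept = NULL, mate_slope = NULL,
                        n_fit = c(centipawn = NA_integer_,
                                  mate = NA_integer_),
                        ridged = c(centipawn = FALSE, mate = FALSE)) {
  if (!is.null(cp_slope) && cp_slope <= 0) {
    stop("`cp_slope` must be positive (more centipawns, higher win ",
         "probability)", call. = FALSE)
  }
  structure(
    list(cp = if (!is.null(cp_intercept))
           c(intercept = cp_intercept, slope = cp_slope),
         mate = if (!is.null(mate_intercept))
           c(intercept = mate_intercept, slope = mate_slope),
         n_fit = n_fit, ridged = ridged),
    class = "utility_map"
  )
}

#' Fit the evaluation-to-win-probability utility map
#'
#' Fits, by maximum likelihood (IRLS via [stats::glm()]), one logistic
#' regression per evaluation channel: win indicator on centipawn advantage,
#' and win indicator on signed ply-distance to mate. The resulting map places
#' both channels on a common \[0, 1\] win-probability ("utility") scale.
#'
#' Rows are filtered before fitting, mirroring the calibration conditions the
#' map is meant for: only games that ended in checkmate (so outcomes are
#' decisive; draws are excluded), only moves where both players had more than
#' `min_clock` seconds remaining, and only the listed time controls. Each
#' filter is applied only when the corresponding column is present
#' (`ended_in_mate`, `clock_before`/`opp_clock`, `tc`).
#'
#' @param pairs A data frame with columns `kind` (`"centipawn"` or `"mate"`),
#'   `value` (signed evaluation from the active player's perspective) and
#'   `outcome` (`"win"`/`"loss"` or 1/0); optional filter columns as above.
#' @param min_clock Clock floor in seconds (default 60).
#' @param time_controls Time-control labels kept when a `tc` column exists
#'   (default `c("300+0", "600+0")`).
#' @param checkmate_only Keep only `ended_in_mate` rows when that column
#'   exists (default `TRUE`).
#' @param min_n Minimum rows per channel to attempt a fit (default 100);
#'   channels with fewer rows are left unfitted with a warning.
#' @param ridge Rescue separated channels with an L2 penalty instead of
#'   erroring (default `FALSE`); rescued channels are flagged in the output.
#' @param ridge_lambda Penalty strength when `ridge = TRUE`.
#' @return A `utility_map` with per-channel coefficients, fit sizes, ridge
#'   flags and a channel-seam diagnostic (win probability at a +/-1000 cp
#'   evaluation versus at a mate-in-30, where both channels exist).
#' @export
fit_utility_map <- function(pairs, min_clock = 60,
                            time_controls = c("300+0", "600+0"),
                            checkmate_only = TRUE, min_n = 100,
                            ridge = FALSE, ridge_lambda = 1e-3) {
  stopifnot(all(c("kind", "value", "outcome") %in% names(pairs)))
  if (checkmate_only && "ended_in_mate" %in% names(pairs)) {
    pairs <- pairs[as.logical(pairs$ended_in_mate), , drop = FALSE]
  }
  if (all(c("clock_before", "opp_clock") %in% names(pairs))) {
    pairs <- pairs[pairs$clock_before > min_clock &
                     pairs$opp_clock > min_clock, , drop = FALSE]
  }
  if ("tc" %in% names(pairs)) {
    pairs <- pairs[pairs$tc %in% time_controls, , drop = FALSE]
  }
  y <- outcome_to_binary(pairs$outcome)
  keep <- !is.na(y)
  n_draw <- sum(!keep)
  if (n_draw > 0) {
    voc_log("fit_utility_map", sprintf("excluding %d drawn rows", n_draw))
  }
  pairs <- pairs[keep, , drop = FALSE]
  y <- y[keep]
  fit_channel <- function(kind) {
    sel <- pairs$kind == kind
    n <- sum(sel)
    if (n == 0) return(NULL)
    if (n < min_n) {
      warning(sprintf("channel '%s' has %d rows (< %d); left unfitted",
                      kind, n, min_n), call. = FALSE)
      return(NULL)
    }
    v <- pairs$value[sel]
    yy <- y[sel]
    if (length(unique(yy)) < 2) {
      stop(sprintf(paste0("perfect separation in channel '%s' (all outcomes",
                          " identical); consider ridge = TRUE"), kind),
           call. = FALSE)
    }
    separated <- FALSE
    fit <- withCallingHandlers(
      stats::glm(yy ~ v, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w)) ||
            grepl("did not converge", conditionMessage(w))) {
          separated <<- TRUE
          invokeRestart("muffleWarning")
        }
      }
    )
    if (separated || !fit$converged) {
      if (!ridge) {
        stop(sprintf("separation detected in channel '%s'; consider ridge = TRUE",
                     kind), call. = FALSE)
      }
      co <- ridge_logistic(v, yy, lambda = ridge_lambda)
      return(list(coef = co, n = n, ridged = TRUE))
    }
    list(coef = unname(coef(fit)), n = n, ridged = FALSE)
  }
  cp <- fit_channel("centipawn")
  mate <- fit_channel("mate")
  out <- utility_map(
    cp_intercept = if (!is.null(cp)) cp$coef[1],
    cp_slope = if (!is.null(cp)) cp$coef[2],
    mate_intercept = if (!is.null(mate)) mate$coef[1],
    mate_slope = if (!is.null(mate)) mate$coef[2],
    n_fit = c(centipawn = if (is.null(cp)) NA_integer_ else cp$n,
              mate = if (is.null(mate)) NA_integer_ else mate$n),
    ridged = c(centipawn = !is.null(cp) && cp$ridged,
               mate = !is.null(mate) && mate$ridged)
  )
  out$seam <- seam_diagnostic(out)
  out
}

# win = 1, loss = 0, draw (or anything else) = NA.
outcome_to_binary <- function(outcome) {
  if (is.numeric(outcome)) {
    ifelse(outcome %in% c(0, 1), outcome, NA_real_)
  } else {
    ifelse(outcome == "win", 1, ifelse(outcome == "loss", 0, NA_real_))
  }
}

# Minimal L2-penalized logistic regression (Newton iterations) used solely as
# a separation rescue; intercept unpenalized.
ridge_logistic <- function(x, y, lambda, max_iter = 100, tol = 1e-10) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  pen <- diag(c(0, lambda))
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    grad <- drop(crossprod(X, y - p)) - pen %*% beta
    hess <- crossprod(X * w, X) + pen
    step <- solve(hess, grad)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  unname(beta)
}

# Win probability gap where the two channels meet: a +/-1000 cp evaluation
# against a mate-in-30, both for and against the active player.
seam_diagnostic <- function(map) {
  if (is.null(map$cp) || is.null(map$mate)) return(NULL)
  cp_hi <- plogis(map$cp["intercept"] + map$cp["slope"] * 1000)
  cp_lo <- plogis(map$cp["intercept"] + map$cp["slope"] * -1000)
  mate_hi <- plogis(map$mate["intercept"] + map$mate["slope"] * 30)
  mate_lo <- plogis(map$mate["intercept"] + map$mate["slope"] * -30)
  c(winning_side = unname(mate_hi - cp_hi),
    losing_side = unname(mate_lo - cp_lo))
}

#' @export
print.utility_map <- function(x, ...) {
  cat("<utility_map>\n")
  for (ch in c("cp", "mate")) {
    nm <- if (ch == "cp") "centipawn" else "mate"
    if (is.null(x[[ch]])) {
      cat(sprintf("  %-9s unfitted\n", nm))
    } else {
      cat(sprintf("  %-9s intercept %.6g  slope %.6g  (n = %s%s)\n", nm,
                  x[[ch]]["intercept"], x[[ch]]["slope"],
                  format(x$n_fit[[nm]]),
                  if (isTRUE(x$ridged[[nm]])) ", ridged" else ""))
    }
  }
  if (!is.null(x$seam)) {
    cat(sprintf("  seam: winning side %+.4f, losing side %+.4f\n",
                x$seam["winning_side"], x$seam["losing_side"]))
  }
  invisible(x)
}

#' Map an engine evaluation to win probability
#'
#' Applies the fitted logistic for the evaluation's channel:
#' `plogis(intercept + slope * value)`. Strictly increasing in centipawn
#' value; output always in (0, 1). Using an unfitted channel is an error.
#'
#' @param map A `utility_map`.
#' @param kind `"centipawn"` or `"mate"` (recycled against `value`).
#' @param value Signed evaluation(s) from the active player's perspective.
#' @return Win probabilities in (0, 1).
#' @export
to_win_prob <- function(map, kind, value) {
  stopifnot(inherits(map, "utility_map"))
  kind <- rep_len(kind, length(value))
  if (!all(kind %in% c("centipawn", "mate"))) {
    stop("`kind` must be 'centipawn' or 'mate'", call. = FALSE)
  }
  out <- numeric(length(value))
  for (ch in unique(kind)) {
    co <- if (ch == "centipawn") map$cp else map$mate
    if (is.null(co)) {
      stop(sprintf("channel '%s' is unfitted in this utility map", ch),
           call. = FALSE)
    }
    sel <- kind == ch
    out[sel] <- plogis(co["intercept"] + co["slope"] * value[sel])
  }
  out
}
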