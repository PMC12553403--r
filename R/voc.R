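#' Consideration sets
#'
#' A consideration set is the small ordered list of candidate moves over which
#' the benefit of computation is scored. Each move carries a *shallow* utility
#' (the advantage estimate available without search, `U[-C]`) and a *deep*
#' utility (the post-search estimate `U[C]`, treated as ground truth), both on
#' the win-probability scale in \[0, 1\]. Set order is meaningful: ties are
#' broken by position, and tables ingested by the package order moves by
#' descending shallow value.
#'
#' @param shallow,deep Numeric vectors of equal length in \[0, 1\].
#' @param move_id Optional character ids (default `"m1"`, `"m2"`, ...).
#' @return An object of class `consideration_set` (a data frame with columns
#'   `move_id`, `shallow`, `deep`).
#' @examples
#' cs <- consideration_set(shallow = c(0.6, 0.5), deep = c(0.40, 0.70))
#' benefit_of_computation(cs)
#' @export
consideration_set <- function(shallow, deep, move_id = NULL) {
  if (length(shallow) != length(deep) || length(shallow) < 1) {
    stop("`shallow` and `deep` must have equal length >= 1", call. = FALSE)
  }
  if (any(shallow < 0 | shallow > 1) || any(deep < 0 | deep > 1)) {
    stop("utilities must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(move_id)) move_id <- paste0("m", seq_along(shallow))
  if (anyDuplicated(move_id)) stop("move ids must be unique", call. = FALSE)
  structure(
    data.frame(move_id = as.character(move_id), shallow = as.numeric(shallow),
               deep = as.numeric(deep), stringsAsFactors = FALSE),
    class = c("consideration_set", "data.frame")
  )
}

#' The move preferred without computation
#'
#' Returns the id of `m[-C]`, the move maximizing the shallow utility; ties
#' are broken by set order (first listed wins).
#'
#' @param cset A [consideration_set()].
#' @return A move id.
#' @export
precomputation_move <- function(cset) {
  cset$move_id[which.max(cset$shallow)]
}

#' Benefit of computation
#'
#' The benefit of computation for a position is the gain in true (deep)
#' utility from playing the deep-search-optimal move `m[C]` instead of the
#' move that would be chosen without computation, `m[-C]`:
#' `dUC = UC(mC) - UC(m-C)`. It is zero exactly when the deep and shallow
#' argmax coincide (under the first-wins tie rule) and non-negative always.
#'
#' @param cset A [consideration_set()].
#' @return A non-negative utility difference.
#' @examples
#' benefit_of_computation(consideration_set(c(0.6, 0.5), c(0.40, 0.70)))
#' @export
benefit_of_computation <- function(cset) {
  d <- cset$deep
  d[which.max(d)] - d[which.max(cset$shallow)]
}

#' Expected value of the maximum of independent Gaussians
#'
#' Computes `E[max_i X_i]` for independent `X_i ~ Normal(mu_i, sigma_i)`,
#' with `sigma_i = 0` treated as a point mass. The expectation is evaluated
#' by adaptive quadrature of the positive/negative-part identity
#' `E[M] = a + int_a^hi (1 - F(x)) dx - int_lo^a F(x) dx` (anchor `a = 0`
#' clamped into the bracket), where `F` is the product of the per-component
#' CDFs and the bracket covers `[min mu - 8 max sigma, max mu + 8 max sigma]`.
#' Integration is split at point-mass locations so step discontinuities do not
#' degrade accuracy. Absolute accuracy is ~1e-6 utility or better; the result
#' is floored at `max(mu)`, which is an exact lower bound.
#'
#' @param mu Numeric vector of means.
#' @param sigma Numeric vector of standard deviations (>= 0), same length.
#' @return The expectation, a single number.
#' @examples
#' expected_max_gaussians(c(0, 0), c(1, 1)) # 1/sqrt(pi)
#' @export
expected_max_gaussians <- function(mu, sigma) {
  if (length(mu) != length(sigma) || length(mu) < 1) {
    stop("`mu` and `sigma` must have equal length >= 1", call. = FALSE)
  }
  if (any(!is.finite(mu)) || any(!is.finite(sigma))) {
    stop("`mu` and `sigma` must be finite", call. = FALSE)
  }
  if (any(sigma < 0)) stop("`sigma` must be non-negative", call. = FALSE)
  smax <- max(sigma)
  if (smax == 0) return(max(mu))
  lo <- min(mu) - 8 * smax
  hi <- max(mu) + 8 * smax
  live <- sigma > 0
  cdf_prod <- function(x) {
    out <- rep(1, length(x))
    for (i in which(live)) out <- out * pnorm(x, mu[i], sigma[i])
    for (m in mu[!live]) out <- out * as.numeric(x >= m)
    out
  }
  a <- min(max(0, lo), hi)
  # split at point-mass jumps so the adaptive rule sees smooth pieces
  knots <- sort(unique(c(a, mu[!live])))
  knots <- knots[knots > lo & knots < hi]
  edges <- sort(unique(c(lo, knots, hi)))
  piece <- function(f, from, to) {
    if (to <= from) return(0)
    stats::integrate(f, from, to, subdivisions = 500L,
                     abs.tol = 1e-9, rel.tol = 1e-9)$value
  }
  upper <- 0
  lower <- 0
  for (j in seq_len(length(edges) - 1)) {
    l <- edges[j]; r <- edges[j + 1]
    if (r <= a) {
      lower <- lower + piece(cdf_prod, l, r)
    } else if (l >= a) {
      upper <- upper + piece(function(x) 1 - cdf_prod(x), l, r)
    } else {
      lower <- lower + piece(cdf_prod, l, a)
      upper <- upper + piece(function(x) 1 - cdf_prod(x), a, r)
    }
  }
  max(a + upper - lower, max(mu))
}

# Beliefs about post-computation utilities: Gaussian per move, centred on the
# shallow value with sd equal to |deep - shallow| (the single-sample MLE).
belief_set <- function(cset) {
  list(mu = cset$shallow, sigma = abs(cset$deep - cset$shallow))
}

#' Expected benefit of computation
#'
#' The benefit of computation marginalized over beliefs about what the search
#' would reveal: each move's post-computation utility is modelled as a
#' Gaussian centred on its shallow value with standard deviation equal to the
#' absolute shallow-deep discrepancy, independent across moves. Then
#' `E[dUC] = E[max_m X_m] - mu(m[-C])`, which is non-negative because
#' `m[-C]` maximizes the means. Unlike the oracle score
#' [benefit_of_computation()], this is computable before the search outcome
#' is known, and is strictly positive whenever beliefs overlap — even when
#' the true benefit is zero.
#'
#' @param cset A [consideration_set()].
#' @return A non-negative utility.
#' @examples
#' # deep and shallow agree on the argmax: true benefit 0, expected benefit > 0
#' cs <- consideration_set(c(0.55, 0.50), c(0.60, 0.58))
#' benefit_of_computation(cs)
#' expected_benefit_of_computation(cs)
#' @export
expected_benefit_of_computation <- function(cset) {
  b <- belief_set(cset)
  if (all(b$sigma == 0)) return(0)
  best <- which.max(b$mu)
  max(0, expected_max_gaussians(b$mu, b$sigma) - b$mu[best])
}

#' Monte-Carlo estimate of the expected benefit of computation
#'
#' Simulation oracle for the quadrature path: draws each move's
#' post-computation utility independently from its belief, and averages
#' `max_m X_m - X_(m[-C])` over draws. The estimand equals
#' `E[max] - mu(m[-C])` in expectation; sharing the `m[-C]` draw across the
#' difference reduces variance.
#'
#' @param cset A [consideration_set()].
#' @param n_samples Number of draws (>= 1000).
#' @param seed Optional seed; the caller's RNG stream is left untouched.
#' @return A list with `estimate` and `se`.
#' @export
mc_expected_benefit <- function(cset, n_samples = 10000, seed = NULL) {
  if (n_samples < 1000) stop("`n_samples` must be >= 1000", call. = FALSE)
  b <- belief_set(cset)
  if (all(b$sigma == 0)) return(list(estimate = 0, se = 0))
  best <- which.max(b$mu)
  draws <- with_preserved_seed(seed, {
    x <- matrix(rnorm(n_samples * length(b$mu),
                      mean = rep(b$mu, each = n_samples),
                      sd = rep(b$sigma, each = n_samples)),
                nrow = n_samples)
    do.call(pmax, asplit(x, 2)) - x[, best]
  })
  list(estimate = mean(draws), se = stats::sd(draws) / sqrt(n_samples))
}

## ---- Table-level scoring --------------------------------------------------

# Extract shallow/deep matrices (n x k) from a wide move table.
set_matrices <- function(records) {
  k <- infer_consideration_size(names(records))
  if (k < 1) stop("records lack consideration-set columns", call. = FALSE)
  list(
    k = k,
    shallow = as.matrix(records[paste0("shallow_", seq_len(k))]),
    deep = as.matrix(records[paste0("deep_", seq_len(k))])
  )
}

#' Row of a move table as a consideration set
#'
#' @param records A move table.
#' @param i Row index.
#' @return A [consideration_set()].
#' @export
consideration_set_from_record <- function(records, i) {
  m <- set_matrices(records)
  ids <- unlist(records[i, paste0("move_id_", seq_len(m$k))], use.names = FALSE)
  consideration_set(m$shallow[i, ], m$deep[i, ], move_id = ids)
}

#' Score every move of a table
#'
#' Adds, per record: `delta_uc` (the oracle benefit of computation),
#' optionally `e_delta_uc` (its expectation under Gaussian beliefs), `u` (the
#' position advantage if no computation is executed — the deep utility of the
#' shallow-preferred move, the advantage convention used by the value grid),
#' and `move_time` (from the clocks and increment under the configured
#' convention).
#'
#' @param records A move table.
#' @param config A [run_config()].
#' @param expected Compute `e_delta_uc` (quadrature per row; the slowest
#'   column — disable for large tables when not needed)? Default `FALSE`.
#' @return The records tibble with score columns appended.
#' @export
score_moves <- function(records, config = run_config(), expected = FALSE) {
  m <- set_matrices(records)
  n <- nrow(records)
  out <- tibble::as_tibble(records)
  if (n == 0) {
    out$delta_uc <- numeric(0)
    out$u <- numeric(0)
    if (expected) out$e_delta_uc <- numeric(0)
    out$move_time <- numeric(0)
    return(out)
  }
  i_shallow <- max.col(m$shallow, ties.method = "first")
  i_deep <- max.col(m$deep, ties.method = "first")
  rows <- seq_len(n)
  out$delta_uc <- m$deep[cbind(rows, i_deep)] - m$deep[cbind(rows, i_shallow)]
  out$u <- m$deep[cbind(rows, i_shallow)]
  if (expected) {
    sig <- abs(m$deep - m$shallow)
    out$e_delta_uc <- vapply(rows, function(i) {
      if (all(sig[i, ] == 0)) return(0)
      best <- i_shallow[i]
      max(0, expected_max_gaussians(m$shallow[i, ], sig[i, ]) -
            m$shallow[i, best])
    }, numeric(1))
  }
  out$move_time <- compute_move_time(records$clock_before,
                                     records$clock_after,
                                     records$tc_inc,
                                     convention = config$clock_convention)
  out
}
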