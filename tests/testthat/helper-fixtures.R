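# Shared fixtures, built in code.

# Random consideration set with utilities in [0, 1]; occasionally exact ties
# and zero-discrepancy moves so tie and degenerate paths get exercised.
random_cset <- function(k = 5, p_tie = 0.1, p_exact = 0.2) {
  deep <- runif(k)
  shallow <- clamp_unit(deep + rnorm(k, 0, 0.1))
  exact <- runif(k) < p_exact
  shallow[exact] <- deep[exact]
  if (runif(1) < p_tie && k >= 2) shallow[2] <- shallow[1]
  consideration_set(shallow, deep)
}

clamp_unit <- function(x) pmin(1, pmax(0, x))

# Closed form for E[max(X1, X2)] of two independent Gaussians.
emax_two_gaussians <- function(m1, s1, m2, s2) {
  theta <- sqrt(s1^2 + s2^2)
  if (theta == 0) return(max(m1, m2))
  d <- m1 - m2
  m1 * pnorm(d / theta) + m2 * pnorm(-d / theta) + theta * dnorm(d / theta)
}

# Minimal hand-built move table: n rows, one game per row by default.
toy_move_table <- function(n = 3, k = 2, game_id = sprintf("g%03d", seq_len(n)),
                           ply = seq_len(n) + 14L,
                           outcome = rep("win", n)) {
  tbl <- tibble::tibble(
    game_id = game_id, ply = ply, elo = rep(1500, n),
    opp_clock = rep(120, n), clock_before = 60 - seq_len(n),
    clock_after = 57 - seq_len(n), tc_start = rep(180, n),
    tc_inc = rep(0, n), outcome = outcome
  )
  for (j in seq_len(k)) {
    tbl[[paste0("move_id_", j)]] <- rep(paste0("m", j), n)
  }
  for (j in seq_len(k)) tbl[[paste0("shallow_", j)]] <- runif(n)
  for (j in seq_len(k)) tbl[[paste0("deep_", j)]] <- runif(n)
  tbl
}

# Quiet wrappers: the pipeline logs to stderr by design.
quiet <- function(expr) suppressMessages(expr)
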