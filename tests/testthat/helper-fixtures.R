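# Shared fixtures: small cohort configurations and brute-force oracles.

# A small, fast cohort for structural tests.
small_config <- function(seed = 7, ...) {
  cohort_config(
    group_sizes = c(HC = 40, sPD = 40, LRRK2_PD = 12, LRRK2_NMC = 12),
    n_sites = 3L,
    seed = seed,
    ...
  )
}

# Exhaustive minimum assignment cost over all permutations (n <= 8).
brute_force_assignment_cost <- function(cost) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  nr <- nrow(cost); nc <- ncol(cost)
  best <- Inf
  if (nr <= nc) {
    for (p in perms(seq_len(nc))) {
      s <- sum(cost[cbind(seq_len(nr), p[seq_len(nr)])])
      if (s < best) best <- s
    }
  } else {
    for (p in perms(seq_len(nr))) {
      s <- sum(cost[cbind(p[seq_len(nc)], seq_len(nc))])
      if (s < best) best <- s
    }
  }
  best
}

# OLS via explicit pseudo-inverse (normal equations), independent of the
# QR path used by the package.
pinv_ols <- function(y, X) {
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# Direct Benjamini-Hochberg step-up computation.
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(n / (n:1) * p[o]))[ro]
  q
}

# Welch two-sample t-test from the textbook formulas.
welch_oracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}
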