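# Shared fixtures and independent oracles for the test suite.

# small 4-point grid for oracle-checkable EM instances
tiny_grid_config <- function(tol = 1e-15, max_iter = 200000L) {
  em_config(b_min = -0.1, b_max = 0.1, step = 0.05, tol = tol,
            max_iter = max_iter)
}

# hand-built summary table
toy_table <- function(beta, var, ids = NULL, n_cases = 1000, n_controls = 1000) {
  m <- length(beta)
  if (is.null(ids)) ids <- sprintf("rs%03d", seq_len(m))
  summary_table(
    data.frame(snp_id = ids, effect_allele = "A", other_allele = "G",
               beta_hat = beta, var_hat = var, stringsAsFactors = FALSE),
    n_cases = n_cases, n_controls = n_controls, provenance = "toy"
  )
}

# naive double-loop log-likelihood, deliberately independent of the
# package's log-space implementation
naive_loglik <- function(y, v, pi, points, masses) {
  total <- 0
  for (j in seq_along(y)) {
    f1 <- 0
    for (k in seq_along(points)) {
      f1 <- f1 + masses[k] * dnorm(y[j], points[k], sqrt(v[j]))
    }
    total <- total + log((1 - pi) * dnorm(y[j], 0, sqrt(v[j])) + pi * f1)
  }
  total
}

# Independent maximizer of the mixture log-likelihood over (pi, p) for small
# B: coarse grid search over the probability simplex followed by
# deterministic mass-exchange refinement with a shrinking step.  The
# likelihood is concave in the full weight vector ((1-pi), pi*p), so this
# converges to the global optimum without sharing any code with the EM.
oracle_max_loglik <- function(y, v, points) {
  m <- length(y)
  B <- length(points)
  F1 <- vapply(points, function(b) dnorm(y, b, sqrt(v)), numeric(m))
  f0 <- dnorm(y, 0, sqrt(v))
  ll_w <- function(w) {
    # w = (w0, w1..wB) on the simplex; w0 is the null weight
    sum(log(cbind(f0, F1) %*% w))
  }
  # coarse start: all vertices plus the barycentre
  best_w <- rep(1 / (B + 1), B + 1)
  best_ll <- ll_w(best_w)
  for (i in seq_len(B + 1)) {
    w <- rep(0.02 / B, B + 1); w[i] <- 1 - 0.02
    w <- w / sum(w)
    ll <- ll_w(w)
    if (ll > best_ll) { best_ll <- ll; best_w <- w }
  }
  delta <- 0.25
  while (delta > 1e-9) {
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      for (from in seq_len(B + 1)) {
        for (to in seq_len(B + 1)) {
          # re-check the donor every time: an accepted move inside this
          # sweep may already have drained it
          if (to == from || best_w[from] < delta) next
          w <- best_w
          w[from] <- w[from] - delta
          w[to] <- w[to] + delta
          ll <- ll_w(w)
          if (is.finite(ll) && ll > best_ll + 1e-14) {
            best_ll <- ll; best_w <- w; improved <- TRUE
          }
        }
      }
    }
    delta <- delta / 2
  }
  list(loglik = best_ll, pi = 1 - best_w[1],
       masses = if (best_w[1] < 1) best_w[-1] / (1 - best_w[1]) else best_w[-1])
}

# two-spike distribution at +-0.05 on the default grid, the canonical
# recovery target
two_spike_g <- function(grid = make_grid()) {
  point_mass_distribution(grid, c(-0.05, 0.05))
}

# minimal stand-in fit object (simulate/predict only need pi and g)
fake_fit <- function(pi, g) {
  structure(list(pi = pi, g = g, config = em_config()), class = "sphmm_fit")
}
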