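# Shared fixtures: randomized recursive models and a finite-difference
# Jacobian oracle (central differences; a test fixture only, never the
# production derivative path).

random_model <- function(n = 5, seed = 1, edge_prob = 0.5,
                         bidir_prob = 0.2) {
  set.seed(seed)
  vars <- paste0("V", seq_len(n))
  directed <- list()
  theta_F <- numeric(0)
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      if (i < j && stats::runif(1) < edge_prob) {
        lab <- sprintf("c%d_%d", j, i)
        directed[[length(directed) + 1L]] <- c(vars[i], vars[j], lab)
        theta_F[lab] <- stats::runif(1, -0.9, 0.9)
      }
    }
  }
  bidirected <- list()
  theta_P <- numeric(0)
  for (i in seq_len(n)) {
    lab <- sprintf("s%d", i)
    bidirected[[length(bidirected) + 1L]] <- c(vars[i], vars[i], lab)
    theta_P[lab] <- stats::runif(1, 0.8, 2)
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && stats::runif(1) < bidir_prob) {
        lab <- sprintf("r%d_%d", i, j)
        bidirected[[length(bidirected) + 1L]] <- c(vars[i], vars[j], lab)
        theta_P[lab] <- stats::runif(1, -0.25, 0.25)
      }
    }
  }
  spec <- model_spec(vars, directed = if (length(directed)) directed else NULL,
                     bidirected = bidirected)
  list(spec = spec, theta = c(theta_F, theta_P))
}

# Central-difference Jacobian of a vector-valued function of theta.
fd_jacobian <- function(f, theta, h = NULL) {
  if (is.null(h)) h <- 1e-6 * pmax(abs(theta), 1)
  f0 <- f(theta)
  J <- matrix(NA_real_, length(f0), length(theta))
  for (k in seq_along(theta)) {
    up <- theta; up[k] <- up[k] + h[k]
    dn <- theta; dn[k] <- dn[k] - h[k]
    J[, k] <- (f(up) - f(dn)) / (2 * h[k])
  }
  J
}

fixture <- illustration_fixture()
fixture_mats <- build_matrices(fixture$spec, fixture$theta)
fixture_Sigma <- model_implied_covariance(fixture_mats)
do_x2 <- intervention(fixture$spec, c(X2 = 11.54))
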