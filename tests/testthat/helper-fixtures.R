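# Shared fixtures, built in code. Seeds fixed so every run is identical.

# small stable VAR network reused across estimator tests
fixture_network <- function(n_regions = 5, density = 0.3, seed = 101) {
  make_true_network(n_regions, density, seed)
}

fixture_series <- function(n_frames = 300, n_regions = 5, seed = 7, tr_s = 0.8) {
  simulate_subject_series(fixture_network(n_regions, 0.3, 101), n_frames, tr_s,
    rng_seed = seed
  )
}

# i.i.d. Gaussian series with a given correlation matrix
gaussian_series <- function(n, R, seed, tr_s = 1) {
  L <- chol(R)
  with_seed(seed, {
    parcellated_ts(matrix(stats::rnorm(n * nrow(R)), n) %*% L, tr_s, "sub-fix")
  })
}

# exact stationary covariance by the Kronecker vec identity:
# vec(S) = (I - A (x) A)^{-1} vec(Q) -- independent of the package's
# doubling-iteration solver
lyapunov_kron <- function(A, Q) {
  p <- nrow(A)
  v <- solve(diag(p^2) - kronecker(A, A), as.numeric(Q))
  matrix(v, p, p)
}

# exact 4x4 lagged covariance of two independent AR(1) processes with unit
# innovations, order (x_t, y_t, x_{t+1}, y_{t+1})
ar1_lagged_cov <- function(phi_x, phi_y) {
  vx <- 1 / (1 - phi_x^2)
  vy <- 1 / (1 - phi_y^2)
  S <- diag(c(vx, vy, vx, vy))
  S[1, 3] <- S[3, 1] <- phi_x * vx
  S[2, 4] <- S[4, 2] <- phi_y * vy
  S
}

# brute-force average-linkage agglomeration over a distance matrix; returns
# the merge history as sorted member sets, independent of stats::hclust
brute_force_average_linkage <- function(D) {
  clusters <- as.list(seq_len(nrow(D)))
  merges <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_d <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        d_ab <- mean(D[clusters[[a]], clusters[[b]]])
        if (d_ab < best_d) {
          best_d <- d_ab
          best <- c(a, b)
        }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1]] <- merged
    clusters <- c(clusters[-best], list(merged))
  }
  merges
}
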