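# Ground-truth network generation and BOLD-like time-series simulation.
# The latent dynamics are a stable VAR(1); observed series are the latent
# process convolved with a canonical double-gamma hemodynamic response and
# degraded with white measurement noise.

#' Generate a ground-truth coupling network
#'
#' Draws a random stable VAR(1) system: diagonal self-decay plus random
#' off-diagonal couplings on a random support of the requested density,
#' rescaled so the spectral radius stays below 1. Region centroids are drawn
#' uniformly in a 140 mm cube, giving a realistic interregional distance range.
#'
#' @param n_regions number of regions (>= 3).
#' @param edge_density fraction of ordered off-diagonal pairs carrying a
#'   coupling, in (0, 1]; 0 gives pure diagonal decay.
#' @param rng_seed integer seed.
#' @param self_decay diagonal VAR coefficient before rescaling.
#' @param coupling_sd standard deviation of nonzero off-diagonal coefficients.
#' @param spectral_target spectral radius the system is rescaled to when the
#'   raw draw is unstable or too close to instability.
#' @return list of class `true_network` with elements
#'   `coupling_coefficients` (regions x regions VAR transition matrix),
#'   `innovation_covariance` (SPD), `centroids` (regions x 3, mm).
#' @export
make_true_network <- function(n_regions, edge_density, rng_seed,
                              self_decay = 0.35, coupling_sd = 0.35,
                              spectral_target = 0.85) {
  stopifnot(n_regions >= 3, edge_density >= 0, edge_density <= 1)
  with_seed(rng_seed, {
    A <- diag(self_decay, n_regions)
    off <- which(row(A) != col(A))
    n_edges <- round(edge_density * length(off))
    if (n_edges > 0) {
      sel <- sample(off, n_edges)
      A[sel] <- stats::rnorm(n_edges, 0, coupling_sd)
    }
    rho <- max(Mod(eigen(A, only.values = TRUE)$values))
    if (rho >= spectral_target) {
      A <- A * (spectral_target / rho)
    }
    # innovation covariance: identity plus a mild random SPD perturbation
    W <- matrix(stats::rnorm(n_regions * n_regions, 0, 0.15), n_regions)
    Q <- diag(n_regions) + crossprod(W) / n_regions
    centroids <- matrix(stats::runif(n_regions * 3, 0, 140), n_regions, 3,
      dimnames = list(NULL, c("x", "y", "z"))
    )
    structure(
      list(
        coupling_coefficients = A,
        innovation_covariance = Q,
        centroids = centroids
      ),
      class = "true_network"
    )
  })
}

#' Stationary covariance of a stable VAR(1) system
#'
#' Solves the discrete Lyapunov equation `S = A S A' + Q` by fixed-point
#' iteration on the doubling recursion, which converges geometrically for
#' spectral radius < 1.
#'
#' @param A transition matrix (spectral radius < 1).
#' @param Q innovation covariance.
#' @param tol convergence tolerance on the max elementwise update.
#' @return the stationary covariance matrix.
#' @export
stationary_covariance <- function(A, Q, tol = 1e-12) {
  rho <- max(Mod(eigen(A, only.values = TRUE)$values))
  if (rho >= 1) stop("VAR(1) system is unstable (spectral radius >= 1)")
  S <- Q
  Ak <- A
  for (iter in seq_len(200)) {
    # doubling recursion: after k steps S = sum_{m < 2^k} A^m Q (A^m)'
    Snext <- S + Ak %*% S %*% t(Ak)
    delta <- max(abs(Snext - S))
    S <- Snext
    Ak <- Ak %*% Ak
    if (delta < tol) break
  }
  (S + t(S)) / 2
}

#' Canonical double-gamma hemodynamic response function
#'
#' Peak at 6 s, undershoot at 16 s, peak/undershoot ratio 6, truncated at
#' 32 s, sampled at the repetition time and normalized to unit sum.
#'
#' @param tr_s sampling interval (seconds).
#' @param duration_s truncation length (seconds).
#' @return numeric vector of HRF samples.
#' @export
canonical_hrf <- function(tr_s, duration_s = 32) {
  t <- seq(0, duration_s, by = tr_s)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / sum(h)
}

#' Simulate one subject's parcellated BOLD series
#'
#' Simulates the latent VAR(1) process (discarding a burn-in), convolves each
#' region with the canonical HRF sampled at the repetition time, and adds
#' white measurement noise.
#'
#' @param true_network a `true_network` (see [make_true_network()]).
#' @param n_frames output frames (>= 64).
#' @param tr_s repetition time, seconds.
#' @param rng_seed integer seed.
#' @param noise_sd measurement-noise standard deviation.
#' @param burn_in discarded latent steps (>= 200).
#' @param subject_id identifier attached to the output.
#' @param hrf convolve with the canonical HRF? `FALSE` returns the latent
#'   VAR(1) process itself (plus measurement noise), which is what the
#'   stationary-covariance diagnostics operate on.
#' @return a `parcellated_ts`: list with `data` (frames x regions), `tr_s`,
#'   `subject_id`.
#' @export
simulate_subject_series <- function(true_network, n_frames, tr_s, rng_seed,
                                    noise_sd = 0.5, burn_in = 200,
                                    subject_id = "sub-01", hrf = TRUE) {
  stopifnot(n_frames >= 64, burn_in >= 200)
  A <- true_network$coupling_coefficients
  Q <- true_network$innovation_covariance
  n <- nrow(A)
  rho <- max(Mod(eigen(A, only.values = TRUE)$values))
  if (rho >= 1) stop("refusing to simulate an unstable network (spectral radius >= 1)")
  kern <- if (hrf) canonical_hrf(tr_s) else 1
  n_total <- burn_in + n_frames + length(kern)
  with_seed(rng_seed, {
    if (max(abs(Q)) == 0) {
      E <- matrix(0, n_total, n)
    } else {
      L <- t(chol(Q))
      E <- matrix(stats::rnorm(n_total * n), n_total, n) %*% t(L)
    }
    Z <- matrix(0, n_total, n)
    for (t in 2:n_total) {
      Z[t, ] <- A %*% Z[t - 1, ] + E[t, ]
    }
    # causal HRF convolution per region, then trim burn-in and filter warm-up
    B <- if (hrf) {
      apply(Z, 2, function(z) stats::filter(z, kern, method = "convolution", sides = 1))
    } else {
      Z
    }
    B <- B[(n_total - n_frames + 1):n_total, , drop = FALSE]
    if (noise_sd > 0) {
      B <- B + matrix(stats::rnorm(n_frames * n, 0, noise_sd), n_frames, n)
    }
    colnames(B) <- sprintf("region_%03d", seq_len(n))
    parcellated_ts(B, tr_s, subject_id)
  })
}

#' Construct a parcellated time-series container
#'
#' @param data frames x regions numeric matrix, no missing values.
#' @param tr_s repetition time, seconds.
#' @param subject_id identifier.
#' @return object of class `parcellated_ts`.
#' @export
parcellated_ts <- function(data, tr_s, subject_id = NA_character_) {
  data <- as.matrix(data)
  stopifnot(nrow(data) >= 2, ncol(data) >= 2, all(is.finite(data)), tr_s > 0)
  structure(list(data = data, tr_s = tr_s, subject_id = subject_id),
    class = "parcellated_ts"
  )
}

#' @export
print.parcellated_ts <- function(x, ...) {
  cat(sprintf(
    "<parcellated_ts> subject=%s frames=%d regions=%d TR=%.3fs\n",
    x$subject_id, nrow(x$data), ncol(x$data), x$tr_s
  ))
  invisible(x)
}
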