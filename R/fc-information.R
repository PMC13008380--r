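# Information-theoretic coupling: binned time-domain mutual information with
# Freedman-Diaconis binning (entropies in nats), and the redundancy/synergy
# components of a partial information decomposition of lagged past/future
# states under a Gaussian estimator.

#' Freedman-Diaconis bin specification
#'
#' Bin width `h = 2 * IQR * n^(-1/3)`; bin count `ceil(range / h)`; edges
#' span `[min, max]`. Zero IQR falls back to Sturges' rule with a warning;
#' constant input yields a single bin.
#'
#' @param x numeric vector (length >= 4).
#' @return list with `breaks` (edges), `n_bins`, `width`.
#' @export
freedman_diaconis_bins <- function(x) {
  stopifnot(length(x) >= 4)
  rng <- range(x)
  if (rng[1] == rng[2]) {
    return(list(breaks = c(rng[1] - 0.5, rng[1] + 0.5), n_bins = 1L, width = 1))
  }
  iqr <- stats::IQR(x)
  if (iqr == 0) {
    warning("zero interquartile range; falling back to Sturges' rule")
    n_bins <- as.integer(ceiling(log2(length(x)) + 1))
  } else {
    h <- 2 * iqr * length(x)^(-1 / 3)
    n_bins <- as.integer(ceiling(diff(rng) / h))
  }
  list(
    breaks = seq(rng[1], rng[2], length.out = n_bins + 1),
    n_bins = n_bins,
    width = diff(rng) / n_bins
  )
}

#' Binned marginal and joint distribution of two series
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `p_x`, `p_y`, `p_xy` (joint matrix), `bins_x`, `bins_y`.
#' @keywords internal
binned_joint <- function(x, y) {
  bx <- freedman_diaconis_bins(x)
  by <- freedman_diaconis_bins(y)
  ix <- findInterval(x, bx$breaks, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(y, by$breaks, rightmost.closed = TRUE, all.inside = TRUE)
  joint <- table(factor(ix, levels = seq_len(bx$n_bins)),
                 factor(iy, levels = seq_len(by$n_bins)))
  p_xy <- as.matrix(joint) / length(x)
  list(
    p_x = rowSums(p_xy), p_y = colSums(p_xy), p_xy = p_xy,
    bins_x = bx, bins_y = by
  )
}

#' Shannon entropy of a probability vector (nats)
#'
#' @param p probabilities (summing to 1).
#' @return entropy in nats.
#' @keywords internal
shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Binned time-domain mutual information coupling
#'
#' Per pair: marginal entropies from Freedman-Diaconis-binned histograms,
#' joint entropy on the product binning, `MI = I(X) + I(Y) - I(X, Y)` in
#' nats. Plug-in estimate; nonnegative up to numerical tolerance. Optionally
#' normalized by the joint entropy.
#'
#' @param series a `parcellated_ts` with >= 32 frames.
#' @param normalize divide MI by the joint entropy?
#' @return symmetric `coupling_matrix`, metric `mi_time`, values in nats.
#' @export
mi_time_fc <- function(series, normalize = FALSE) {
  X <- series$data
  stopifnot(nrow(X) >= 32)
  p <- ncol(X)
  out <- matrix(NA_real_, p, p)
  for (i in seq_len(p)) {
    for (j in seq_len(i - 1)) {
      bj <- binned_joint(X[, i], X[, j])
      mi <- shannon_entropy(bj$p_x) + shannon_entropy(bj$p_y) -
        shannon_entropy(as.numeric(bj$p_xy))
      if (normalize) {
        hxy <- shannon_entropy(as.numeric(bj$p_xy))
        mi <- if (hxy > 0) mi / hxy else 0
      }
      out[i, j] <- mi
      out[j, i] <- mi
    }
  }
  coupling_matrix(out, "mi_time", series$subject_id, symmetric = TRUE)
}

#' Gaussian mutual information between two blocks of a covariance matrix
#'
#' `I(A; B) = 0.5 * log(det(S_AA) det(S_BB) / det(S))` in nats.
#'
#' @param S covariance of the concatenated vector.
#' @param idx_a,idx_b index sets of the two blocks.
#' @return MI in nats (floored at 0).
#' @keywords internal
gaussian_mi <- function(S, idx_a, idx_b) {
  idx <- c(idx_a, idx_b)
  ld <- function(M) as.numeric(determinant(M, logarithm = TRUE)$modulus)
  mi <- 0.5 * (ld(S[idx_a, idx_a, drop = FALSE]) +
    ld(S[idx_b, idx_b, drop = FALSE]) -
    ld(S[idx, idx, drop = FALSE]))
  max(mi, 0)
}

#' Redundancy and synergy coupling from lagged past/future states
#'
#' For each region pair, the past is `(X_t, Y_t)` and the joint future
#' `N = (X_{t+lag}, Y_{t+lag})`. All mutual-information terms are computed
#' from the 4x4 sample covariance under a Gaussian model. Redundancy is the
#' minimum of the two marginal past-to-joint-future MIs; synergy is the joint
#' MI minus the union information `I(N; X_t) + I(N; Y_t) - R`. A
#' rank-deficient covariance is ridge-regularized (1e-8 on the diagonal) with
#' a warning.
#'
#' @param series a `parcellated_ts` with frames > `lag + 8`.
#' @param lag frame lag between past and future states.
#' @return list with `redundancy` and `synergy` (symmetric
#'   `coupling_matrix` objects, nats).
#' @export
phiid_components_fc <- function(series, lag = 1) {
  X <- series$data
  n <- nrow(X)
  stopifnot(n > lag + 8)
  p <- ncol(X)
  red <- matrix(NA_real_, p, p)
  syn <- matrix(NA_real_, p, p)
  past <- seq_len(n - lag)
  fut <- past + lag
  for (i in seq_len(p)) {
    for (j in seq_len(i - 1)) {
      Z <- cbind(X[past, i], X[past, j], X[fut, i], X[fut, j])
      comp <- phiid_pair(stats::cov(Z))
      red[i, j] <- comp["redundancy"]
      red[j, i] <- comp["redundancy"]
      syn[i, j] <- comp["synergy"]
      syn[j, i] <- comp["synergy"]
    }
  }
  list(
    redundancy = coupling_matrix(red, "redundancy", series$subject_id, symmetric = TRUE),
    synergy = coupling_matrix(syn, "synergy", series$subject_id, symmetric = TRUE)
  )
}

#' Redundancy/synergy components from a 4x4 lagged covariance
#'
#' Variable order: (X past, Y past, X future, Y future).
#'
#' @param S 4x4 covariance.
#' @return named vector: `redundancy`, `synergy`, `mi_joint`, `mi_x`, `mi_y`.
#' @export
phiid_pair <- function(S) {
  if (rcond(S) < 1e-12) {
    warning("rank-deficient lagged covariance; applying 1e-8 ridge")
    S <- S + diag(1e-8 * mean(diag(S)), 4)
  }
  idx_n <- c(3, 4) # joint future
  mi_x <- gaussian_mi(S, idx_n, 1)
  mi_y <- gaussian_mi(S, idx_n, 2)
  mi_joint <- gaussian_mi(S, idx_n, c(1, 2))
  r <- min(mi_x, mi_y)
  s <- mi_joint - (mi_x + mi_y - r)
  c(redundancy = r, synergy = s, mi_joint = mi_joint, mi_x = mi_x, mi_y = mi_y)
}
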