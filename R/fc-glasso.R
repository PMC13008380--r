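# L1-regularized partial correlation via the graphical lasso, with the
# two-stage lambda-range selection used for cohort-level tuning.
# The solver is the block coordinate-descent algorithm (lasso regression on
# each column of the working covariance), penalizing off-diagonals only;
# series are standardized internally so lambda lives on the correlation scale.

#' Graphical-lasso precision estimate
#'
#' Maximizes `log det(theta) - tr(S theta) - lambda * sum_{j != k} |theta_jk|`
#' over SPD matrices by block coordinate descent. Off-diagonals only are
#' penalized; zeros in the estimate are exact.
#'
#' @param S sample correlation (or covariance) matrix.
#' @param lambda regularization strength (>= 0).
#' @param tol convergence: max elementwise change of the working covariance
#'   between sweeps.
#' @param max_iter outer sweep limit; non-convergence is an error.
#' @param init optional warm start: a previous fit's `warm` element (used by
#'   [select_lambda()] when sweeping a lambda grid).
#' @return list with `precision` (theta), `covariance` (its working inverse),
#'   `lambda`, `nonzero_edge_count` (upper-triangle support size),
#'   `iterations`, `warm` (state for warm-starting a neighboring lambda).
#' @export
glasso_fit <- function(S, lambda, tol = 1e-6, max_iter = 10000, init = NULL) {
  stopifnot(lambda >= 0, isTRUE(all.equal(S, t(S))))
  p <- nrow(S)
  if (is.null(init)) {
    W <- S
    B <- matrix(0, p - 1, p) # column-wise lasso coefficients
  } else {
    W <- init$W
    B <- init$B
  }
  soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
  for (iter in seq_len(max_iter)) {
    W_old <- W
    for (j in seq_len(p)) {
      idx <- setdiff(seq_len(p), j)
      W11 <- W[idx, idx, drop = FALSE]
      s12 <- S[idx, j]
      beta <- B[, j]
      # coordinate descent on 0.5 b'W11 b - s12'b + lambda |b|_1, with the
      # fitted vector v = W11 b maintained incrementally
      v <- as.numeric(W11 %*% beta)
      d11 <- diag(W11)
      for (cd in seq_len(1000)) {
        beta_old <- beta
        for (k in seq_len(p - 1)) {
          bk_new <- soft(s12[k] - v[k] + d11[k] * beta[k], lambda) / d11[k]
          delta_k <- bk_new - beta[k]
          if (delta_k != 0) {
            v <- v + W11[, k] * delta_k
            beta[k] <- bk_new
          }
        }
        if (max(abs(beta - beta_old)) < tol * 0.1) break
      }
      B[, j] <- beta
      w12 <- as.numeric(W11 %*% beta)
      W[idx, j] <- w12
      W[j, idx] <- w12
    }
    if (max(abs(W - W_old)) < tol) break
    if (iter == max_iter) {
      stop(sprintf(
        "graphical lasso did not converge in %d sweeps (last delta %.3g, lambda %.3g)",
        max_iter, max(abs(W - W_old)), lambda
      ))
    }
  }
  theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- setdiff(seq_len(p), j)
    theta_jj <- 1 / (W[j, j] - sum(W[idx, j] * B[, j]))
    theta[j, j] <- theta_jj
    theta[idx, j] <- -B[, j] * theta_jj
  }
  theta <- (theta + t(theta)) / 2
  # symmetrization never creates support: zero stays exactly zero
  nz <- sum(theta[upper.tri(theta)] != 0)
  list(
    precision = theta, covariance = W, lambda = lambda,
    nonzero_edge_count = nz, iterations = iter,
    warm = list(W = W, B = B)
  )
}

#' Regularized partial-correlation coupling via graphical lasso
#'
#' Standardizes the series internally, fits [glasso_fit()] on the sample
#' correlation matrix, and converts the precision estimate to partial
#' correlations `-theta_xy / sqrt(theta_xx theta_yy)`.
#'
#' @param series a `parcellated_ts`.
#' @param lambda regularization strength (>= 0).
#' @return list with `fit` (the [glasso_fit()] result) and `fc` (symmetric
#'   `coupling_matrix`, metric `glasso`, exact zeros preserved).
#' @export
glasso_fc <- function(series, lambda) {
  S <- stats::cor(series$data)
  fit <- glasso_fit(S, lambda)
  r <- precision_to_partial(fit$precision)
  diag(r) <- NA_real_
  list(
    fit = fit,
    fc = coupling_matrix(r, "glasso", series$subject_id, symmetric = TRUE)
  )
}

#' Extended-BIC score of a graphical-lasso fit
#'
#' `-2 * loglik + k * log(n) + 4 * gamma * k * log(p)` with the Gaussian
#' profile log-likelihood `(n/2) * (log det theta - tr(S theta))` and `k` the
#' upper-triangle support size.
#'
#' @param fit a [glasso_fit()] result.
#' @param S sample correlation matrix the fit was computed from.
#' @param n number of frames.
#' @param gamma extended-BIC weight.
#' @return scalar score (lower is better).
#' @keywords internal
ebic_score <- function(fit, S, n, gamma = 0.5) {
  theta <- fit$precision
  ld <- determinant(theta, logarithm = TRUE)
  loglik <- (n / 2) * (as.numeric(ld$modulus) - sum(S * theta))
  k <- fit$nonzero_edge_count
  -2 * loglik + k * log(n) + 4 * gamma * k * log(nrow(S))
}

#' Two-stage lambda selection on a subject subset
#'
#' Stage 1 scores a wide logarithmic lambda grid per subject by extended BIC
#' and takes the median per-subject optimum; stage 2 re-grids tightly around
#' that median (clipped to the coarse range) and returns the refined median
#' optimum. Deterministic given the subject list.
#'
#' @param series_list list of `parcellated_ts` (>= 2 subjects; the cohort
#'   procedure uses a subset of 20).
#' @param coarse_grid increasing vector of candidate lambdas.
#' @param refine_factor half-width of the refinement window as a multiplicative
#'   factor around the stage-1 median.
#' @param n_refine refined-grid size.
#' @param gamma extended-BIC weight.
#' @return list with `lambda` (selected), `stage1_lambda`, `coarse_grid`,
#'   `refined_grid`, `per_subject_stage2`.
#' @export
select_lambda <- function(series_list,
                          coarse_grid = exp(seq(log(0.01), log(1), length.out = 10)),
                          refine_factor = 3, n_refine = 10, gamma = 0.5) {
  stopifnot(length(series_list) >= 2)
  if (length(coarse_grid) < 1 || any(diff(coarse_grid) <= 0) && length(coarse_grid) > 1) {
    stop("degenerate lambda grid")
  }
  if (length(coarse_grid) == 1) {
    return(list(
      lambda = coarse_grid, stage1_lambda = coarse_grid,
      coarse_grid = coarse_grid, refined_grid = coarse_grid,
      per_subject_stage2 = rep(coarse_grid, length(series_list))
    ))
  }
  best_on_grid <- function(series, grid) {
    S <- stats::cor(series$data)
    n <- nrow(series$data)
    # sweep from the sparsest end down, warm-starting each fit from its
    # neighbor; identical solutions, far fewer sweeps
    ord <- order(grid, decreasing = TRUE)
    scores <- numeric(length(grid))
    warm <- NULL
    for (k in ord) {
      fit <- glasso_fit(S, grid[k], init = warm)
      warm <- fit$warm
      scores[k] <- ebic_score(fit, S, n, gamma)
    }
    grid[which.min(scores)]
  }
  stage1 <- vapply(series_list, best_on_grid, numeric(1), grid = coarse_grid)
  m <- stats::median(stage1)
  lo <- max(m / refine_factor, min(coarse_grid))
  hi <- min(m * refine_factor, max(coarse_grid))
  refined <- exp(seq(log(lo), log(hi), length.out = n_refine))
  stage2 <- vapply(series_list, best_on_grid, numeric(1), grid = refined)
  list(
    lambda = stats::median(stage2), stage1_lambda = m,
    coarse_grid = coarse_grid, refined_grid = refined,
    per_subject_stage2 = stage2
  )
}
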