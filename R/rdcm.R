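# Effective connectivity by regression dynamic causal modeling: each region's
# Fourier-transformed temporal derivative is regressed on the (underived)
# spectra of all regions by variational Bayesian linear regression with a
# conjugate Gaussian-Gamma posterior. Resting-state variant: no driving
# inputs; the design holds only region spectra plus an optional constant.

#' Spectrum of the discrete temporal derivative of a series
#'
#' Multiplies the FFT by the first-difference transfer function
#' `(exp(i w dt) - 1) / dt`, so the inverse FFT is exactly the circular
#' forward difference divided by the sampling interval.
#'
#' @param x numeric series.
#' @param tr_s sampling interval, seconds.
#' @return complex vector, all FFT bins.
#' @keywords internal
diff_spectrum <- function(x, tr_s) {
  n <- length(x)
  omega <- 2 * pi * fft_frequencies(n, tr_s)
  stats::fft(x) * (exp(1i * omega * tr_s) - 1) / tr_s
}

#' Build the frequency-domain regression design
#'
#' `F` holds, per target region, the Fourier transform of the temporal
#' derivative of its signal; `D` holds the underived region spectra (the
#' endogenous-connectivity regressors) plus an optional constant confound
#' column. Rows are restricted to the positive half-spectrum (DC excluded)
#' below `cutoff_hz`.
#'
#' @param series a `parcellated_ts` with >= 64 frames.
#' @param cutoff_hz upper frequency bound for retained rows; `NULL` keeps the
#'   full positive half-spectrum.
#' @param confound_col include a constant confound column in `D`?
#' @return list of class `rdcm_design`: `F` (bins x regions, complex), `D`
#'   (bins x regressors, complex), `frequencies` (Hz), `n_regions`, `tr_s`.
#' @export
build_rdcm_design <- function(series, cutoff_hz = NULL, confound_col = FALSE) {
  X <- series$data
  n <- nrow(X)
  stopifnot(n >= 64)
  p <- ncol(X)
  freqs <- fft_frequencies(n, series$tr_s)
  keep <- which(freqs > 0)
  if (!is.null(cutoff_hz)) keep <- keep[freqs[keep] < cutoff_hz]
  Fmat <- sapply(seq_len(p), function(j) diff_spectrum(X[, j], series$tr_s)[keep])
  Dmat <- sapply(seq_len(p), function(j) stats::fft(X[, j])[keep])
  colnames(Dmat) <- colnames(X)
  if (confound_col) Dmat <- cbind(Dmat, confound = 1 + 0i)
  structure(
    list(
      F = Fmat, D = Dmat, frequencies = freqs[keep],
      n_regions = p, tr_s = series$tr_s
    ),
    class = "rdcm_design"
  )
}

#' Default rDCM priors
#'
#' Off-diagonal afferent weights N(0, 1); self-connections N(-1, 1)
#' (encouraging decay); noise precision Gamma(shape 2, rate 1).
#'
#' @return list with `off_mean`, `off_var`, `self_mean`, `self_var`,
#'   `confound_mean`, `confound_var`, `tau_shape`, `tau_rate`.
#' @export
rdcm_priors <- function() {
  list(
    off_mean = 0, off_var = 1, self_mean = -1, self_var = 1,
    confound_mean = 0, confound_var = 1, tau_shape = 2, tau_rate = 1
  )
}

#' Invert the rDCM model by variational Bayes
#'
#' Per target region, iterates the conjugate Gaussian-Gamma updates (Gaussian
#' posterior over afferent weights given the expected noise precision; Gamma
#' posterior over the precision given the expected residual) on the
#' real/imaginary-stacked design until the posterior mean stabilizes. The
#' variational free energy is tracked and must not decrease.
#'
#' @param design an `rdcm_design`.
#' @param priors prior list (see [rdcm_priors()]).
#' @param fix_tau if non-`NULL`, the noise precision is held at this value
#'   (degenerate Gamma prior) and the weight posterior is the closed-form
#'   Bayesian ridge solution.
#' @param tol convergence tolerance on the posterior-mean update.
#' @param max_iter iteration cap per region.
#' @return list of class `rdcm_posterior`: `A` (regions x regions posterior
#'   mean; entry \[x, y\] is the strength of y -> x), `posterior` (per-region
#'   list with `mean`, `cov`, `tau_shape`, `tau_rate`, `free_energy`,
#'   `iterations`), `design_regions`.
#' @export
rdcm_invert <- function(design, priors = rdcm_priors(), fix_tau = NULL,
                        tol = 1e-6, max_iter = 500) {
  p <- design$n_regions
  q <- ncol(design$D)
  Xmat <- rbind(Re(design$D), Im(design$D))
  XtX <- crossprod(Xmat)
  n_obs <- nrow(Xmat)
  per_region <- vector("list", p)
  A <- matrix(0, p, p)
  for (x in seq_len(p)) {
    y <- c(Re(design$F[, x]), Im(design$F[, x]))
    mu0 <- rep(priors$off_mean, q)
    v0 <- rep(priors$off_var, q)
    mu0[x] <- priors$self_mean
    v0[x] <- priors$self_var
    if (q > p) {
      mu0[(p + 1):q] <- priors$confound_mean
      v0[(p + 1):q] <- priors$confound_var
    }
    S0inv <- diag(1 / v0, q)
    Xty <- crossprod(Xmat, y)
    if (!is.null(fix_tau)) {
      Sg <- solve(fix_tau * XtX + S0inv)
      mu <- Sg %*% (fix_tau * Xty + S0inv %*% mu0)
      per_region[[x]] <- list(
        mean = as.numeric(mu), cov = Sg, tau_shape = NA_real_,
        tau_rate = NA_real_, free_energy = NA_real_, iterations = 1L
      )
      A[x, ] <- as.numeric(mu)[seq_len(p)]
      next
    }
    a0 <- priors$tau_shape
    b0 <- priors$tau_rate
    e_tau <- a0 / b0
    mu <- mu0
    elbo_prev <- -Inf
    n_drops <- 0
    a <- a0 + n_obs / 2
    for (iter in seq_len(max_iter)) {
      Sg <- solve(e_tau * XtX + S0inv)
      mu_new <- as.numeric(Sg %*% (e_tau * Xty + S0inv %*% mu0))
      resid2 <- sum((y - Xmat %*% mu_new)^2) + sum(XtX * Sg)
      b <- b0 + resid2 / 2
      e_tau <- a / b
      e_lntau <- digamma(a) - log(b)
      elbo <- (n_obs / 2) * (e_lntau - log(2 * pi)) - (e_tau / 2) * resid2 +
        (-q / 2 * log(2 * pi) - 0.5 * sum(log(v0)) -
          0.5 * (sum((mu_new - mu0)^2 / v0) + sum(diag(Sg) / v0))) +
        (a0 * log(b0) - lgamma(a0) + (a0 - 1) * e_lntau - b0 * e_tau) +
        0.5 * as.numeric(determinant(Sg)$modulus) + q / 2 * (1 + log(2 * pi)) +
        lgamma(a) - (a - 1) * digamma(a) - log(b) + a
      if (elbo < elbo_prev - 1e-8) {
        n_drops <- n_drops + 1
        if (n_drops >= 10) {
          stop(sprintf(
            "rDCM inversion diverged for region %d (free energy decreasing; iter %d, ELBO %.6g -> %.6g)",
            x, iter, elbo_prev, elbo
          ))
        }
      } else {
        n_drops <- 0
      }
      converged <- max(abs(mu_new - mu)) < tol
      mu <- mu_new
      elbo_prev <- elbo
      if (converged) break
    }
    per_region[[x]] <- list(
      mean = mu, cov = Sg, tau_shape = a, tau_rate = b,
      free_energy = elbo, iterations = iter
    )
    A[x, ] <- mu[seq_len(p)]
  }
  structure(list(A = A, posterior = per_region, design_regions = p),
    class = "rdcm_posterior"
  )
}

#' Extract full / incoming / outgoing effective-connectivity views
#'
#' The full view holds all `N(N-1)` off-diagonal entries of the assembled
#' A-matrix; the two triangle views split them into the directed entries below
#' (`incoming`) and above (`outgoing`) the diagonal, each with `N(N-1)/2`
#' features so EC models can be compared with FC models of equal feature
#' count.
#'
#' @param posterior an `rdcm_posterior` (or a bare A-matrix).
#' @return named list of numeric feature vectors: `full`, `incoming`,
#'   `outgoing`, each carrying an `edge_index` attribute (target, source).
#' @export
extract_ec_views <- function(posterior) {
  A <- if (inherits(posterior, "rdcm_posterior")) posterior$A else as.matrix(posterior)
  n <- nrow(A)
  ei_full <- edge_index_directed(n)
  full <- A[cbind(ei_full$i, ei_full$j)]
  attr(full, "edge_index") <- ei_full
  lower <- ei_full[ei_full$i > ei_full$j, ]
  upper <- ei_full[ei_full$i < ei_full$j, ]
  incoming <- A[cbind(lower$i, lower$j)]
  attr(incoming, "edge_index") <- lower
  outgoing <- A[cbind(upper$i, upper$j)]
  attr(outgoing, "edge_index") <- upper
  list(full = full, incoming = incoming, outgoing = outgoing)
}
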