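# Correlation-family coupling estimators: Pearson, Spearman (averaged tied
# ranks), and full partial correlation from the inverse sample covariance.

#' Pearson functional coupling
#'
#' Pairwise product-moment correlation between all region pairs, optionally
#' Fisher r-to-z transformed (atanh with inputs clipped to +/-(1 - 1e-7)).
#' Zero-variance regions yield NaN rows/columns with a warning.
#'
#' @param series a `parcellated_ts`.
#' @param fisher_z apply the r-to-z transform?
#' @return symmetric `coupling_matrix`, metric `pearson`, diagonal `NA`.
#' @export
pearson_fc <- function(series, fisher_z = TRUE) {
  X <- series$data
  sds <- apply(X, 2, stats::sd)
  bad <- sds == 0
  if (any(bad)) {
    warning(sprintf("%d zero-variance region(s); correlations set to NaN", sum(bad)))
  }
  r <- suppressWarnings(stats::cor(X))
  r[bad, ] <- NaN
  r[, bad] <- NaN
  if (fisher_z) r <- fisher_r_to_z(r)
  diag(r) <- NA_real_
  coupling_matrix(r, "pearson", series$subject_id, symmetric = TRUE, fisher_z = fisher_z)
}

#' Fisher r-to-z transform with clipping
#'
#' @param r correlations.
#' @param clip magnitude bound applied before `atanh`.
#' @return transformed values.
#' @export
fisher_r_to_z <- function(r, clip = 1 - 1e-7) {
  atanh(pmin(pmax(r, -clip), clip))
}

#' Spearman functional coupling
#'
#' Pearson correlation of the rank-transformed series, tied ranks resolved by
#' averaging.
#'
#' @inheritParams pearson_fc
#' @return symmetric `coupling_matrix`, metric `spearman`.
#' @export
spearman_fc <- function(series, fisher_z = TRUE) {
  ranked <- apply(series$data, 2, rank, ties.method = "average")
  out <- pearson_fc(parcellated_ts(ranked, series$tr_s, series$subject_id),
    fisher_z = fisher_z
  )
  attr(out, "metric_name") <- "spearman"
  out
}

#' Full partial-correlation coupling
#'
#' Partial correlation between each pair controlling for all remaining
#' regions, computed from the inverse sample covariance (precision matrix
#' theta) as `-theta_xy / sqrt(theta_xx * theta_yy)`. With two regions this
#' reduces to the Pearson correlation; with three it equals the classical
#' one-control recursion. A singular covariance falls back to the
#' Moore-Penrose pseudo-inverse with a warning; fewer frames than regions
#' triggers an ill-conditioning warning.
#'
#' @param series a `parcellated_ts`.
#' @return symmetric `coupling_matrix`, metric `partial`.
#' @export
partial_corr_fc <- function(series) {
  X <- series$data
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) {
    warning("frames <= regions: partial-correlation estimate is ill-conditioned")
  }
  S <- stats::cov(X)
  theta <- tryCatch(solve(S), error = function(e) {
    warning("singular covariance; using pseudo-inverse")
    MASS::ginv(S)
  })
  r <- precision_to_partial(theta)
  diag(r) <- NA_real_
  coupling_matrix(r, "partial", series$subject_id, symmetric = TRUE)
}

#' Partial correlations from a precision matrix
#'
#' @param theta precision matrix.
#' @return matrix of partial correlations `-theta_xy / sqrt(theta_xx theta_yy)`
#'   with unit diagonal.
#' @keywords internal
precision_to_partial <- function(theta) {
  d <- sqrt(abs(diag(theta)))
  r <- -theta / outer(d, d)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r
}
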