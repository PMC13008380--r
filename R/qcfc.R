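# Motion-sensitivity benchmarking: edgewise QC-FC correlations with mean
# framewise displacement, their distance dependence, sparsity matching to the
# graphical-lasso support, and the cross-metric similarity analysis.

#' Edgewise QC-FC correlations
#'
#' For every edge of a subjects-by-edges stack, the cross-subject correlation
#' between the edge's coupling value and the subjects' mean FD. Summaries are
#' the distribution mean and the population variance (divisor = number of
#' edges). Zero-variance edges yield `NaN` and are excluded from summaries.
#'
#' @param stack edge stack (list with `values`, see [stack_cohort()]) or bare
#'   subjects x edges matrix; >= 10 subjects.
#' @param mean_fd_per_subject numeric vector aligned to the stack's subjects.
#' @param method correlation type: `pearson` (default) or `spearman`.
#' @return list of class `qcfc_result`: `qcfc` (per-edge vector), `mu`,
#'   `sigma2` (population variance), `n_dropped` (zero-variance edges),
#'   `method`, `metric_name`.
#' @export
qcfc_correlations <- function(stack, mean_fd_per_subject, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  vals <- if (is.list(stack)) stack$values else as.matrix(stack)
  stopifnot(nrow(vals) >= 10, length(mean_fd_per_subject) == nrow(vals))
  q <- suppressWarnings(
    as.numeric(stats::cor(vals, mean_fd_per_subject, method = method))
  )
  zero_var <- apply(vals, 2, stats::sd) == 0
  q[zero_var] <- NaN
  ok <- is.finite(q)
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    message(sprintf("%d zero-variance edge(s) excluded from QC-FC summaries", n_dropped))
  }
  structure(
    list(
      qcfc = q,
      mu = mean(q[ok]),
      sigma2 = mean((q[ok] - mean(q[ok]))^2),
      n_dropped = n_dropped,
      method = method,
      metric_name = if (is.list(stack)) stack$metric_name else NA_character_
    ),
    class = "qcfc_result"
  )
}

#' QC-FC distance dependence
#'
#' Spearman rank correlation between the per-edge QC-FC values and the
#' Euclidean distance between the edge's regional centroids. `NaN` edges are
#' dropped pairwise.
#'
#' @param qcfc_result a `qcfc_result` (or bare QC-FC vector).
#' @param centroids regions x 3 coordinate matrix covering all regions, or a
#'   precomputed per-edge distance vector of matching length.
#' @return list with `rho` (Spearman correlation), `distance_mm` (per-edge
#'   vector), `n_edges_used`.
#' @export
distance_dependence <- function(qcfc_result, centroids) {
  q <- if (inherits(qcfc_result, "qcfc_result")) qcfc_result$qcfc else as.numeric(qcfc_result)
  d <- if (is.matrix(centroids) && ncol(centroids) == 3) {
    edge_distances(centroids)
  } else {
    as.numeric(centroids)
  }
  if (length(d) != length(q)) {
    stop("distance vector length does not match the QC-FC edge count")
  }
  ok <- is.finite(q)
  if (!any(ok)) stop("all QC-FC values are NaN")
  rho <- stats::cor(q[ok], d[ok], method = "spearman")
  list(rho = rho, distance_mm = d, n_edges_used = sum(ok))
}

#' Threshold a stack to match per-subject graphical-lasso sparsity
#'
#' Per subject, keeps the top-k edges by absolute weight (k from the
#' subject's graphical-lasso nonzero count) and zeroes the rest. Ties at the
#' k-th weight are broken by lower edge index, deterministically.
#'
#' @param stack edge stack or subjects x edges matrix.
#' @param reference_glasso_counts integer vector, one k per subject (each
#'   <= edge count); a scalar is recycled.
#' @return the stack with thresholded `values`.
#' @export
match_sparsity <- function(stack, reference_glasso_counts) {
  vals <- if (is.list(stack)) stack$values else as.matrix(stack)
  n_edges <- ncol(vals)
  k <- rep_len(as.integer(reference_glasso_counts), nrow(vals))
  stopifnot(all(k >= 0), all(k <= n_edges))
  for (s in seq_len(nrow(vals))) {
    if (k[s] == 0) {
      warning(sprintf("k = 0 for subject row %d: all edges zeroed", s))
      vals[s, ] <- 0
      next
    }
    if (k[s] == n_edges) next
    ord <- order(-abs(vals[s, ]), seq_len(n_edges)) # ties -> lower edge index
    drop <- ord[(k[s] + 1):n_edges]
    vals[s, drop] <- 0
  }
  if (is.list(stack)) {
    stack$values <- vals
    stack
  } else {
    vals
  }
}

#' Cross-metric similarity of group-mean coupling patterns
#'
#' Pairwise Pearson correlations among the metrics' group-mean edge vectors,
#' with an average-linkage agglomerative ordering on distance `1 - r`.
#' Directed (EC) stacks must be reduced to the shared undirected edge index
#' beforehand (see [directed_to_undirected_stack()]).
#'
#' @param mean_edge_vectors named list of group-mean edge vectors on a shared
#'   edge index, or a metrics x edges matrix with rownames.
#' @return list of class `metric_similarity`: `similarity` (metric x metric
#'   correlation matrix), `order` (average-linkage dendrogram order),
#'   `hclust` (the clustering object).
#' @export
metric_similarity <- function(mean_edge_vectors) {
  M <- if (is.list(mean_edge_vectors)) {
    do.call(rbind, mean_edge_vectors)
  } else {
    as.matrix(mean_edge_vectors)
  }
  stopifnot(nrow(M) >= 2)
  r <- stats::cor(t(M))
  hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
  structure(
    list(similarity = r, order = hc$order, hclust = hc),
    class = "metric_similarity"
  )
}

#' Reduce a directed edge stack to the undirected edge index
#'
#' Averages the two directions of every region pair, yielding a stack on the
#' `edge_index()` ordering shared with undirected metrics.
#'
#' @param stack directed edge stack (from [stack_cohort()] with
#'   `symmetric = FALSE`).
#' @param n_regions number of regions.
#' @return subjects x undirected-edges matrix.
#' @export
directed_to_undirected_stack <- function(stack, n_regions) {
  vals <- if (is.list(stack)) stack$values else as.matrix(stack)
  ei_dir <- edge_index_directed(n_regions)
  ei_und <- edge_index(n_regions)
  key_dir <- paste(pmax(ei_dir$i, ei_dir$j), pmin(ei_dir$i, ei_dir$j))
  key_und <- paste(ei_und$i, ei_und$j)
  out <- matrix(0, nrow(vals), nrow(ei_und))
  for (e in seq_len(nrow(ei_und))) {
    cols <- which(key_dir == key_und[e])
    out[, e] <- rowMeans(vals[, cols, drop = FALSE])
  }
  out
}
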