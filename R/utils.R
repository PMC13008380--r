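#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so seeded helpers never disturb the
#' caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

#' Undirected edge index for a parcellation
#'
#' Enumerates the lower triangle (i > j) in column-major order; every
#' subjects-by-edges stack in the package uses this ordering.
#'
#' @param n_regions number of regions.
#' @return data.frame with integer columns `i`, `j` (`i > j`), one row per edge.
#' @export
edge_index <- function(n_regions) {
  stopifnot(n_regions >= 2)
  idx <- which(lower.tri(matrix(0, n_regions, n_regions)), arr.ind = TRUE)
  data.frame(i = as.integer(idx[, 1]), j = as.integer(idx[, 2]))
}

#' Directed off-diagonal edge index
#'
#' All ordered region pairs (target, source) with target != source, column-major.
#'
#' @param n_regions number of regions.
#' @return data.frame with integer columns `i` (target), `j` (source).
#' @export
edge_index_directed <- function(n_regions) {
  stopifnot(n_regions >= 2)
  idx <- which(row(diag(n_regions)) != col(diag(n_regions)), arr.ind = TRUE)
  data.frame(i = as.integer(idx[, 1]), j = as.integer(idx[, 2]))
}

#' Vectorize the lower triangle of a symmetric coupling matrix
#'
#' @param m square matrix.
#' @return numeric vector in `edge_index()` order.
#' @export
lower_edges <- function(m) {
  m[lower.tri(m)]
}

#' Rebuild a symmetric matrix from its lower-triangle edge vector
#'
#' @param edges vector in `edge_index()` order.
#' @param n_regions number of regions.
#' @param diag_value value placed on the diagonal (default `NA`).
#' @return symmetric `n_regions` x `n_regions` matrix.
#' @export
edges_to_matrix <- function(edges, n_regions, diag_value = NA_real_) {
  m <- matrix(0, n_regions, n_regions)
  m[lower.tri(m)] <- edges
  m <- m + t(m)
  diag(m) <- diag_value
  m
}

#' Construct a per-subject coupling matrix container
#'
#' A plain matrix with metadata attributes: `subject_id`, `metric_name`,
#' `symmetric`, `fisher_z`. The diagonal convention is `NA` (undefined) for
#' undirected metrics; directed metrics keep their self-connections.
#'
#' @param values regions x regions matrix.
#' @param metric_name metric label.
#' @param subject_id subject identifier.
#' @param symmetric logical; undirected metric?
#' @param fisher_z logical; values are Fisher r-to-z transformed?
#' @return a `coupling_matrix` object.
#' @export
coupling_matrix <- function(values, metric_name, subject_id = NA_character_,
                            symmetric = TRUE, fisher_z = FALSE) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  structure(values,
    class = c("coupling_matrix", "matrix", "array"),
    metric_name = metric_name, subject_id = subject_id,
    symmetric = symmetric, fisher_z = fisher_z
  )
}

#' @export
print.coupling_matrix <- function(x, ...) {
  cat(sprintf(
    "<coupling_matrix> metric=%s subject=%s regions=%d symmetric=%s\n",
    attr(x, "metric_name"), attr(x, "subject_id"), nrow(x),
    attr(x, "symmetric")
  ))
  invisible(x)
}

#' Stack per-subject coupling matrices into a subjects-by-edges matrix
#'
#' Symmetric metrics contribute their lower triangle (`edge_index()` order,
#' n(n-1)/2 columns); directed metrics contribute all off-diagonal entries
#' (`edge_index_directed()` order, n(n-1) columns).
#'
#' @param mats list of coupling matrices (one per subject).
#' @param symmetric logical; if `NULL`, taken from the first matrix's attribute.
#' @return list with `values` (subjects x edges), `edge_index`, `metric_name`,
#'   `subjects`.
#' @export
stack_cohort <- function(mats, symmetric = NULL) {
  stopifnot(length(mats) >= 1)
  if (is.null(symmetric)) {
    symmetric <- isTRUE(attr(mats[[1]], "symmetric"))
  }
  n <- nrow(mats[[1]])
  ei <- if (symmetric) edge_index(n) else edge_index_directed(n)
  take <- function(m) {
    if (symmetric) lower_edges(m) else m[cbind(ei$i, ei$j)]
  }
  values <- do.call(rbind, lapply(mats, take))
  subjects <- vapply(mats, function(m) {
    s <- attr(m, "subject_id")
    if (is.null(s)) NA_character_ else as.character(s)
  }, character(1))
  rownames(values) <- subjects
  list(
    values = values, edge_index = ei,
    metric_name = attr(mats[[1]], "metric_name"), subjects = subjects
  )
}

#' Pairwise Euclidean distances for the undirected edge set
#'
#' @param centroids regions x 3 coordinate matrix (mm).
#' @return numeric vector of distances in `edge_index()` order.
#' @export
edge_distances <- function(centroids) {
  d <- as.matrix(stats::dist(centroids))
  lower_edges(d)
}
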