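test_that("QC-FC vectors have the parcellation's edge counts", {
  # undirected stack at 300 regions: 44,850 edges; directed: 89,700
  n_sub <- 12
  und <- with_seed(1, matrix(stats::rnorm(n_sub * 44850), n_sub))
  fd <- with_seed(2, stats::runif(n_sub, 0.05, 0.3))
  q <- qcfc_correlations(und, fd)
  expect_length(q$qcfc, 44850)
  dir <- with_seed(3, matrix(stats::rnorm(n_sub * 89700), n_sub))
  expect_length(qcfc_correlations(dir, fd)$qcfc, 89700)
})

test_that("zero-variance edges give NaN and are excluded from summaries", {
  vals <- with_seed(4, matrix(stats::rnorm(200), 20))
  vals[, 3] <- 1
  fd <- with_seed(5, stats::runif(20))
  expect_message(q <- qcfc_correlations(vals, fd), "zero-variance")
  expect_true(is.nan(q$qcfc[3]))
  expect_equal(q$n_dropped, 1)
  expect_true(is.finite(q$mu) && is.finite(q$sigma2))
  # population variance: divisor is the edge count
  ok <- is.finite(q$qcfc)
  expect_equal(q$sigma2, mean((q$qcfc[ok] - mean(q$qcfc[ok]))^2))
})

test_that("QC-FC is invariant to a common permutation of subjects", {
  vals <- with_seed(6, matrix(stats::rnorm(30 * 50), 30))
  fd <- with_seed(7, stats::runif(30))
  perm <- with_seed(8, sample(30))
  a <- qcfc_correlations(vals, fd)
  b <- qcfc_correlations(vals[perm, ], fd[perm])
  expect_equal(a$qcfc, b$qcfc, tolerance = 1e-12)
})

test_that("distance dependence recovers planted monotone structure and rejects none", {
  cents <- with_seed(9, matrix(stats::runif(20 * 3, 0, 140), 20))
  d <- edge_distances(cents)
  # strictly decreasing function of distance -> Spearman -1
  dd <- distance_dependence(exp(-d / 50), d)
  expect_equal(dd$rho, -1, tolerance = 1e-12)
  # permuted (distance-free) QC-FC -> near-zero rho
  q_perm <- with_seed(10, sample(exp(-d / 50)))
  expect_lt(abs(distance_dependence(q_perm, d)$rho), 0.2)
  expect_error(distance_dependence(rep(NaN, length(d)), d), "NaN")
})

test_that("distance dependence is invariant to rigid motion of the centroids", {
  cents <- with_seed(11, matrix(stats::runif(15 * 3, 0, 140), 15))
  q <- with_seed(12, stats::rnorm(nrow(edge_index(15))))
  theta <- 0.7
  R <- matrix(c(cos(theta), -sin(theta), 0, sin(theta), cos(theta), 0, 0, 0, 1), 3)
  cents2 <- sweep(cents %*% R, 2, c(10, -4, 2), "+")
  expect_equal(
    distance_dependence(q, cents)$rho,
    distance_dependence(q, cents2)$rho,
    tolerance = 1e-10
  )
})

test_that("sparsity matching keeps the top-k absolute weights with deterministic ties", {
  row <- matrix(c(0.9, -0.8, 0.1, 0.05), 1)
  out <- match_sparsity(row, 2)
  expect_equal(as.numeric(out), c(0.9, -0.8, 0, 0))
  # k = edge count is the identity
  expect_equal(match_sparsity(row, 4), row)
  # ties broken by lower edge index
  tie <- matrix(c(0.5, 0.5, 0.5), 1)
  expect_equal(as.numeric(match_sparsity(tie, 2)), c(0.5, 0.5, 0))
  # per-subject counts are honored exactly
  vals <- with_seed(13, matrix(stats::rnorm(5 * 30), 5))
  k <- c(3, 10, 30, 1, 7)
  thr <- match_sparsity(vals, k)
  expect_equal(rowSums(thr != 0), k)
  expect_warning(match_sparsity(matrix(1, 1, 4), 0), "zeroed")
})

test_that("metric similarity reproduces hand correlations and brute-force average linkage", {
  v <- with_seed(14, stats::rnorm(100))
  ms <- metric_similarity(list(a = v, b = -v, c = v + stats::rnorm(100, 0, 0.2)))
  expect_equal(ms$similarity["a", "a"], 1)
  expect_equal(ms$similarity["a", "b"], -1, tolerance = 1e-12)
  expect_gt(ms$similarity["a", "c"], 0.9)
  # brute-force linkage oracle on a larger set
  M <- with_seed(15, matrix(stats::rnorm(5 * 60), 5))
  rownames(M) <- letters[1:5]
  ms2 <- metric_similarity(M)
  D <- 1 - ms2$similarity
  oracle <- brute_force_average_linkage(D)
  got_sets <- list()
  members <- function(k) if (k < 0) -k else got_sets[[k]]
  for (i in seq_len(nrow(ms2$hclust$merge))) {
    got_sets[[i]] <- sort(c(
      members(ms2$hclust$merge[i, 1]), members(ms2$hclust$merge[i, 2])
    ))
  }
  expect_equal(got_sets, oracle, ignore_attr = TRUE)
})

test_that("directed stacks reduce to the undirected index by direction averaging", {
  n_reg <- 4
  A <- matrix(seq_len(16), 4)
  stack <- list(
    values = rbind(
      A[cbind(edge_index_directed(4)$i, edge_index_directed(4)$j)]
    ),
    edge_index = edge_index_directed(4)
  )
  und <- directed_to_undirected_stack(stack, 4)
  ei <- edge_index(4)
  expected <- (A[cbind(ei$i, ei$j)] + A[cbind(ei$j, ei$i)]) / 2
  expect_equal(as.numeric(und), expected)
})
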