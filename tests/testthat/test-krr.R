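# small deterministic prediction fixture: subjects x edges features with a
# planted linear signal, families of size 1-2
krr_fixture <- function(n = 60, e = 40, seed = 201, effect = 0.5) {
  with_seed(seed, {
    feats <- matrix(stats::rnorm(n * e), n)
    w <- c(rep(1, 8), rep(0, e - 8))
    score <- as.numeric(scale(feats %*% w))
    y <- effect * score + sqrt(1 - effect^2) * stats::rnorm(n)
    fam <- rep(sprintf("f%03d", seq_len(ceiling(n / 2))), each = 2)[seq_len(n)]
    covars <- data.frame(
      age = stats::runif(n, 20, 40), sex = stats::rbinom(n, 1, 0.5),
      mean_fd = stats::runif(n, 0.05, 0.3)
    )
    list(feats = feats, y = y, family = fam, covars = covars)
  })
}

test_that("train-fold behavior residualization matches the direct OLS oracle", {
  fx <- krr_fixture()
  tr <- 1:40
  te <- 41:60
  # planted slope with distinct train/test covariate distributions
  covars <- fx$covars
  covars$age[te] <- covars$age[te] + 20
  y <- 2 + 0.3 * covars$age + 0.5 * covars$sex + fx$y * 0.1
  res <- residualize_behavior(y, covars, tr, te)
  X <- cbind(1, as.matrix(covars))
  beta <- solve(crossprod(X[tr, ]), crossprod(X[tr, ], y[tr]))
  expect_lt(max(abs(res$test - (y[te] - X[te, ] %*% beta))), 1e-10)
  # behavior exactly linear in covariates -> residuals ~ 0 in train and test
  y_lin <- 1 + 0.2 * covars$age - 0.7 * covars$sex
  res_lin <- residualize_behavior(y_lin, covars, tr, te)
  expect_lt(max(abs(c(res_lin$train, res_lin$test))), 1e-8)
  # covariates orthogonal to the behavior on the training rows -> train
  # residuals equal the demeaned behavior
  y_raw <- with_seed(7, stats::rnorm(60))
  Xc <- cbind(1, as.matrix(covars))
  y_orth <- y_raw
  y_orth[tr] <- stats::resid(stats::lm(y_raw[tr] ~ Xc[tr, -1]))
  res_orth <- residualize_behavior(y_orth, covars, tr, te)
  expect_equal(res_orth$train, y_orth[tr] - mean(y_orth[tr]), tolerance = 1e-8)
})

test_that("the subject-similarity kernel matches hand-computed correlations", {
  v <- matrix(c(
    1, 2, 3, 4,
    2, 4, 6, 8,
    -1, -2, -3, -4
  ), 3, byrow = TRUE)
  K <- build_kernel(v)
  expect_equal(K[1, 2], 1, tolerance = 1e-12)
  expect_equal(K[1, 3], -1, tolerance = 1e-12)
  expect_equal(unname(diag(K)), rep(1, 3))
  m <- matrix(with_seed(3, stats::rnorm(12)), 3)
  K2 <- build_kernel(m)
  expect_equal(K2[2, 3], stats::cor(m[2, ], m[3, ]), tolerance = 1e-12)
  expect_error(build_kernel(rbind(m, 1)), "zero-variance")
})

test_that("kernel ridge predictions match explicit matrix algebra and its limits", {
  with_seed(4, {
    Kfull <- stats::cor(matrix(stats::rnorm(5 * 50), 5))
  })
  y <- c(1.2, -0.4, 0.3, 0.8, -1.9)
  K_tr <- Kfull[1:4, 1:4]
  K_te <- Kfull[5, 1:4, drop = FALSE]
  lam <- 0.3
  pred <- krr_fit_predict(K_tr, y[1:4], K_te, lam)
  oracle <- K_te %*% solve(K_tr + diag(lam, 4)) %*% y[1:4]
  expect_lt(abs(pred - oracle), 1e-10)
  # huge penalty shrinks predictions to zero for centered targets
  yc <- y[1:4] - mean(y[1:4])
  expect_lt(abs(krr_fit_predict(K_tr, yc, K_te, 1e9)), 1e-6)
  # vanishing penalty interpolates the training data
  interp <- krr_fit_predict(K_tr, y[1:4], K_tr, 1e-10)
  expect_lt(max(abs(interp - y[1:4])), 1e-4)
})

test_that("the eigendecomposition ridge path equals the direct solve at every penalty", {
  fx <- krr_fixture(n = 30)
  K <- build_kernel(fx$feats)
  tr <- 1:20
  te <- 21:30
  eig <- eigen(K[tr, tr], symmetric = TRUE)
  grid <- krr_lambda_grid()
  path <- couplingbench:::krr_path(eig, fx$y[tr], K[te, tr, drop = FALSE], grid)
  for (l in seq_along(grid)) {
    expect_equal(
      path[, l],
      krr_fit_predict(K[tr, tr], fx$y[tr], K[te, tr, drop = FALSE], grid[l]),
      tolerance = 1e-10
    )
  }
})

test_that("family members always share an outer fold, across repetitions", {
  fx <- krr_fixture(n = 80)
  for (r in 1:5) {
    folds <- make_family_folds(fx$family, 5, 300 + r)
    per_fam <- tapply(folds, fx$family, function(v) length(unique(v)))
    expect_true(all(per_fam == 1))
  }
  # fold sizes stay balanced
  folds <- make_family_folds(fx$family, 5, 1)
  expect_lte(diff(range(table(folds))), 2)
})

test_that("an oversized family is placed alone with a message", {
  fam <- c(rep("big", 10), sprintf("s%02d", 1:10))
  expect_message(folds <- make_family_folds(fam, 5, 2), "placed alone")
  expect_equal(length(unique(folds[1:10])), 1)
})

test_that("nested CV recovers a planted effect and its accuracy is deterministic in the seed", {
  fx <- krr_fixture(n = 80, effect = 0.6)
  K <- build_kernel(fx$feats)
  res <- nested_cv_kernel(K, fx$y, fx$covars, fx$family,
    outer = 4, inner = 3, reps = 2, seed = 11
  )
  expect_gt(res$mean_accuracy, 0.2)
  res2 <- nested_cv_kernel(K, fx$y, fx$covars, fx$family,
    outer = 4, inner = 3, reps = 2, seed = 11
  )
  expect_identical(res$folds, res2$folds)
})

test_that("test predictions do not depend on test-subject behavior (anti-leakage)", {
  fx <- krr_fixture(n = 60)
  K <- build_kernel(fx$feats)
  folds <- make_family_folds(fx$family, 4, 9)
  te <- which(folds == 1)
  tr <- which(folds != 1)
  run_fold <- function(y_all) {
    resid <- residualize_behavior(y_all, fx$covars, tr, te)
    inner <- make_family_folds(fx$family[tr], 3, 10)
    grid <- krr_lambda_grid()
    acc <- matrix(NA_real_, 3, length(grid))
    for (g in 1:3) {
      iv <- tr[inner == g]
      it <- tr[inner != g]
      r_in <- residualize_behavior(y_all, fx$covars, it, iv)
      for (l in seq_along(grid)) {
        p <- krr_fit_predict(K[it, it], r_in$train, K[iv, it, drop = FALSE], grid[l])
        acc[g, l] <- stats::cor(r_in$test, p)
      }
    }
    lam <- grid[which.max(colMeans(acc))]
    krr_fit_predict(K[tr, tr], resid$train, K[te, tr, drop = FALSE], lam)
  }
  y_a <- fx$y
  y_b <- fx$y
  y_b[te] <- with_seed(12, stats::rnorm(length(te), 5, 3)) # corrupt test-fold behavior
  expect_identical(run_fold(y_a), run_fold(y_b))
})

test_that("family-blockwise permutation preserves the multiset and is seed-deterministic", {
  fx <- krr_fixture(n = 50)
  p1 <- permute_by_family(fx$y, fx$family, 21)
  p2 <- permute_by_family(fx$y, fx$family, 21)
  expect_identical(p1, p2)
  expect_equal(sort(p1), sort(fx$y))
  expect_false(identical(p1, fx$y))
})

test_that("the permutation test is deterministic and detects an extreme observation", {
  fx <- krr_fixture(n = 40)
  K <- build_kernel(fx$feats)
  pt <- permutation_test(K, fx$y, fx$covars, fx$family,
    observed = 0.999, n_perm = 19, outer = 4, inner = 3, seed = 31,
    lambda_grid = c(0.1, 10)
  )
  expect_equal(pt$p, 1 / 20)
  pt2 <- permutation_test(K, fx$y, fx$covars, fx$family,
    observed = 0.999, n_perm = 19, outer = 4, inner = 3, seed = 31,
    lambda_grid = c(0.1, 10)
  )
  expect_identical(pt$null_accuracies, pt2$null_accuracies)
})

test_that("Benjamini-Hochberg step-up reproduces hand-evaluated decisions", {
  # every p_(k) <= 0.01 k, so all five are rejected at q = 0.05
  flags <- fdr_bh(c(0.01, 0.02, 0.03, 0.04, 0.05), q = 0.05)
  expect_true(all(flags))
  expect_true(all(attr(flags, "q_values") >= c(0.01, 0.02, 0.03, 0.04, 0.05) - 1e-12))
  expect_false(any(fdr_bh(rep(1, 6), q = 0.05)))
  expect_true(fdr_bh(0.04, q = 0.05))
  expect_length(fdr_bh(numeric(0)), 0)
  # q-values never fall below their p-values
  p <- c(0.001, 0.2, 0.8, 0.04)
  expect_true(all(attr(fdr_bh(p), "q_values") >= p))
})
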