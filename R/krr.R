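# Behavioral prediction: correlation-kernel ridge regression with
# family-aware nested cross-validation, train-fold behavioral confound
# regression, permutation significance, and Benjamini-Hochberg FDR.

#' Family-blocked fold assignment
#'
#' Greedy bin-packing: families are shuffled (seeded), sorted by decreasing
#' size, and each assigned to the currently smallest fold, so all members of
#' a family always share a fold. A family larger than the target fold size is
#' placed alone with a logged imbalance message.
#'
#' @param family_id vector of family labels, one per subject.
#' @param n_folds number of folds.
#' @param seed integer seed.
#' @return integer vector of fold assignments (1..n_folds) per subject.
#' @export
make_family_folds <- function(family_id, n_folds, seed) {
  family_id <- as.character(family_id)
  fams <- unique(family_id)
  sizes <- table(family_id)[fams]
  target <- length(family_id) / n_folds
  with_seed(seed, {
    ord <- sample(length(fams))
    fams <- fams[ord]
    sizes <- sizes[ord]
    fams <- fams[order(-sizes)]
    sizes <- sort(sizes, decreasing = TRUE)
    fold_load <- rep(0, n_folds)
    fold_of_family <- integer(length(fams))
    for (k in seq_along(fams)) {
      if (sizes[k] > target) {
        message(sprintf(
          "family '%s' (size %d) exceeds the target fold size %.1f; placed alone",
          fams[k], sizes[k], target
        ))
      }
      f <- which.min(fold_load)
      fold_of_family[k] <- f
      fold_load[f] <- fold_load[f] + sizes[k]
    }
    names(fold_of_family) <- fams
    unname(fold_of_family[family_id])
  })
}

#' Train-fold behavioral confound regression
#'
#' OLS of the behavior on an intercept plus the covariates, fit on the
#' training rows only; residuals for both train and test rows use the
#' training coefficients (no leakage). Collinear covariate columns are
#' dropped with a warning.
#'
#' @param behavior numeric vector over all subjects.
#' @param covariates matrix/data.frame over all subjects (conventionally age,
#'   sex, mean FD).
#' @param train_index,test_index row indices.
#' @return list with `train`, `test` (residual vectors) and `coefficients`.
#' @export
residualize_behavior <- function(behavior, covariates, train_index, test_index) {
  X <- cbind(1, as.matrix(as.data.frame(covariates)))
  Xtr <- X[train_index, , drop = FALSE]
  qrX <- qr(Xtr)
  if (qrX$rank < ncol(Xtr)) {
    keep <- sort(qrX$pivot[seq_len(qrX$rank)])
    warning("dropping collinear covariate column(s) in behavior residualization")
    X <- X[, keep, drop = FALSE]
    Xtr <- X[train_index, , drop = FALSE]
    qrX <- qr(Xtr)
  }
  beta <- qr.coef(qrX, behavior[train_index])
  list(
    train = behavior[train_index] - as.numeric(Xtr %*% beta),
    test = behavior[test_index] - as.numeric(X[test_index, , drop = FALSE] %*% beta),
    coefficients = beta
  )
}

#' Correlation kernel between subjects' coupling features
#'
#' `K[i, j]` is the product-moment correlation between subject i's and
#' subject j's edge vectors; symmetric with unit diagonal.
#'
#' @param stack edge stack (list with `values`) or subjects x edges matrix.
#' @param subset optional subject-row subset.
#' @return subjects x subjects kernel matrix.
#' @export
build_kernel <- function(stack, subset = NULL) {
  vals <- if (is.list(stack)) stack$values else as.matrix(stack)
  if (!is.null(subset)) vals <- vals[subset, , drop = FALSE]
  stopifnot(nrow(vals) >= 2, ncol(vals) >= 2)
  sds <- apply(vals, 1, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf(
      "zero-variance feature vector for subject row(s): %s",
      paste(which(sds == 0), collapse = ", ")
    ))
  }
  K <- stats::cor(t(vals))
  diag(K) <- 1
  K
}

#' Kernel ridge fit-and-predict (closed form)
#'
#' `alpha = (K_train + lambda I)^{-1} y_train`; predictions are
#' `K_cross alpha`. An ill-conditioned solve (condition number above 1e12)
#' triggers a warning and a 1e-10 diagonal jitter.
#'
#' @param K_train train x train kernel.
#' @param y_train training targets.
#' @param K_cross test x train kernel block.
#' @param ridge_lambda L2 penalty (> 0).
#' @return numeric vector of predictions.
#' @export
krr_fit_predict <- function(K_train, y_train, K_cross, ridge_lambda) {
  stopifnot(ridge_lambda > 0)
  M <- K_train + diag(ridge_lambda, nrow(K_train))
  if (rcond(M) < 1e-12) {
    warning("ill-conditioned kernel solve; adding 1e-10 jitter")
    M <- M + diag(1e-10, nrow(M))
  }
  alpha <- solve(M, y_train)
  as.numeric(K_cross %*% alpha)
}

#' Multi-lambda KRR predictions via one eigendecomposition
#'
#' @param eig eigen decomposition of the train kernel.
#' @param y_train targets.
#' @param K_cross test x train block.
#' @param lambdas penalty grid.
#' @return test x lambda matrix of predictions.
#' @keywords internal
krr_path <- function(eig, y_train, K_cross, lambdas) {
  Vty <- crossprod(eig$vectors, y_train)
  KV <- K_cross %*% eig$vectors
  sapply(lambdas, function(l) as.numeric(KV %*% (Vty / (eig$values + l))))
}

#' Safe accuracy: correlation of true vs predicted
#'
#' @param y true values.
#' @param yhat predictions.
#' @return correlation, or 0 when either side has zero variance.
#' @keywords internal
safe_cor <- function(y, yhat) {
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0) return(0)
  stats::cor(y, yhat)
}

#' Default ridge-penalty grid
#'
#' 16 points log-spaced in \[1e-4, 1e4\].
#'
#' @return numeric vector.
#' @export
krr_lambda_grid <- function() {
  exp(seq(log(1e-4), log(1e4), length.out = 16))
}

#' Family-aware nested cross-validated KRR for one behavior
#'
#' Outer folds are family-blocked; within each outer training fold, the
#' behavior is residualized on the covariates with train-fold coefficients,
#' an inner family-blocked CV selects the ridge penalty by mean inner-fold
#' accuracy, the model is refit on the full training fold, and the outer-fold
#' accuracy is the correlation between true and predicted residualized
#' scores. Repeated with reshuffled folds.
#'
#' @param K subjects x subjects kernel (see [build_kernel()]).
#' @param behavior numeric behavior vector.
#' @param covariates covariate matrix/data.frame (age, sex, mean FD).
#' @param family_id family labels.
#' @param outer,inner fold counts.
#' @param reps number of repetitions (fold reshuffles).
#' @param lambda_grid ridge-penalty candidates.
#' @param seed integer seed; repetition r uses `seed + r`.
#' @return list with `folds` (data.frame: rep, fold, lambda, accuracy,
#'   n_test), `mean_accuracy`.
#' @export
nested_cv_kernel <- function(K, behavior, covariates, family_id,
                             outer = 20, inner = 20, reps = 20,
                             lambda_grid = krr_lambda_grid(), seed = 1) {
  n <- nrow(K)
  stopifnot(length(behavior) == n, n >= 2 * outer)
  rows <- list()
  for (r in seq_len(reps)) {
    fold_id <- make_family_folds(family_id, outer, seed + r)
    for (f in sort(unique(fold_id))) {
      te <- which(fold_id == f)
      tr <- which(fold_id != f)
      resid <- residualize_behavior(behavior, covariates, tr, te)
      y_tr <- resid$train
      y_te <- resid$test
      inner_id <- make_family_folds(family_id[tr], inner, seed + 1000L * r + f)
      acc_grid <- matrix(NA_real_, max(inner_id), length(lambda_grid))
      for (g in sort(unique(inner_id))) {
        iv <- tr[inner_id == g]
        it <- tr[inner_id != g]
        resid_in <- residualize_behavior(behavior, covariates, it, iv)
        eig_in <- eigen(K[it, it], symmetric = TRUE)
        preds <- krr_path(eig_in, resid_in$train, K[iv, it, drop = FALSE], lambda_grid)
        acc_grid[g, ] <- apply(preds, 2, safe_cor, y = resid_in$test)
      }
      lam <- lambda_grid[which.max(colMeans(acc_grid, na.rm = TRUE))]
      pred <- krr_fit_predict(K[tr, tr], y_tr, K[te, tr, drop = FALSE], lam)
      rows[[length(rows) + 1]] <- data.frame(
        rep = r, fold = f, lambda = lam,
        accuracy = safe_cor(y_te, pred), n_test = length(te)
      )
    }
  }
  folds <- do.call(rbind, rows)
  list(folds = folds, mean_accuracy = mean(folds$accuracy))
}

#' Nested-CV prediction across a behavior table
#'
#' Runs [nested_cv_kernel()] for every `beh_*` column of a behavior table
#' against one metric's edge stack.
#'
#' @param stack edge stack or subjects x edges matrix.
#' @param behavior_table data.frame with columns `age`, `sex`, `mean_fd`,
#'   `family_id`, and one or more `beh_*` behavior columns.
#' @param outer,inner,reps,lambda_grid,seed passed through.
#' @return list with `summary` (data.frame: behavior, mean_accuracy) and
#'   `folds` (long data.frame across behaviors).
#' @export
nested_cv <- function(stack, behavior_table, outer = 20, inner = 20, reps = 20,
                      lambda_grid = krr_lambda_grid(), seed = 1) {
  K <- build_kernel(stack)
  covars <- behavior_table[, c("age", "sex", "mean_fd")]
  beh_cols <- grep("^beh_", names(behavior_table), value = TRUE)
  stopifnot(length(beh_cols) >= 1)
  all_folds <- list()
  summary_rows <- list()
  for (b in beh_cols) {
    res <- nested_cv_kernel(
      K, behavior_table[[b]], covars, behavior_table$family_id,
      outer = outer, inner = inner, reps = reps,
      lambda_grid = lambda_grid, seed = seed
    )
    res$folds$behavior <- b
    all_folds[[b]] <- res$folds
    summary_rows[[b]] <- data.frame(behavior = b, mean_accuracy = res$mean_accuracy)
  }
  list(
    summary = do.call(rbind, summary_rows),
    folds = do.call(rbind, all_folds)
  )
}

#' Permutation significance of a prediction accuracy
#'
#' Permutes behavior across subjects blockwise by family (behavior vectors
#' are exchanged between families of equal size; covariates stay with their
#' subjects), reruns the full nested CV at a reduced inner/outer scheme per
#' permutation, and reports `p = (1 + #{null >= observed}) / (1 + n_perm)`.
#'
#' @param K subjects x subjects kernel.
#' @param behavior behavior vector.
#' @param covariates covariate matrix/data.frame.
#' @param family_id family labels.
#' @param observed observed mean accuracy to test.
#' @param n_perm number of permutations (>= 100 for reported analyses;
#'   smaller values are allowed for diagnostics).
#' @param outer,inner reduced fold counts for the null models.
#' @param lambda_grid ridge-penalty candidates.
#' @param seed integer seed.
#' @return list with `p`, `null_accuracies`.
#' @export
permutation_test <- function(K, behavior, covariates, family_id, observed,
                             n_perm = 1000, outer = 20, inner = 10,
                             lambda_grid = krr_lambda_grid(), seed = 1) {
  n <- length(behavior)
  null_acc <- numeric(n_perm)
  for (perm in seq_len(n_perm)) {
    b_perm <- permute_by_family(behavior, family_id, seed + perm)
    res <- nested_cv_kernel(
      K, b_perm, covariates, family_id,
      outer = outer, inner = inner, reps = 1,
      lambda_grid = lambda_grid, seed = seed
    )
    null_acc[perm] <- res$mean_accuracy
  }
  list(
    p = (1 + sum(null_acc >= observed)) / (1 + n_perm),
    null_accuracies = null_acc
  )
}

#' Family-blockwise permutation of a behavior vector
#'
#' Families of equal size exchange their (ordered) behavior blocks;
#' within-family order is preserved. Singleton families permute freely among
#' themselves.
#'
#' @param behavior numeric vector.
#' @param family_id family labels.
#' @param seed integer seed.
#' @return permuted behavior vector.
#' @export
permute_by_family <- function(behavior, family_id, seed) {
  family_id <- as.character(family_id)
  fams <- split(seq_along(behavior), family_id)
  sizes <- lengths(fams)
  out <- behavior
  with_seed(seed, {
    for (s in unique(sizes)) {
      group <- fams[sizes == s]
      if (length(group) < 2) next
      perm <- sample(length(group))
      donor <- group[perm]
      for (k in seq_along(group)) {
        out[group[[k]]] <- behavior[donor[[k]]]
      }
    }
  })
  out
}

#' Benjamini-Hochberg FDR rejection flags
#'
#' Step-up rule at level `q`: reject all ordered p-values up to the largest k
#' with `p_(k) <= k q / m` (computed via `p.adjust(p, "BH") <= q`).
#'
#' @param p_values p-values in \[0, 1\].
#' @param q FDR level.
#' @return logical rejection vector (empty input gives empty output); the
#'   adjusted q-values are attached as attribute `q_values`.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (length(p_values) == 0) {
    return(structure(logical(0), q_values = numeric(0)))
  }
  stopifnot(all(p_values >= 0 & p_values <= 1))
  q_values <- stats::p.adjust(p_values, method = "BH")
  structure(q_values <= q, q_values = q_values)
}
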