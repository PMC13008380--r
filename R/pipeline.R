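# End-to-end orchestration: generate -> prep -> estimate -> harmonize ->
# QC -> predict from a single config list, with content-hash caching and a
# benchmark report ranking metrics on the three evaluation axes (QC-FC
# mean/variance, distance dependence, prediction accuracy).

#' Canonical metric ordering by estimator family
#'
#' Correlation, partial correlation, mutual information, coherence,
#' information decomposition, then the three rDCM views.
#'
#' @return character vector of the 13 metric names.
#' @export
metric_order <- function() {
  c(
    "pearson", "spearman", "partial", "glasso", "mi_time", "mi_freq",
    "coh_spectral", "coh_wavelet", "redundancy", "synergy",
    "rdcm_full", "rdcm_in", "rdcm_out"
  )
}

#' Estimate coupling stacks for a cohort
#'
#' Runs the requested estimators on every subject's series and stacks the
#' results into subjects x edges matrices. The three rDCM views share one
#' model inversion; redundancy and synergy share one decomposition; the
#' frequency-domain MI reuses the wavelet coherence spectrum.
#'
#' @param series_list list of `parcellated_ts`.
#' @param metrics subset of [metric_order()].
#' @param glasso_lambda penalty for the `glasso` metric; if `NULL` it is
#'   selected by [select_lambda()] on a subset of up to 20 subjects.
#' @param band frequency band for spectral metrics, Hz.
#' @return named list of edge stacks (see [stack_cohort()]); the `glasso`
#'   stack additionally carries `nonzero_counts` and `lambda`.
#' @export
estimate_cohort <- function(series_list, metrics = metric_order(),
                            glasso_lambda = NULL, band = c(0.008, 0.08)) {
  stopifnot(all(metrics %in% metric_order()))
  out <- list()
  n_sub <- length(series_list)
  want_rdcm <- any(c("rdcm_full", "rdcm_in", "rdcm_out") %in% metrics)
  want_phiid <- any(c("redundancy", "synergy") %in% metrics)
  want_wavelet <- any(c("coh_wavelet", "mi_freq") %in% metrics)
  if ("glasso" %in% metrics && is.null(glasso_lambda)) {
    subset <- series_list[seq_len(min(20, n_sub))]
    glasso_lambda <- select_lambda(subset)$lambda
  }
  per_subject <- lapply(series_list, function(ts) {
    res <- list()
    if ("pearson" %in% metrics) res$pearson <- pearson_fc(ts)
    if ("spearman" %in% metrics) res$spearman <- spearman_fc(ts)
    if ("partial" %in% metrics) res$partial <- partial_corr_fc(ts)
    if ("glasso" %in% metrics) {
      g <- glasso_fc(ts, glasso_lambda)
      res$glasso <- g$fc
      attr(res$glasso, "nonzero_edge_count") <- g$fit$nonzero_edge_count
    }
    if ("mi_time" %in% metrics) res$mi_time <- mi_time_fc(ts)
    if ("coh_spectral" %in% metrics) res$coh_spectral <- spectral_coherence_fc(ts, band)
    if (want_wavelet) {
      wc <- wavelet_coherence(ts, band)
      if ("coh_wavelet" %in% metrics) {
        in_band <- wc$frequencies >= band[1] & wc$frequencies <= band[2]
        fc <- apply(wc$coherence[in_band, , , drop = FALSE], c(2, 3), mean)
        diag(fc) <- NA_real_
        res$coh_wavelet <- coupling_matrix(fc, "coh_wavelet", ts$subject_id)
      }
      if ("mi_freq" %in% metrics) {
        res$mi_freq <- mi_frequency_fc(wc, band, subject_id = ts$subject_id)
      }
    }
    if (want_phiid) {
      ph <- phiid_components_fc(ts)
      if ("redundancy" %in% metrics) res$redundancy <- ph$redundancy
      if ("synergy" %in% metrics) res$synergy <- ph$synergy
    }
    if (want_rdcm) {
      post <- rdcm_invert(build_rdcm_design(ts))
      views <- extract_ec_views(post)
      res$rdcm <- list(A = post$A, views = views)
    }
    res
  })
  for (m in intersect(metrics, c(
    "pearson", "spearman", "partial", "glasso", "mi_time", "mi_freq",
    "coh_spectral", "coh_wavelet", "redundancy", "synergy"
  ))) {
    out[[m]] <- stack_cohort(lapply(per_subject, `[[`, m))
    if (m == "glasso") {
      out[[m]]$nonzero_counts <- vapply(
        per_subject, function(r) attr(r$glasso, "nonzero_edge_count"), numeric(1)
      )
      out[[m]]$lambda <- glasso_lambda
    }
  }
  if (want_rdcm) {
    n_reg <- ncol(series_list[[1]]$data)
    subjects <- vapply(series_list, `[[`, "", "subject_id")
    for (view in c("full", "incoming", "outgoing")) {
      key <- c(full = "rdcm_full", incoming = "rdcm_in", outgoing = "rdcm_out")[[view]]
      if (!key %in% metrics) next
      vals <- do.call(rbind, lapply(per_subject, function(r) r$rdcm$views[[view]]))
      rownames(vals) <- subjects
      out[[key]] <- list(
        values = vals,
        edge_index = attr(per_subject[[1]]$rdcm$views[[view]], "edge_index"),
        metric_name = key, subjects = subjects
      )
    }
  }
  out[metric_order()[metric_order() %in% names(out)]]
}

#' Parcellated-level preprocessing for a cohort
#'
#' Per subject: 24-parameter motion regression (plus a surrogate global
#' signal, the cross-region mean, when `global_signal`), rectangular
#' bandpass, respiratory-notched FD, and optionally the three-rule
#' exclusions.
#'
#' @param series_list list of `parcellated_ts`.
#' @param motion_list matching list of `motion_trace`.
#' @param bandpass two-element passband, Hz.
#' @param notch_band respiratory band removed from motion before FD, Hz.
#' @param global_signal include the surrogate global signal as a confound?
#' @param exclusion `"strict"` applies the three rules; `"none"` retains all.
#' @return list with `series` (processed, retained subjects), `fd`
#'   (notch-filtered `fd_trace` list), `mean_fd`, `exclusions` (full report),
#'   `retained` (indices into the input lists).
#' @export
prep_cohort <- function(series_list, motion_list, bandpass = c(0.008, 0.08),
                        notch_band = c(0.31, 0.43), global_signal = TRUE,
                        exclusion = c("strict", "none")) {
  exclusion <- match.arg(exclusion)
  stopifnot(length(series_list) == length(motion_list))
  fd <- lapply(motion_list, compute_fd, notch_band = notch_band, apply_notch = TRUE)
  report <- apply_exclusions(fd)
  retained <- if (exclusion == "strict") which(!report$excluded) else seq_along(series_list)
  if (length(retained) == 0) stop("all subjects excluded by motion criteria")
  proc <- lapply(retained, function(s) {
    conf <- motion_params24(motion_list[[s]])
    if (global_signal) conf <- cbind(conf, gs = rowMeans(series_list[[s]]$data))
    bandpass_rectangular(
      regress_confounds(series_list[[s]], conf),
      bandpass[1], bandpass[2]
    )
  })
  list(
    series = proc, fd = fd[retained],
    mean_fd = vapply(fd[retained], function(tr) mean(tr$fd_mm), numeric(1)),
    exclusions = report, retained = retained
  )
}

#' Run the full benchmark pipeline from one config
#'
#' Stages (in order): cohort generation, preprocessing, estimation,
#' harmonization (multi-site only), QC-FC, prediction, report. Stage outputs
#' are cached under `out_dir/cache` keyed by the md5 of the config content
#' that feeds the stage, so rerunning an identical config is a full cache
#' hit with byte-identical outputs.
#'
#' @param config list with elements `cohort` (arguments to [cohort_spec()]),
#'   `metrics`, `prep` (`exclusion`, `global_signal`), `harmonize` (logical),
#'   `predict` (`outer`, `inner`, `reps`, `seed`; `NULL` skips prediction),
#'   `out_dir`, `seed`.
#' @return list of class `pipeline_run`: `qc` (per-metric data.frame),
#'   `prediction` (per metric x behavior), `similarity`, `manifest`
#'   (stage cache keys and output files).
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$out_dir))
  dir.create(file.path(config$out_dir, "cache"), recursive = TRUE, showWarnings = FALSE)
  metrics <- config$metrics %||% metric_order()
  seed <- config$seed %||% 1L
  cache <- function(key_obj, tag, fn) {
    key <- substr(content_hash(key_obj), 1, 16)
    path <- file.path(config$out_dir, "cache", sprintf("%s-%s.rds", tag, key))
    if (file.exists(path)) {
      return(list(value = readRDS(path), hit = TRUE, key = key))
    }
    value <- fn()
    saveRDS(value, path, version = 2)
    list(value = value, hit = FALSE, key = key)
  }
  manifest <- list()

  st <- cache(list(config$cohort, seed), "cohort", function() {
    spec <- do.call(cohort_spec, c(config$cohort, list(rng_seed = seed)))
    simulate_cohort(spec)
  })
  cohort <- st$value
  manifest$cohort <- list(key = st$key, cache_hit = st$hit)

  st <- cache(list(config$cohort, config$prep, seed), "prep", function() {
    do.call(prep_cohort, c(
      list(cohort$series, cohort$motion),
      config$prep %||% list()
    ))
  })
  prep <- st$value
  manifest$prep <- list(key = st$key, cache_hit = st$hit, retained = length(prep$retained))

  st <- cache(list(config$cohort, config$prep, metrics, seed), "estimate", function() {
    estimate_cohort(prep$series, metrics)
  })
  stacks <- st$value
  manifest$estimate <- list(key = st$key, cache_hit = st$hit)

  behavior <- cohort$behavior[prep$retained, , drop = FALSE]
  behavior$mean_fd <- prep$mean_fd
  harmonize <- isTRUE(config$harmonize) && length(unique(behavior$site)) > 1
  if (harmonize) {
    st <- cache(list(manifest$estimate$key, "combat"), "harmonize", function() {
      lapply(stacks, function(stk) {
        combat_fit_transform(
          stk, behavior$site,
          covariates = data.frame(
            age = behavior$age - mean(behavior$age), sex = behavior$sex
          )
        )
      })
    })
    stacks <- st$value
    manifest$harmonize <- list(key = st$key, cache_hit = st$hit)
  }

  centroids <- cohort$network$centroids
  qc_rows <- lapply(names(stacks), function(m) {
    stk <- stacks[[m]]
    qr <- qcfc_correlations(stk, behavior$mean_fd)
    dvec <- if (ncol(stk$values) == nrow(edge_index(nrow(centroids)))) {
      edge_distances(centroids)
    } else {
      d <- as.matrix(stats::dist(centroids))
      d[cbind(stk$edge_index$i, stk$edge_index$j)]
    }
    dd <- distance_dependence(qr, dvec)
    data.frame(
      metric = m, qcfc_mu = qr$mu, qcfc_sigma2 = qr$sigma2,
      distance_rho = dd$rho, n_edges = ncol(stk$values)
    )
  })
  qc <- do.call(rbind, qc_rows)

  prediction <- NULL
  if (!is.null(config$predict)) {
    ps <- config$predict
    st <- cache(list(manifest$estimate$key, harmonize, ps), "predict", function() {
      rows <- lapply(names(stacks), function(m) {
        res <- nested_cv(
          stacks[[m]], behavior,
          outer = ps$outer %||% 20, inner = ps$inner %||% 20,
          reps = ps$reps %||% 20, seed = ps$seed %||% seed
        )
        res$summary$metric <- m
        res$summary
      })
      do.call(rbind, rows)
    })
    prediction <- st$value
    manifest$predict <- list(key = st$key, cache_hit = st$hit)
  }

  similarity <- NULL
  if (length(stacks) >= 2) {
    n_reg <- nrow(centroids)
    means <- lapply(names(stacks), function(m) {
      stk <- stacks[[m]]
      if (ncol(stk$values) == nrow(edge_index(n_reg))) {
        colMeans(stk$values)
      } else if (ncol(stk$values) == nrow(edge_index_directed(n_reg))) {
        colMeans(directed_to_undirected_stack(stk, n_reg))
      } else {
        NULL # triangle EC views are not comparable on the undirected index
      }
    })
    names(means) <- names(stacks)
    means <- means[!vapply(means, is.null, logical(1))]
    if (length(means) >= 2) similarity <- metric_similarity(means)
  }

  run <- structure(
    list(
      qc = qc, prediction = prediction, similarity = similarity,
      manifest = manifest, metrics = names(stacks)
    ),
    class = "pipeline_run"
  )
  write_report(run, config$out_dir)
  run
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' md5 content hash of an arbitrary R object
#'
#' Serializes (format version 2, so the hash is stable across sessions) to a
#' temporary file and hashes it.
#'
#' @param obj any serializable object.
#' @return md5 hex string.
#' @keywords internal
content_hash <- function(obj) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(serialize(obj, NULL, version = 2), tmp)
  as.character(tools::md5sum(tmp))
}

#' Write the benchmark report tables
#'
#' Emits `qc_report.csv` (metrics ordered by estimator family, with QC-FC
#' mean, population variance and distance dependence), `prediction_report.csv`
#' when prediction ran, and `metric_similarity.csv` with the average-linkage
#' ordering. Regeneration from the same results is deterministic.
#'
#' @param run a `pipeline_run`.
#' @param out_dir output directory.
#' @return character vector of written file paths (invisibly).
#' @export
write_report <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  ord <- metric_order()
  qc <- run$qc[order(match(run$qc$metric, ord)), , drop = FALSE]
  path <- file.path(out_dir, "qc_report.csv")
  utils::write.csv(qc, path, row.names = FALSE)
  written <- c(written, path)
  if (!is.null(run$prediction)) {
    pred <- run$prediction[order(match(run$prediction$metric, ord)), , drop = FALSE]
    path <- file.path(out_dir, "prediction_report.csv")
    utils::write.csv(pred, path, row.names = FALSE)
    written <- c(written, path)
  }
  if (!is.null(run$similarity)) {
    sim <- run$similarity$similarity
    sim_ord <- run$similarity$order
    path <- file.path(out_dir, "metric_similarity.csv")
    utils::write.csv(
      data.frame(metric = rownames(sim)[sim_ord], sim[sim_ord, sim_ord]),
      path, row.names = FALSE
    )
    written <- c(written, path)
  }
  invisible(written)
}
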