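# Behavior synthesis: each behavior is a standardized weighted edge score
# scaled to a target population correlation, plus noise carrying a
# family-level random intercept and optional loadings on age, sex and mean FD
# (so confound-regression stages have real signal to remove).

#' Generate behaviors tied to coupling features
#'
#' For behavior b: `score = standardize(features %*% w_b)`;
#' `behavior = r * score + sqrt(1 - r^2) * eps` with
#' `eps = family intercept (variance = family_icc) + individual noise
#' (variance = 1 - family_icc)`; covariate loadings are then added on the
#' standardized covariates.
#'
#' @param features subjects x edges coupling feature matrix.
#' @param behavior_weights edges x n_behaviors weight matrix (or a vector for
#'   one behavior).
#' @param behavior_effect_r target population correlation in \[0, 0.9\] between
#'   each behavior and its generating edge score (before covariate loadings).
#' @param covariates data.frame with `age`, `sex`, `mean_fd`, `family_id`,
#'   `site`, `subject_id` (one row per subject).
#' @param rng_seed integer seed.
#' @param covariate_loadings named vector `c(age=, sex=, fd=)` of loadings on
#'   the standardized covariates; default all zero.
#' @param family_icc intraclass correlation of the noise within families.
#' @return data.frame: `subject_id`, `site`, `family_id`, `age`, `sex`,
#'   `mean_fd`, then `beh_1..beh_k`; the generating scores are attached as
#'   attribute `edge_scores`.
#' @export
generate_behavior <- function(features, behavior_weights, behavior_effect_r,
                              covariates, rng_seed,
                              covariate_loadings = c(age = 0, sex = 0, fd = 0),
                              family_icc = 0.3) {
  stopifnot(behavior_effect_r >= 0, behavior_effect_r < 1,
            family_icc >= 0, family_icc < 1)
  W <- as.matrix(behavior_weights)
  stopifnot(nrow(W) == ncol(features))
  n <- nrow(features)
  stopifnot(nrow(covariates) == n)
  scores <- scale(features %*% W)
  r <- behavior_effect_r
  fam <- as.character(covariates$family_id)
  fam_levels <- unique(fam)
  with_seed(rng_seed, {
    beh <- sapply(seq_len(ncol(W)), function(b) {
      u <- stats::rnorm(length(fam_levels), 0, sqrt(family_icc))
      names(u) <- fam_levels
      eps <- u[fam] + stats::rnorm(n, 0, sqrt(1 - family_icc))
      y <- r * scores[, b] + sqrt(1 - r^2) * eps
      std0 <- function(v) {
        s <- stats::sd(v)
        if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
      }
      y +
        covariate_loadings[["age"]] * std0(covariates$age) +
        covariate_loadings[["sex"]] * std0(covariates$sex) +
        covariate_loadings[["fd"]] * std0(covariates$mean_fd)
    })
    colnames(beh) <- sprintf("beh_%d", seq_len(ncol(W)))
    out <- cbind(
      covariates[, c("subject_id", "site", "family_id", "age", "sex", "mean_fd")],
      as.data.frame(beh)
    )
    rownames(out) <- NULL
    attr(out, "edge_scores") <- scores
    out
  })
}

#' Specification of a synthetic cohort
#'
#' Validates and fills the parameters that define the study conditions the
#' generator emulates: ~subject-varying head motion with a respiratory band,
#' distance-dependent motion contamination of edges, multi-site offsets,
#' family clustering, and behaviors correlated with coupling features at
#' small effect sizes.
#'
#' @param n_subjects number of subjects.
#' @param n_regions number of regions (>= 3).
#' @param n_frames frames per subject (>= 64).
#' @param tr_s repetition time, seconds.
#' @param n_sites number of acquisition sites.
#' @param family_sizes integer vector summing to `n_subjects`; default is a
#'   realistic mixture of two-member families (~40% of subjects) and
#'   singletons.
#' @param motion_severity_range per-subject unfiltered mean-FD range, mm.
#' @param artifact_gain coupling-contamination strength (0 = clean).
#' @param artifact_distance_scale e-folding length of the distance-dependent
#'   contamination, mm.
#' @param behavior_effect_r target behavior/edge-score correlation.
#' @param site_offset_sd site edge-offset scale (0 = no site effects).
#' @param edge_density density of true off-diagonal couplings.
#' @param n_behaviors number of planted behaviors.
#' @param rng_seed integer seed.
#' @return validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, n_regions = 30, n_frames = 400, tr_s = 0.8,
                        n_sites = 1, family_sizes = NULL,
                        motion_severity_range = c(0.05, 0.35),
                        artifact_gain = 0, artifact_distance_scale = 40,
                        behavior_effect_r = 0.15, site_offset_sd = 0,
                        edge_density = 0.1, n_behaviors = 3, rng_seed = 1) {
  stopifnot(
    n_regions >= 3, n_frames >= 64, n_subjects >= 1,
    behavior_effect_r >= 0, behavior_effect_r <= 0.9,
    artifact_gain >= 0, site_offset_sd >= 0, n_sites >= 1
  )
  if (is.null(family_sizes)) {
    n_pairs <- floor(0.2 * n_subjects)
    family_sizes <- c(rep(2L, n_pairs), rep(1L, n_subjects - 2L * n_pairs))
  }
  if (sum(family_sizes) != n_subjects) {
    stop("family_sizes must sum to n_subjects")
  }
  structure(
    list(
      n_subjects = n_subjects, n_regions = n_regions, n_frames = n_frames,
      tr_s = tr_s, n_sites = n_sites, family_sizes = as.integer(family_sizes),
      motion_severity_range = motion_severity_range,
      artifact_gain = artifact_gain,
      artifact_distance_scale = artifact_distance_scale,
      behavior_effect_r = behavior_effect_r, site_offset_sd = site_offset_sd,
      edge_density = edge_density, n_behaviors = n_behaviors,
      rng_seed = as.integer(rng_seed)
    ),
    class = "cohort_spec"
  )
}

#' Simulate a full multi-subject cohort
#'
#' Draws one ground-truth network, gives every subject a mild coupling-gain
#' perturbation (so coupling genuinely varies across subjects), simulates
#' BOLD-like series and head motion, contaminates the series with
#' distance-dependent motion artifact, plants site offsets as site-specific
#' shared-signal loadings, and synthesizes behaviors from the subjects'
#' clean-series Pearson edge features.
#'
#' @param spec a `cohort_spec`.
#' @param covariate_loadings passed to [generate_behavior()]; default plants
#'   modest age/sex/FD loadings so confound regression matters.
#' @return list of class `synthetic_cohort`: `spec`, `network`,
#'   `ground_truth` (susceptibility, behavior weights, per-subject severities
#'   and gains), `series` (list of contaminated `parcellated_ts`), `motion`
#'   (list of `motion_trace`), `fd` (list of unfiltered `fd_trace`),
#'   `behavior` (data.frame; `mean_fd` is the notch-filtered mean FD), and
#'   `clean_features` (subjects x edges Pearson-z edges of the uncontaminated
#'   series).
#' @export
simulate_cohort <- function(spec,
                            covariate_loadings = c(age = 0.15, sex = 0.15, fd = 0.2)) {
  stopifnot(inherits(spec, "cohort_spec"))
  base <- spec$rng_seed
  network <- make_true_network(spec$n_regions, spec$edge_density, base)
  suscept <- susceptibility_from_distance(
    network$centroids, spec$artifact_distance_scale
  )
  n <- spec$n_subjects
  ids <- sprintf("sub-%04d", seq_len(n))
  family_id <- rep(sprintf("fam-%04d", seq_along(spec$family_sizes)),
    times = spec$family_sizes
  )
  # whole families share a site; families dealt to sites round-robin
  fam_site <- rep_len(sprintf("site-%02d", seq_len(spec$n_sites)),
    length(spec$family_sizes)
  )
  site <- rep(fam_site, times = spec$family_sizes)
  meta <- with_seed(base + 1L, {
    data.frame(
      subject_id = ids, site = site, family_id = family_id,
      age = stats::runif(n, 22, 36),
      sex = stats::rbinom(n, 1, 0.5),
      severity = stats::runif(
        n, spec$motion_severity_range[1], spec$motion_severity_range[2]
      ),
      gain = stats::runif(n, 0.6, 1.4),
      stringsAsFactors = FALSE
    )
  })
  site_loadings <- with_seed(base + 2L, {
    matrix(stats::rnorm(spec$n_sites * spec$n_regions), spec$n_sites,
      dimnames = list(sprintf("site-%02d", seq_len(spec$n_sites)), NULL)
    )
  })
  A0 <- network$coupling_coefficients
  off <- row(A0) != col(A0)
  series <- vector("list", n)
  motion <- vector("list", n)
  fd_raw <- vector("list", n)
  mean_fd_notched <- numeric(n)
  clean_features <- matrix(NA_real_, n, spec$n_regions * (spec$n_regions - 1) / 2)
  for (s in seq_len(n)) {
    net_s <- network
    net_s$coupling_coefficients[off] <- A0[off] * meta$gain[s]
    rho <- max(Mod(eigen(net_s$coupling_coefficients, only.values = TRUE)$values))
    if (rho >= 0.98) {
      net_s$coupling_coefficients <- net_s$coupling_coefficients * (0.95 / rho)
    }
    clean <- simulate_subject_series(
      net_s, spec$n_frames, spec$tr_s,
      rng_seed = base + 100L + s, subject_id = ids[s]
    )
    clean_features[s, ] <- lower_edges(pearson_fc(clean, fisher_z = TRUE))
    motion[[s]] <- simulate_motion(
      spec$n_frames, spec$tr_s, meta$severity[s],
      rng_seed = base + 20000L + s, subject_id = ids[s]
    )
    fd_raw[[s]] <- compute_fd(motion[[s]], apply_notch = FALSE)
    mean_fd_notched[s] <- mean(compute_fd(motion[[s]], apply_notch = TRUE)$fd_mm)
    contaminated <- inject_motion_artifact(
      clean, fd_raw[[s]], suscept, spec$artifact_gain
    )
    if (spec$site_offset_sd > 0 && spec$n_sites > 1) {
      shared <- with_seed(base + 40000L + s, stats::rnorm(spec$n_frames))
      contaminated <- parcellated_ts(
        contaminated$data +
          spec$site_offset_sd * outer(shared, site_loadings[meta$site[s], ]),
        spec$tr_s, ids[s]
      )
    }
    series[[s]] <- contaminated
  }
  weights <- with_seed(base + 3L, {
    n_edges <- ncol(clean_features)
    # load behaviors on the edges that genuinely vary across subjects (the
    # gain-modulated true couplings), so the planted effect is identifiable
    n_sig <- max(2, round(0.1 * n_edges))
    signal_pool <- order(-apply(clean_features, 2, stats::var))[seq_len(2 * n_sig)]
    W <- matrix(0, n_edges, spec$n_behaviors)
    for (b in seq_len(spec$n_behaviors)) {
      sel <- sample(signal_pool, n_sig)
      W[sel, b] <- stats::rnorm(length(sel))
    }
    W
  })
  covars <- meta[, c("subject_id", "site", "family_id", "age", "sex")]
  covars$mean_fd <- mean_fd_notched
  behavior <- generate_behavior(
    clean_features, weights, spec$behavior_effect_r, covars,
    rng_seed = base + 4L, covariate_loadings = covariate_loadings
  )
  structure(
    list(
      spec = spec, network = network,
      ground_truth = list(
        edge_susceptibility = suscept,
        behavior_weights = weights,
        per_subject_motion_severity = meta$severity,
        per_subject_gain = meta$gain,
        site_loadings = site_loadings
      ),
      series = series, motion = motion, fd = fd_raw,
      behavior = behavior, clean_features = clean_features
    ),
    class = "synthetic_cohort"
  )
}
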