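test_that("true networks are stable and their stationary covariance solves the Lyapunov equation", {
  net <- make_true_network(6, 0.3, 42)
  A <- net$coupling_coefficients
  Q <- net$innovation_covariance
  expect_lt(max(Mod(eigen(A, only.values = TRUE)$values)), 1)
  expect_true(all(eigen(Q, symmetric = TRUE, only.values = TRUE)$values > 0))
  S <- stationary_covariance(A, Q)
  expect_lt(max(abs(S - (A %*% S %*% t(A) + Q))), 1e-8)
  # independent oracle: Kronecker vec solve
  expect_lt(max(abs(S - lyapunov_kron(A, Q))), 1e-8)
  expect_true(all(eigen(S, symmetric = TRUE, only.values = TRUE)$values > 0))
})

test_that("zero edge density gives diagonal-only coupling and diagonal stationary structure", {
  net <- make_true_network(5, 0, 1)
  A <- net$coupling_coefficients
  expect_true(all(A[row(A) != col(A)] == 0))
})

test_that("network generation and subject simulation are deterministic in the seed", {
  expect_identical(make_true_network(5, 0.4, 9), make_true_network(5, 0.4, 9))
  net <- fixture_network()
  expect_identical(
    simulate_subject_series(net, 100, 0.8, 3)$data,
    simulate_subject_series(net, 100, 0.8, 3)$data
  )
})

test_that("zero innovation covariance and zero noise give a constant series", {
  net <- fixture_network()
  net$innovation_covariance <- matrix(0, 5, 5)
  ts <- simulate_subject_series(net, 100, 0.8, 1, noise_sd = 0)
  expect_equal(max(abs(ts$data)), 0)
})

test_that("an unstable network is rejected", {
  net <- fixture_network()
  net$coupling_coefficients <- diag(1.05, 5)
  expect_error(simulate_subject_series(net, 100, 0.8, 1), "unstable")
})

test_that("a planted directed coupling leaves its sign in the lagged cross-correlation", {
  # 3-region system with one strong positive coupling 1 -> 2
  net <- make_true_network(3, 0, 5)
  net$coupling_coefficients[2, 1] <- 0.7
  net$innovation_covariance <- diag(3)
  hits <- vapply(seq_len(60), function(r) {
    ts <- simulate_subject_series(net, 2000, 0.8, 500 + r, noise_sd = 0.2)
    x <- ts$data
    n <- nrow(x)
    sign(stats::cor(x[-n, 1], x[-1, 2])) == 1
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("the simulated latent process matches the Lyapunov stationary covariance", {
  net <- make_true_network(4, 0.3, 77)
  S_true <- stationary_covariance(
    net$coupling_coefficients, net$innovation_covariance
  )
  acc <- matrix(0, 4, 4)
  reps <- 100
  for (r in seq_len(reps)) {
    ts <- simulate_subject_series(net, 400, 0.8, 9000 + r,
      noise_sd = 0, hrf = FALSE
    )
    acc <- acc + stats::cov(ts$data)
  }
  emp <- acc / reps
  expect_lt(max(abs(emp - S_true) / max(abs(S_true))), 0.05)
})

test_that("motion traces hit the target severity and carry the respiratory band", {
  mo <- simulate_motion(1000, 0.8, 0.3, 11)
  fd <- compute_fd(mo, apply_notch = FALSE)
  expect_lt(abs(mean(fd$fd_mm) - 0.3) / 0.3, 0.2)
  # periodogram of the x-translation peaks inside 0.31-0.43 Hz
  sp <- stats::spec.pgram(stats::ts(mo$params[, 1], frequency = 1 / 0.8),
    plot = FALSE, taper = 0, detrend = TRUE
  )
  band <- sp$freq >= 0.25 & sp$freq <= 0.5
  f_peak <- sp$freq[band][which.max(sp$spec[band])]
  expect_gte(f_peak, 0.31)
  expect_lte(f_peak, 0.43)
})

test_that("zero severity yields identically zero motion and FD", {
  mo <- simulate_motion(100, 0.8, 0, 1)
  expect_equal(max(abs(mo$params)), 0)
  expect_equal(max(compute_fd(mo, apply_notch = FALSE)$fd_mm), 0)
})

test_that("artifact injection is the identity at zero gain or zero susceptibility", {
  ts <- fixture_series(100)
  fd <- compute_fd(simulate_motion(100, 0.8, 0.3, 2), apply_notch = FALSE)
  sus <- susceptibility_from_distance(fixture_network()$centroids, 40)
  expect_identical(inject_motion_artifact(ts, fd, sus, 0)$data, ts$data)
  expect_identical(
    inject_motion_artifact(ts, fd, matrix(0, 5, 5), 2)$data, ts$data
  )
  expect_error(
    inject_motion_artifact(ts, fd$fd_mm[-1], sus, 1),
    "length"
  )
})

test_that("behavior generation hits the planted effect size and respects the null", {
  n <- 2000
  with_seed(31, {
    features <- matrix(stats::rnorm(n * 40), n)
  })
  covars <- data.frame(
    subject_id = sprintf("s%04d", 1:n),
    site = "site-01",
    family_id = sprintf("f%04d", 1:n),
    age = rep(30, n), sex = rep(0, n), mean_fd = rep(0.1, n)
  )
  w <- c(rep(1, 10), rep(0, 30))
  beh <- generate_behavior(features, w, 0.5, covars, 3)
  score <- attr(beh, "edge_scores")[, 1]
  expect_lt(abs(stats::cor(beh$beh_1, score) - 0.5), 0.05)
  beh0 <- generate_behavior(features, w, 0, covars, 4)
  expect_lt(abs(stats::cor(beh0$beh_1, attr(beh0, "edge_scores")[, 1])),
            3 / sqrt(n))
  expect_identical(
    generate_behavior(features, w, 0.3, covars, 5)$beh_1,
    generate_behavior(features, w, 0.3, covars, 5)$beh_1
  )
})

test_that("identical cohort specs give bit-identical cohorts", {
  spec <- cohort_spec(n_subjects = 6, n_regions = 6, n_frames = 80, rng_seed = 8)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(lapply(a$series, `[[`, "data"), lapply(b$series, `[[`, "data"))
  expect_identical(a$behavior, b$behavior)
})

test_that("cohort spec validates its invariants", {
  expect_error(cohort_spec(10, n_regions = 2), "n_regions")
  expect_error(cohort_spec(10, n_frames = 32), "n_frames")
  expect_error(cohort_spec(10, behavior_effect_r = 0.95), "behavior_effect_r")
  expect_error(cohort_spec(10, family_sizes = c(4, 4)), "sum")
})

test_that("written cohorts round-trip bit-exactly with a complete, tamper-evident manifest", {
  spec <- cohort_spec(n_subjects = 3, n_regions = 5, n_frames = 70, rng_seed = 13)
  coh <- simulate_cohort(spec)
  dir <- withr::local_tempdir()
  man <- write_cohort(coh, dir)
  expect_length(man$files, 3 * 2 + 3)
  back <- read_cohort(dir)
  for (s in 1:3) {
    expect_identical(unname(back$series[[s]]$data), unname(coh$series[[s]]$data))
    expect_identical(unname(back$motion[[s]]$params), unname(coh$motion[[s]]$params))
  }
  expect_identical(back$behavior$beh_1, coh$behavior$beh_1)
  expect_identical(unname(back$centroids), unname(coh$network$centroids))
  # tampering with any file is detected
  f <- file.path(dir, "behavior.csv")
  writeLines(c(readLines(f), "tampered"), f)
  expect_error(read_cohort(dir), "checksum mismatch")
})
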