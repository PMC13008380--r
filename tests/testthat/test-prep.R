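test_that("confound regression produces residuals orthogonal to the confounds", {
  ts <- fixture_series(120)
  # intercept only -> demeaning
  dem <- regress_confounds(ts)
  expect_equal(unname(dem$data),
    unname(sweep(ts$data, 2, colMeans(ts$data))),
    tolerance = 1e-12
  )
  # series equal to a confound column -> zero residual
  conf <- with_seed(2, matrix(stats::rnorm(120 * 2), 120))
  ts2 <- parcellated_ts(cbind(conf[, 1], ts$data[, 1]), 0.8)
  res2 <- regress_confounds(ts2, conf)
  expect_lt(max(abs(res2$data[, 1])), 1e-10)
  # 24-parameter expansion: orthogonality of residuals to all columns
  mo <- simulate_motion(120, 0.8, 0.2, 4)
  X24 <- motion_params24(mo)
  expect_equal(ncol(X24), 24)
  res <- regress_confounds(ts, X24)
  ip <- crossprod(X24, res$data)
  norms <- outer(sqrt(colSums(X24^2)), sqrt(colSums(res$data^2)))
  expect_lt(max(abs(ip) / norms), 1e-8)
})

test_that("rank-deficient confounds are dropped with a warning", {
  ts <- fixture_series(100)
  conf <- with_seed(3, matrix(stats::rnorm(100), 100, 1))
  conf <- cbind(conf, 2 * conf[, 1])
  expect_warning(res <- regress_confounds(ts, conf), "collinear")
  expect_equal(nrow(res$data), 100)
})

test_that("rectangular bandpass keeps in-band sinusoids, kills out-of-band ones, and removes DC", {
  n <- 1200
  tr <- 0.72
  t_s <- (0:(n - 1)) * tr
  # exact-bin frequencies so the filter's ideal response is testable analytically
  f_pass <- round(0.04 * n * tr) / (n * tr)
  f_stop <- round(0.20 * n * tr) / (n * tr)
  x_pass <- sin(2 * pi * f_pass * t_s)
  x_stop <- sin(2 * pi * f_stop * t_s)
  const <- rep(5, n)
  ts <- parcellated_ts(cbind(x_pass, x_stop, const + x_pass), tr)
  out <- bandpass_rectangular(ts)
  expect_lt(abs(sqrt(mean(out$data[, 1]^2)) / sqrt(mean(x_pass^2)) - 1), 0.01)
  expect_lt(sqrt(mean(out$data[, 2]^2)) / sqrt(mean(x_stop^2)), 0.01)
  expect_lt(max(abs(colMeans(out$data))), 1e-10)
  # constant series -> all zero
  zz <- bandpass_rectangular(parcellated_ts(cbind(const, const), tr))
  expect_lt(max(abs(zz$data)), 1e-10)
})

test_that("bandpass is idempotent and validates its band", {
  ts <- fixture_series(256)
  once <- bandpass_rectangular(ts)
  twice <- bandpass_rectangular(once)
  expect_lt(max(abs(once$data - twice$data)), 1e-10)
  expect_error(bandpass_rectangular(ts, 0.008, 1), "Nyquist")
  expect_error(bandpass_rectangular(ts, 0.1, 0.05), "f_lo")
})

test_that("framewise displacement follows its definition", {
  zero <- motion_trace(matrix(0, 50, 6), 0.8)
  expect_equal(compute_fd(zero, apply_notch = FALSE)$fd_mm, rep(0, 50))
  # single 0.2 mm translation step
  p <- matrix(0, 50, 6)
  p[25:50, 1] <- 0.2
  fd <- compute_fd(motion_trace(p, 0.8), apply_notch = FALSE)
  expect_equal(fd$fd_mm[25], 0.2)
  expect_equal(sum(fd$fd_mm), 0.2)
  # single 0.01 rad rotation step -> 50 mm * 0.01 = 0.5 mm arc
  q <- matrix(0, 50, 6)
  q[10:50, 4] <- 0.01
  fdr <- compute_fd(motion_trace(q, 0.8), apply_notch = FALSE)
  expect_equal(fdr$fd_mm[10], 0.5)
  # constant offsets don't matter
  fd_off <- compute_fd(motion_trace(p + 3, 0.8), apply_notch = FALSE)
  expect_equal(fd_off$fd_mm, fd$fd_mm)
})

test_that("the respiratory notch removes the planted 0.37 Hz component", {
  mo <- simulate_motion(800, 0.8, 0.3, 21)
  fd_raw <- compute_fd(mo, apply_notch = FALSE)
  fd_notch <- compute_fd(mo, apply_notch = TRUE)
  expect_lt(mean(fd_notch$fd_mm), mean(fd_raw$fd_mm))
})

test_that("the notch is skipped with a warning when the band reaches Nyquist", {
  mo <- simulate_motion(100, 2.0, 0.2, 5) # Nyquist 0.25 Hz < 0.43 Hz
  expect_warning(fd <- compute_fd(mo, apply_notch = TRUE), "Nyquist")
  expect_equal(fd$fd_mm, compute_fd(mo, apply_notch = FALSE)$fd_mm)
})

test_that("the three exclusion rules trigger exactly as printed", {
  # (a) mean FD > 0.3 mm without tripping the frame-fraction rule
  a <- c(rep(1.55, 20), rep(0, 80))
  # (b) > 20% of frames above 0.2 mm, mean kept low
  b <- c(rep(0.25, 25), rep(0.05, 75))
  # (c) any FD > 5 mm
  cc <- c(rep(0.05, 99), 5.1)
  # retained: uniformly low
  d <- rep(0.05, 100)
  # boundary: mean exactly 0.3 and exactly 20% above 0.2 are NOT excluded
  e <- c(rep(1.5, 20), rep(0, 80))
  f <- c(rep(0.25, 20), rep(0.1, 80))
  rep_tbl <- apply_exclusions(list(a, b, cc, d, e, f))
  expect_equal(rep_tbl$excluded, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(rep_tbl$triggered_rules[1:3], c("a", "b", "c"))
  expect_true(all((rep_tbl$triggered_rules != "") == rep_tbl$excluded))
})
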