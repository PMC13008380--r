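test_that("identical and sign-flipped signals have unit coherence everywhere", {
  x <- with_seed(1, stats::rnorm(512))
  ts <- parcellated_ts(cbind(x, x), 0.72)
  sp <- welch_coherence(ts)
  expect_true(all(abs(sp$coherence[, 1, 2] - 1) < 1e-8))
  expect_equal(spectral_coherence_fc(ts)[1, 2], 1, tolerance = 1e-8)
  # magnitude-squared coherence is phase/sign-blind
  ts2 <- parcellated_ts(cbind(x, -2.5 * x), 0.72)
  expect_equal(spectral_coherence_fc(ts2)[1, 2], 1, tolerance = 1e-8)
})

test_that("independent noise shows the 1/K averaged-periodogram bias", {
  K <- 4
  L <- 64
  n <- K * L
  means <- with_seed(2, vapply(seq_len(400), function(i) {
    ts <- parcellated_ts(cbind(stats::rnorm(n), stats::rnorm(n)), 1)
    sp <- welch_coherence(ts, window_frames = L, overlap_fraction = 0)
    mean(sp$coherence[, 1, 2])
  }, numeric(1)))
  se <- stats::sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 1 / K), 2 * se + 0.002)
})

test_that("band handling of the Welch estimator is validated", {
  ts <- fixture_series(256, seed = 5)
  expect_error(spectral_coherence_fc(ts, band = c(0.1, 0.8)), "Nyquist")
  fc <- spectral_coherence_fc(ts)
  v <- fc[lower.tri(fc)]
  expect_true(all(v >= 0 & v <= 1))
})

test_that("wavelet coherence is ~1 for identical signals but not for independent noise", {
  x <- with_seed(3, stats::rnorm(512))
  ts <- parcellated_ts(cbind(x, x), 0.8)
  expect_gte(wavelet_coherence_fc(ts)[1, 2], 0.99)
  # the smoothing is what prevents the degenerate coherence == 1; independent
  # noise must come out well below 1
  ts0 <- with_seed(4, parcellated_ts(cbind(stats::rnorm(512), stats::rnorm(512)), 0.8))
  expect_lt(wavelet_coherence_fc(ts0)[1, 2], 0.9)
})

test_that("a shared in-band oscillation separates from the independent-noise baseline", {
  n <- 512
  tr <- 0.8
  tt <- (0:(n - 1)) * tr
  fc_common <- numeric(120)
  fc_indep <- numeric(120)
  with_seed(6, {
    for (i in seq_len(120)) {
      s <- sqrt(2) * sin(2 * pi * 0.03 * tt + stats::runif(1, 0, 2 * pi))
      ts1 <- parcellated_ts(cbind(s + stats::rnorm(n), s + stats::rnorm(n)), tr)
      ts0 <- parcellated_ts(
        cbind(stats::rnorm(n, 0, sqrt(2)), stats::rnorm(n, 0, sqrt(2))), tr
      )
      fc_common[i] <- wavelet_coherence_fc(ts1)[1, 2]
      fc_indep[i] <- wavelet_coherence_fc(ts0)[1, 2]
    }
  })
  sep <- (mean(fc_common) - mean(fc_indep)) /
    sqrt(stats::var(fc_common) / 120 + stats::var(fc_indep) / 120)
  expect_gte(sep, 3)
})

test_that("frequency-domain MI follows the closed-form transform of the coherence", {
  # synthetic flat spectrum C = 0.36 over a known band
  freqs <- seq(0.005, 0.1, by = 0.0025)
  C <- array(0.36, dim = c(length(freqs), 2, 2))
  phi <- mi_frequency_fc(list(frequencies = freqs, coherence = C))
  in_band <- freqs >= 0.008 & freqs <= 0.08
  width <- max(freqs[in_band]) - min(freqs[in_band])
  expected <- 1 - exp(-2 * abs(log(1 - 0.36)) * width)
  expect_equal(phi[1, 2], expected, tolerance = 1e-10)
  # zero coherence -> phi = 0
  C0 <- array(0, dim = c(length(freqs), 2, 2))
  expect_equal(mi_frequency_fc(list(frequencies = freqs, coherence = C0))[1, 2], 0)
})

test_that("frequency-domain MI estimated from correlated white noise matches the plug-in value", {
  rho <- 0.6
  n <- 20000
  ts <- gaussian_series(n, matrix(c(1, rho, rho, 1), 2), 77)
  sp <- welch_coherence(ts, window_frames = 256, overlap_fraction = 0.5)
  phi <- mi_frequency_fc(sp, band = c(0.008, 0.08))[1, 2]
  in_band <- sp$frequencies >= 0.008 & sp$frequencies <= 0.08
  width <- max(sp$frequencies[in_band]) - min(sp$frequencies[in_band])
  expected <- 1 - exp(-2 * abs(log(1 - rho^2)) * width)
  expect_lt(abs(phi - expected) / expected, 0.15)
})

test_that("frequency-domain MI is monotone in pointwise coherence and sign-switchable", {
  freqs <- seq(0.01, 0.07, by = 0.005)
  hi <- array(0.5, dim = c(length(freqs), 2, 2))
  lo <- array(0.2, dim = c(length(freqs), 2, 2))
  phi_hi <- mi_frequency_fc(list(frequencies = freqs, coherence = hi))[1, 2]
  phi_lo <- mi_frequency_fc(list(frequencies = freqs, coherence = lo))[1, 2]
  expect_gt(phi_hi, phi_lo)
  signed <- mi_frequency_fc(list(frequencies = freqs, coherence = hi), signed = TRUE)
  expect_lt(signed[1, 2], 0)
  # C = 1 clips with a warning and stays finite
  one <- array(1, dim = c(length(freqs), 2, 2))
  expect_warning(out <- mi_frequency_fc(list(frequencies = freqs, coherence = one)))
  expect_true(is.finite(out[1, 2]))
})

test_that("widening the band with zero-coherence bins cannot raise the band average", {
  freqs <- seq(0.01, 0.09, by = 0.005)
  C <- array(0, dim = c(length(freqs), 2, 2))
  C[freqs <= 0.05, 1, 2] <- 0.6
  C[freqs <= 0.05, 2, 1] <- 0.6
  ts_narrow <- apply(C[freqs >= 0.01 & freqs <= 0.05, , , drop = FALSE], c(2, 3), mean)
  ts_wide <- apply(C, c(2, 3), mean)
  expect_lte(ts_wide[1, 2], ts_narrow[1, 2])
})
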