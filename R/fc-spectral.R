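# Frequency-domain coupling: magnitude-squared coherence from Welch averaged
# periodograms, Morlet wavelet coherence with the standard time/scale
# smoothing, and the normalized mutual-information transform of a coherence
# spectrum. All estimators band-average over 0.008-0.08 Hz by default.

#' Welch averaged-periodogram coherence for all region pairs
#'
#' Splits each region's series into Hann-tapered overlapping segments,
#' averages auto- and cross-spectra over segments, and forms the
#' magnitude-squared coherence `|Pxy|^2 / (Pxx Pyy)` at every positive
#' frequency bin.
#'
#' @param series a `parcellated_ts`.
#' @param window_frames segment length; default
#'   `min(2^floor(log2(frames / 4)), 256)`.
#' @param overlap_fraction fractional segment overlap in \[0, 1).
#' @return list with `frequencies` (Hz, positive bins excluding DC),
#'   `coherence` (freq x regions x regions array in \[0, 1\]),
#'   `n_segments`.
#' @export
welch_coherence <- function(series, window_frames = NULL, overlap_fraction = 0.5) {
  X <- series$data
  n <- nrow(X)
  p <- ncol(X)
  if (is.null(window_frames)) {
    # floor of 32 frames keeps at least two bins inside the default low-
    # frequency band at typical TRs; cap of 256 bounds the variance
    window_frames <- min(max(2^floor(log2(n / 4)), 32), 256, 2^floor(log2(n)))
  }
  stopifnot(window_frames >= 8, window_frames <= n,
            overlap_fraction >= 0, overlap_fraction < 1)
  L <- window_frames
  step <- max(1, round(L * (1 - overlap_fraction)))
  starts <- seq(1, n - L + 1, by = step)
  K <- length(starts)
  taper <- 0.5 * (1 - cos(2 * pi * seq(0, L - 1) / (L - 1)))
  n_pos <- floor(L / 2)
  bins <- seq(2, n_pos + 1) # positive frequencies, DC excluded
  cross <- array(0 + 0i, dim = c(length(bins), p, p))
  for (s in starts) {
    seg <- X[s:(s + L - 1), , drop = FALSE]
    seg <- sweep(seg, 2, colMeans(seg)) * taper
    Fs <- stats::mvfft(seg)[bins, , drop = FALSE]
    for (f in seq_along(bins)) {
      cross[f, , ] <- cross[f, , ] + outer(Fs[f, ], Conj(Fs[f, ]))
    }
  }
  cross <- cross / K
  coh <- array(0, dim = c(length(bins), p, p))
  for (f in seq_along(bins)) {
    auto <- Re(diag(cross[f, , ]))
    coh[f, , ] <- Mod(cross[f, , ])^2 / outer(auto, auto)
  }
  coh <- pmin(pmax(coh, 0), 1)
  list(
    frequencies = (bins - 1) / (L * series$tr_s),
    coherence = coh, n_segments = K
  )
}

#' Spectral-coherence functional coupling
#'
#' Band average of the Welch magnitude-squared coherence over the in-band
#' frequency bins (unweighted mean).
#'
#' @inheritParams welch_coherence
#' @param band two-element frequency band, Hz; must contain at least two bins
#'   and stay below Nyquist.
#' @return symmetric `coupling_matrix`, metric `coh_spectral`, values in \[0, 1\].
#' @export
spectral_coherence_fc <- function(series, band = c(0.008, 0.08),
                                  window_frames = NULL, overlap_fraction = 0.5) {
  if (band[2] >= 1 / (2 * series$tr_s)) stop("band extends to or beyond Nyquist")
  sp <- welch_coherence(series, window_frames, overlap_fraction)
  in_band <- sp$frequencies >= band[1] & sp$frequencies <= band[2]
  if (sum(in_band) < 2) stop("fewer than 2 frequency bins fall inside the band")
  fc <- apply(sp$coherence[in_band, , , drop = FALSE], c(2, 3), mean)
  diag(fc) <- NA_real_
  coupling_matrix(fc, "coh_spectral", series$subject_id, symmetric = TRUE)
}

#' Continuous Morlet wavelet transform (FFT implementation)
#'
#' @param x numeric series.
#' @param tr_s sampling interval, seconds.
#' @param scales wavelet scales (seconds).
#' @param omega0 Morlet center frequency (nondimensional).
#' @return complex matrix, time x scales.
#' @keywords internal
morlet_cwt <- function(x, tr_s, scales, omega0 = 6) {
  n <- length(x)
  Fx <- stats::fft(x - mean(x))
  omega <- 2 * pi * fft_frequencies(n, tr_s)
  W <- matrix(0 + 0i, n, length(scales))
  for (k in seq_along(scales)) {
    s <- scales[k]
    psi_hat <- ifelse(omega > 0,
      pi^(-0.25) * sqrt(2 * pi * s / tr_s) * exp(-(s * omega - omega0)^2 / 2),
      0
    )
    W[, k] <- stats::fft(Fx * psi_hat, inverse = TRUE) / n
  }
  W
}

#' Dyadic Morlet scale grid covering a frequency band
#'
#' @param band two-element band, Hz.
#' @param omega0 Morlet center frequency.
#' @param voices voices per octave.
#' @param margin_octaves extra half-band coverage on each side.
#' @return list with `scales` (seconds) and `frequencies` (Hz, decreasing in
#'   scale order? no: returned increasing in frequency).
#' @keywords internal
morlet_scales <- function(band, omega0 = 6, voices = 12, margin_octaves = 0.5) {
  fourier_factor <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  p_min <- (1 / band[2]) / 2^margin_octaves
  p_max <- (1 / band[1]) * 2^margin_octaves
  n_oct <- log2(p_max / p_min)
  periods <- p_min * 2^(seq(0, n_oct, by = 1 / voices))
  scales <- periods / fourier_factor
  list(scales = scales, frequencies = 1 / periods)
}

#' Morlet wavelet coherence, time-averaged, for all region pairs
#'
#' Auto- and cross-wavelet spectra (scale-normalized) are smoothed in time by
#' a scale-matched Gaussian and across scales by a boxcar spanning 0.6
#' octave; coherence is `|smoothed cross|^2 / (smoothed autos)`. Without this
#' smoothing the estimator degenerates to 1 for any pair. Cone-of-influence
#' points are included in the time average.
#'
#' @param series a `parcellated_ts`.
#' @param band frequency band used to place the scale grid, Hz.
#' @param omega0 Morlet center frequency.
#' @param voices voices per octave of the dyadic scale grid.
#' @return list with `frequencies` (Hz per scale), `coherence`
#'   (scale x regions x regions, time-averaged, in \[0, 1\]).
#' @export
wavelet_coherence <- function(series, band = c(0.008, 0.08), omega0 = 6,
                              voices = 12) {
  X <- series$data
  n <- nrow(X)
  p <- ncol(X)
  sg <- morlet_scales(band, omega0, voices)
  in_band_possible <- sg$frequencies >= band[1] & sg$frequencies <= band[2]
  if (sum(in_band_possible) < 2) stop("fewer than 2 wavelet scales map into the band")
  scales <- sg$scales
  ns <- length(scales)
  cwt <- lapply(seq_len(p), function(j) morlet_cwt(X[, j], series$tr_s, scales, omega0))
  smooth_t <- function(M) {
    # per-scale Gaussian time smoothing, std = scale (in samples), via FFT
    out <- M
    t_idx <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1) * series$tr_s
    for (k in seq_len(ns)) {
      g <- exp(-t_idx^2 / (2 * scales[k]^2))
      g <- g / sum(g)
      out[, k] <- stats::fft(stats::fft(M[, k]) * stats::fft(g), inverse = TRUE) / n
    }
    out
  }
  smooth_s <- function(M) {
    half <- max(0, floor(0.6 * voices / 2))
    if (half == 0) return(M)
    out <- M
    for (k in seq_len(ns)) {
      win <- max(1, k - half):min(ns, k + half)
      out[, k] <- rowMeans(M[, win, drop = FALSE])
    }
    out
  }
  inv_s <- matrix(1 / scales, n, ns, byrow = TRUE)
  s_auto <- lapply(cwt, function(W) Re(smooth_s(smooth_t(Mod(W)^2 * inv_s))))
  coh <- array(0, dim = c(ns, p, p))
  for (i in seq_len(p)) {
    coh[, i, i] <- 1
    if (i == p) break
    for (j in seq((i + 1), p)) {
      sxy <- smooth_s(smooth_t(cwt[[i]] * Conj(cwt[[j]]) * inv_s))
      c_ij <- Mod(sxy)^2 / (s_auto[[i]] * s_auto[[j]])
      c_ij <- pmin(pmax(c_ij, 0), 1)
      m <- colMeans(c_ij)
      coh[, i, j] <- m
      coh[, j, i] <- m
    }
  }
  list(frequencies = sg$frequencies, coherence = coh)
}

#' Wavelet-coherence functional coupling
#'
#' Mean of the smoothed Morlet wavelet coherence over in-band scales and all
#' time points.
#'
#' @inheritParams wavelet_coherence
#' @return symmetric `coupling_matrix`, metric `coh_wavelet`, values in \[0, 1\].
#' @export
wavelet_coherence_fc <- function(series, band = c(0.008, 0.08), omega0 = 6,
                                 voices = 12) {
  wc <- wavelet_coherence(series, band, omega0, voices)
  in_band <- wc$frequencies >= band[1] & wc$frequencies <= band[2]
  fc <- apply(wc$coherence[in_band, , , drop = FALSE], c(2, 3), mean)
  diag(fc) <- NA_real_
  coupling_matrix(fc, "coh_wavelet", series$subject_id, symmetric = TRUE)
}

#' Frequency-domain mutual information from a coherence spectrum
#'
#' Integrates `log(1 - C(f))` over the in-band grid by the trapezoidal rule
#' and maps the magnitude to `phi = 1 - exp(-2 * delta)`, a normalized MI in
#' [0, 1). The raw integral is nonpositive; by default its absolute value is
#' used so phi is nonnegative (set `signed = TRUE` for the verbatim-sign
#' variant). Coherence values of 1 are clipped to `1 - 1e-10` with a warning.
#'
#' @param spectrum list with `frequencies` (Hz) and `coherence`
#'   (freq x regions x regions), as returned by [welch_coherence()] or
#'   [wavelet_coherence()].
#' @param band two-element frequency band, Hz.
#' @param signed keep the nonpositive sign of the integral?
#' @param subject_id identifier for the output.
#' @return symmetric `coupling_matrix`, metric `mi_freq`.
#' @export
mi_frequency_fc <- function(spectrum, band = c(0.008, 0.08), signed = FALSE,
                            subject_id = NA_character_) {
  in_band <- spectrum$frequencies >= band[1] & spectrum$frequencies <= band[2]
  if (sum(in_band) < 2) stop("fewer than 2 spectrum bins fall inside the band")
  f <- spectrum$frequencies[in_band]
  ord <- order(f)
  f <- f[ord]
  C <- spectrum$coherence[in_band, , , drop = FALSE][ord, , , drop = FALSE]
  if (any(C >= 1)) {
    warning("coherence values at 1 clipped to 1 - 1e-10")
    C <- pmin(C, 1 - 1e-10)
  }
  p <- dim(C)[2]
  phi <- matrix(NA_real_, p, p)
  w <- diff(f)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) next
      g <- log(1 - C[, i, j])
      delta <- sum(w * (g[-1] + g[-length(g)]) / 2)
      if (!signed) delta <- abs(delta)
      phi[i, j] <- 1 - exp(-2 * delta)
    }
  }
  coupling_matrix(phi, "mi_freq", subject_id, symmetric = TRUE)
}
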