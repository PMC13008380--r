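# Parcellated-level preprocessing tail: nuisance regression, Fourier
# rectangular bandpass, framewise displacement with respiratory-band
# filtering, and the three-rule motion exclusion.

#' Regress confounds out of a parcellated series
#'
#' Ordinary least squares of every region on an intercept plus the supplied
#' confound columns; returns the residuals. Collinear confound columns are
#' dropped with a warning.
#'
#' @param series a `parcellated_ts`.
#' @param confound_matrix frames x k numeric matrix (no intercept needed).
#' @return residual `parcellated_ts`; residuals are orthogonal to every
#'   retained confound column.
#' @export
regress_confounds <- function(series, confound_matrix = NULL) {
  Y <- series$data
  if (is.null(confound_matrix)) {
    X <- matrix(1, nrow(Y), 1)
  } else {
    confound_matrix <- as.matrix(confound_matrix)
    stopifnot(nrow(confound_matrix) == nrow(Y))
    X <- cbind(1, confound_matrix)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    warning(sprintf(
      "dropping %d collinear confound column(s)", ncol(X) - qrX$rank
    ))
    X <- X[, sort(keep), drop = FALSE]
    qrX <- qr(X)
  }
  res <- Y - X %*% qr.coef(qrX, Y)
  parcellated_ts(res, series$tr_s, series$subject_id)
}

#' Expand six motion parameters to the 24-parameter set
#'
#' The standard expansion: the six rigid-body parameters, their backward
#' temporal derivatives (first row zero), and the squares of both.
#'
#' @param motion a `motion_trace` or frames x 6 matrix.
#' @return frames x 24 matrix.
#' @export
motion_params24 <- function(motion) {
  p <- if (inherits(motion, "motion_trace")) motion$params else as.matrix(motion)
  stopifnot(ncol(p) == 6)
  dp <- rbind(0, diff(p))
  cbind(p, dp, p^2, dp^2)
}

#' Fourier rectangular bandpass filter
#'
#' Per region: forward FFT, zero every bin whose frequency magnitude lies
#' outside `[f_lo, f_hi]` (the DC bin is always zeroed), inverse FFT. The
#' filter is ideal (rectangular) in the frequency domain and idempotent.
#'
#' @param series a `parcellated_ts`.
#' @param f_lo,f_hi passband edges in Hz; `f_hi` must stay below Nyquist.
#' @return filtered `parcellated_ts` with per-region mean ~0.
#' @export
bandpass_rectangular <- function(series, f_lo = 0.008, f_hi = 0.08) {
  n <- nrow(series$data)
  nyq <- 1 / (2 * series$tr_s)
  if (!(f_lo < f_hi)) stop("f_lo must be below f_hi")
  if (f_hi >= nyq) stop(sprintf("f_hi (%.4g Hz) must be below Nyquist (%.4g Hz)", f_hi, nyq))
  freqs <- fft_frequencies(n, series$tr_s)
  keep <- abs(freqs) >= f_lo & abs(freqs) <= f_hi
  keep[1] <- FALSE # DC always removed
  out <- apply(series$data, 2, function(x) {
    X <- stats::fft(x)
    X[!keep] <- 0
    Re(stats::fft(X, inverse = TRUE)) / n
  })
  parcellated_ts(out, series$tr_s, series$subject_id)
}

#' Two-sided FFT bin frequencies
#'
#' @param n number of samples.
#' @param tr_s sampling interval, seconds.
#' @return length-`n` vector of signed frequencies in Hz matching R's FFT
#'   bin order.
#' @keywords internal
fft_frequencies <- function(n, tr_s) {
  k <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1))
  k / (n * tr_s)
}

#' Framewise displacement with optional respiratory-band filtering
#'
#' Rotations are converted to arc displacement on a sphere of
#' `head_radius_mm`; optionally, a frequency-domain band-stop removes the
#' respiratory band (default 0.31-0.43 Hz) from each parameter trace; FD at
#' frame t is the sum over the six parameters of the absolute frame-to-frame
#' difference, with FD(1) defined as 0.
#'
#' @param motion a `motion_trace`.
#' @param notch_band two-element band (Hz) removed when `apply_notch`.
#' @param head_radius_mm rotation-to-mm conversion radius.
#' @param apply_notch remove the respiratory band before differencing? If the
#'   band's upper edge reaches Nyquist the notch is skipped with a warning.
#' @return an `fd_trace`: list with `fd_mm` (per-frame FD, first element 0),
#'   `subject_id`.
#' @export
compute_fd <- function(motion, notch_band = c(0.31, 0.43),
                       head_radius_mm = 50, apply_notch = TRUE) {
  p <- motion$params
  stopifnot(nrow(p) >= 2)
  if (!all(is.finite(p))) stop("motion parameters contain non-finite values")
  p[, 4:6] <- p[, 4:6] * head_radius_mm
  if (apply_notch) {
    nyq <- 1 / (2 * motion$tr_s)
    if (notch_band[2] >= nyq) {
      warning("notch band reaches Nyquist; skipping respiratory filtering")
    } else {
      p <- apply(p, 2, bandstop_fft, tr_s = motion$tr_s, band = notch_band)
    }
  }
  fd <- c(0, rowSums(abs(diff(p))))
  structure(list(fd_mm = fd, subject_id = motion$subject_id),
    class = "fd_trace"
  )
}

#' Frequency-domain band-stop (notch) filter for one trace
#'
#' @param x numeric vector.
#' @param tr_s sampling interval, seconds.
#' @param band two-element stop band, Hz.
#' @return filtered vector.
#' @keywords internal
bandstop_fft <- function(x, tr_s, band) {
  n <- length(x)
  freqs <- fft_frequencies(n, tr_s)
  drop <- abs(freqs) >= band[1] & abs(freqs) <= band[2]
  X <- stats::fft(x)
  X[drop] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Apply the three-rule motion exclusion criteria
#'
#' A subject is excluded when any of: (a) mean FD > 0.3 mm; (b) more than 20%
#' of frames have FD > 0.2 mm; (c) any FD > 5 mm. All inequalities strict.
#'
#' @param fd_traces list of `fd_trace` objects (or numeric FD vectors).
#' @param mean_fd_limit rule (a) threshold, mm.
#' @param frame_fd_limit per-frame threshold for rule (b), mm.
#' @param frame_fraction_limit maximum tolerated fraction above
#'   `frame_fd_limit`.
#' @param max_fd_limit rule (c) threshold, mm.
#' @return data.frame with one row per subject: `subject_id`, `mean_fd`,
#'   `fraction_above_0p2`, `max_fd`, `excluded`, `triggered_rules`
#'   (comma-separated subset of "a", "b", "c").
#' @export
apply_exclusions <- function(fd_traces, mean_fd_limit = 0.3,
                             frame_fd_limit = 0.2,
                             frame_fraction_limit = 0.2,
                             max_fd_limit = 5) {
  stopifnot(length(fd_traces) >= 1)
  rows <- lapply(seq_along(fd_traces), function(k) {
    tr <- fd_traces[[k]]
    fd <- if (inherits(tr, "fd_trace")) tr$fd_mm else as.numeric(tr)
    sid <- if (inherits(tr, "fd_trace") && !is.na(tr$subject_id)) {
      tr$subject_id
    } else {
      sprintf("sub-%03d", k)
    }
    rules <- c(
      a = mean(fd) > mean_fd_limit,
      b = mean(fd > frame_fd_limit) > frame_fraction_limit,
      c = any(fd > max_fd_limit)
    )
    data.frame(
      subject_id = sid,
      mean_fd = mean(fd),
      fraction_above_0p2 = mean(fd > frame_fd_limit),
      max_fd = max(fd),
      excluded = any(rules),
      triggered_rules = paste(names(rules)[rules], collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
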