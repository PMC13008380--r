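# Head-motion simulation and motion-artifact injection.
# Motion traces carry a slow AR(1) drift, a respiratory-band sinusoid at
# 0.37 Hz (so a 0.31-0.43 Hz notch demonstrably removes it), and white jitter,
# scaled so the subject's unfiltered mean framewise displacement hits a target.

#' Simulate six rigid-body motion parameters
#'
#' Each of the three translations (mm) and three rotations (radians) is the
#' sum of an AR(1) drift, a sinusoid at `resp_freq_hz` with a random phase,
#' and white jitter. All six traces are jointly rescaled so the unfiltered
#' mean framewise displacement equals `severity_mm` (FD is positively
#' homogeneous in the parameters, so the match is exact up to rounding).
#'
#' @param n_frames number of frames (>= 2).
#' @param tr_s repetition time, seconds.
#' @param severity_mm target unfiltered mean FD (>= 0); 0 gives all-zero traces.
#' @param rng_seed integer seed.
#' @param resp_freq_hz respiratory frequency planted in the traces.
#' @param head_radius_mm sphere radius used when targeting mean FD.
#' @return a `motion_trace`: list with `params` (frames x 6 matrix, columns
#'   `trans_x, trans_y, trans_z, rot_x, rot_y, rot_z`), `tr_s`, `subject_id`.
#' @export
simulate_motion <- function(n_frames, tr_s, severity_mm, rng_seed,
                            resp_freq_hz = 0.37, head_radius_mm = 50,
                            subject_id = NA_character_) {
  stopifnot(n_frames >= 2, severity_mm >= 0)
  cols <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  if (severity_mm == 0) {
    params <- matrix(0, n_frames, 6, dimnames = list(NULL, cols))
    return(motion_trace(params, tr_s, subject_id))
  }
  with_seed(rng_seed, {
    t_s <- (seq_len(n_frames) - 1) * tr_s
    params <- sapply(seq_len(6), function(k) {
      drift <- as.numeric(stats::arima.sim(
        model = list(ar = 0.97), n = n_frames, sd = 0.05
      ))
      resp <- 0.08 * sin(2 * pi * resp_freq_hz * t_s + stats::runif(1, 0, 2 * pi))
      jitter <- stats::rnorm(n_frames, 0, 0.02)
      drift + resp + jitter
    })
    # rotations live on a smaller numeric scale (radians at 50 mm arm)
    params[, 4:6] <- params[, 4:6] / head_radius_mm
    colnames(params) <- cols
    tr <- motion_trace(params, tr_s, subject_id)
    fd0 <- mean(compute_fd(tr,
      apply_notch = FALSE,
      head_radius_mm = head_radius_mm
    )$fd_mm)
    params <- params * (severity_mm / fd0)
    motion_trace(params, tr_s, subject_id)
  })
}

#' Construct a motion-trace container
#'
#' @param params frames x 6 matrix (translations mm, rotations radians).
#' @param tr_s repetition time, seconds.
#' @param subject_id identifier.
#' @return object of class `motion_trace`.
#' @export
motion_trace <- function(params, tr_s, subject_id = NA_character_) {
  params <- as.matrix(params)
  stopifnot(ncol(params) == 6, nrow(params) >= 2, all(is.finite(params)))
  structure(list(params = params, tr_s = tr_s, subject_id = subject_id),
    class = "motion_trace"
  )
}

#' Inject distance-dependent motion artifact into a series
#'
#' Adds to each region a scaled copy of the standardized FD trace with
#' per-region weights taken from the leading (Perron) eigenvector of the
#' edge-susceptibility matrix, so the induced spurious coupling on edge
#' (i, j) scales with `edge_susceptibility[i, j]`. `artifact_gain = 0`
#' returns the input unchanged.
#'
#' @param series a `parcellated_ts`.
#' @param fd_trace an `fd_trace` (see [compute_fd()]) or numeric FD vector,
#'   one value per frame.
#' @param edge_susceptibility regions x regions nonnegative symmetric matrix.
#' @param artifact_gain contamination strength (unitless).
#' @return contaminated `parcellated_ts`.
#' @export
inject_motion_artifact <- function(series, fd_trace, edge_susceptibility,
                                   artifact_gain) {
  fd <- if (inherits(fd_trace, "fd_trace")) fd_trace$fd_mm else as.numeric(fd_trace)
  if (length(fd) != nrow(series$data)) {
    stop("fd_trace length does not match the series frame count")
  }
  if (artifact_gain == 0 || max(edge_susceptibility) == 0) {
    return(series)
  }
  stopifnot(all(edge_susceptibility >= 0))
  w <- region_susceptibility_weights(edge_susceptibility)
  if (stats::sd(fd) == 0) {
    return(series)
  }
  # standardized FD shape, amplitude proportional to the subject's mean FD so
  # contamination grows with motion severity across subjects
  fd_reg <- as.numeric(scale(fd)) * mean(fd)
  out <- series$data + artifact_gain * outer(fd_reg, w)
  parcellated_ts(out, series$tr_s, series$subject_id)
}

#' Per-region weights approximating an edge-susceptibility pattern
#'
#' Rank-one factorization: the leading eigenvector (nonnegative by
#' Perron-Frobenius for a nonnegative matrix) scaled by the root eigenvalue,
#' so `w_i * w_j` tracks `S[i, j]`.
#'
#' @param edge_susceptibility nonnegative symmetric matrix.
#' @return nonnegative weight vector, one entry per region.
#' @keywords internal
region_susceptibility_weights <- function(edge_susceptibility) {
  S <- (edge_susceptibility + t(edge_susceptibility)) / 2
  e <- eigen(S, symmetric = TRUE)
  v <- e$vectors[, 1]
  if (sum(v) < 0) v <- -v
  pmax(v, 0) * sqrt(max(e$values[1], 0))
}

#' Distance-decaying edge susceptibility
#'
#' Susceptibility of edge (i, j) is `exp(-d_ij / artifact_distance_scale)`,
#' emulating the vulnerability of short connections to motion-induced
#' spurious coupling.
#'
#' @param centroids regions x 3 coordinates, mm.
#' @param artifact_distance_scale e-folding length, mm.
#' @return regions x regions symmetric susceptibility matrix (zero diagonal).
#' @export
susceptibility_from_distance <- function(centroids, artifact_distance_scale) {
  stopifnot(artifact_distance_scale > 0)
  d <- as.matrix(stats::dist(centroids))
  S <- exp(-d / artifact_distance_scale)
  diag(S) <- 0
  S
}
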