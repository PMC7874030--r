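#' Event-detection configuration
#'
#' Tunable parameters of the three event detectors. The defaults follow
#' the pipeline's conventions: a zero GRF threshold suits noiseless
#' synthetic force traces (use ~10 N for real plates, which never read
#' exactly zero), the lift-off estimate is searched in the 800 ms before
#' touchdown, and the refined lift-off in a (-50, +200) ms neighborhood
#' of that estimate.
#'
#' @param grf_threshold contact threshold on the Euclidean GRF norm, N.
#' @param lpf_cutoff low-pass cutoff for foot kinematics, Hz.
#' @param search_window_ms lift-off estimate search window before
#'   touchdown, ms.
#' @param neighborhood_ms length-2 window around the lift-off estimate in
#'   which the jerk-zero acceleration minimum is accepted, ms.
#' @param changepoint_alpha significance level of the change-point and
#'   zero-slope permutation tests.
#' @param changepoint_min_segment minimum change-point segment length,
#'   kinematic samples.
#' @param n_permutations permutations per test.
#' @return a named list of class `event_config`.
#' @export
event_config <- function(grf_threshold = 0,
                         lpf_cutoff = 50,
                         search_window_ms = 800,
                         neighborhood_ms = c(-50, 200),
                         changepoint_alpha = 0.05,
                         changepoint_min_segment = 30L,
                         n_permutations = 199L) {
  if (search_window_ms <= 0) abort("search window must be positive.")
  if (diff(neighborhood_ms) <= 0) abort("neighborhood must have positive length.")
  structure(
    list(
      grf_threshold = grf_threshold, lpf_cutoff = lpf_cutoff,
      search_window_ms = search_window_ms,
      neighborhood_ms = neighborhood_ms,
      changepoint_alpha = changepoint_alpha,
      changepoint_min_segment = as.integer(changepoint_min_segment),
      n_permutations = as.integer(n_permutations)
    ),
    class = "event_config"
  )
}

#' Detect touchdown from the ground reaction force
#'
#' Touchdown is the first sample whose Euclidean GRF norm exceeds the
#' configured threshold ("first non-zero value" for noiseless data).
#'
#' @param grf numeric matrix or data frame with the three force
#'   components in columns, or a numeric vector of the GRF norm.
#' @param cfg an [event_config()].
#' @return sample index of touchdown.
#' @export
detect_touchdown <- function(grf, cfg = event_config()) {
  nrm <- grf_norm(grf)
  idx <- which(nrm > cfg$grf_threshold)
  if (length(idx) == 0L) {
    abort("no contact: GRF never exceeds the threshold.")
  }
  idx[1]
}

grf_norm <- function(grf) {
  if (is.numeric(grf) && is.null(dim(grf))) return(abs(grf))
  grf <- as.matrix(grf)
  sqrt(rowSums(grf^2))
}

#' Detect lift-off from the fifth-metatarsal vertical trajectory
#'
#' Foot acceleration-and-jerk algorithm: the trajectory is low-pass
#' filtered (zero-phase 4th-order Butterworth), acceleration and jerk are
#' taken as 2nd and 3rd central finite differences, a lift-off estimate
#' (LOe) is the global maximum of the vertical acceleration in the
#' `search_window_ms` before touchdown, and the refined lift-off is the
#' jerk zero-crossing corresponding to a local acceleration minimum
#' inside `neighborhood_ms` around LOe (nearest to LOe; ties toward the
#' earlier sample). If no qualifying minimum exists the estimate is
#' returned with a warning.
#'
#' @param metatarsal_z numeric vector, vertical position of the fifth
#'   metatarsal head (kinematic rate).
#' @param td touchdown sample index on the same timebase.
#' @param fs sampling rate of `metatarsal_z`, Hz.
#' @param cfg an [event_config()].
#' @return lift-off sample index on the `metatarsal_z` timebase.
#' @export
detect_liftoff <- function(metatarsal_z, td, fs, cfg = event_config()) {
  if (td < 3L || td > length(metatarsal_z)) {
    abort("touchdown index outside the trace.")
  }
  z <- filter_zerophase(metatarsal_z, cfg$lpf_cutoff, fs, "low")
  dt <- 1 / fs
  acc <- central_diff(central_diff(z, dt), dt)
  jerk <- central_diff(acc, dt)
  w0 <- max(1L, td - round(cfg$search_window_ms / 1000 * fs))
  window <- w0:td
  loe <- window[which.max(acc[window])]
  n0 <- max(1L, loe + round(cfg$neighborhood_ms[1] / 1000 * fs))
  n1 <- min(length(acc) - 1L, loe + round(cfg$neighborhood_ms[2] / 1000 * fs))
  cand <- integer(0)
  for (i in n0:n1) {
    # jerk sign change marking a local acceleration minimum
    if (jerk[i] < 0 && jerk[i + 1L] >= 0) {
      cand <- c(cand, if (abs(jerk[i]) <= abs(jerk[i + 1L])) i else i + 1L)
    }
  }
  if (length(cand) == 0L) {
    warn("no jerk-zero acceleration minimum near the estimate; falling back to LOe.")
    return(loe)
  }
  dist <- abs(cand - loe)
  cand[order(dist, cand)][1]
}

central_diff <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1L]) / dt
  d
}

#' Detect the post-touchdown steady state from the knee angle
#'
#' Locates maximum knee flexion after touchdown (plateau ties broken
#' toward the earliest sample), computes the slope of the knee angle from
#' that point on, segments the slope series by divisive energy-statistic
#' change-point detection, and returns the start of the first segment
#' whose mean slope does not significantly depart from zero (one-sample
#' sign-flip permutation test at the same alpha).
#'
#' @param knee_angle numeric vector, knee angle in degrees (180 = full
#'   extension) sampled at the kinematic rate.
#' @param td touchdown sample index on the same timebase.
#' @param fs sampling rate, Hz.
#' @param cfg an [event_config()].
#' @return sample index of the steady-state onset on the `knee_angle`
#'   timebase.
#' @export
detect_steady_state <- function(knee_angle, td, fs, cfg = event_config()) {
  n <- length(knee_angle)
  if (td >= n - 2L) abort("touchdown too close to the end of the trace.")
  post <- knee_angle[td:n]
  flex <- -post # flexion = decreasing knee angle under the 180-extension convention
  i_max <- which.max(flex) # first index on ties
  start <- td + i_max - 1L
  slope <- central_diff(knee_angle[start:n], 1 / fs)
  cps <- energy_divisive(
    slope,
    alpha = cfg$changepoint_alpha,
    min_size = cfg$changepoint_min_segment,
    n_perm = cfg$n_permutations
  )
  bounds <- c(1L, cps, length(slope) + 1L)
  for (s in seq_len(length(bounds) - 1L)) {
    seg <- slope[bounds[s]:(bounds[s + 1L] - 1L)]
    p <- mean_zero_pvalue(seg, cfg$n_permutations)
    if (p > cfg$changepoint_alpha) {
      return(start + bounds[s] - 1L)
    }
  }
  abort("no steady state: the knee-angle slope never settles before the trace ends.")
}

#' Segment a trial into its lunge cycle
#'
#' Composes the three detectors: touchdown from the GRF (analog rate),
#' lift-off from the fifth-metatarsal vertical trajectory (kinematic
#' rate), and the steady-state end from the knee angle (kinematic rate).
#' All indices are returned on the analog (1 kHz) timebase; kinematic
#' indices are converted by rate ratio with round-half-up.
#'
#' @param trial a [trial_recording()].
#' @param cfg an [event_config()].
#' @return a [lunge_cycle()] on the analog timebase.
#' @export
segment_trial <- function(trial, cfg = event_config()) {
  stopifnot(inherits(trial, "trial_recording"))
  trial <- gap_fill_markers(trial)
  id <- trial$meta$participant %||% "?"
  td_a <- withCallingHandlers(
    detect_touchdown(
      trial$analog[, c("grf_x", "grf_y", "grf_z")], cfg
    ),
    error = function(e) abort(paste0("trial ", id, ": ", conditionMessage(e)))
  )
  td_k <- analog_to_kin_index(td_a, trial$rate_kin, trial$rate_analog)
  lo_k <- detect_liftoff(
    trial$markers$metatarsal5_z, td_k, trial$rate_kin, cfg
  )
  angles <- joint_angles(trial$markers, lpf_cutoff = cfg$lpf_cutoff,
                         fs = trial$rate_kin)
  ss_k <- detect_steady_state(angles$knee, td_k, trial$rate_kin, cfg)
  lunge_cycle(
    kin_to_analog_index(lo_k, trial$rate_kin, trial$rate_analog),
    td_a,
    kin_to_analog_index(ss_k, trial$rate_kin, trial$rate_analog),
    rate = trial$rate_analog, timebase = "analog"
  )
}
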