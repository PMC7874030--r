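#' Lunge cycle events
#'
#' The three event indices bounding one lunge repetition: lift-off of the
#' stepping foot, touchdown on the force plate, and the end of the
#' post-touchdown steady state. Swing is `[lift_off, touchdown)`, stance
#' `[touchdown, steady_state_end]`. Indices refer to one stated timebase;
#' by convention the pipeline stores events on the analog (1 kHz) timebase
#' and converts kinematic indices by rate ratio (round-half-up).
#'
#' @param lift_off,touchdown,steady_state_end sample indices.
#' @param rate sampling rate (Hz) of the timebase the indices refer to.
#' @param timebase `"analog"` or `"kin"`.
#' @return a `lunge_cycle` object.
#' @export
lunge_cycle <- function(lift_off, touchdown, steady_state_end,
                        rate = 1000, timebase = "analog") {
  lift_off <- as.integer(lift_off)
  touchdown <- as.integer(touchdown)
  steady_state_end <- as.integer(steady_state_end)
  if (!(lift_off < touchdown && touchdown < steady_state_end)) {
    abort("cycle events out of order: need lift_off < touchdown < steady_state_end.")
  }
  structure(
    list(
      lift_off = lift_off, touchdown = touchdown,
      steady_state_end = steady_state_end,
      rate = rate, timebase = timebase
    ),
    class = "lunge_cycle"
  )
}

#' @export
print.lunge_cycle <- function(x, ...) {
  cat(sprintf(
    "<lunge_cycle> lift-off %d, touchdown %d, steady-state end %d (@%g Hz %s)\n",
    x$lift_off, x$touchdown, x$steady_state_end, x$rate, x$timebase
  ))
  invisible(x)
}

# rescale a cycle to another timebase
convert_cycle <- function(cycle, rate_to, timebase_to) {
  lunge_cycle(
    round_half_up((cycle$lift_off - 1) * rate_to / cycle$rate) + 1,
    round_half_up((cycle$touchdown - 1) * rate_to / cycle$rate) + 1,
    round_half_up((cycle$steady_state_end - 1) * rate_to / cycle$rate) + 1,
    rate = rate_to, timebase = timebase_to
  )
}

#' EMG linear envelope
#'
#' Classic envelope chain: zero-phase 4th-order Butterworth high-pass at
#' 50 Hz, full-wave rectification, zero-phase 4th-order Butterworth
#' low-pass at 20 Hz, and a final clip at zero (the zero-phase low-pass
#' can undershoot slightly). The operator is positively homogeneous:
#' `emg_envelope(c * x) = c * emg_envelope(x)` for `c > 0`.
#'
#' @param x numeric vector, one raw EMG channel.
#' @param fs sampling rate in Hz (> 100).
#' @param high,low high- and low-pass cutoffs in Hz.
#' @param order Butterworth order per pass.
#' @return non-negative envelope, same length as `x`.
#' @export
emg_envelope <- function(x, fs, high = 50, low = 20, order = 4L) {
  if (fs <= 2 * high) {
    abort(sprintf("sampling rate %g Hz too low for a %g Hz high-pass.", fs, high))
  }
  hp <- filter_zerophase(x, high, fs, "high", order)
  env <- filter_zerophase(abs(hp), low, fs, "low", order)
  pmax(env, 0)
}

#' Envelope all EMG channels of a trial
#'
#' @param trial a [trial_recording()].
#' @inheritParams emg_envelope
#' @return tibble with `time` and one column per muscle code, the
#'   envelopes in the canonical muscle order.
#' @export
envelope_trial <- function(trial, high = 50, low = 20, order = 4L) {
  stopifnot(inherits(trial, "trial_recording"))
  fs <- trial$rate_analog
  out <- tibble(time = trial$analog$time)
  for (m in lunge_muscles()) {
    out[[m]] <- emg_envelope(trial$analog[[paste0("emg_", m)]], fs,
                             high = high, low = low, order = order)
  }
  out
}

#' Time-normalize one cycle to 200 points
#'
#' The swing phase (`[lift_off, touchdown)`) is linearly resampled to 50
#' points and the stance phase (`[touchdown, steady_state_end]`) to 150
#' points, so the touchdown always maps to the boundary between points 50
#' and 51.
#'
#' @param trace numeric vector sampled on the cycle's timebase.
#' @param cycle a [lunge_cycle()] with indices into `trace`.
#' @return numeric vector of exactly 200 points.
#' @export
time_normalize_cycle <- function(trace, cycle) {
  stopifnot(inherits(cycle, "lunge_cycle"))
  lo <- cycle$lift_off
  td <- cycle$touchdown
  ss <- cycle$steady_state_end
  if (lo < 1L || ss > length(trace)) {
    abort("cycle indices fall outside the trace.")
  }
  if (td - lo < 2L) abort("swing phase shorter than 2 samples.")
  if (ss - td < 2L) abort("stance phase shorter than 2 samples.")
  idx <- seq_along(trace)
  swing_grid <- seq(lo, td, length.out = SWING_POINTS + 1L)[-(SWING_POINTS + 1L)]
  stance_grid <- seq(td, ss, length.out = STANCE_POINTS)
  c(
    approx(idx, trace, xout = swing_grid)$y,
    approx(idx, trace, xout = stance_grid)$y
  )
}

new_envelope_matrix <- function(values, normalization, n_cycles) {
  stopifnot(is.matrix(values), nrow(values) == length(lunge_muscles()))
  if (any(values < 0)) abort("envelope matrix entries must be non-negative.")
  if (ncol(values) != CYCLE_POINTS * n_cycles) {
    abort("envelope matrix must have 200 columns per cycle.")
  }
  rownames(values) <- lunge_muscles()
  structure(
    values,
    class = c("envelope_matrix", "matrix", "array"),
    normalization = normalization,
    n_cycles = as.integer(n_cycles)
  )
}

#' @export
print.envelope_matrix <- function(x, ...) {
  cat(sprintf(
    "<envelope_matrix> %d muscles x %d points (%d cycles of %d), normalization: %s\n",
    nrow(x), ncol(x), attr(x, "n_cycles"), CYCLE_POINTS, attr(x, "normalization")
  ))
  invisible(x)
}

#' @method as_tibble envelope_matrix
#' @export
as_tibble.envelope_matrix <- function(x, ...) {
  tibble(
    muscle = rep(rownames(x), times = ncol(x)),
    cycle = rep(rep(seq_len(attr(x, "n_cycles")), each = CYCLE_POINTS),
                each = nrow(x)),
    point = rep(rep(seq_len(CYCLE_POINTS), times = attr(x, "n_cycles")),
                each = nrow(x)),
    value = as.vector(x)
  ) %>% arrange(.data$muscle, .data$cycle, .data$point)
}

#' Build the concatenated envelope matrix V for synergy extraction
#'
#' Each muscle's envelope over the whole trial is scaled to its trial
#' maximum and shifted by its minimum so the concatenated signal spans
#' exactly `[0, 1]`; each cycle is then time-normalized to 200 points
#' (50 swing + 150 stance) and the cycles are concatenated. The result is
#' the 13 x (200 * n_cycles) matrix factorized by [synergy_nmf()].
#'
#' @param envelopes tibble as returned by [envelope_trial()] (a `time`
#'   column plus one column per muscle code), or a numeric matrix/data
#'   frame with one column per muscle.
#' @param cycles a [lunge_cycle()] or list of them, with indices on the
#'   envelope timebase.
#' @return an `envelope_matrix` (muscles x points) with normalization tag
#'   `"synergy"`.
#' @export
normalize_for_synergies <- function(envelopes, cycles) {
  env <- envelope_channels(envelopes)
  cycles <- as_cycle_list(cycles)
  blocks <- lapply(cycles, function(cy) {
    vapply(lunge_muscles(), function(m) time_normalize_cycle(env[[m]], cy),
           numeric(CYCLE_POINTS))
  })
  v <- t(do.call(rbind, blocks)) # muscles x (200 * n_cycles)
  rng <- apply(v, 1, range)
  dead <- rng[2, ] <= 0
  if (any(dead)) {
    abort(paste0(
      "dead EMG channel(s) with zero maximum: ",
      paste(lunge_muscles()[dead], collapse = ", ")
    ))
  }
  flat <- rng[2, ] - rng[1, ] <= 0
  if (any(flat)) {
    warn(paste0(
      "constant channel(s) become all-zero after min subtraction: ",
      paste(lunge_muscles()[flat], collapse = ", ")
    ))
  }
  denom <- ifelse(flat, 1, rng[2, ] - rng[1, ])
  v <- (v - rng[1, ]) / denom
  new_envelope_matrix(v, "synergy", length(cycles))
}

#' Normalize envelopes to the per-direction maximum
#'
#' For EMG amplitude comparisons (and the coactivation index) each
#' muscle's envelope is scaled by its maximum over all of a participant's
#' trials in one lunge direction; no minimum subtraction is applied. The
#' output is invariant to uniform positive rescaling of the inputs.
#'
#' @param trials list of envelope tibbles ([envelope_trial()] output), all
#'   trials of one participant in one direction.
#' @param cycles list (same length) of [lunge_cycle()] objects or lists of
#'   them, with indices on the envelope timebase.
#' @return list of `envelope_matrix` objects with normalization tag
#'   `"per-direction-max"`, one per trial.
#' @export
normalize_per_direction <- function(trials, cycles) {
  stopifnot(length(trials) == length(cycles))
  envs <- lapply(trials, envelope_channels)
  raw <- purrr::map2(envs, cycles, function(env, cys) {
    cys <- as_cycle_list(cys)
    blocks <- lapply(cys, function(cy) {
      vapply(lunge_muscles(),
             function(m) time_normalize_cycle(env[[m]], cy),
             numeric(CYCLE_POINTS))
    })
    t(do.call(rbind, blocks))
  })
  # divisor: per-muscle maximum over all of the direction's trials
  maxima <- apply(do.call(cbind, raw), 1, max)
  if (any(maxima <= 0)) {
    abort(paste0(
      "dead EMG channel(s) with zero maximum: ",
      paste(lunge_muscles()[maxima <= 0], collapse = ", ")
    ))
  }
  purrr::map(raw, function(v) {
    new_envelope_matrix(v / maxima, "per-direction-max",
                        ncol(v) %/% CYCLE_POINTS)
  })
}

#' Coactivation indices at hip, knee and ankle
#'
#' Per-time-point ratio of the averaged normalized antagonist EMG to the
#' averaged agonist EMG:
#' hip `(FL + RF)/2 : (ME + MA)/2`,
#' knee `(BF + ST)/2 : (RF + VM + VL)/3`,
#' ankle `TA : (GM + GL + SO)/3`.
#' Points with a zero denominator are undefined and returned as `NA`
#' (never silently zero), so that averages are not biased downward.
#'
#' @param v an `envelope_matrix` normalized to the per-direction maximum
#'   (see [normalize_per_direction()]).
#' @return tibble with `cycle`, `point`, `hip`, `knee`, `ankle`.
#' @export
coactivation <- function(v) {
  stopifnot(inherits(v, "envelope_matrix"))
  if (!identical(attr(v, "normalization"), "per-direction-max")) {
    warn("coactivation is defined on per-direction-max normalized envelopes.")
  }
  m <- function(...) colMeans(v[c(...), , drop = FALSE])
  ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  tibble(
    cycle = rep(seq_len(attr(v, "n_cycles")), each = CYCLE_POINTS),
    point = rep(seq_len(CYCLE_POINTS), times = attr(v, "n_cycles")),
    hip = ratio(m("FL", "RF"), m("ME", "MA")),
    knee = ratio(m("BF", "ST"), m("RF", "VM", "VL")),
    ankle = ratio(v["TA", ], m("GM", "GL", "SO"))
  )
}

# accept an envelope tibble (time + muscle columns) or matrix-like input
envelope_channels <- function(envelopes) {
  if (is.matrix(envelopes)) {
    if (nrow(envelopes) == length(lunge_muscles()) &&
        !is.null(rownames(envelopes))) {
      envelopes <- as.data.frame(t(envelopes))
    } else {
      envelopes <- as.data.frame(envelopes)
    }
  }
  missing <- setdiff(lunge_muscles(), names(envelopes))
  if (length(missing) > 0L) {
    abort(paste0("missing envelope channel(s): ", paste(missing, collapse = ", ")))
  }
  envelopes
}

as_cycle_list <- function(cycles) {
  if (inherits(cycles, "lunge_cycle")) cycles <- list(cycles)
  if (length(cycles) < 1L) abort("need at least one cycle.")
  stopifnot(all(vapply(cycles, inherits, logical(1), "lunge_cycle")))
  cycles
}
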