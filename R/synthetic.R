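#' Ground-truth synergies and synthetic trial specification
#'
#' `default_truth_modules()` returns a fixed, physiologically plausible
#' 13 x 4 module matrix (columns max-normalized to 1) for the four
#' fundamental lunge synergies: swing (dorsiflexor / hip-flexor
#' dominated), touchdown (plantar flexors and hamstrings), weight
#' acceptance (knee and hip extensors) and stabilization (foot
#' stabilizers, dorsiflexors and knee extensors).
#'
#' `synthetic_spec()` bundles everything the generators need: the
#' ground-truth synergies (modules plus Gaussian-bump primitives), the
#' number of cycles, the noise scale, cycle timing and the seed. The
#' generator output is a pure function of the spec (identical spec +
#' seed gives bit-identical output).
#'
#' @param centers primitive centers in normalized points (0-200).
#' @param width_sigma Gaussian width(s) of the primitives, in points.
#' @param amplitudes peak activations in (0, 1].
#' @param modules 13 x r non-negative matrix, columns max-normalized.
#' @param n_cycles number of cycles to generate.
#' @param noise_sd additive Gaussian noise sd relative to unit amplitude
#'   (truncated at zero after mixing).
#' @param jitter_center_sd cycle-to-cycle jitter of primitive centers, in
#'   points.
#' @param jitter_amp_sd relative cycle-to-cycle amplitude jitter.
#' @param swing_ms,stance_ms swing (lift-off to touchdown) and stance
#'   (touchdown to steady state) durations in ms.
#' @param seed integer seed.
#' @return `synthetic_spec()`: a `synthetic_spec` list.
#' @export
synthetic_spec <- function(centers = c(25, 60, 85, 120),
                           width_sigma = 6,
                           amplitudes = 1,
                           modules = default_truth_modules(length(centers)),
                           n_cycles = 25L,
                           noise_sd = 0.05,
                           jitter_center_sd = 2,
                           jitter_amp_sd = 0.05,
                           swing_ms = 350,
                           stance_ms = 800,
                           seed = 1L) {
  r <- length(centers)
  width_sigma <- rep_len(width_sigma, r)
  amplitudes <- rep_len(amplitudes, r)
  stopifnot(
    is.matrix(modules), nrow(modules) == length(lunge_muscles()),
    ncol(modules) == r
  )
  if (any(modules < 0)) abort("module weights must be non-negative.")
  if (any(abs(apply(modules, 2, max) - 1) > 1e-12)) {
    abort("module columns must be max-normalized to 1.")
  }
  if (any(centers <= 0 | centers >= CYCLE_POINTS)) {
    abort("primitive centers must lie strictly inside (0, 200).")
  }
  if (any(width_sigma <= 0)) abort("width_sigma must be positive.")
  if (any(amplitudes <= 0 | amplitudes > 1)) {
    abort("amplitudes must lie in (0, 1].")
  }
  if (n_cycles < 1L) abort("n_cycles must be >= 1.")
  if (noise_sd < 0) abort("noise_sd must be >= 0.")
  if (swing_ms <= 0 || stance_ms <= 0) abort("durations must be positive.")
  structure(
    list(
      centers = centers, width_sigma = width_sigma,
      amplitudes = amplitudes, modules = modules,
      n_cycles = as.integer(n_cycles), noise_sd = noise_sd,
      jitter_center_sd = jitter_center_sd, jitter_amp_sd = jitter_amp_sd,
      swing_ms = swing_ms, stance_ms = stance_ms, seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

#' @param r number of synergies (up to 5).
#' @rdname synthetic_spec
#' @return `default_truth_modules()`: 13 x r matrix.
#' @export
default_truth_modules <- function(r = 4L) {
  mm <- lunge_muscles()
  base <- matrix(0.05, nrow = length(mm), ncol = 5,
                 dimnames = list(mm, NULL))
  set_w <- function(j, w) {
    base[names(w), j] <<- w
  }
  set_w(1, c(TA = 1.0, FL = 0.8, RF = 0.6, ME = 0.5))
  set_w(2, c(GM = 1.0, GL = 0.9, SO = 0.8, ST = 0.5, BF = 0.4))
  set_w(3, c(VM = 1.0, VL = 0.9, RF = 0.7, MA = 0.6))
  set_w(4, c(PL = 1.0, TA = 0.7, GM = 0.5, SO = 0.5, VM = 0.4, VL = 0.3))
  set_w(5, c(MA = 1.0, ME = 0.8, BF = 0.6, ST = 0.5))
  if (r > 5L) abort("default truth modules support at most 5 synergies.")
  base[, seq_len(r), drop = FALSE]
}

gaussian_primitive <- function(center, sigma, amplitude,
                               n = CYCLE_POINTS) {
  t <- seq_len(n)
  amplitude * exp(-(t - center)^2 / (2 * sigma^2))
}

#' Generate a synthetic envelope matrix with known ground truth
#'
#' Builds `V = clip0(W H + noise)` from the spec's ground-truth modules
#' and Gaussian-bump primitives. Primitive centers and amplitudes are
#' jittered independently per cycle (emulating repetition-to-repetition
#' variability), the cycles are concatenated, and each muscle row is
#' rescaled to unit maximum, the scale the synergy extraction expects.
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements `v` (an `envelope_matrix`), and `truth`
#'   (modules `w`, noiseless primitive matrix `h`, per-cycle jittered
#'   centers, and the spec).
#' @export
simulate_envelopes <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  r <- length(spec$centers)
  n <- CYCLE_POINTS * spec$n_cycles
  h <- matrix(0, nrow = r, ncol = n)
  centers <- matrix(0, nrow = spec$n_cycles, ncol = r)
  for (k in seq_len(spec$n_cycles)) {
    for (j in seq_len(r)) {
      ck <- spec$centers[j] + rnorm(1, 0, spec$jitter_center_sd)
      ck <- min(max(ck, 1), CYCLE_POINTS)
      ak <- spec$amplitudes[j] * (1 + rnorm(1, 0, spec$jitter_amp_sd))
      ak <- max(ak, 0.05)
      centers[k, j] <- ck
      h[j, (k - 1) * CYCLE_POINTS + seq_len(CYCLE_POINTS)] <-
        gaussian_primitive(ck, spec$width_sigma[j], ak)
    }
  }
  v <- spec$modules %*% h
  if (spec$noise_sd > 0) {
    v <- v + matrix(rnorm(length(v), 0, spec$noise_sd), nrow = nrow(v))
  }
  v <- pmax(v, 0)
  mx <- apply(v, 1, max)
  if (any(mx <= 0)) {
    warn(paste0(
      "all-zero synthetic channel(s) after clipping: ",
      paste(lunge_muscles()[mx <= 0], collapse = ", ")
    ))
    mx[mx <= 0] <- 1
  }
  v <- v / mx
  list(
    v = new_envelope_matrix(v, "synergy", spec$n_cycles),
    truth = list(
      w = spec$modules, h = h, centers = centers, spec = spec
    )
  )
}

# quintic smoothstep and its derivatives; S'' peaks at s = 1/2 -/+ 1/(2 sqrt(3))
smoothstep5 <- function(s) {
  s <- pmin(pmax(s, 0), 1)
  6 * s^5 - 15 * s^4 + 10 * s^3
}
# fraction of the rise at which the acceleration has its jerk-zero minimum
S5_ACC_MIN <- 0.5 + 1 / (2 * sqrt(3))
S5_ACC_MAX <- 0.5 - 1 / (2 * sqrt(3))

#' Generate one synthetic lunge trial with known event times
#'
#' Constructs a full [trial_recording()]: a fifth-metatarsal vertical
#' trajectory whose filtered acceleration has its global maximum shortly
#' before a jerk-zero acceleration minimum at the known lift-off (a
#' quintic-smoothstep rise, hold, and slower descent); a ground reaction
#' force that is exactly zero during swing and ramps smoothly after the
#' known contact time; a knee angle that flexes, oscillates with a
#' decaying envelope and settles to an exact plateau at the known
#' steady-state time; and 13 EMG channels built as amplitude-modulated
#' noise whose modulation follows the spec's ground-truth synergies.
#'
#' @param spec a [synthetic_spec()].
#' @param direction `"forward"` or `"backward"`.
#' @param ground `"stable"` or `"unstable"`.
#' @param participant participant id string.
#' @param body_mass body mass in kg.
#' @param noise_kin_mm marker noise sd in mm (0 = noiseless).
#' @param noise_grf_n GRF noise sd in N (0 = noiseless).
#' @param cycle_index which cycle of the spec drives the EMG modulation
#'   (jittered per cycle); wrapped modulo `n_cycles`.
#' @return a [trial_recording()] with attribute `"truth"`: a list with
#'   the generative event times `t_liftoff`, `t_touchdown`, `t_steady`
#'   (s), the same as analog-timebase indices, and the EMG ground truth.
#' @export
simulate_trial <- function(spec, direction = "forward", ground = "stable",
                           participant = "P01", body_mass = 70,
                           noise_kin_mm = 0, noise_grf_n = 0,
                           cycle_index = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 7919L * as.integer(cycle_index))
  rate_kin <- 250
  rate_analog <- 1000
  swing <- spec$swing_ms / 1000
  stance <- spec$stance_ms / 1000
  pre <- 0.6   # quiet standing before the step
  post <- 0.4  # plateau carried past the steady state
  t_lo <- pre
  t_td <- t_lo + swing
  t_ss <- t_td + stance
  total <- t_ss + post

  tk <- seq(0, total, by = 1 / rate_kin)
  ta <- seq(0, total, by = 1 / rate_analog)

  # --- fifth metatarsal vertical trajectory (mm) ---
  t_rise <- 0.20
  t_desc <- min(0.30, swing - 0.25 * t_rise - 0.01)
  if (t_desc <= t_rise * 0.8) {
    abort("swing too short for a well-separated lift-off signature.")
  }
  rise_start <- t_lo - S5_ACC_MIN * t_rise
  desc_start <- t_td - t_desc
  h_foot <- 80 # mm
  foot_z <- h_foot * (smoothstep5((tk - rise_start) / t_rise) -
                        smoothstep5((tk - desc_start) / t_desc))

  # --- knee angle (deg, 180 = full extension) ---
  # deep flexion at touchdown, monotone settling toward the plateau with a
  # decaying oscillatory ripple that ends exactly at the steady state
  theta_plateau <- 155
  settle_amp <- 20
  ripple_amp <- 1.5
  f_osc <- 2.5 # Hz
  flex_td <- theta_plateau - settle_amp - ripple_amp
  theta <- rep(170, length(tk))
  sw <- tk >= t_lo & tk < t_td
  theta[sw] <- 170 - (170 - flex_td) * smoothstep5((tk[sw] - t_lo) / swing)
  st <- tk >= t_td & tk < t_ss
  s_st <- (tk[st] - t_td) / stance
  theta[st] <- theta_plateau - settle_amp * (1 - s_st)^2 -
    ripple_amp * (1 - s_st) * cos(2 * pi * f_osc * (tk[st] - t_td))
  theta[tk >= t_ss] <- theta_plateau

  # --- markers ---
  phi_th <- 20 * pi / 180
  l_th <- 400
  l_sh <- 400
  hip <- c(0, 0, 900)
  thigh_dir <- c(sin(phi_th), 0, -cos(phi_th))
  knee_pos <- t(vapply(seq_along(tk), function(i) hip + l_th * thigh_dir,
                       numeric(3)))
  bend <- (180 - theta) * pi / 180
  shank_dir <- cbind(sin(phi_th - bend), 0, -cos(phi_th - bend))
  ankle_pos <- knee_pos + l_sh * shank_dir
  prog <- smoothstep5((tk - t_lo) / swing)
  met5 <- cbind(500 + 120 * prog, 0, 20 + foot_z)
  calc <- met5 + matrix(rep(c(-150, 0, 40), each = length(tk)), ncol = 3)
  toe <- met5 + matrix(rep(c(60, 0, -5), each = length(tk)), ncol = 3)

  markers <- tibble(
    time = tk,
    trochanter_x = rep(hip[1], length(tk)),
    trochanter_y = rep(hip[2], length(tk)),
    trochanter_z = rep(hip[3], length(tk)),
    epicondyle_lat_x = knee_pos[, 1], epicondyle_lat_y = knee_pos[, 2],
    epicondyle_lat_z = knee_pos[, 3],
    malleolus_lat_x = ankle_pos[, 1], malleolus_lat_y = ankle_pos[, 2],
    malleolus_lat_z = ankle_pos[, 3],
    calcaneus_x = calc[, 1], calcaneus_y = calc[, 2], calcaneus_z = calc[, 3],
    metatarsal5_x = met5[, 1], metatarsal5_y = met5[, 2],
    metatarsal5_z = met5[, 3],
    toe_x = toe[, 1], toe_y = toe[, 2], toe_z = toe[, 3]
  )
  if (noise_kin_mm > 0) {
    for (cn in setdiff(names(markers), "time")) {
      markers[[cn]] <- markers[[cn]] + rnorm(length(tk), 0, noise_kin_mm)
    }
  }

  # --- ground reaction force (N) ---
  bw <- body_mass * 9.81
  tau <- ta - t_td
  # half-sine loading onset (peak 1.2 BW at 100 ms) then settling to BW;
  # the steep initial loading rate matches real impact plates
  loading <- sin(pi * pmin(pmax(tau, 0), 0.1) / 0.2)
  fz_clean <- ifelse(
    tau > 0,
    bw * (1.2 * loading - 0.2 * smoothstep5(tau / 0.6)),
    0
  )
  fx_clean <- ifelse(tau > 0, 0.08 * fz_clean * sin(pi * pmin(tau / stance, 1)), 0)
  first_loaded <- which(fz_clean > 0)[1]
  fz <- fz_clean
  fx <- fx_clean
  fy <- rep(0, length(ta))
  if (noise_grf_n > 0) {
    fz <- fz + rnorm(length(ta), 0, noise_grf_n)
    fx <- fx + rnorm(length(ta), 0, noise_grf_n)
    fy <- fy + rnorm(length(ta), 0, noise_grf_n)
  }

  # --- EMG: amplitude-modulated noise following the truth envelopes ---
  k <- ((as.integer(cycle_index) - 1L) %% spec$n_cycles) + 1L
  env_truth <- simulate_envelopes(spec)
  cols <- (k - 1L) * CYCLE_POINTS + seq_len(CYCLE_POINTS)
  env_cycle <- env_truth$v[, cols, drop = FALSE] # 13 x 200
  point_of_t <- function(t) {
    ifelse(
      t < t_lo, 1,
      ifelse(
        t < t_td, 1 + (t - t_lo) / swing * SWING_POINTS,
        ifelse(t <= t_ss,
               SWING_POINTS + 1 + (t - t_td) / stance * (STANCE_POINTS - 1),
               CYCLE_POINTS)
      )
    )
  }
  pts <- point_of_t(ta)
  analog <- tibble(time = ta, grf_x = fx, grf_y = fy, grf_z = fz)
  set.seed(spec$seed + 104729L * as.integer(cycle_index) + 1L)
  for (i in seq_along(lunge_muscles())) {
    env_t <- approx(seq_len(CYCLE_POINTS), env_cycle[i, ], xout = pts)$y
    analog[[paste0("emg_", lunge_muscles()[i])]] <-
      (0.02 + env_t) * rnorm(length(ta))
  }

  trial <- trial_recording(
    markers, analog,
    meta = list(
      participant = participant, body_mass = body_mass,
      limb_length = 0.9, direction = direction, ground = ground
    ),
    rate_kin = rate_kin, rate_analog = rate_analog
  )
  attr(trial, "truth") <- list(
    t_liftoff = t_lo, t_touchdown = t_td, t_steady = t_ss,
    liftoff_index = which.min(abs(ta - t_lo)),
    touchdown_index = first_loaded,
    steady_index = which.min(abs(ta - t_ss)),
    emg = list(w = env_truth$truth$w,
               centers = env_truth$truth$centers[k, ],
               cycle = k)
  )
  trial
}

#' Generate a static posture with analytic joint moments
#'
#' A motionless posture with a constant ground reaction force applied at
#' a fixed center of pressure. The expected hip, knee and ankle moments
#' are computed by static equilibrium (each joint balances the moment of
#' the GRF and of the weights of all segments distal to it), giving an
#' exact oracle for the inverse-dynamics stage.
#'
#' @param body_mass body mass in kg.
#' @param grf length-2 numeric, GRF in the sagittal plane `(Fx, Fz)` in N.
#' @param cop_offset anterior offset of the center of pressure from the
#'   ankle joint, in m.
#' @param duration_s recording length in s.
#' @param params segment parameters, see [winter_parameters()].
#' @param posture named list of sagittal joint positions in m:
#'   `hip`, `knee`, `ankle`, `toe` (each `c(x, z)`); defaults to a
#'   slightly flexed stance.
#' @return list with `trial` (a [trial_recording()] whose EMG channels
#'   are resting noise), `cop` (constant CoP trace, m), and `expected`
#'   (tibble of static hip/knee/ankle moments in N m,
#'   extension/plantarflexion positive).
#' @export
simulate_static_case <- function(body_mass = 70,
                                 grf = c(0, 700),
                                 cop_offset = 0.10,
                                 duration_s = 0.5,
                                 params = winter_parameters(),
                                 posture = NULL) {
  if (body_mass <= 0) abort("body mass must be positive.")
  if (is.null(posture)) {
    posture <- list(
      hip = c(0.00, 0.90), knee = c(0.10, 0.50),
      ankle = c(0.05, 0.10), toe = c(0.25, 0.05)
    )
  }
  seg_len <- function(a, b) sqrt(sum((a - b)^2))
  if (seg_len(posture$hip, posture$knee) <= 0 ||
      seg_len(posture$knee, posture$ankle) <= 0 ||
      seg_len(posture$ankle, posture$toe) <= 0) {
    abort("degenerate geometry: zero-length segment.")
  }
  rate_kin <- 250
  rate_analog <- 1000
  tk <- seq(0, duration_s, by = 1 / rate_kin)
  ta <- seq(0, duration_s, by = 1 / rate_analog)
  mm <- 1000
  const <- function(v) rep(v, length(tk))
  markers <- tibble(
    time = tk,
    trochanter_x = const(posture$hip[1] * mm),
    trochanter_y = const(0), trochanter_z = const(posture$hip[2] * mm),
    epicondyle_lat_x = const(posture$knee[1] * mm),
    epicondyle_lat_y = const(0),
    epicondyle_lat_z = const(posture$knee[2] * mm),
    malleolus_lat_x = const(posture$ankle[1] * mm),
    malleolus_lat_y = const(0),
    malleolus_lat_z = const(posture$ankle[2] * mm),
    calcaneus_x = const((posture$ankle[1] - 0.05) * mm),
    calcaneus_y = const(0),
    calcaneus_z = const((posture$ankle[2] - 0.05) * mm),
    metatarsal5_x = const((posture$toe[1] - 0.05) * mm),
    metatarsal5_y = const(0),
    metatarsal5_z = const(posture$toe[2] * mm),
    toe_x = const(posture$toe[1] * mm), toe_y = const(0),
    toe_z = const(posture$toe[2] * mm)
  )
  analog <- tibble(
    time = ta,
    grf_x = rep(grf[1], length(ta)),
    grf_y = rep(0, length(ta)),
    grf_z = rep(grf[2], length(ta))
  )
  set.seed(1L)
  for (m in lunge_muscles()) {
    analog[[paste0("emg_", m)]] <- 0.01 * rnorm(length(ta))
  }
  trial <- trial_recording(
    markers, analog,
    meta = list(participant = "static", body_mass = body_mass,
                limb_length = 0.9, direction = "forward",
                ground = "stable"),
    rate_kin = rate_kin, rate_analog = rate_analog
  )
  cop <- c(posture$ankle[1] + cop_offset, 0)
  expected <- static_joint_moments(
    joints = posture, cop = cop, grf = grf,
    body_mass = body_mass, params = params
  )
  list(trial = trial, cop = cop, expected = expected)
}

# static-equilibrium oracle: the internal moment at each joint balances
# the moment of the GRF and of all distal segment weights about it.
static_joint_moments <- function(joints, cop, grf, body_mass, params,
                                 g = 9.81) {
  coms <- segment_coms(joints, params)
  masses <- segment_masses(body_mass, params)
  cross2 <- function(r, f) r[2] * f[1] - r[1] * f[2]
  ext_moment <- function(joint, segs) {
    m <- cross2(cop - joints[[joint]], grf)
    for (s in segs) {
      m <- m + cross2(coms[[s]] - joints[[joint]], c(0, -masses[[s]] * g))
    }
    m
  }
  tibble(
    joint = c("ankle", "knee", "hip"),
    moment = c(
      -ext_moment("ankle", "foot"),
      -ext_moment("knee", c("foot", "shank")),
      -ext_moment("hip", c("foot", "shank", "thigh"))
    )
  )
}

segment_coms <- function(joints, params) {
  list(
    foot = joints$ankle +
      params$foot$com_frac * (joints$toe - joints$ankle),
    shank = joints$knee +
      params$shank$com_frac * (joints$ankle - joints$knee),
    thigh = joints$hip +
      params$thigh$com_frac * (joints$knee - joints$hip)
  )
}

segment_masses <- function(body_mass, params) {
  list(
    foot = params$foot$mass_frac * body_mass,
    shank = params$shank$mass_frac * body_mass,
    thigh = params$thigh$mass_frac * body_mass
  )
}

#' Simulate a whole study as a tibble of trials
#'
#' One row per lunge repetition, the layout [run_pipeline()] consumes.
#' Each condition (direction x ground) gets `n_cycles` repetitions whose
#' EMG modulation follows the per-cycle jittered ground truth of a shared
#' [synthetic_spec()].
#'
#' @param spec a [synthetic_spec()]; its `n_cycles` is the number of
#'   repetitions per condition.
#' @param participants character vector of participant ids.
#' @param directions,grounds condition levels to cross.
#' @return tibble with columns `participant`, `direction`, `ground`,
#'   `cycle` and a list-column `trial` of [trial_recording()] objects.
#' @export
simulate_study <- function(spec,
                           participants = "P01",
                           directions = "forward",
                           grounds = c("stable", "unstable")) {
  grid <- tidyr::expand_grid(
    participant = participants,
    direction = directions,
    ground = grounds,
    cycle = seq_len(spec$n_cycles)
  )
  grid$trial <- purrr::pmap(grid, function(participant, direction, ground,
                                           cycle) {
    sp <- spec
    sp$seed <- spec$seed +
      31L * match(ground, grounds) +
      131L * match(direction, directions) +
      1009L * match(participant, participants)
    simulate_trial(
      sp, direction = direction, ground = ground,
      participant = participant, cycle_index = cycle
    )
  })
  grid
}
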