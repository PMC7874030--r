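#' Winter-style segment inertial parameters
#'
#' Mass fraction of body mass, center-of-mass location as a fraction of
#' segment length from the proximal end, and radius of gyration about the
#' CoM as a fraction of segment length, for foot, shank and thigh. These
#' are external literature constants (standard anthropometry tables);
#' they can be overridden directly or loaded from a YAML file with the
#' same structure.
#'
#' @param path optional YAML file with entries
#'   `foot/shank/thigh: {mass_frac, com_frac, rog_frac}`.
#' @return nested named list of class `segment_parameters`.
#' @export
winter_parameters <- function(path = NULL) {
  p <- if (is.null(path)) {
    list(
      foot = list(mass_frac = 0.0145, com_frac = 0.50, rog_frac = 0.475),
      shank = list(mass_frac = 0.0465, com_frac = 0.433, rog_frac = 0.302),
      thigh = list(mass_frac = 0.100, com_frac = 0.433, rog_frac = 0.323)
    )
  } else {
    yaml::read_yaml(path)
  }
  for (s in c("foot", "shank", "thigh")) {
    for (f in c("mass_frac", "com_frac", "rog_frac")) {
      v <- p[[s]][[f]]
      if (is.null(v) || v <= 0 || v >= 1) {
        abort(sprintf("segment parameter %s$%s must lie in (0, 1).", s, f))
      }
    }
  }
  if (sum(vapply(p, `[[`, numeric(1), "mass_frac")) >= 1) {
    abort("limb segment masses must sum to less than the body mass.")
  }
  structure(p, class = c("segment_parameters", "list"))
}

#' Sagittal-plane joint angles from markers
#'
#' Projects the marker trajectories onto the sagittal (x-z) plane and
#' computes, per frame: the hip angle as the inclination of the thigh
#' vector (greater trochanter to lateral epicondyle) from the downward
#' vertical, positive when the knee is anterior to the hip (flexion);
#' the knee angle as the inter-segment angle between thigh and shank
#' (epicondyle to malleolus) vectors with 180 deg at full extension; and
#' the ankle angle as the inter-segment angle between the shank and foot
#' (calcaneus to fifth metatarsal) vectors, 90 deg at the anatomical
#' reference. Inter-segment angles are invariant to rigid rotation of
#' all markers; the hip inclination shifts with the rotation.
#'
#' @param markers marker tibble of a [trial_recording()] (a `time`
#'   column plus `<marker>_{x,y,z}` columns in mm).
#' @param fs kinematic sampling rate (Hz); when given together with
#'   `lpf_cutoff`, marker columns are zero-phase low-pass filtered first.
#' @param lpf_cutoff optional low-pass cutoff in Hz.
#' @return tibble with `time`, `hip`, `knee`, `ankle` (deg) and the
#'   segment inclinations `thigh_incl`, `shank_incl`, `foot_incl` (deg,
#'   from the downward vertical, anterior positive).
#' @export
joint_angles <- function(markers, fs = NULL, lpf_cutoff = NULL) {
  need <- as.vector(outer(lunge_markers(), c("x", "z"), paste, sep = "_"))
  missing <- setdiff(need, names(markers))
  if (length(missing) > 0L) {
    abort(paste0("missing marker column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyNA(markers[need])) {
    abort("marker dropout beyond the gap-fill limit; cannot compute angles.")
  }
  get <- function(cn) {
    v <- markers[[cn]]
    if (!is.null(lpf_cutoff) && !is.null(fs)) {
      v <- filter_zerophase(v, lpf_cutoff, fs, "low")
    }
    v
  }
  vx <- function(a, b) get(paste0(b, "_x")) - get(paste0(a, "_x"))
  vz <- function(a, b) get(paste0(b, "_z")) - get(paste0(a, "_z"))
  th_x <- vx("trochanter", "epicondyle_lat")
  th_z <- vz("trochanter", "epicondyle_lat")
  sh_x <- vx("epicondyle_lat", "malleolus_lat")
  sh_z <- vz("epicondyle_lat", "malleolus_lat")
  ft_x <- vx("calcaneus", "metatarsal5")
  ft_z <- vz("calcaneus", "metatarsal5")
  incl <- function(x, z) atan2(x, -z) * 180 / pi
  between <- function(ax, az, bx, bz) {
    dot <- ax * bx + az * bz
    na <- sqrt(ax^2 + az^2)
    nb <- sqrt(bx^2 + bz^2)
    acos(pmin(pmax(dot / (na * nb), -1), 1)) * 180 / pi
  }
  tibble(
    time = markers$time,
    hip = incl(th_x, th_z),
    knee = 180 - between(th_x, th_z, sh_x, sh_z),
    ankle = between(sh_x, sh_z, ft_x, ft_z),
    thigh_incl = incl(th_x, th_z),
    shank_incl = incl(sh_x, sh_z),
    foot_incl = incl(ft_x, ft_z)
  )
}

# planar Newton-Euler balance of one segment.
# Returns the proximal joint force and moment given the distal external
# load. Moments about the mediolateral axis with cross2(r, f) =
# r_z f_x - r_x f_z, which makes extension / plantarflexion moments of a
# right limb positive in an x-forward, z-up frame.
planar_segment_load <- function(m_seg, i_seg, p_com, a_com, alpha,
                                p_prox, f_dist, p_dist, m_dist,
                                g = 9.81) {
  cross2 <- function(r, f) r[2] * f[1] - r[1] * f[2]
  f_prox <- m_seg * a_com - c(0, -m_seg * g) - f_dist
  # alpha is the counter-clockwise angular acceleration; stored moments
  # are clockwise-positive (extension/plantarflexion), hence the minus
  m_prox <- -i_seg * alpha - m_dist -
    cross2(p_dist - p_com, f_dist) -
    cross2(p_prox - p_com, f_prox)
  list(f = f_prox, m = m_prox)
}

#' Resultant sagittal joint moments by link-segment inverse dynamics
#'
#' Bottom-up Newton-Euler recursion in the sagittal plane. For each
#' frame, the foot segment balances the ground reaction force applied at
#' the center of pressure (zero during swing), its own weight and
#' inertial load; the resulting ankle reaction is propagated to the
#' shank and thigh. Segment masses, CoM locations and moments of inertia
#' come from [winter_parameters()] fractions of body mass and measured
#' segment lengths. Linear accelerations are 2nd central differences of
#' the filtered marker-based CoM positions, angular accelerations 2nd
#' differences of the unwrapped segment angles. Extension and
#' plantarflexion moments are positive.
#'
#' @param trial a [trial_recording()].
#' @param cop center of pressure: matrix/data frame with x and z in m on
#'   the analog timebase, a length-2 vector for a constant CoP, or
#'   `NULL` to place it under the fifth metatarsal head.
#' @param params a [winter_parameters()] list.
#' @param lpf_cutoff marker low-pass cutoff (Hz).
#' @return tibble with `time`, `ankle`, `knee`, `hip` moments (N m) at
#'   the kinematic rate.
#' @export
inverse_dynamics <- function(trial, cop = NULL,
                             params = winter_parameters(),
                             lpf_cutoff = 50) {
  stopifnot(inherits(trial, "trial_recording"))
  mass <- trial$meta$body_mass
  if (is.null(mass) || mass <= 0) abort("trial metadata needs a positive body_mass.")
  mk <- trial$markers
  fs <- trial$rate_kin
  nk <- nrow(mk)
  sm <- function(cn) filter_zerophase(mk[[cn]], lpf_cutoff, fs, "low") / 1000
  hip_p <- cbind(sm("trochanter_x"), sm("trochanter_z"))
  knee_p <- cbind(sm("epicondyle_lat_x"), sm("epicondyle_lat_z"))
  ankle_p <- cbind(sm("malleolus_lat_x"), sm("malleolus_lat_z"))
  toe_p <- cbind(sm("toe_x"), sm("toe_z"))
  met_p <- cbind(sm("metatarsal5_x"), sm("metatarsal5_z"))

  segs <- list(
    foot = list(prox = ankle_p, dist = toe_p, par = params$foot),
    shank = list(prox = knee_p, dist = ankle_p, par = params$shank),
    thigh = list(prox = hip_p, dist = knee_p, par = params$thigh)
  )
  dt <- 1 / fs
  kin <- lapply(segs, function(s) {
    com <- s$prox + s$par$com_frac * (s$dist - s$prox)
    len <- sqrt(rowSums((s$dist - s$prox)^2))
    ang <- unwrap_angle(atan2(
      s$dist[, 2] - s$prox[, 2], s$dist[, 1] - s$prox[, 1]
    ))
    list(
      com = com,
      acc = cbind(second_diff(com[, 1], dt), second_diff(com[, 2], dt)),
      alpha = second_diff(ang, dt),
      m = s$par$mass_frac * mass,
      i = s$par$mass_frac * mass * (s$par$rog_frac * mean(len))^2
    )
  })

  # GRF and CoP on the kinematic timebase
  ka <- function(i) kin_to_analog_index(i, fs, trial$rate_analog)
  ai <- pmin(ka(seq_len(nk)), nrow(trial$analog))
  grf <- cbind(trial$analog$grf_x[ai], trial$analog$grf_z[ai])
  loaded <- sqrt(trial$analog$grf_x[ai]^2 + trial$analog$grf_y[ai]^2 +
                   trial$analog$grf_z[ai]^2) > 0
  grf[!loaded, ] <- 0
  cop_k <- if (is.null(cop)) {
    met_p
  } else if (is.numeric(cop) && is.null(dim(cop))) {
    matrix(rep(cop[c(1, length(cop))], each = nk), ncol = 2)
  } else {
    cop <- as.matrix(cop)
    cbind(cop[ai, 1], cop[ai, ncol(cop)])
  }
  if (any(loaded & (is.na(cop_k[, 1]) | is.na(cop_k[, 2])))) {
    abort("missing center of pressure during loaded samples.")
  }

  out <- matrix(NA_real_, nrow = nk, ncol = 3,
                dimnames = list(NULL, c("ankle", "knee", "hip")))
  for (t in seq_len(nk)) {
    f_dist <- grf[t, ]
    p_dist <- cop_k[t, ]
    m_dist <- 0
    joints <- list(
      list(seg = "foot", prox = ankle_p[t, ]),
      list(seg = "shank", prox = knee_p[t, ]),
      list(seg = "thigh", prox = hip_p[t, ])
    )
    for (j in seq_along(joints)) {
      s <- joints[[j]]$seg
      load <- planar_segment_load(
        kin[[s]]$m, kin[[s]]$i, kin[[s]]$com[t, ], kin[[s]]$acc[t, ],
        kin[[s]]$alpha[t], joints[[j]]$prox, f_dist, p_dist, m_dist
      )
      out[t, j] <- load$m
      f_dist <- -load$f
      p_dist <- joints[[j]]$prox
      m_dist <- -load$m
    }
  }
  tibble(
    time = mk$time,
    ankle = out[, "ankle"], knee = out[, "knee"], hip = out[, "hip"]
  )
}

second_diff <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1L)] <- (x[3:n] - 2 * x[2:(n - 1L)] + x[1:(n - 2L)]) / dt^2
  d[1] <- d[2]
  d[n] <- d[n - 1L]
  d
}

unwrap_angle <- function(a) {
  d <- diff(a)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(a[1], a[1] + cumsum(d))
}
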