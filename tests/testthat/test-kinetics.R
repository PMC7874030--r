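test_that("joint angle conventions hold on constructed geometries", {
  mk <- tibble::tibble(
    time = c(0, 0.004),
    trochanter_x = 0, trochanter_y = 0, trochanter_z = 900,
    epicondyle_lat_x = 0, epicondyle_lat_y = 0, epicondyle_lat_z = 500,
    malleolus_lat_x = 0, malleolus_lat_y = 0, malleolus_lat_z = 100,
    calcaneus_x = -50, calcaneus_y = 0, calcaneus_z = 100,
    metatarsal5_x = 150, metatarsal5_y = 0, metatarsal5_z = 100,
    toe_x = 210, toe_y = 0, toe_z = 95
  )
  ang <- joint_angles(mk)
  # collinear thigh and shank: fully extended knee = 180 deg
  expect_equal(ang$knee, rep(180, 2), tolerance = 1e-9)
  # vertical shank, horizontal foot: anatomical ankle = 90 deg
  expect_equal(ang$ankle, rep(90, 2), tolerance = 1e-9)
  # vertical thigh: zero hip inclination
  expect_equal(ang$hip, rep(0, 2), tolerance = 1e-9)
})

test_that("rigid rotation shifts segment inclinations but not joint angles", {
  tr <- simulate_trial(tiny_spec(seed = 71))
  mk <- tr$markers[100:140, ]
  phi <- 17 * pi / 180
  rot <- mk
  for (m in lunge_markers()) {
    x <- mk[[paste0(m, "_x")]]
    z <- mk[[paste0(m, "_z")]]
    rot[[paste0(m, "_x")]] <- cos(phi) * x - sin(phi) * z
    rot[[paste0(m, "_z")]] <- sin(phi) * x + cos(phi) * z
  }
  a0 <- joint_angles(mk)
  a1 <- joint_angles(rot)
  expect_equal(a1$knee, a0$knee, tolerance = 1e-9)
  expect_equal(a1$ankle, a0$ankle, tolerance = 1e-9)
  expect_equal(a1$thigh_incl - a0$thigh_incl,
               rep(phi * 180 / pi, nrow(mk)), tolerance = 1e-9)
})

test_that("inverse dynamics matches the static-equilibrium oracle exactly", {
  for (off in c(0, 0.10)) {
    case <- simulate_static_case(cop_offset = off)
    mom <- inverse_dynamics(case$trial, cop = case$cop)
    mid <- 30:100 # away from finite-difference edges
    got <- colMeans(mom[mid, c("ankle", "knee", "hip")])
    expect_equal(unname(got), case$expected$moment, tolerance = 1e-10)
  }
  # the canonical lever case: 700 N at 0.10 m anterior to the ankle adds
  # exactly 70 N m of plantarflexion moment
  c0 <- simulate_static_case(cop_offset = 0)
  c1 <- simulate_static_case(cop_offset = 0.10)
  m0 <- inverse_dynamics(c0$trial, cop = c0$cop)
  m1 <- inverse_dynamics(c1$trial, cop = c1$cop)
  expect_equal(mean(m1$ankle[30:100]) - mean(m0$ankle[30:100]), 70,
               tolerance = 1e-10)
})

test_that("doubling body mass doubles the gravitational moment share", {
  case1 <- simulate_static_case(body_mass = 70, grf = c(0, 0.001))
  case2 <- simulate_static_case(body_mass = 140, grf = c(0, 0.001))
  m1 <- inverse_dynamics(case1$trial, cop = case1$cop)
  m2 <- inverse_dynamics(case2$trial, cop = case2$cop)
  expect_equal(mean(m2$hip[30:100]) / mean(m1$hip[30:100]), 2,
               tolerance = 1e-4)
})

test_that("moments are invariant to horizontal translation of the frame", {
  case <- simulate_static_case(cop_offset = 0.08)
  tr2 <- case$trial
  for (m in lunge_markers()) {
    cn <- paste0(m, "_x")
    tr2$markers[[cn]] <- tr2$markers[[cn]] + 1500 # mm
  }
  m1 <- inverse_dynamics(case$trial, cop = case$cop)
  m2 <- inverse_dynamics(tr2, cop = case$cop + c(1.5, 0))
  expect_equal(m2[30:100, -1], m1[30:100, -1], tolerance = 1e-9)
})

test_that("a prescribed pendulum's torque is recovered within 1% RMS", {
  fs <- 1000
  tt <- seq(0, 2, by = 1 / fs)
  len <- 1
  m_seg <- 2
  th0 <- 0.3
  om <- sqrt(9.81 / (0.5 * len))
  theta <- th0 * cos(om * tt) # angle from the downward vertical
  com <- cbind(0.5 * len * sin(theta), -0.5 * len * cos(theta))
  i_com <- m_seg * (0.3 * len)^2
  alpha <- lungesyn:::second_diff(theta, 1 / fs)
  acc <- cbind(lungesyn:::second_diff(com[, 1], 1 / fs),
               lungesyn:::second_diff(com[, 2], 1 / fs))
  tau <- vapply(seq_along(tt), function(i) {
    lungesyn:::planar_segment_load(
      m_seg, i_com, com[i, ], acc[i, ], alpha[i],
      p_prox = c(0, 0), f_dist = c(0, 0), p_dist = c(0, 0), m_dist = 0
    )$m
  }, numeric(1))
  i_piv <- i_com + m_seg * (0.5 * len)^2
  tau_ref <- -(i_piv * (-th0 * om^2 * cos(om * tt)) +
                 m_seg * 9.81 * 0.5 * len * sin(theta))
  keep <- 10:(length(tt) - 10)
  rel_rms <- sqrt(mean((tau[keep] - tau_ref[keep])^2)) /
    sqrt(mean(tau_ref[keep]^2))
  expect_lt(rel_rms, 0.01)
})

test_that("anthropometric parameters are validated", {
  expect_error(
    winter_parameters(path = withr::local_tempfile(
      lines = "foot:\n  mass_frac: 1.5\n  com_frac: 0.5\n  rog_frac: 0.4\n",
      fileext = ".yaml"
    )),
    "mass_frac"
  )
  p <- winter_parameters()
  expect_lt(sum(vapply(p, `[[`, numeric(1), "mass_frac")), 1)
})
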