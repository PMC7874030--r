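test_that("touchdown is the first sample whose GRF norm exceeds threshold", {
  grf <- matrix(0, nrow = 1000, ncol = 3)
  grf[412:1000, 3] <- 700
  expect_equal(detect_touchdown(grf), 412L)
  grf2 <- matrix(1, nrow = 100, ncol = 3)
  expect_equal(detect_touchdown(grf2), 1L)
  expect_error(detect_touchdown(matrix(0, 100, 3)), "no contact")
  # threshold as configured
  grf3 <- matrix(0, 500, 3)
  grf3[, 3] <- c(rep(4, 200), rep(50, 300))
  expect_equal(detect_touchdown(grf3, event_config(grf_threshold = 10)), 201L)
})

test_that("noisy touchdown detection stays within 2 ms of the true contact", {
  for (s in c(4L, 11L, 30L)) {
    tr <- simulate_trial(synthetic_spec(seed = s), noise_grf_n = 2)
    truth <- attr(tr, "truth")
    td <- detect_touchdown(tr$analog[, c("grf_x", "grf_y", "grf_z")],
                           event_config(grf_threshold = 10))
    expect_lte(abs(td - truth$touchdown_index), 2L)
  }
})

test_that("lift-off lands on the jerk-zero acceleration minimum", {
  # constructed trajectory with a unique acceleration max then a unique
  # jerk-zero acceleration minimum, as in the generator
  tr <- simulate_trial(tiny_spec(seed = 31))
  truth <- attr(tr, "truth")
  td_k <- lungesyn:::analog_to_kin_index(truth$touchdown_index, 250, 1000)
  lo_k <- detect_liftoff(tr$markers$metatarsal5_z, td_k, 250)
  lo_ms <- (lo_k - 1) * 4
  expect_lte(abs(lo_ms - truth$t_liftoff * 1000), 5)
  # offsetting the whole trace does not move the event
  lo_k2 <- detect_liftoff(tr$markers$metatarsal5_z + 250, td_k, 250)
  expect_equal(lo_k2, lo_k)
})

test_that("with several jerk-zero minima the one nearest the estimate wins,
           ties toward the earlier sample", {
  fs <- 250
  tt <- seq(0, 2, by = 1 / fs)
  # oscillation superimposed on a dominant acceleration peak gives several
  # jerk-zero acceleration minima inside the neighborhood
  z <- 40 * exp(-((tt - 1.6) / 0.05)^2) + 2 * sin(2 * pi * 8 * tt)
  td <- length(tt)
  cfg <- event_config(lpf_cutoff = 40)
  # brute-force scan mirroring the detector's definitions
  z_f <- filter_zerophase(z, 40, fs, "low")
  acc <- lungesyn:::central_diff(lungesyn:::central_diff(z_f, 1 / fs), 1 / fs)
  jerk <- lungesyn:::central_diff(acc, 1 / fs)
  w0 <- max(1L, td - round(800 / 1000 * fs))
  loe <- (w0:td)[which.max(acc[w0:td])]
  n0 <- loe + round(-50 / 1000 * fs)
  n1 <- min(length(acc) - 1L, loe + round(200 / 1000 * fs))
  cand <- integer(0)
  for (i in n0:n1) {
    if (jerk[i] < 0 && jerk[i + 1] >= 0) {
      cand <- c(cand, if (abs(jerk[i]) <= abs(jerk[i + 1])) i else i + 1L)
    }
  }
  got <- detect_liftoff(z, td, fs, cfg)
  expect_true(got %in% cand)
  expect_equal(got, cand[order(abs(cand - loe), cand)][1])
})

test_that("the energy split agrees with the O(n^3) brute-force scan", {
  set.seed(6)
  cases <- list(
    c(rnorm(60, 0, 1), rnorm(80, 3, 1)),
    c(rnorm(70, 0, 0.3), rnorm(90, 0, 2.5)), # variance change
    c(rnorm(100, -1, 1), rnorm(100, 1.2, 1))
  )
  for (x in cases) {
    a <- lungesyn:::best_energy_split(x, 30L)
    b <- lungesyn:::energy_best_split_bruteforce(x, 30L)
    expect_equal(a$tau, b$tau)
    expect_equal(a$q, b$q, tolerance = 1e-9)
  }
})

test_that("divisive segmentation finds an obvious slope boundary and
           handles flat series", {
  # constant nonzero slope then exactly zero
  x <- c(rep(2, 90), rep(0, 110))
  set.seed(7)
  cps <- energy_divisive(x)
  expect_true(any(abs(cps - 91) <= 1))
  set.seed(7)
  expect_equal(detect_steady_state(
    c(seq(100, 130, length.out = 91), rep(130, 109)), td = 1, fs = 250
  ) > 80, TRUE)
  # entirely flat series: no change point, steady from the start
  set.seed(8)
  expect_equal(energy_divisive(rep(1.5, 120)), integer(0))
  expect_equal(detect_steady_state(rep(130, 200), td = 5, fs = 250), 5L)
})

test_that("all three events are recovered on noiseless generator trials", {
  for (s in c(3L, 21L)) {
    tr <- simulate_trial(synthetic_spec(seed = s))
    truth <- attr(tr, "truth")
    set.seed(100 + s)
    cy <- segment_trial(tr)
    expect_equal(cy$touchdown, truth$touchdown_index)
    expect_lte(abs(cy$lift_off - truth$liftoff_index), 5)
    expect_lte(abs(cy$steady_state_end - truth$steady_index), 50)
    expect_true(cy$lift_off < cy$touchdown &&
                  cy$touchdown < cy$steady_state_end)
  }
})

test_that("trials without contact fail loudly and out-of-order events are
           refused", {
  tr <- simulate_trial(tiny_spec(seed = 32))
  tr$analog$grf_x <- 0
  tr$analog$grf_y <- 0
  tr$analog$grf_z <- 0
  expect_error(segment_trial(tr), "no contact")
  expect_error(lunge_cycle(500, 400, 900), "out of order")
  expect_error(lunge_cycle(100, 400, 300), "out of order")
})
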