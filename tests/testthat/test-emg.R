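test_that("zero-phase filtering is symmetric under time reversal", {
  set.seed(1)
  x <- sin(2 * pi * 3 * seq(0, 2, by = 1e-3)) + cumsum(rnorm(2001, 0, 1e-3))
  for (type in c("low", "high")) {
    co <- if (type == "low") 20 else 50
    y <- filter_zerophase(x, co, 1000, type)
    yr <- rev(filter_zerophase(rev(x), co, 1000, type))
    expect_lt(max(abs(y - yr)) / diff(range(x)), 1e-8)
  }
})

test_that("the envelope of a pure sine matches the rectified-sine mean", {
  t <- seq(0, 2, by = 1e-3)
  for (a in c(0.5, 1, 3)) {
    env <- emg_envelope(a * sin(2 * pi * 100 * t), 1000)
    mid <- 500:1500
    expect_lt(abs(mean(env[mid]) - 2 * a / pi) / (2 * a / pi), 0.05)
  }
})

test_that("the envelope kills DC, maps zero to zero and is homogeneous", {
  n <- 2000
  expect_lt(max(emg_envelope(rep(3.3, n), 1000)[300:1700]), 0.02)
  expect_equal(emg_envelope(rep(0, n), 1000), rep(0, n))
  set.seed(2)
  x <- rnorm(n)
  expect_equal(emg_envelope(2.5 * x, 1000), 2.5 * emg_envelope(x, 1000),
               tolerance = 1e-10)
  expect_error(emg_envelope(x, 90), "too low")
})

test_that("time normalization puts 50 swing + 150 stance points with the
           touchdown at the 50/51 boundary", {
  # identity grid: input already 50 + 150 samples
  x <- rnorm(200)
  cy <- lunge_cycle(1, 51, 200, rate = 200)
  expect_equal(time_normalize_cycle(x, cy), x)
  # linear ramp stays a linear ramp
  ramp <- seq(0, 1, length.out = 400)
  cy2 <- lunge_cycle(10, 110, 390, rate = 1000)
  out <- time_normalize_cycle(ramp, cy2)
  expect_equal(length(out), 200L)
  expect_lt(max(abs(diff(out[1:50]) - diff(out[1:50])[1])), 1e-9)
  expect_equal(out[51], ramp[110]) # touchdown sample maps to point 51
  # sine segment against its closed form
  fs <- 1000
  tt <- seq(0, 1, by = 1 / fs)
  s <- sin(2 * pi * 3 * tt)
  cy3 <- lunge_cycle(101, 301, 901, rate = fs)
  out3 <- time_normalize_cycle(s, cy3)
  swing_t <- (seq(101, 301, length.out = 51)[-51] - 1) / fs
  stance_t <- (seq(301, 901, length.out = 150) - 1) / fs
  expect_equal(out3, sin(2 * pi * 3 * c(swing_t, stance_t)),
               tolerance = 1e-4)
  expect_error(time_normalize_cycle(s, lunge_cycle(1, 2, 500)), "swing")
})

test_that("synergy normalization spans [0,1] per muscle and concatenates
           cycles blockwise", {
  set.seed(3)
  n <- 3000
  env <- flat_envelopes(abs(rnorm(n)))
  for (m in lunge_muscles()) env[[m]] <- abs(rnorm(n)) * runif(1, 0.5, 4)
  cycles <- list(
    lunge_cycle(1, 300, 1000), lunge_cycle(1001, 1300, 2000),
    lunge_cycle(2001, 2300, 2990)
  )
  v <- normalize_for_synergies(env, cycles)
  expect_s3_class(v, "envelope_matrix")
  expect_equal(ncol(v), 600L)
  expect_equal(unname(apply(v, 1, min)), rep(0, 13))
  expect_equal(unname(apply(v, 1, max)), rep(1, 13))
  expect_error(
    normalize_for_synergies(dplyr::mutate(env, SO = 0), cycles), "SO"
  )
  expect_warning(
    normalize_for_synergies(dplyr::mutate(env, SO = 2), cycles), "constant"
  )
})

test_that("per-direction normalization shares the divisor across trials and
           is scale invariant", {
  set.seed(4)
  env1 <- flat_envelopes(abs(rnorm(1000)))
  env2 <- dplyr::mutate(env1, dplyr::across(-time, ~ .x * 2))
  cys <- list(lunge_cycle(1, 200, 900))
  # single trial: identical to per-trial max scaling
  v1 <- normalize_per_direction(list(env1), list(cys))[[1]]
  expect_equal(unname(apply(v1, 1, max)), rep(1, 13), tolerance = 1e-9)
  # two trials, max in trial 2: trial 1 peak < 1
  both <- normalize_per_direction(list(env1, env2), list(cys, cys))
  expect_true(all(apply(both[[1]], 1, max) <= 0.5 + 1e-9))
  expect_equal(unname(apply(both[[2]], 1, max)), rep(1, 13),
               tolerance = 1e-9)
  # uniform positive rescaling of all inputs changes nothing
  scaled <- normalize_per_direction(
    list(dplyr::mutate(env1, dplyr::across(-time, ~ .x * 7)),
         dplyr::mutate(env2, dplyr::across(-time, ~ .x * 7))),
    list(cys, cys)
  )
  expect_equal(unclass(scaled[[1]]), unclass(both[[1]]), tolerance = 1e-12)
})

test_that("coactivation matches a direct evaluation of the ratio formulas", {
  set.seed(5)
  for (rep in 1:20) {
    v <- matrix(runif(13 * 200), 13, 200,
                dimnames = list(lunge_muscles(), NULL))
    vm <- lungesyn:::new_envelope_matrix(v, "per-direction-max", 1L)
    got <- coactivation(vm)
    want <- coactivation_bruteforce(v)
    expect_equal(got$hip, unname(want[, "hip"]), tolerance = 1e-12)
    expect_equal(got$knee, unname(want[, "knee"]), tolerance = 1e-12)
    expect_equal(got$ankle, unname(want[, "ankle"]), tolerance = 1e-12)
  }
  # symmetry: all channels equal -> all ratios 1; zero antagonists -> 0
  v <- matrix(0.7, 13, 200, dimnames = list(lunge_muscles(), NULL))
  vm <- lungesyn:::new_envelope_matrix(v, "per-direction-max", 1L)
  cc <- coactivation(vm)
  expect_equal(cc$hip, rep(1, 200))
  expect_equal(cc$knee, rep(1, 200))
  expect_equal(cc$ankle, rep(1, 200))
  v2 <- v
  v2[c("FL", "RF", "BF", "ST", "TA"), ] <- 0
  # RF is both a hip antagonist and knee agonist; knee ratio is 0, hip
  # numerator only partly zero
  vm2 <- lungesyn:::new_envelope_matrix(v2, "per-direction-max", 1L)
  cc2 <- coactivation(vm2)
  expect_equal(cc2$knee, rep(0, 200))
  expect_equal(cc2$ankle, rep(0, 200))
  # zero denominator is NA, not zero
  v3 <- v
  v3[c("ME", "MA"), ] <- 0
  vm3 <- lungesyn:::new_envelope_matrix(v3, "per-direction-max", 1L)
  expect_true(all(is.na(coactivation(vm3)$hip)))
})
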