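test_that("an exact low-rank matrix is reconstructed at its true rank", {
  set.seed(51)
  w0 <- matrix(runif(13 * 3), 13, 3)
  h0 <- matrix(runif(3 * 400), 3, 400)
  fit <- synergy_nmf(w0 %*% h0, 3, seed = 52L, n_restarts = 5)
  expect_gte(fit$r2, 0.999)
  expect_true(all(fit$w >= 0))
  expect_true(all(fit$h >= 0))
  # stored solution is the best of the restarts
  expect_equal(fit$r2, max(fit$restarts$r2))
  # primitive rows are unit-maximum after scale fixing
  expect_equal(unname(apply(fit$h, 1, max)), rep(1, 3), tolerance = 1e-12)
})

test_that("R^2 never decreases across iterations within a restart", {
  set.seed(53)
  v <- matrix(runif(13 * 400), 13, 400)
  fit <- synergy_nmf(v, 2, seed = 54L, n_restarts = 2, trace_r2 = TRUE)
  expect_true(all(diff(fit$r2_path) >= -1e-12))
})

test_that("R^2 is monotone in rank up to restart noise", {
  set.seed(55)
  v <- matrix(runif(13 * 300), 13, 300)
  r2 <- vapply(c(2L, 5L, 9L), function(r) {
    synergy_nmf(v, r, seed = 56L, n_restarts = 3)$r2
  }, numeric(1))
  expect_true(all(diff(r2) > -1e-3))
})

test_that("degenerate inputs are refused", {
  v <- matrix(runif(13 * 100), 13, 100)
  expect_error(synergy_nmf(v, 11), "rank")
  expect_error(synergy_nmf(v, 0), "rank")
  vneg <- v
  vneg[1, 1] <- -1
  expect_error(synergy_nmf(vneg, 2), "non-negative")
  expect_error(synergy_nmf(matrix(0.5, 13, 100), 2), "variance")
  vdead <- v
  vdead[4, ] <- 0
  expect_error(synergy_nmf(vdead, 2), "all-zero")
})

test_that("permuting the muscle order permutes W and leaves H-side metrics
           unchanged", {
  spec <- tiny_spec(n_cycles = 2L, seed = 57L)
  v <- unclass(simulate_envelopes(spec)$v)
  fit <- synergy_nmf(v, 4, seed = 58L, n_restarts = 4)
  set.seed(59)
  perm <- sample(13)
  fitp <- synergy_nmf(v[perm, ], 4, seed = 58L, n_restarts = 4)
  expect_equal(fitp$r2, fit$r2, tolerance = 1e-4)
  # match primitives across the two fits and compare CoA / FWHM
  p1 <- primitive_mean_cycle(fit)
  p2 <- primitive_mean_cycle(fitp)
  match_j <- apply(p1 %*% t(p2) /
                     outer(sqrt(rowSums(p1^2)), sqrt(rowSums(p2^2))),
                   1, which.max)
  expect_equal(sort(match_j), 1:4)
  circ_diff <- function(a, b) {
    d <- abs(a - b) %% 200
    min(d, 200 - d)
  }
  for (j in 1:4) {
    expect_lt(circ_diff(compute_coa(p1[j, ]), compute_coa(p2[match_j[j], ])), 3)
    expect_lte(abs(compute_fwhm(p1[j, ]) - compute_fwhm(p2[match_j[j], ])), 3)
  }
})

test_that("rank selection enumerates and picks the elbow of the curve", {
  # dropping-loop oracle on a saturating-then-linear curve with its elbow
  # at 4: the window ending at rank 4 is the first with a near-zero MSE
  curve_r2 <- c(0.5, 0.75, 0.9, 0.97 + 0.004 * (0:6))
  expect_equal(lungesyn:::rank_from_curve(1:10, curve_r2), 4L)
  # a slowly flattening tail keeps one more rank in the window
  curve_b <- c(0.5, 0.75, 0.9, 0.97, 0.98, 0.99, 0.992, 0.994, 0.996, 0.998)
  expect_equal(lungesyn:::rank_from_curve(1:10, curve_b), 5L)
  # perfectly linear curve: MSE < 1e-5 at the first fit, rank 1
  expect_equal(lungesyn:::rank_from_curve(1:10, seq(0.5, 0.95, length.out = 10)),
               1L)
  # exhausting to two points returns the lower of the two
  jagged <- c(0.1, 0.5, 0.2, 0.8, 0.3, 0.9, 0.4, 0.95, 0.5, 0.99)
  expect_equal(lungesyn:::rank_from_curve(1:10, jagged), 9L)
})

test_that("CoA matches the direct circular-statistics evaluation", {
  expect_equal(compute_coa(replace(rep(0, 200), 100, 1)), 100)
  g <- lungesyn:::gaussian_primitive(150, 10, 1)
  expect_lt(abs(compute_coa(g) - 150), 0.5)
  expect_error(compute_coa(rep(0.5, 200)), "undefined")
  expect_error(compute_coa(rep(0, 200)), "zero")
  expect_error(compute_coa(c(-1, rep(1, 99))), "non-negative")
  set.seed(60)
  for (i in 1:100) {
    h <- runif(200)
    expect_equal(compute_coa(h), coa_bruteforce(h), tolerance = 1e-9)
  }
})

test_that("FWHM counts points above half maximum after min subtraction", {
  rect <- c(rep(0, 80), rep(1, 40), rep(0, 80))
  expect_equal(compute_fwhm(rect), 40L)
  # Gaussian sigma = 10: 2 sqrt(2 ln 2) sigma ~ 23.5, discretized to 23
  g <- lungesyn:::gaussian_primitive(100, 10, 1)
  expect_true(compute_fwhm(g) %in% c(23L, 24L))
  expect_error(compute_fwhm(rep(2, 200)), "constant")
  set.seed(61)
  for (i in 1:100) {
    h <- runif(200)
    expect_identical(as.integer(compute_fwhm(h)), as.integer(fwhm_bruteforce(h)))
  }
})

test_that("classification clusters shapes, labels by CoA order and flags
           blends as combined", {
  set.seed(62)
  centers <- c(25, 60, 85, 120)
  dd <- purrr::map(1:4, function(tr) {
    tibble::tibble(
      trial = paste0("t", tr), synergy = 1:4,
      module = purrr::map(1:4, ~ default_truth_modules(4)[, .x]),
      primitive = purrr::map(centers,
                             ~ lungesyn:::gaussian_primitive(.x + rnorm(1), 6, 1))
    )
  }) %>% dplyr::bind_rows()
  cls <- classify_synergies(dd)
  expect_equal(unname(table(cls$label)[synergy_labels()]), rep(4L, 4),
               ignore_attr = TRUE)
  by_label <- cls %>% dplyr::group_by(label) %>%
    dplyr::summarise(coa = mean(coa)) %>% dplyr::arrange(coa)
  expect_equal(by_label$label, synergy_labels())
  # a sum of two cluster medoids has two peaks: combined, no metrics
  blend <- tibble::tibble(
    trial = "t5", synergy = 1L,
    module = list(default_truth_modules(4)[, 1]),
    primitive = list(lungesyn:::gaussian_primitive(60, 6, 1) +
                       lungesyn:::gaussian_primitive(120, 6, 1))
  )
  cls2 <- classify_synergies(dplyr::bind_rows(dd, blend))
  expect_equal(cls2$label[cls2$trial == "t5"], "combined")
  expect_true(is.na(cls2$coa[cls2$trial == "t5"]))
  expect_error(classify_synergies(dd[0, ]), "no decompositions")
})

test_that("identical decompositions cluster with zero dispersion", {
  one <- tibble::tibble(
    trial = "x", synergy = 1:3,
    primitive = purrr::map(c(30, 90, 150),
                           ~ lungesyn:::gaussian_primitive(.x, 8, 1))
  )
  dd <- dplyr::bind_rows(purrr::map(1:5, ~ dplyr::mutate(one, trial = paste0("t", .x))))
  cls <- classify_synergies(dd)
  clusters <- attr(cls, "clusters")
  expect_equal(sort(clusters$size), rep(5L, 3))
  per_label_sd <- cls %>% dplyr::group_by(label) %>%
    dplyr::summarise(s = sd(coa))
  expect_true(all(per_label_sd$s == 0))
})

test_that("overlap counts equal the brute-force per-point census", {
  # two rectangles overlapping on 30 points
  r1 <- c(rep(0, 50), rep(1, 60), rep(0, 90))
  r2 <- c(rep(0, 80), rep(1, 60), rep(0, 60))
  dd <- tibble::tibble(
    trial = "t1", synergy = 1:2, label = c("swing", "touchdown"),
    primitive = list(r1, r2)
  )
  ov <- primitive_overlaps(dd)
  expect_equal(sum(ov$mean$overlap == 1), 30)
  expect_equal(sum(ov$mean$overlap), 30)
  # disjoint primitives: all zeros
  dd2 <- dd
  dd2$primitive <- list(c(rep(1, 40), rep(0, 160)), c(rep(0, 160), rep(1, 40)))
  expect_true(all(primitive_overlaps(dd2)$mean$overlap == 0))
  # random set against an independent census
  set.seed(63)
  prims <- purrr::map(1:4, ~ runif(200))
  dd3 <- tibble::tibble(trial = "t1", synergy = 1:4,
                        label = synergy_labels(), primitive = prims)
  got <- primitive_overlaps(dd3)$mean$overlap
  want <- numeric(200)
  for (t in 1:200) {
    cnt <- 0L
    for (h in prims) {
      h0 <- h - min(h)
      if (h0[t] > max(h0) / 2) cnt <- cnt + 1L
    }
    want[t] <- max(cnt - 1L, 0L)
  }
  expect_equal(got, want)
  expect_error(primitive_overlaps(dd[0, ]), "at least 2")
})
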