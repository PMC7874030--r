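# small shared fixtures, built in code

tiny_spec <- function(n_cycles = 2L, noise_sd = 0, seed = 11L, ...) {
  synthetic_spec(
    n_cycles = n_cycles, noise_sd = noise_sd,
    jitter_center_sd = 0, jitter_amp_sd = 0, seed = seed, ...
  )
}

# envelope tibble with one column per muscle, all equal to `values`
flat_envelopes <- function(values) {
  out <- tibble::tibble(time = seq_along(values) / 1000)
  for (m in lunge_muscles()) out[[m]] <- values
  out
}

# independent evaluation of the CoA equations, written directly from the
# circular-statistics definition (loop form, no shared code)
coa_bruteforce <- function(h) {
  n <- length(h)
  a <- 0
  b <- 0
  for (t in seq_len(n)) {
    theta <- 2 * pi * (t - 1) / n
    a <- a + cos(theta) * h[t]
    b <- b + sin(theta) * h[t]
  }
  ang <- atan2(b, a)
  if (ang < 0) ang <- ang + 2 * pi
  1 + n * ang / (2 * pi)
}

fwhm_bruteforce <- function(h) {
  h <- h - min(h)
  thr <- max(h) / 2
  cnt <- 0L
  for (t in seq_along(h)) if (h[t] > thr) cnt <- cnt + 1L
  cnt
}

# direct per-point evaluation of the three coactivation ratios
coactivation_bruteforce <- function(env13) {
  # env13: 13 x n matrix with canonical rownames
  n <- ncol(env13)
  out <- matrix(NA_real_, nrow = n, ncol = 3,
                dimnames = list(NULL, c("hip", "knee", "ankle")))
  for (t in seq_len(n)) {
    e <- env13[, t]
    den <- (e[["ME"]] + e[["MA"]]) / 2
    if (den > 0) out[t, "hip"] <- ((e[["FL"]] + e[["RF"]]) / 2) / den
    den <- (e[["RF"]] + e[["VM"]] + e[["VL"]]) / 3
    if (den > 0) out[t, "knee"] <- ((e[["BF"]] + e[["ST"]]) / 2) / den
    den <- (e[["GM"]] + e[["GL"]] + e[["SO"]]) / 3
    if (den > 0) out[t, "ankle"] <- e[["TA"]] / den
  }
  out
}
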