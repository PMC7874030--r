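#' Muscle-synergy extraction by Gaussian non-negative matrix factorization
#'
#' Factorizes the non-negative muscles-by-time envelope matrix `V`
#' (m x n) as `V ~ V_R = W H`, with `W` the m x r motor-module matrix
#' (time-invariant muscle weightings) and `H` the r x n motor-primitive
#' matrix (time-dependent activation coefficients). The multiplicative
#' update rules are
#' `H <- H * (W'V) / (W'WH)` and `W <- W * (VH') / (WHH')`
#' (elementwise, with the already-updated `H` in the `W` step and a small
#' epsilon guarding the denominators). Iterations stop when the relative
#' change of `R^2 = 1 - ||V - WH||_F^2 / ||V - mean(V)||_F^2` over the
#' last 20 iterations falls below 0.01%, or an iteration cap is hit. The
#' whole computation is repeated from `n_restarts` uniform-random
#' non-negative initializations (seeded `seed + restart - 1`) and the
#' highest-R^2 solution is kept.
#'
#' Before metric computation each row of `H` is rescaled to unit maximum
#' with the scale folded into `W`, fixing the scale indeterminacy of the
#' factorization.
#'
#' @param v non-negative numeric matrix (muscles x time points), e.g. an
#'   `envelope_matrix`; no all-zero rows.
#' @param rank number of synergies r, `1 <= r <= round(0.75 * nrow(v))`.
#' @param seed master seed for the random restarts.
#' @param n_restarts number of random restarts (default 10).
#' @param tol relative R^2 change defining convergence (default 1e-4,
#'   i.e. 0.01%).
#' @param conv_window iteration window over which the change is measured.
#' @param max_iter iteration cap per restart.
#' @param trace_r2 if `TRUE`, store the per-iteration R^2 path of the
#'   best restart (used by the monotonicity checks).
#' @return an object of class `synergy_nmf`: list with `w`, `h`, `rank`,
#'   `r2`, `restarts` (per-restart tibble), `iterations`, `converged`,
#'   `seed`, and optionally `r2_path`.
#' @export
synergy_nmf <- function(v, rank, seed = 1L, n_restarts = 10L,
                        tol = 1e-4, conv_window = 20L, max_iter = 10000L,
                        trace_r2 = FALSE) {
  v <- as_v_matrix(v)
  m <- nrow(v)
  n <- ncol(v)
  r_max <- round(0.75 * m)
  if (rank < 1L || rank > r_max) {
    abort(sprintf("rank must lie in 1..%d for %d muscles.", r_max, m))
  }
  sst <- sum((v - mean(v))^2)
  if (sst <= 0) abort("V has zero total variance; R^2 is undefined.")
  eps <- 1e-12
  best <- NULL
  rec <- vector("list", n_restarts)
  for (restart in seq_len(n_restarts)) {
    set.seed(as.integer(seed) + restart - 1L)
    w <- matrix(runif(m * rank), m, rank)
    h <- matrix(runif(rank * n), rank, n)
    r2_prev <- -Inf
    r2_hist <- numeric(0)
    converged <- FALSE
    iter <- 0L
    path <- if (trace_r2) numeric(max_iter) else NULL
    while (iter < max_iter) {
      iter <- iter + 1L
      h <- h * crossprod(w, v) / (crossprod(w) %*% h + eps)
      w <- w * tcrossprod(v, h) / (w %*% tcrossprod(h) + eps)
      r2 <- 1 - sum((v - w %*% h)^2) / sst
      if (trace_r2) path[iter] <- r2
      r2_hist <- c(r2_hist, r2)
      if (iter > conv_window) {
        past <- r2_hist[iter - conv_window]
        if (abs(r2 - past) / max(abs(past), eps) < tol) {
          converged <- TRUE
          break
        }
      }
    }
    if (!converged) {
      warn(sprintf("restart %d hit the %d-iteration cap.", restart, max_iter))
    }
    r2 <- 1 - sum((v - w %*% h)^2) / sst
    rec[[restart]] <- tibble(
      restart = restart, r2 = r2, iterations = iter, converged = converged
    )
    if (is.null(best) || r2 > best$r2) {
      best <- list(
        w = w, h = h, r2 = r2, iterations = iter, converged = converged,
        r2_path = if (trace_r2) path[seq_len(iter)] else NULL
      )
    }
  }
  # fix the scale indeterminacy: unit-maximum primitive rows
  scl <- apply(best$h, 1L, max)
  scl[scl <= 0] <- 1
  h <- best$h / scl
  w <- best$w * rep(scl, each = m)
  if (!is.null(rownames(v))) rownames(w) <- rownames(v)
  structure(
    list(
      w = w, h = h, rank = as.integer(rank), r2 = best$r2,
      restarts = bind_rows(rec), iterations = best$iterations,
      converged = best$converged, seed = as.integer(seed),
      n_cycles = attr(v, "n_cycles") %||% (ncol(v) %/% CYCLE_POINTS),
      r2_path = best$r2_path
    ),
    class = "synergy_nmf"
  )
}

as_v_matrix <- function(v) {
  if (inherits(v, "envelope_matrix")) {
    nc <- attr(v, "n_cycles")
    v <- structure(unclass(v), normalization = NULL, n_cycles = NULL)
    attr(v, "n_cycles") <- nc
  } else {
    v <- as.matrix(v)
  }
  if (!is.numeric(v)) abort("V must be numeric.")
  if (any(v < 0)) abort("V must be non-negative.")
  if (any(rowSums(v) <= 0)) {
    abort("V contains all-zero rows; drop or regenerate the dead channels.")
  }
  v
}

#' @export
print.synergy_nmf <- function(x, ...) {
  cat(sprintf(
    "<synergy_nmf> rank %d, R^2 = %.4f (best of %d restarts, %d iterations%s)\n",
    x$rank, x$r2, nrow(x$restarts), x$iterations,
    if (x$converged) "" else ", cap hit"
  ))
  invisible(x)
}

#' @method tidy synergy_nmf
#' @export
tidy.synergy_nmf <- function(x, matrix = c("w", "h"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "w") {
    tibble(
      muscle = rep(rownames(x$w) %||% as.character(seq_len(nrow(x$w))),
                   times = x$rank),
      synergy = rep(seq_len(x$rank), each = nrow(x$w)),
      weight = as.vector(x$w)
    )
  } else {
    tibble(
      synergy = rep(seq_len(x$rank), times = ncol(x$h)),
      point = rep(seq_len(ncol(x$h)), each = x$rank),
      activation = as.vector(x$h)
    )
  }
}

#' @method glance synergy_nmf
#' @export
glance.synergy_nmf <- function(x, ...) {
  tibble(
    rank = x$rank, r2 = x$r2, iterations = x$iterations,
    converged = x$converged, n_restarts = nrow(x$restarts),
    seed = x$seed
  )
}

#' Choose the number of synergies from the R^2-vs-rank curve
#'
#' Runs [synergy_nmf()] for every candidate rank 1..round(0.75 m) (10 for
#' the 13-muscle set), fits a straight line to the (rank, R^2) points and
#' computes the mean squared error of the fit; the lowest-rank point is
#' dropped and the line refitted until the MSE falls below `mse_tol`
#' (default 1e-5) or only two points remain. The chosen model order is
#' the smallest rank in the final fit window. A perfectly linear curve
#' therefore yields rank 1, and an exhausted loop returns the lower of
#' the last two ranks.
#'
#' @inheritParams synergy_nmf
#' @param mse_tol MSE threshold ending the dropping loop.
#' @param ranks candidate ranks; defaults to `1:round(0.75 * nrow(v))`.
#' @return object of class `rank_selection`: list with `rank`, `curve`
#'   (tibble rank/r2), `fits` (per-step tibble), `models` (the
#'   `synergy_nmf` fit at each rank) and `best` (the fit at the chosen
#'   rank).
#' @export
select_rank <- function(v, seed = 1L, n_restarts = 10L, mse_tol = 1e-5,
                        ranks = NULL, ...) {
  v <- as_v_matrix(v)
  if (is.null(ranks)) ranks <- seq_len(round(0.75 * nrow(v)))
  models <- lapply(ranks, function(r) {
    synergy_nmf(v, r, seed = seed + 1000L * r, n_restarts = n_restarts, ...)
  })
  r2 <- vapply(models, function(m) m$r2, numeric(1))
  curve <- tibble(rank = as.integer(ranks), r2 = r2)
  pts <- curve
  steps <- list()
  repeat {
    fit <- lm(r2 ~ rank, data = pts)
    mse <- mean(residuals(fit)^2)
    steps[[length(steps) + 1L]] <- tibble(
      from_rank = min(pts$rank), n_points = nrow(pts), mse = mse
    )
    if (mse < mse_tol || nrow(pts) <= 2L) break
    pts <- pts[-1L, ]
  }
  chosen <- min(pts$rank)
  structure(
    list(
      rank = as.integer(chosen),
      curve = curve,
      fits = bind_rows(steps),
      models = setNames(models, paste0("r", ranks)),
      best = models[[match(chosen, ranks)]]
    ),
    class = "rank_selection"
  )
}

#' @export
print.rank_selection <- function(x, ...) {
  cat(sprintf(
    "<rank_selection> chosen rank %d (candidates %d..%d, R^2 at choice %.4f)\n",
    x$rank, min(x$curve$rank), max(x$curve$rank), x$best$r2
  ))
  invisible(x)
}

#' @method tidy rank_selection
#' @export
tidy.rank_selection <- function(x, ...) x$curve

#' @method glance rank_selection
#' @export
glance.rank_selection <- function(x, ...) {
  tibble(
    rank = x$rank, r2 = x$best$r2,
    final_mse = tail(x$fits$mse, 1),
    candidates = nrow(x$curve)
  )
}

# the dropping loop alone, on a given R^2 curve; used for oracle tests
rank_from_curve <- function(rank, r2, mse_tol = 1e-5) {
  pts <- tibble(rank = rank, r2 = r2)
  repeat {
    fit <- lm(r2 ~ rank, data = pts)
    if (mean(residuals(fit)^2) < mse_tol || nrow(pts) <= 2L) break
    pts <- pts[-1L, ]
  }
  min(pts$rank)
}
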