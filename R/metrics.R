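#' Center of activity of a motor primitive
#'
#' The cycle is mapped onto the unit circle (`theta_t = 2 pi (t-1) / n`)
#' and the primitive treated as a circular mass distribution; the CoA is
#' the angle of the resultant vector
#' `A = sum(cos theta_t H_t)`, `B = sum(sin theta_t H_t)`,
#' `CoA = atan2(B, A)`, mapped back to cycle points on the 1-based point
#' circle (a unit impulse at point t has CoA exactly t).
#'
#' @param h non-negative numeric vector, one primitive over a cycle.
#' @param tol relative tolerance below which the resultant is considered
#'   zero (uniform primitive) and the CoA undefined.
#' @return CoA in cycle points, in `[1, n + 1)`.
#' @export
compute_coa <- function(h, tol = 1e-9) {
  n <- length(h)
  if (any(h < 0)) abort("primitive must be non-negative.")
  if (all(h == 0)) abort("CoA undefined: primitive is all zero.")
  theta <- 2 * pi * (seq_len(n) - 1) / n
  a <- sum(cos(theta) * h)
  b <- sum(sin(theta) * h)
  if (sqrt(a^2 + b^2) < tol * sum(h)) {
    abort("CoA undefined: zero resultant (uniform primitive).")
  }
  ang <- atan2(b, a) %% (2 * pi)
  1 + n * ang / (2 * pi)
}

#' Full width at half maximum of a motor primitive
#'
#' The cycle minimum is subtracted and the number of points strictly
#' exceeding half of the resulting maximum is counted.
#'
#' @param h numeric vector, one primitive over a cycle.
#' @return width in points.
#' @export
compute_fwhm <- function(h) {
  if (diff(range(h)) <= 0) {
    abort("FWHM undefined: primitive is constant.")
  }
  h0 <- h - min(h)
  sum(h0 > max(h0) / 2)
}

#' Mean 200-point cycle of each primitive
#'
#' Averages the concatenated primitive matrix `H` of a fit over its
#' cycles, yielding one mean 200-point primitive per synergy.
#'
#' @param fit a `synergy_nmf` object.
#' @return matrix rank x 200.
#' @export
primitive_mean_cycle <- function(fit) {
  stopifnot(inherits(fit, "synergy_nmf"))
  n_cycles <- fit$n_cycles
  h <- fit$h
  if (ncol(h) != n_cycles * CYCLE_POINTS) {
    abort("primitive matrix length is not a multiple of 200 points.")
  }
  out <- matrix(0, nrow = fit$rank, ncol = CYCLE_POINTS)
  for (k in seq_len(n_cycles)) {
    out <- out + h[, (k - 1) * CYCLE_POINTS + seq_len(CYCLE_POINTS),
                   drop = FALSE]
  }
  out / n_cycles
}

#' Per-cycle CoA and FWHM of a fit
#'
#' @param fit a `synergy_nmf` object.
#' @return tibble with `synergy`, `cycle`, `coa`, `fwhm`.
#' @export
cycle_metrics <- function(fit) {
  stopifnot(inherits(fit, "synergy_nmf"))
  grid <- tidyr::expand_grid(
    synergy = seq_len(fit$rank), cycle = seq_len(fit$n_cycles)
  )
  grid %>%
    mutate(
      coa = purrr::map2_dbl(.data$synergy, .data$cycle, function(s, k) {
        h <- fit$h[s, (k - 1) * CYCLE_POINTS + seq_len(CYCLE_POINTS)]
        tryCatch(compute_coa(h), error = function(e) NA_real_)
      }),
      fwhm = purrr::map2_dbl(.data$synergy, .data$cycle, function(s, k) {
        h <- fit$h[s, (k - 1) * CYCLE_POINTS + seq_len(CYCLE_POINTS)]
        tryCatch(compute_fwhm(h), error = function(e) NA_real_)
      })
    )
}

count_peaks <- function(h) {
  h0 <- h - min(h)
  half <- max(h0) / 2
  above <- h0 > half
  # local maxima above half max; flats inherit the preceding slope so a
  # plateau counts as a single peak
  d <- diff(h0)
  s <- sign(d)
  s[s == 0] <- NA
  s <- zoo::na.locf(s, na.rm = FALSE)
  s[is.na(s)] <- 1
  idx <- which(diff(s) < 0) + 1L
  if (length(idx) == 0L) idx <- which.max(h0)
  sum(above[idx])
}

#' Classify synergies across trials
#'
#' Clusters the mean-cycle primitives of several decompositions by shape
#' (agglomerative, average linkage, cosine distance, cut at
#' `1 - sim_threshold`). Clusters whose medoid shows a single activation
#' peak (one local maximum above half maximum after min subtraction) are
#' fundamental; they are ordered by ascending CoA and labelled
#' swing, touchdown, weight_acceptance, stabilization (or the available
#' subset/prefix when fewer or more exist). Primitives outside every
#' fundamental cluster are classified as combined (a blend of two or
#' more fundamentals), for which no CoA/FWHM is reported.
#'
#' @param decompositions data frame with one row per extracted synergy:
#'   a `trial` identifier column, and list-columns `primitive` (mean
#'   200-point cycle) and optionally `module` (13 weights). Use
#'   [decomposition_table()] to build it from `synergy_nmf` fits.
#' @param sim_threshold cosine similarity threshold (default 0.80).
#' @return the input tibble with `label`, `coa` and `fwhm` columns added
#'   (`coa`/`fwhm` are `NA` for combined synergies) and attribute
#'   `"clusters"` describing each cluster.
#' @export
classify_synergies <- function(decompositions, sim_threshold = 0.80) {
  dd <- as_tibble(decompositions)
  if (nrow(dd) == 0L) abort("no decompositions to classify.")
  if (!all(c("trial", "primitive") %in% names(dd))) {
    abort("decompositions need `trial` and `primitive` columns.")
  }
  p <- do.call(rbind, dd$primitive)
  pn <- p / sqrt(rowSums(p^2))
  sim <- pn %*% t(pn)
  sim[sim > 1] <- 1
  d <- stats::as.dist(1 - sim)
  if (nrow(p) >= 2L) {
    hc <- stats::hclust(d, method = "average")
    cl <- stats::cutree(hc, h = 1 - sim_threshold)
  } else {
    cl <- 1L
  }
  clusters <- tibble(cluster = sort(unique(cl))) %>%
    mutate(
      members = purrr::map(.data$cluster, ~ which(cl == .x)),
      size = lengths(.data$members),
      medoid = purrr::map_int(.data$members, function(ix) {
        if (length(ix) == 1L) return(ix)
        ix[which.max(colMeans(sim[ix, ix, drop = FALSE]))]
      }),
      peaks = purrr::map_int(.data$medoid, ~ count_peaks(p[.x, ])),
      coa_medoid = purrr::map_dbl(.data$medoid, ~ compute_coa(p[.x, ])),
      fundamental = .data$peaks == 1L
    )
  fnd <- clusters %>% filter(.data$fundamental) %>% arrange(.data$coa_medoid)
  lbl <- synergy_labels()
  fnd$label <- c(head(lbl, nrow(fnd)),
                 rep("combined", max(0L, nrow(fnd) - length(lbl))))
  cl_label <- setNames(rep("combined", nrow(clusters)), clusters$cluster)
  cl_label[as.character(fnd$cluster)] <- fnd$label
  dd$label <- unname(cl_label[as.character(cl)])
  dd$coa <- ifelse(
    dd$label == "combined", NA_real_,
    vapply(dd$primitive, function(h) compute_coa(h), numeric(1))
  )
  dd$fwhm <- ifelse(
    dd$label == "combined", NA_real_,
    vapply(dd$primitive, function(h) compute_fwhm(h), numeric(1))
  )
  attr(dd, "clusters") <- clusters
  dd
}

#' Build the classification input from fits
#'
#' @param fits named list of `synergy_nmf` objects (names become trial
#'   ids).
#' @return tibble with `trial`, `synergy`, `module`, `primitive` (mean
#'   cycle) columns.
#' @export
decomposition_table <- function(fits) {
  if (is.null(names(fits))) names(fits) <- paste0("trial", seq_along(fits))
  purrr::imap(fits, function(fit, id) {
    pm <- primitive_mean_cycle(fit)
    tibble(
      trial = id,
      synergy = seq_len(fit$rank),
      module = purrr::map(seq_len(fit$rank), ~ fit$w[, .x]),
      primitive = purrr::map(seq_len(fit$rank), ~ pm[.x, ])
    )
  }) %>% bind_rows()
}

#' Temporal overlaps between fundamental motor primitives
#'
#' Each primitive is binarized at half maximum (after min subtraction,
#' consistent with the FWHM); per time point the overlap count is the
#' number of primitives above threshold minus one, floored at zero, then
#' averaged across trials.
#'
#' @param classified output of [classify_synergies()] (fundamental rows
#'   are used; combined rows are ignored).
#' @return list with `per_trial` (tibble trial/point/overlap) and `mean`
#'   (tibble point/overlap).
#' @export
primitive_overlaps <- function(classified) {
  dd <- as_tibble(classified) %>% filter(.data$label != "combined")
  if (nrow(dd) < 2L) abort("need at least 2 fundamental synergies.")
  per_trial <- dd %>%
    group_by(.data$trial) %>%
    summarise(counts = list({
      bin <- vapply(.data$primitive, function(h) {
        h0 <- h - min(h)
        h0 > max(h0) / 2
      }, logical(CYCLE_POINTS))
      pmax(rowSums(bin) - 1, 0)
    }), .groups = "drop") %>%
    tidyr::unnest_longer(col = "counts", values_to = "overlap",
                         indices_to = "point")
  mean_curve <- per_trial %>%
    group_by(.data$point) %>%
    summarise(overlap = mean(.data$overlap), .groups = "drop")
  list(per_trial = per_trial, mean = mean_curve)
}
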