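#' Pipeline configuration
#'
#' @param event_cfg an [event_config()].
#' @param seed master seed for the factorization restarts.
#' @param n_restarts NMF restarts per rank.
#' @param sim_threshold cosine similarity threshold for classification.
#' @param central_max maximum number of central cycles kept per condition
#'   after dropping the first and last repetition (default 50).
#' @param early_late_size size of the early/late repetition blocks used
#'   for the CoA/FWHM summaries (default 25).
#' @param mse_tol rank-selection MSE threshold.
#' @return named list of class `run_config`.
#' @export
run_config <- function(event_cfg = event_config(), seed = 1L,
                       n_restarts = 10L, sim_threshold = 0.80,
                       central_max = 50L, early_late_size = 25L,
                       mse_tol = 1e-5) {
  structure(
    list(
      event_cfg = event_cfg, seed = as.integer(seed),
      n_restarts = as.integer(n_restarts),
      sim_threshold = sim_threshold,
      central_max = as.integer(central_max),
      early_late_size = as.integer(early_late_size),
      mse_tol = mse_tol
    ),
    class = "run_config"
  )
}

# repetition bookkeeping: drop first and last, keep the central block
central_cycles <- function(n, central_max) {
  if (n < 3L) return(integer(0))
  kept <- 2L:(n - 1L)
  if (length(kept) > central_max) {
    start <- floor((length(kept) - central_max) / 2)
    kept <- kept[(start + 1L):(start + central_max)]
  }
  kept
}

#' Run the full analysis over a table of trials
#'
#' Orchestrates every stage per participant x direction x ground
#' condition: segments each repetition, drops the first and last and
#' keeps the central block, builds the concatenated envelope matrix,
#' selects the model order and extracts synergies, computes per-cycle
#' CoA/FWHM, coactivation (per-direction-max normalization), averaged
#' joint angles and inverse-dynamics moments, then classifies the
#' extracted synergies across all conditions and computes primitive
#' overlaps. Failures are logged per repetition and the pipeline
#' continues. Identical input and config give identical output.
#'
#' @param trials tibble with columns `participant`, `direction`,
#'   `ground`, `cycle` and list-column `trial` of [trial_recording()]
#'   objects (see [simulate_study()]).
#' @param config a [run_config()].
#' @param kinetics if `FALSE`, the inverse-dynamics stage is skipped
#'   (faster when only the EMG side is of interest).
#' @return a `lunge_bundle` list: `conditions` (one row per condition
#'   with the fit and averaged curves as list-columns), `classified`
#'   (synergy classification across conditions), `overlaps`, `summary`
#'   (Table-1 shaped CoA/FWHM summary), `synergy_counts`, and `log`.
#' @export
run_pipeline <- function(trials, config = run_config(), kinetics = TRUE) {
  stopifnot(is.data.frame(trials))
  need <- c("participant", "direction", "ground", "trial")
  if (!all(need %in% names(trials))) {
    abort(paste0("`trials` needs columns: ", paste(need, collapse = ", ")))
  }
  if (!"cycle" %in% names(trials)) trials$cycle <- seq_len(nrow(trials))
  set.seed(config$seed) # permutation tests draw from the RNG
  log_rows <- list()
  note <- function(stage, id, msg) {
    log_rows[[length(log_rows) + 1L]] <<- tibble(
      stage = stage, trial = id, message = msg
    )
  }

  groups <- trials %>%
    group_by(.data$participant, .data$direction, .data$ground) %>%
    tidyr::nest(.key = "reps") %>%
    ungroup()

  cond_rows <- vector("list", nrow(groups))
  for (gi in seq_len(nrow(groups))) {
    g <- groups[gi, ]
    reps <- g$reps[[1]] %>% arrange(.data$cycle)
    cond_id <- paste(g$participant, g$direction, g$ground, sep = "/")

    seg <- vector("list", nrow(reps))
    ok <- logical(nrow(reps))
    for (i in seq_len(nrow(reps))) {
      res <- tryCatch(
        segment_trial(reps$trial[[i]], config$event_cfg),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        note("segmentation", paste0(cond_id, "#", reps$cycle[i]),
             conditionMessage(res))
      } else {
        seg[[i]] <- res
        ok[i] <- TRUE
      }
    }
    reps <- reps[ok, ]
    seg <- seg[ok]
    kept <- central_cycles(nrow(reps), config$central_max)
    if (length(kept) < 2L) {
      note("cycles", cond_id, "fewer than 2 usable cycles; condition dropped")
      next
    }
    reps <- reps[kept, ]
    seg <- seg[kept]
    k <- nrow(reps)

    # envelopes, raw 200-point blocks, per-repetition
    envs <- purrr::map(reps$trial, envelope_trial)
    blocks <- purrr::map2(envs, seg, function(env, cy) {
      vapply(lunge_muscles(), function(m) time_normalize_cycle(env[[m]], cy),
             numeric(CYCLE_POINTS))
    })
    v_raw <- t(do.call(rbind, blocks))
    rng <- apply(v_raw, 1, range)
    denom <- pmax(rng[2, ] - rng[1, ], 1e-12)
    v <- new_envelope_matrix((v_raw - rng[1, ]) / denom, "synergy", k)

    sel <- select_rank(v, seed = config$seed + 17L * gi,
                       n_restarts = config$n_restarts,
                       mse_tol = config$mse_tol)
    fit <- sel$best

    # per-direction-max normalization for coactivation / EMG averages
    dir_max <- apply(v_raw, 1, max)
    v_dir <- new_envelope_matrix(v_raw / dir_max, "per-direction-max", k)
    coact <- coactivation(v_dir) %>%
      group_by(.data$point) %>%
      summarise(across(c("hip", "knee", "ankle"),
                       ~ mean(.x, na.rm = TRUE)), .groups = "drop")

    ang_mean <- mom_mean <- NULL
    if (kinetics) {
      curves <- purrr::map2(reps$trial, seg, function(tr, cy) {
        tryCatch({
          cy_k <- convert_cycle(cy, tr$rate_kin, "kin")
          ang <- joint_angles(gap_fill_markers(tr)$markers,
                              fs = tr$rate_kin,
                              lpf_cutoff = config$event_cfg$lpf_cutoff)
          mom <- inverse_dynamics(tr, lpf_cutoff = config$event_cfg$lpf_cutoff)
          list(
            ang = vapply(c("hip", "knee", "ankle"),
                         function(j) time_normalize_cycle(ang[[j]], cy_k),
                         numeric(CYCLE_POINTS)),
            mom = vapply(c("hip", "knee", "ankle"),
                         function(j) time_normalize_cycle(mom[[j]], cy_k),
                         numeric(CYCLE_POINTS))
          )
        }, error = function(e) {
          note("kinetics", cond_id, conditionMessage(e))
          NULL
        })
      })
      curves <- purrr::compact(curves)
      if (length(curves) > 0L) {
        ang_mean <- Reduce(`+`, purrr::map(curves, "ang")) / length(curves)
        mom_mean <- Reduce(`+`, purrr::map(curves, "mom")) / length(curves)
      }
    }

    cond_rows[[gi]] <- tibble(
      participant = g$participant, direction = g$direction,
      ground = g$ground, condition = cond_id,
      n_cycles_used = k, rank = fit$rank, r2 = fit$r2,
      fit = list(fit), rank_curve = list(sel$curve), v = list(v),
      coactivation = list(coact),
      angles = list(ang_mean), moments = list(mom_mean)
    )
  }
  conditions <- bind_rows(purrr::compact(cond_rows))
  if (nrow(conditions) == 0L) {
    abort("no condition produced a usable decomposition.")
  }

  fits <- setNames(conditions$fit, conditions$condition)
  classified <- classify_synergies(
    decomposition_table(fits), sim_threshold = config$sim_threshold
  )
  overlaps <- tryCatch(primitive_overlaps(classified),
                       error = function(e) NULL)

  bundle <- structure(
    list(
      conditions = conditions,
      classified = classified,
      overlaps = overlaps,
      log = if (length(log_rows)) bind_rows(log_rows) else
        tibble(stage = character(), trial = character(), message = character()),
      config = config
    ),
    class = "lunge_bundle"
  )
  bundle$summary <- summarize_synergies(bundle)
  bundle$synergy_counts <- conditions %>%
    group_by(.data$direction, .data$ground) %>%
    summarise(mean_synergies = mean(.data$rank), .groups = "drop")
  bundle
}

#' @export
print.lunge_bundle <- function(x, ...) {
  cat(sprintf(
    "<lunge_bundle> %d condition(s), %d classified synergies, %d log entries\n",
    nrow(x$conditions), nrow(x$classified), nrow(x$log)
  ))
  invisible(x)
}

#' Summary table of CoA and FWHM per synergy, ground and repetition block
#'
#' Per-cycle CoA and FWHM of each fundamental synergy are split into
#' early and late repetition blocks (the first and last
#' `early_late_size` kept cycles) and summarized as mean and sd per
#' synergy label x ground x block, in the layout of a classic
#' synergy-comparison table. Conditions lacking a fundamental synergy
#' yield `"n.a."` cells; a single-cycle block reports `sd = 0`.
#'
#' @param bundle a `lunge_bundle` from [run_pipeline()].
#' @return tibble with `direction`, `metric` (`fwhm`/`coa`), `label` and
#'   formatted `mean +/- sd` character columns per ground x early/late
#'   cell, plus the numeric columns.
#' @export
summarize_synergies <- function(bundle) {
  stopifnot(inherits(bundle, "lunge_bundle"))
  es <- bundle$config$early_late_size
  per_cycle <- purrr::pmap(
    list(bundle$conditions$condition, bundle$conditions$fit,
         bundle$conditions$direction, bundle$conditions$ground),
    function(cond, fit, direction, ground) {
      lbl <- bundle$classified %>% filter(.data$trial == cond)
      cm <- cycle_metrics(fit) %>%
        left_join(lbl %>% select("synergy", "label"), by = "synergy") %>%
        mutate(direction = direction, ground = ground, condition = cond)
      nk <- fit$n_cycles
      half <- min(es, floor(nk / 2))
      cm %>%
        mutate(block = dplyr::case_when(
          .data$cycle <= half ~ "early",
          .data$cycle > nk - half ~ "late",
          TRUE ~ NA_character_
        )) %>%
        filter(!is.na(.data$block))
    }
  ) %>% bind_rows()

  long <- per_cycle %>%
    filter(.data$label != "combined") %>%
    tidyr::pivot_longer(c("coa", "fwhm"), names_to = "metric",
                        values_to = "value") %>%
    group_by(.data$direction, .data$metric, .data$label, .data$ground,
             .data$block) %>%
    summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = if (sum(!is.na(.data$value)) > 1L) {
        sd(.data$value, na.rm = TRUE)
      } else 0,
      .groups = "drop"
    )

  shell <- tidyr::expand_grid(
    direction = unique(bundle$conditions$direction),
    metric = c("fwhm", "coa"),
    label = synergy_labels(),
    ground = unique(bundle$conditions$ground),
    block = c("early", "late")
  )
  shell %>%
    left_join(long, by = c("direction", "metric", "label", "ground",
                           "block")) %>%
    mutate(cell = ifelse(
      is.na(.data$mean), "n.a.",
      sprintf("%.1f ± %.1f", .data$mean, .data$sd)
    )) %>%
    tidyr::pivot_wider(
      names_from = c("ground", "block"),
      values_from = c("mean", "sd", "cell")
    )
}
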