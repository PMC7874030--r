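#' Trial recording container
#'
#' A `trial_recording` holds the raw multirate streams of one lunge
#' repetition: 3-D marker trajectories (mm, kinematic rate, nominally
#' 250 Hz), 13 surface-EMG channels and a triaxial ground reaction force
#' (both at the analog rate, nominally 1 kHz), plus participant metadata.
#' Every downstream stage consumes this type; no stage re-reads files.
#'
#' @param markers tibble with a `time` column (s) and one
#'   `<marker>_{x,y,z}` column triplet per marker (mm). Must include the
#'   markers in [lunge_markers()].
#' @param analog tibble with a `time` column (s), `grf_x`, `grf_y`,
#'   `grf_z` (N) and one `emg_<muscle>` column per muscle in
#'   [lunge_muscles()] (arbitrary units).
#' @param meta named list: `participant`, `body_mass` (kg),
#'   `limb_length` (m), `direction` (`"forward"`/`"backward"`),
#'   `ground` (`"stable"`/`"unstable"`).
#' @param rate_kin,rate_analog sampling rates in Hz.
#' @return a validated `trial_recording` object.
#' @export
trial_recording <- function(markers, analog, meta = list(),
                            rate_kin = 250, rate_analog = 1000) {
  x <- structure(
    list(
      markers = as_tibble(markers),
      analog = as_tibble(analog),
      meta = meta,
      rate_kin = rate_kin,
      rate_analog = rate_analog
    ),
    class = "trial_recording"
  )
  validate_trial(x)
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf(
    "<trial_recording> %d kinematic samples @ %g Hz, %d analog samples @ %g Hz\n",
    nrow(x$markers), x$rate_kin, nrow(x$analog), x$rate_analog
  ))
  cat(sprintf(
    "  direction: %s, ground: %s, participant: %s\n",
    x$meta$direction %||% "?", x$meta$ground %||% "?",
    x$meta$participant %||% "?"
  ))
  invisible(x)
}

validate_trial <- function(x) {
  if (nrow(x$markers) == 0L || nrow(x$analog) == 0L) {
    abort("trial streams must be non-empty.")
  }
  if (x$rate_kin <= 0 || x$rate_analog <= 0) {
    abort("sampling rates must be positive.")
  }
  emg_cols <- paste0("emg_", lunge_muscles())
  missing_emg <- setdiff(emg_cols, names(x$analog))
  if (length(missing_emg) > 0L) {
    abort(paste0(
      "missing EMG channel(s): ",
      paste(sub("^emg_", "", missing_emg), collapse = ", ")
    ))
  }
  extra_emg <- setdiff(grep("^emg_", names(x$analog), value = TRUE), emg_cols)
  if (length(extra_emg) > 0L) {
    abort(paste0("unknown EMG channel(s): ", paste(extra_emg, collapse = ", ")))
  }
  grf_cols <- c("grf_x", "grf_y", "grf_z")
  if (!all(grf_cols %in% names(x$analog))) {
    abort("analog block must contain grf_x, grf_y, grf_z.")
  }
  need <- as.vector(outer(lunge_markers(), c("x", "y", "z"), paste, sep = "_"))
  missing_mk <- setdiff(need, names(x$markers))
  if (length(missing_mk) > 0L) {
    abort(paste0(
      "missing marker column(s): ", paste(missing_mk, collapse = ", ")
    ))
  }
  for (df in list(x$markers, x$analog)) {
    tt <- df$time
    if (is.null(tt)) abort("each stream needs a `time` column.")
    if (any(diff(tt) <= 0)) abort("non-monotone time column.")
  }
  x
}

#' Read / write a trial file
#'
#' The interchange format is one plain TSV per trial, wide, with metadata
#' in leading `# key: value` comment lines. The kinematic block
#' (`time_kin`, `<marker>_{x,y,z}`) and the analog block (`time_analog`,
#' `GRF_{x,y,z}`, `EMG_<muscle>`) sit side by side; because the kinematic
#' rate is lower, its columns are padded with trailing empty cells.
#' `read_trial(write_trial(x))` reproduces `x` stream-for-stream within
#' format precision.
#'
#' @param path file path.
#' @param schema optional column-name mapping: a named list (or path to a
#'   YAML file containing one) whose names are the canonical column names
#'   and whose values are the names used in the file.
#' @return `read_trial()`: a [trial_recording()].
#' @export
read_trial <- function(path, schema = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  meta <- read_trial_meta(path)
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (!is.null(schema)) {
    if (is.character(schema) && length(schema) == 1L) {
      schema <- yaml::read_yaml(schema)
    }
    map <- unlist(schema)
    hit <- map[map %in% names(df)]
    names(df)[match(hit, names(df))] <- names(hit)
  }
  if (!"time_kin" %in% names(df) || !"time_analog" %in% names(df)) {
    abort("file must contain `time_kin` and `time_analog` columns.")
  }
  kin_cols <- setdiff(grep("_(x|y|z)$", names(df), value = TRUE),
                      c("grf_x", "grf_y", "grf_z"))
  kin_cols <- setdiff(kin_cols, grep("^(GRF|EMG|grf|emg)_", kin_cols,
                                     value = TRUE))
  ana_cols <- grep("^(GRF|grf)_(x|y|z)$|^(EMG|emg)_", names(df), value = TRUE)
  kin <- df[!is.na(df$time_kin), c("time_kin", kin_cols)]
  names(kin) <- c("time", kin_cols)
  ana <- df[!is.na(df$time_analog), c("time_analog", ana_cols)]
  names(ana) <- c("time", tolower(sub("^GRF_", "grf_", sub("^EMG_", "emg_", ana_cols))))
  names(ana) <- sub("^emg_(.*)$", "emg_\\U\\1", names(ana), perl = TRUE)
  rate_kin <- meta$rate_kin %||% infer_rate(kin$time)
  rate_analog <- meta$rate_analog %||% infer_rate(ana$time)
  meta$rate_kin <- NULL
  meta$rate_analog <- NULL
  trial_recording(kin, ana, meta, rate_kin = rate_kin,
                  rate_analog = rate_analog)
}

#' @param trial a [trial_recording()].
#' @rdname read_trial
#' @return `write_trial()`: `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "trial_recording"))
  validate_trial(trial)
  if (anyNA(trial$markers[-1])) {
    inform("trial has marker gaps (NA); they are preserved in the file.")
  }
  nk <- nrow(trial$markers)
  na <- nrow(trial$analog)
  n <- max(nk, na)
  pad <- function(v, n) c(v, rep(NA_real_, n - length(v)))
  kin <- trial$markers
  names(kin)[1] <- "time_kin"
  ana <- trial$analog
  nm <- names(ana)
  nm[nm == "time"] <- "time_analog"
  nm <- sub("^grf_", "GRF_", nm)
  nm <- sub("^emg_", "EMG_", nm)
  names(ana) <- nm
  out <- c(
    lapply(kin, pad, n = n),
    lapply(ana, pad, n = n)
  )
  out <- as_tibble(out)
  hdr <- c(
    sprintf("# rate_kin: %.10g", trial$rate_kin),
    sprintf("# rate_analog: %.10g", trial$rate_analog),
    vapply(
      names(trial$meta),
      function(k) sprintf("# %s: %s", k, as.character(trial$meta[[k]])),
      character(1)
    )
  )
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(hdr, con)
  body <- readr::format_tsv(out, na = "")
  writeLines(sub("\n$", "", body), con)
  invisible(path)
}

read_trial_meta <- function(path) {
  lines <- readLines(path, n = 64L, encoding = "UTF-8")
  lines <- lines[startsWith(lines, "#")]
  meta <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) {
      key <- trimws(m[2])
      val <- trimws(m[3])
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (!is.na(num)) num else val
    }
  }
  meta
}

infer_rate <- function(tt) {
  if (length(tt) < 2L) abort("cannot infer sampling rate from < 2 samples.")
  1 / stats::median(diff(tt))
}

#' Fill short marker gaps by linear interpolation
#'
#' Differentiation amplifies gaps, so marker dropouts must be filled before
#' any event detection or kinetics. Gaps of up to `max_gap` consecutive
#' missing samples are linearly interpolated; longer gaps are left missing
#' and downstream stages refuse them.
#'
#' @param trial a [trial_recording()].
#' @param max_gap maximum gap length to interpolate, in kinematic samples.
#' @return the trial with gap-filled marker columns.
#' @export
gap_fill_markers <- function(trial, max_gap = 10L) {
  stopifnot(inherits(trial, "trial_recording"))
  mk <- trial$markers
  for (cn in setdiff(names(mk), "time")) {
    v <- mk[[cn]]
    if (anyNA(v)) {
      mk[[cn]] <- as.numeric(zoo::na.approx(v, maxgap = max_gap, na.rm = FALSE))
    }
  }
  trial$markers <- mk
  trial
}

# multirate index conversions; event indices live on the analog (1 kHz)
# timebase, kinematic indices are converted by rate ratio, round-half-up.
round_half_up <- function(x) floor(x + 0.5)

kin_to_analog_index <- function(i, rate_kin, rate_analog) {
  as.integer(round_half_up((i - 1) * rate_analog / rate_kin) + 1)
}

analog_to_kin_index <- function(i, rate_kin, rate_analog) {
  as.integer(round_half_up((i - 1) * rate_kin / rate_analog) + 1)
}
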