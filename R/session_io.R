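# On-disk session format: a directory holding manifest.json (session/task
# metadata), units.csv, trials.csv and spikes.csv. Times are seconds,
# trial-relative. All analysis windows are half-open [start, end).

BODY_PARTS <- c("forehead", "vertex", "back_head", "cheek", "neck",
                "shoulder", "hand", paste0("site", 1:9), "null")
SIDES   <- c("left", "right", "midline", "none")
FORMATS <- c("actual", "imagery", "null")
TASKS   <- c("touch_map", "latency", "rf_gradient", "imagery")

#' Build a condition identifier from its components
#'
#' Conditions are labelled by body part, body side and stimulus format
#' (actual touch, imagined touch, or the null/baseline condition). The
#' identifier is the string `format.body_part.side`.
#'
#' @param body_part Character vector of body parts.
#' @param side Character vector of body sides.
#' @param format Character vector of stimulus formats.
#' @return Character vector of condition identifiers.
#' @export
condition_id <- function(body_part, side, format) {
  paste(format, body_part, side, sep = ".")
}

#' Construct a session recording
#'
#' Bundles unit metadata, trial metadata and spike events for one recording
#' session and validates structural integrity.
#'
#' @param session_id Character scalar.
#' @param task One of `"touch_map"`, `"latency"`, `"rf_gradient"`, `"imagery"`.
#' @param units Data frame with columns `unit_id`, `channel`, `snr`,
#'   `mean_rate`, `isolation` (`"single"` or `"multi"`).
#' @param trials Data frame with columns `trial_id`, `body_part`, `side`,
#'   `format`, `cue_onset`, `go_onset`, `contact_time` (may be `NA`),
#'   `duration`.
#' @param spikes Data frame with columns `unit_id`, `trial_id`, `time`
#'   (seconds, trial-relative).
#' @param validate Check invariants (default `TRUE`).
#' @return An object of class `session_recording`.
#' @export
session_recording <- function(session_id, task, units, trials, spikes,
                              validate = TRUE) {
  task <- match.arg(task, TASKS)
  units <- as.data.frame(units, stringsAsFactors = FALSE)
  trials <- as.data.frame(trials, stringsAsFactors = FALSE)
  spikes <- as.data.frame(spikes, stringsAsFactors = FALSE)
  if (!"contact_time" %in% names(trials)) trials$contact_time <- NA_real_
  s <- structure(list(session_id = as.character(session_id), task = task,
                      units = units, trials = trials, spikes = spikes),
                 class = "session_recording")
  if (validate) validate_session(s)
  s
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf("Session '%s' (%s task): %d units, %d trials, %d spikes\n",
              x$session_id, x$task, nrow(x$units), nrow(x$trials),
              nrow(x$spikes)))
  invisible(x)
}

#' Validate a session recording
#'
#' Checks the structural invariants of the session container: unique unit
#' ids, finite non-negative unit metadata, event times ordered and inside the
#' trial, spikes referencing existing units/trials and lying inside their
#' trial, and at least two trials per condition.
#'
#' @param session A `session_recording`.
#' @return Invisibly `TRUE`; stops with an informative message otherwise.
#' @export
validate_session <- function(session) {
  u <- session$units; tr <- session$trials; sp <- session$spikes
  need_u <- c("unit_id", "channel", "snr", "mean_rate", "isolation")
  if (!all(need_u %in% names(u)))
    stop("units table missing columns: ",
         paste(setdiff(need_u, names(u)), collapse = ", "))
  if (anyDuplicated(u$unit_id))
    stop("duplicate unit_id: ", u$unit_id[duplicated(u$unit_id)][1L])
  if (!all(is.finite(u$snr)) || any(u$snr < 0))
    stop("unit snr must be finite and >= 0")
  if (!all(is.finite(u$mean_rate)) || any(u$mean_rate < 0))
    stop("unit mean_rate must be finite and >= 0")
  if (!all(u$isolation %in% c("single", "multi")))
    stop("unit isolation must be 'single' or 'multi'")

  need_t <- c("trial_id", "body_part", "side", "format",
              "cue_onset", "go_onset", "duration")
  if (!all(need_t %in% names(tr)))
    stop("trials table missing columns: ",
         paste(setdiff(need_t, names(tr)), collapse = ", "))
  if (anyDuplicated(tr$trial_id))
    stop("duplicate trial_id: ", tr$trial_id[duplicated(tr$trial_id)][1L])
  if (!all(tr$body_part %in% BODY_PARTS))
    stop("unknown body_part: ",
         paste(unique(setdiff(tr$body_part, BODY_PARTS)), collapse = ", "))
  if (!all(tr$side %in% SIDES)) stop("unknown side value")
  if (!all(tr$format %in% FORMATS)) stop("unknown format value")
  bad <- xor(tr$format == "null", tr$body_part == "null")
  if (any(bad))
    stop("format 'null' and body_part 'null' must co-occur (trial ",
         tr$trial_id[bad][1L], ")")
  bad <- tr$side == "midline" & !tr$body_part %in% c("forehead", "vertex")
  if (any(bad))
    stop("side 'midline' only allowed for forehead/vertex (trial ",
         tr$trial_id[bad][1L], ")")
  ev <- cbind(tr$cue_onset, tr$go_onset, tr$contact_time)
  bad <- which(apply(ev, 1L, function(z) any(!is.na(z) & (z < 0))) |
                 !is.finite(tr$duration) | tr$duration <= 0)
  if (length(bad))
    stop("negative event time or non-positive duration (trial ",
         tr$trial_id[bad[1L]], ")")
  bad <- which(apply(ev > tr$duration, 1L, function(z) any(z, na.rm = TRUE)))
  if (length(bad))
    stop("event time beyond trial duration (trial ", tr$trial_id[bad[1L]], ")")
  bad <- which(tr$cue_onset > tr$go_onset)
  if (length(bad))
    stop("cue_onset after go_onset (trial ", tr$trial_id[bad[1L]], ")")
  bad <- which(!is.na(tr$contact_time) & tr$contact_time < tr$go_onset)
  if (length(bad))
    stop("contact_time before go_onset (trial ", tr$trial_id[bad[1L]], ")")

  cond <- condition_id(tr$body_part, tr$side, tr$format)
  few <- names(which(table(cond) < 2L))
  if (length(few))
    stop("condition with fewer than 2 trials: ", few[1L])

  if (nrow(sp)) {
    bad <- which(!sp$unit_id %in% u$unit_id)
    if (length(bad))
      stop("spike row ", bad[1L], " references unknown unit_id '",
           sp$unit_id[bad[1L]], "'")
    bad <- which(!sp$trial_id %in% tr$trial_id)
    if (length(bad))
      stop("spike row ", bad[1L], " references unknown trial_id '",
           sp$trial_id[bad[1L]], "'")
    dur <- tr$duration[match(sp$trial_id, tr$trial_id)]
    bad <- which(!is.finite(sp$time) | sp$time < 0 | sp$time > dur)
    if (length(bad))
      stop("spike row ", bad[1L], " has time outside [0, trial duration]")
  }
  invisible(TRUE)
}

#' Write a session recording to disk
#'
#' Writes `manifest.json`, `units.csv`, `trials.csv` and `spikes.csv` into a
#' directory, creating it if needed. `read_session()` inverts this exactly
#' (event and spike times round-trip well below 1 microsecond).
#'
#' @param session A validated `session_recording`.
#' @param path Directory to write into.
#' @return Invisibly, `path`.
#' @export
write_session <- function(session, path) {
  validate_session(session)
  if (!dir.exists(path))
    dir.create(path, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create directory: ", path)
  jsonlite::write_json(list(session_id = session$session_id,
                            task = session$task),
                       file.path(path, "manifest.json"), auto_unbox = TRUE)
  wr <- function(df, f)
    utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     file.path(path, f), row.names = FALSE, quote = TRUE)
  wr(session$units, "units.csv")
  wr(session$trials, "trials.csv")
  wr(session$spikes, "spikes.csv")
  invisible(path)
}

#' Read a session recording from disk
#'
#' @param path Directory written by [write_session()].
#' @return A validated `session_recording`.
#' @export
read_session <- function(path) {
  man_f <- file.path(path, "manifest.json")
  if (!file.exists(man_f)) stop("no manifest.json under: ", path)
  man <- jsonlite::read_json(man_f, simplifyVector = TRUE)
  rd <- function(f, cls) {
    ff <- file.path(path, f)
    if (!file.exists(ff)) stop("missing file: ", ff)
    utils::read.csv(ff, stringsAsFactors = FALSE, colClasses = cls)
  }
  units <- rd("units.csv", c(unit_id = "character", isolation = "character"))
  trials <- rd("trials.csv", c(body_part = "character", side = "character",
                               format = "character"))
  trials$contact_time <- as.numeric(trials$contact_time)
  spikes <- rd("spikes.csv", c(unit_id = "character"))
  session_recording(man$session_id, man$task, units, trials, spikes)
}

# ---- analysis configuration ------------------------------------------------

config_defaults <- function() {
  list(
    min_rate = 0.5,                 # Hz, unit-selection floor (strict >)
    min_snr = 0.5,                  # waveform SNR floor (strict >)
    fdr_q = 0.05,                   # Benjamini-Hochberg q
    stim_window = c(0.5, 2.5),      # s after go, [start, end)
    baseline_window = c(-1.5, 0),   # s relative to cue, [start, end)
    n_corr_splits = 250,            # 50-50 split resamples for cv correlation
    n_perm = 2000,                  # permutation shuffles
    n_boot = 1000,                  # bootstrap resamples
    dyn_window = 0.5,               # s, sliding-window width
    dyn_step = 0.1,                 # s, sliding-window step
    seed = 1L
  )
}

#' Load an analysis configuration
#'
#' Reads a YAML or JSON configuration file and fills in defaults for any key
#' not given. Unknown keys and out-of-range values are errors.
#'
#' Defaults: `min_rate` 0.5 Hz, `min_snr` 0.5, `fdr_q` 0.05, `stim_window`
#' \[0.5, 2.5) s after go, `baseline_window` \[-1.5, 0) s relative to cue,
#' `n_corr_splits` 250, `n_perm` 2000, `n_boot` 1000, `dyn_window` 0.5 s,
#' `dyn_step` 0.1 s, `seed` 1.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file, or `NULL` for pure
#'   defaults.
#' @return A named list of class `analysis_config`.
#' @export
load_config <- function(path = NULL) {
  defs <- config_defaults()
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    ext <- tolower(tools::file_ext(path))
    user <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
            else if (ext == "json") jsonlite::read_json(path,
                                                        simplifyVector = TRUE)
            else stop("unsupported config format: .", ext)
    if (is.null(user)) user <- list()
  }
  unknown <- setdiff(names(user), names(defs))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defs, user)
  chk_pos <- function(key) {
    if (!is.numeric(cfg[[key]]) || length(cfg[[key]]) != 1L ||
        !is.finite(cfg[[key]]) || cfg[[key]] <= 0)
      stop("config key '", key, "' must be a positive number")
  }
  for (k in c("min_rate", "min_snr", "dyn_window", "dyn_step"))
    chk_pos(k)
  for (k in c("n_corr_splits", "n_perm", "n_boot")) {
    chk_pos(k)
    cfg[[k]] <- as.integer(cfg[[k]])
  }
  if (!is.numeric(cfg$fdr_q) || cfg$fdr_q <= 0 || cfg$fdr_q >= 1)
    stop("config key 'fdr_q' must be in (0, 1)")
  for (k in c("stim_window", "baseline_window")) {
    w <- as.numeric(cfg[[k]])
    if (length(w) != 2L || !all(is.finite(w)) || w[1L] >= w[2L])
      stop("config key '", k, "' must be two increasing finite numbers")
    if (diff(w) <= 0) stop("config key '", k, "' has non-positive width")
    cfg[[k]] <- w
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "analysis_config")
}
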