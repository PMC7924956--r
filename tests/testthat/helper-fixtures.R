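# Fixture builders shared across test files. Everything is generated in
# code; no data files are read.

# firing_rate_matrix from a plain units x trials matrix and a label vector
make_rates <- function(mat, condition, body_part = NULL, side = NULL,
                       format = NULL, window = list(event = "go_onset",
                                                    start = 0.5, end = 2.5)) {
  n <- nrow(mat)
  uid <- sprintf("u%02d", seq_len(n))
  split3 <- function(x, i) if (is.null(x)) NA_character_ else x
  labels <- data.frame(trial_id = seq_len(ncol(mat)),
                       body_part = if (is.null(body_part))
                         sub("^[^.]*\\.([^.]*)\\..*$", "\\1", condition)
                       else body_part,
                       side = if (is.null(side))
                         sub("^.*\\.", "", condition) else side,
                       format = if (is.null(format))
                         sub("\\..*$", "", condition) else format,
                       condition = condition, stringsAsFactors = FALSE)
  structure(list(rates = mat, unit_ids = uid, labels = labels,
                 window = window),
            class = "firing_rate_matrix")
}

# binned_tensor from a units x trials x bins array
make_tensor <- function(counts, condition, t_start, bin_size,
                        format = NULL, body_part = NULL) {
  nb <- dim(counts)[3L]
  labels <- data.frame(trial_id = seq_len(dim(counts)[2L]),
                       body_part = if (is.null(body_part))
                         sub("^[^.]*\\.([^.]*)\\..*$", "\\1", condition)
                       else body_part,
                       side = sub("^.*\\.", "", condition),
                       format = if (is.null(format))
                         sub("\\..*$", "", condition) else format,
                       condition = condition, stringsAsFactors = FALSE)
  structure(list(counts = counts, bin_size = bin_size,
                 align_event = "cue_onset", t_start = t_start,
                 t_end = t_start + nb * bin_size,
                 bin_centers = t_start + (seq_len(nb) - 0.5) * bin_size,
                 unit_ids = sprintf("u%02d", seq_len(dim(counts)[1L])),
                 labels = labels),
            class = "binned_tensor")
}

# minimal valid hand-built session: n units, one condition, n_trials trials
toy_session <- function(spike_times = list(), n_units = 2L, n_trials = 2L,
                        duration = 10, snr = NULL, task = "touch_map") {
  units <- data.frame(unit_id = sprintf("u%02d", seq_len(n_units)),
                      channel = seq_len(n_units),
                      snr = if (is.null(snr)) rep(1, n_units) else snr,
                      mean_rate = rep(1, n_units),
                      isolation = rep("single", n_units),
                      stringsAsFactors = FALSE)
  trials <- data.frame(trial_id = seq_len(n_trials),
                       body_part = "cheek", side = "right",
                       format = "actual", cue_onset = 1.5,
                       go_onset = 4.0, contact_time = NA_real_,
                       duration = duration, stringsAsFactors = FALSE)
  sp <- do.call(rbind, lapply(seq_along(spike_times), function(i) {
    st <- spike_times[[i]]
    data.frame(unit_id = st$unit_id, trial_id = st$trial_id,
               time = st$time, stringsAsFactors = FALSE)
  }))
  if (is.null(sp))
    sp <- data.frame(unit_id = character(0), trial_id = integer(0),
                     time = numeric(0), stringsAsFactors = FALSE)
  session_recording("toy", task, units, trials, sp)
}

# hand-built tuning_result with given responsiveness flags
toy_tuning <- function(responsive, tuned = NULL, conditions = NULL) {
  n <- nrow(responsive)
  if (is.null(conditions)) conditions <- colnames(responsive)
  dimnames(responsive) <- list(sprintf("u%02d", seq_len(n)), conditions)
  structure(list(unit_ids = rownames(responsive), conditions = conditions,
                 beta0 = rep(0, n),
                 beta = responsive * 1.0, tstat = responsive * 1.0,
                 pval = 1 - responsive * 0.999, F = rep(1, n),
                 p_F = rep(0.5, n), responsive = responsive,
                 tuned = if (is.null(tuned)) rowSums(responsive) > 0
                         else tuned,
                 q = 0.05),
            class = "tuning_result")
}
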