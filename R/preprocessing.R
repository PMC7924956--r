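# Unit selection, windowed firing-rate extraction, event-aligned binning.
# All windows are half-open [start, end) relative to a named trial event.

#' Select units by session-wide mean rate and SNR
#'
#' Retains units whose session-wide mean firing rate (total spikes divided by
#' total trial time) is strictly greater than `min_rate` and whose waveform
#' SNR (metadata) is strictly greater than `min_snr`; both thresholds follow
#' the "greater than" convention, so a unit sitting exactly on a threshold is
#' excluded. Spikes of dropped units are removed. Optionally restricts to
#' single- or multi-units for isolation-robustness re-runs.
#'
#' @param session A `session_recording`.
#' @param min_rate Minimum mean rate (Hz), default 0.5.
#' @param min_snr Minimum SNR, default 0.5.
#' @param isolation `"any"` (default), `"single"` or `"multi"`.
#' @return A `session_recording` with the retained units (possibly none).
#' @export
select_units <- function(session, min_rate = 0.5, min_snr = 0.5,
                         isolation = c("any", "single", "multi")) {
  isolation <- match.arg(isolation)
  total_time <- sum(session$trials$duration)
  cnt <- table(factor(session$spikes$unit_id,
                      levels = session$units$unit_id))
  rate <- as.numeric(cnt) / total_time
  keep <- rate > min_rate & session$units$snr > min_snr
  if (isolation != "any") keep <- keep & session$units$isolation == isolation
  units <- session$units[keep, , drop = FALSE]
  rownames(units) <- NULL
  spikes <- session$spikes[session$spikes$unit_id %in% units$unit_id, ,
                           drop = FALSE]
  rownames(spikes) <- NULL
  out <- session
  out$units <- units
  out$spikes <- spikes
  tr <- attr(session, "truth")
  if (!is.null(tr)) attr(out, "truth") <- tr
  out
}

trial_labels <- function(trials) {
  data.frame(trial_id = trials$trial_id, body_part = trials$body_part,
             side = trials$side, format = trials$format,
             condition = condition_id(trials$body_part, trials$side,
                                      trials$format),
             stringsAsFactors = FALSE)
}

event_times <- function(trials, align_event) {
  if (!align_event %in% names(trials))
    stop("unknown alignment event: ", align_event)
  ev <- trials[[align_event]]
  if (anyNA(ev))
    stop("trial ", trials$trial_id[which(is.na(ev))[1L]],
         " lacks event '", align_event, "'")
  ev
}

#' Windowed mean firing rates
#'
#' Computes, for every unit and trial, the mean firing rate (spike count
#' divided by window width) in the half-open window
#' \[event + start, event + end) around a named trial event.
#'
#' @param session A `session_recording`.
#' @param align_event `"cue_onset"`, `"go_onset"` or `"contact_time"`.
#' @param start,end Window bounds in seconds relative to the event,
#'   `start < end`.
#' @return An object of class `firing_rate_matrix`: list with `rates`
#'   (units x trials, Hz), `unit_ids`, `labels` (per-trial condition labels)
#'   and `window`.
#' @export
window_rates <- function(session, align_event, start, end) {
  stopifnot(start < end)
  tr <- session$trials
  ev <- event_times(tr, align_event)
  uid <- session$units$unit_id
  sp <- session$spikes
  t0 <- ev[match(sp$trial_id, tr$trial_id)]
  rel <- sp$time - t0
  inside <- rel >= start & rel < end
  cnt <- table(factor(sp$unit_id[inside], levels = uid),
               factor(sp$trial_id[inside], levels = tr$trial_id))
  rates <- matrix(as.numeric(cnt), nrow = length(uid),
                  dimnames = list(uid, tr$trial_id)) / (end - start)
  structure(list(rates = rates, unit_ids = uid, labels = trial_labels(tr),
                 window = list(event = align_event, start = start, end = end)),
            class = "firing_rate_matrix")
}

#' Event-aligned spike-count tensor
#'
#' Bins spikes into uniform half-open bins aligned to a named trial event.
#' The defaults used for latency analysis (`t_start = -0.150`,
#' `t_end = 0.252`, `bin_size = 0.002`, aligned to `contact_time`) yield 201
#' bins of 2 ms; no smoothing is applied.
#'
#' @param session A `session_recording`.
#' @param align_event Trial event name.
#' @param t_start,t_end Tensor extent (s) relative to the event; the width
#'   must be an integer multiple of `bin_size` (to within 1e-9).
#' @param bin_size Bin width in seconds.
#' @return An object of class `binned_tensor`: list with `counts`
#'   (units x trials x bins array), `bin_size`, `align_event`, `t_start`,
#'   `t_end`, `bin_centers`, `unit_ids`, `labels`.
#' @export
bin_spikes <- function(session, align_event, t_start, t_end, bin_size) {
  stopifnot(t_start < t_end, bin_size > 0)
  nb_real <- (t_end - t_start) / bin_size
  nb <- round(nb_real)
  if (abs(nb_real - nb) > 1e-9)
    stop("window width is not an integer number of bins")
  tr <- session$trials
  ev <- event_times(tr, align_event)
  uid <- session$units$unit_id
  sp <- session$spikes
  t0 <- ev[match(sp$trial_id, tr$trial_id)]
  rel <- sp$time - t0
  inside <- rel >= t_start & rel < t_end
  bin <- floor((rel[inside] - t_start) / bin_size) + 1L
  bin[bin > nb] <- nb  # guard against floating-point edge
  ui <- match(sp$unit_id[inside], uid)
  ti <- match(sp$trial_id[inside], tr$trial_id)
  counts <- array(0L, dim = c(length(uid), nrow(tr), nb))
  if (length(bin)) {
    lin <- (bin - 1L) * length(uid) * nrow(tr) + (ti - 1L) * length(uid) + ui
    counts[] <- tabulate(lin, nbins = length(uid) * nrow(tr) * nb)
  }
  structure(list(counts = counts, bin_size = bin_size,
                 align_event = align_event, t_start = t_start, t_end = t_end,
                 bin_centers = t_start + (seq_len(nb) - 0.5) * bin_size,
                 unit_ids = uid, labels = trial_labels(tr)),
            class = "binned_tensor")
}

#' Restrict a binned tensor to a condition subset
#'
#' @param binned A `binned_tensor`.
#' @param conditions Condition identifiers to keep.
#' @return A `binned_tensor` over the matching trials.
#' @export
restrict_tensor <- function(binned, conditions) {
  keep <- binned$labels$condition %in% conditions
  if (!any(keep)) stop("no trials match the requested conditions")
  out <- binned
  out$counts <- binned$counts[, keep, , drop = FALSE]
  out$labels <- binned$labels[keep, , drop = FALSE]
  rownames(out$labels) <- NULL
  out
}
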