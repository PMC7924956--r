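# End-to-end orchestration: per-session preprocessing and the analyses
# applicable to each task type, cross-session averaging where appropriate,
# CSV outputs, a text summary, and a run manifest for reproducibility.

write_matrix_csv <- function(m, path)
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)

#' Run the full analysis pipeline over one or more sessions
#'
#' Loads (or accepts in-memory) sessions, applies unit selection, runs the
#' analyses applicable to each task type — touch mapping: tuning summary,
#' leave-one-out decoding, cross-validated condition correlation, field
#' counts; latency: population PC1 latency with bootstrap IQR per side;
#' receptive-field gradient: peak-structure classification and Gaussian
#' field sizes; imagery: decoding, condition correlation, cross-temporal
#' dynamics — and writes CSV results, a text summary and a JSON run manifest
#' (config snapshot, seeds, input/output hashes, package version) into
#' `out_dir`. Decoding confusions are averaged across sessions of the same
#' task. Analyses inapplicable to a session's task are skipped with a logged
#' reason. Identical configs and sessions reproduce identical outputs.
#'
#' @param config An `analysis_config` from [load_config()] (or `NULL` for
#'   defaults).
#' @param sessions List of `session_recording` objects and/or paths to
#'   session directories.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with per-session results, averaged confusions,
#'   the log, and the manifest path.
#' @export
run_pipeline <- function(config = NULL, sessions, out_dir) {
  if (is.null(config)) config <- load_config()
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  sess_list <- lapply(sessions, function(s)
    if (is.character(s)) read_session(s) else s)
  in_paths <- vapply(sessions, function(s)
    if (is.character(s)) s else "<in-memory>", "")

  results <- list()
  confusions <- list()
  for (s in sess_list) {
    t0 <- Sys.time()
    sel <- select_units(s, config$min_rate, config$min_snr)
    note("session %s (%s): %d/%d units retained", s$session_id, s$task,
         nrow(sel$units), nrow(s$units))
    res <- list(session_id = s$session_id, task = s$task,
                n_units = nrow(sel$units))
    if (nrow(sel$units) < 2L) {
      note("session %s: skipped analyses (fewer than 2 units)", s$session_id)
      results[[s$session_id]] <- res
      next
    }
    stim <- window_rates(sel, "go_onset", config$stim_window[1L],
                         config$stim_window[2L])
    base <- window_rates(sel, "cue_onset", config$baseline_window[1L],
                         config$baseline_window[2L])
    if (s$task %in% c("touch_map", "imagery")) {
      tun <- fit_linear_tuning(stim, base, q = config$fdr_q)
      res$tuning <- tun
      res$summary <- population_summary(tun, alpha = 0.05,
                                        n_boot = config$n_boot,
                                        seed = config$seed)
      cm <- loo_confusion(stim)
      res$confusion <- cm
      confusions[[s$task]] <- c(confusions[[s$task]], list(cm))
      res$correlation <- cv_condition_correlation(
        stim, n_splits = config$n_corr_splits, seed = config$seed,
        baseline = base)
      if (s$task == "touch_map")
        res$field_counts <- tryCatch(field_count_matrix(tun),
                                     error = function(e) {
                                       note("session %s: field counts skipped (%s)",
                                            s$session_id, conditionMessage(e))
                                       NULL
                                     })
    } else {
      note("session %s: tuning/decoding skipped (task %s)", s$session_id,
           s$task)
    }
    if (s$task == "latency") {
      if (all(is.na(sel$trials$contact_time)))
        note("session %s: latency skipped (no contact times)", s$session_id)
      else {
        binned <- bin_spikes(sel, "contact_time", -0.150, 0.252, 0.002)
        for (side in c("left", "right")) {
          conds <- unique(sel$trials[sel$trials$side == side &
                                       sel$trials$body_part != "hand",
                                     c("body_part", "side", "format")])
          cids <- condition_id(conds$body_part, conds$side, conds$format)
          bl <- bootstrap_latency(binned, conditions = cids,
                                  n_boot = config$n_boot, seed = config$seed)
          res[[paste0("latency_", side)]] <- bl
        }
      }
    }
    if (s$task == "rf_gradient") {
      sites <- condition_id(paste0("site", 1:9), "right", "actual")
      site_rates <- stim
      peak4 <- condition_id(c("site1", "site3", "site5", "site7"), "right",
                            "actual")
      res$peaks <- classify_peak_structure(site_rates, peak4,
                                           alpha = config$fdr_q)
      prof <- vapply(sites, function(cid)
        rowMeans(stim$rates[, stim$labels$condition == cid, drop = FALSE]),
        numeric(nrow(stim$rates)))
      aov <- anova_discrimination(restrict_conditions(stim, sites))
      selc <- fdr_correct(aov$p, config$fdr_q)$reject
      fits <- lapply(which(selc), function(ui)
        fit_rf_gaussian(prof[ui, ]))
      res$rf_fwhm <- vapply(fits, function(f)
        if (f$flagged) NA_real_ else f$fwhm, 0)
    }
    if (s$task == "imagery") {
      ep <- c(-0.7, max(sel$trials$go_onset - sel$trials$cue_onset) + 3.5)
      binned <- bin_spikes(sel, "cue_onset", ep[1L],
                           ep[1L] + ceiling(diff(ep) / 0.1) * 0.1, 0.1)
      res$dynamics <- dynamic_classification(binned,
                                             window = config$dyn_window,
                                             step = config$dyn_step)
    }
    message(sprintf("session %s analysed in %.1f s", s$session_id,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    results[[s$session_id]] <- res
  }

  avg <- lapply(confusions, average_confusions)
  # outputs
  for (sid in names(results)) {
    r <- results[[sid]]
    if (!is.null(r$confusion))
      write_matrix_csv(r$confusion$accuracy,
                       file.path(out_dir, paste0(sid, "_confusion.csv")))
    if (!is.null(r$correlation))
      write_matrix_csv(r$correlation$mean_corr,
                       file.path(out_dir, paste0(sid, "_correlation.csv")))
    if (!is.null(r$summary))
      utils::write.csv(r$summary$fraction_responsive,
                       file.path(out_dir, paste0(sid, "_responsive.csv")),
                       row.names = FALSE)
  }
  for (task in names(avg))
    write_matrix_csv(avg[[task]]$accuracy,
                     file.path(out_dir, paste0("avg_confusion_", task,
                                               ".csv")))
  summary_path <- file.path(out_dir, "summary.txt")
  writeLines(c(sprintf("pctouch pipeline run, %d session(s)",
                       length(results)), log_lines), summary_path)
  out_files <- list.files(out_dir, full.names = TRUE)
  manifest <- list(
    config = unclass(config),
    seed = config$seed,
    tool_version = as.character(utils::packageVersion("pctouch")),
    inputs = in_paths,
    output_hashes = as.list(tools::md5sum(setdiff(out_files,
                                                  file.path(out_dir,
                                                            "manifest.json"))))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(sessions = results, averaged_confusions = avg,
                 log = log_lines, manifest = manifest_path))
}

#' Restrict a firing-rate matrix to a condition subset
#'
#' @param rates A `firing_rate_matrix`.
#' @param conditions Condition identifiers to keep.
#' @return A `firing_rate_matrix` over the matching trials.
#' @export
restrict_conditions <- function(rates, conditions) {
  keep <- rates$labels$condition %in% conditions
  if (!any(keep)) stop("no trials match the requested conditions")
  out <- rates
  out$rates <- rates$rates[, keep, drop = FALSE]
  out$labels <- rates$labels[keep, , drop = FALSE]
  rownames(out$labels) <- NULL
  out
}
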