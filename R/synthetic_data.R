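# Ground-truth spike-train generator. Units are inhomogeneous Poisson
# processes with rate b + G * r(t - onset - L), where r is a linear 0->1
# ramp of duration ramp_rise followed by a sustained plateau for the rest of
# the stimulation epoch. G is the actual-touch gain, the imagery gain, or the
# cue-epoch gain depending on trial format and epoch; null trials and
# actual touch to the (insensate) hands add no modulation.

LATERAL_PARTS <- c("back_head", "cheek", "neck", "shoulder", "hand")
MIDLINE_PARTS <- c("forehead", "vertex")
IMAGERY_PARTS <- c("cheek", "shoulder", "hand")

gain_keys <- function() {
  c(paste(MIDLINE_PARTS, "midline", sep = "."),
    paste(rep(LATERAL_PARTS, each = 2L), c("left", "right"), sep = "."),
    paste(paste0("site", 1:9), "right", sep = "."))
}

#' Task presets for the four experimental paradigms
#'
#' Returns the condition set, trial counts and epoch durations for one of the
#' four paradigms: `touch_map` (13 conditions, 10 trials each: bilateral
#' forehead/vertex/back of head/cheek/neck/shoulder plus insensate hands and
#' a null condition), `latency` (6 conditions, 8 trials, capacitive-probe
#' contact times on every stimulated trial), `rf_gradient` (9 collinear
#' sites 2 cm apart on the right cheek-to-neck line plus null, 10 trials),
#' and `imagery` (actual touch to bilateral cheek/shoulder/hand, imagined
#' touch to the right cheek/shoulder/hand, and null; 8 trials each).
#'
#' Epochs: cue 1.5 s, delay 1 s, stimulus 3 s for the actual-touch tasks;
#' the imagery task uses a 0.5 s auditory cue and 2 s delay.
#'
#' @param name Task name.
#' @return A list of class `task_spec` with elements `task`, `conditions`
#'   (data frame `body_part`/`side`/`format`), `trials_per_condition`,
#'   `epochs` (named list `cue`, `delay`, `stim`, `iti`, `pre_cue`) and
#'   `contact_jitter` (latency task only, else `NULL`).
#' @export
make_task_spec <- function(name = c("touch_map", "latency", "rf_gradient",
                                    "imagery")) {
  name <- match.arg(name)
  cnd <- function(part, side, format = "actual")
    data.frame(body_part = part, side = side, format = format,
               stringsAsFactors = FALSE)
  lateral <- function(parts)
    cnd(rep(parts, each = 2L), rep(c("left", "right"), length(parts)))
  nullc <- cnd("null", "none", "null")
  epochs <- list(cue = 1.5, delay = 1.0, stim = 3.0, iti = 1.0, pre_cue = 1.5)
  jit <- NULL
  if (name == "touch_map") {
    conditions <- rbind(cnd(c("forehead", "vertex"), "midline"),
                        lateral(c("back_head", "cheek", "neck", "shoulder",
                                  "hand")),
                        nullc)
    tpc <- 10L
  } else if (name == "latency") {
    conditions <- lateral(c("cheek", "shoulder", "hand"))
    tpc <- 8L
    jit <- 0.3
  } else if (name == "rf_gradient") {
    conditions <- rbind(cnd(paste0("site", 1:9), "right"), nullc)
    tpc <- 10L
  } else {
    conditions <- rbind(lateral(c("cheek", "shoulder", "hand")),
                        cnd(IMAGERY_PARTS, "right", "imagery"),
                        nullc)
    tpc <- 8L
    epochs$cue <- 0.5
    epochs$delay <- 2.0
  }
  structure(list(task = name, conditions = conditions,
                 trials_per_condition = tpc, epochs = epochs,
                 contact_jitter = jit),
            class = "task_spec")
}

#' Ground-truth population specification
#'
#' Collects the generator parameters controlling a simulated population.
#' `tuned_fraction` of the units carry nonzero touch gains; each tuned unit
#' responds to each sensate body part with probability `field_prob`, with
#' gamma-distributed gain amplitudes of mean `gain_mean` Hz. Left/right gains
#' for the same body part differ by zero-mean Gaussian asymmetry noise whose
#' difference has standard deviation `mirror_sigma` Hz (mirror-symmetric
#' coding when 0), unless `independent_sides` draws the two sides
#' independently. Imagery gains share a fraction `imagery_share` (kappa) of
#' the latent touch gains, cue-epoch gains a fraction `cue_share` (alpha) of
#' the imagery gains, each completed by an independent unique component so
#' that share = 1 means identical patterns. Onset latencies are Gaussian with
#' mean `latency_mean` and SD `latency_jitter` seconds.
#'
#' @param n_units Number of units.
#' @param tuned_fraction Fraction of units with nonzero touch gains.
#' @param mirror_sigma SD (Hz) of the left-right gain difference.
#' @param independent_sides Draw left/right gains independently (overrides
#'   `mirror_sigma`).
#' @param imagery_share Shared fraction kappa in \[0, 1\].
#' @param cue_share Shared fraction alpha in \[0, 1\].
#' @param latency_mean,latency_jitter Onset latency mean/SD (s).
#' @param ramp_rise Rise time (s) of the onset ramp.
#' @param baseline_mean Mean baseline rate (Hz).
#' @param gain_mean Mean gain amplitude (Hz).
#' @param field_prob Per-body-part probability of a receptive field.
#' @param seed Integer seed (required; generation is fully reproducible).
#' @return A list of class `population_spec`.
#' @export
population_spec <- function(n_units = 100L, tuned_fraction = 0.66,
                            mirror_sigma = 0, independent_sides = FALSE,
                            imagery_share = 0.7, cue_share = 0.5,
                            latency_mean = 0.05, latency_jitter = 0.005,
                            ramp_rise = 0.01, baseline_mean = 5,
                            gain_mean = 25, field_prob = 0.6, seed) {
  if (missing(seed)) stop("population_spec: 'seed' is required")
  stopifnot(n_units >= 1, tuned_fraction >= 0, tuned_fraction <= 1,
            mirror_sigma >= 0, imagery_share >= 0, imagery_share <= 1,
            cue_share >= 0, cue_share <= 1, latency_mean >= 0,
            ramp_rise > 0, baseline_mean >= 0, gain_mean >= 0,
            field_prob >= 0, field_prob <= 1)
  structure(list(n_units = as.integer(n_units),
                 tuned_fraction = tuned_fraction,
                 mirror_sigma = mirror_sigma,
                 independent_sides = independent_sides,
                 imagery_share = imagery_share, cue_share = cue_share,
                 latency_mean = latency_mean, latency_jitter = latency_jitter,
                 ramp_rise = ramp_rise, baseline_mean = baseline_mean,
                 gain_mean = gain_mean, field_prob = field_prob,
                 seed = as.integer(seed)),
            class = "population_spec")
}

draw_amplitudes <- function(n, spec) {
  # gamma with shape 3: strictly positive, right-skewed, mean = gain_mean
  stats::rgamma(n, shape = 3, rate = 3 / spec$gain_mean)
}

#' Draw a ground-truth population
#'
#' Realises the unit-level ground truth implied by a [population_spec()]:
#' baseline rates, per-condition touch gains, imagery and cue-epoch gains,
#' onset latencies and unit metadata. Reproducible given the seed in the specification object.
#'
#' @param spec A `population_spec`.
#' @return An object of class `population_truth`: list with `baseline`
#'   (Hz per unit), `gains` (units x condition-key matrix, Hz), `imagery_gains`
#'   and `cue_gains` (units x cheek/shoulder/hand), `latency`, `ramp_rise`,
#'   `tuned`, `snr`, `mean_rate_nominal`, `isolation`, `unit_id`, `spec`.
#' @export
make_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  n <- spec$n_units
  keys <- gain_keys()
  baseline <- stats::rgamma(n, shape = 2, rate = 2 / max(spec$baseline_mean,
                                                         1e-12))
  n_tuned <- round(spec$tuned_fraction * n)
  tuned <- rep(FALSE, n)
  if (n_tuned > 0) tuned[sample.int(n, n_tuned)] <- TRUE

  parts <- c(MIDLINE_PARTS, LATERAL_PARTS)
  # latent per-part gains (hand included; actual-touch hand gain is zeroed
  # below, the latent value still seeds the imagery pattern)
  latent <- matrix(0, n, length(parts), dimnames = list(NULL, parts))
  has_field <- matrix(stats::runif(n * length(parts)) < spec$field_prob,
                      n, length(parts))
  amp <- matrix(draw_amplitudes(n * length(parts), spec), n)
  latent[] <- has_field * amp
  latent[!tuned, ] <- 0

  gains <- matrix(0, n, length(keys), dimnames = list(NULL, keys))
  for (p in MIDLINE_PARTS)
    gains[, paste0(p, ".midline")] <- latent[, p]
  for (p in LATERAL_PARTS) {
    if (spec$independent_sides) {
      l <- draw_amplitudes(n, spec) *
        (stats::runif(n) < spec$field_prob) * tuned
      r <- draw_amplitudes(n, spec) *
        (stats::runif(n) < spec$field_prob) * tuned
    } else {
      e <- matrix(stats::rnorm(2L * n, sd = spec$mirror_sigma / sqrt(2)),
                  n, 2L)
      l <- pmax(latent[, p] + e[, 1L] * (latent[, p] > 0), 0)
      r <- pmax(latent[, p] + e[, 2L] * (latent[, p] > 0), 0)
    }
    gains[, paste0(p, ".left")] <- l
    gains[, paste0(p, ".right")] <- r
  }
  latent_hand_right <- gains[, "hand.right"]
  gains[, c("hand.left", "hand.right")] <- 0  # insensate control

  # fine-grained sites: Gaussian spatial profile along the 9-site line
  pref <- sample.int(9L, n, replace = TRUE)
  sigma_cm <- stats::runif(n, 1.5, 4)
  site_amp <- draw_amplitudes(n, spec) * tuned
  for (k in 1:9)
    gains[, paste0("site", k, ".right")] <-
      site_amp * exp(-0.5 * ((k - pref) * 2 / sigma_cm)^2)

  # imagery gains: kappa-share of latent right-side touch gains
  kap <- spec$imagery_share
  latent_im <- cbind(cheek = gains[, "cheek.right"],
                     shoulder = gains[, "shoulder.right"],
                     hand = latent_hand_right)
  uniq <- matrix(draw_amplitudes(3L * n, spec) *
                   (stats::runif(3L * n) < spec$field_prob), n, 3L) * tuned
  imagery_gains <- kap * latent_im + sqrt(1 - kap^2) * uniq
  colnames(imagery_gains) <- IMAGERY_PARTS

  al <- spec$cue_share
  uniq2 <- matrix(draw_amplitudes(3L * n, spec) *
                    (stats::runif(3L * n) < spec$field_prob), n, 3L) * tuned
  cue_gains <- al * imagery_gains + sqrt(1 - al^2) * uniq2
  colnames(cue_gains) <- IMAGERY_PARTS

  latency <- pmax(stats::rnorm(n, spec$latency_mean, spec$latency_jitter), 0)
  snr <- stats::rlnorm(n, log(1.5), 0.6)
  isolation <- sample(c("single", "multi"), n, replace = TRUE,
                      prob = c(0.6, 0.4))
  if (any(baseline < 0)) stop("negative baseline rate generated")
  structure(list(unit_id = sprintf("u%03d", seq_len(n)), baseline = baseline,
                 gains = gains, imagery_gains = imagery_gains,
                 cue_gains = cue_gains, latency = latency,
                 ramp_rise = rep(spec$ramp_rise, n), tuned = tuned,
                 snr = snr, mean_rate_nominal = baseline, isolation = isolation,
                 spec = spec),
            class = "population_truth")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# piecewise rate profile of one unit on one trial, evaluated at times tt
unit_trial_rate <- function(tt, b, G_stim, G_cue, onset, stim_end,
                            cue_onset, go_onset, L, ramp) {
  r <- rep(b, length(tt))
  if (G_cue != 0) {
    t0 <- cue_onset + L
    up <- pmin(pmax((tt - t0) / ramp, 0), 1)
    up[tt >= go_onset] <- 0
    r <- r + G_cue * up
  }
  if (G_stim != 0) {
    t0 <- onset + L
    up <- pmin(pmax((tt - t0) / ramp, 0), 1)
    up[tt >= stim_end] <- 0
    r <- r + G_stim * up
  }
  r
}

#' Simulate a session from a ground-truth population
#'
#' Draws trial-structured spike trains from inhomogeneous Poisson processes
#' (thinning) according to the rate model described in
#' [population_spec()]: on actual-touch trials the gain for the touched
#' body part ramps in after the onset latency (anchored to the probe contact
#' time when the task records one, otherwise to the go signal) and is
#' sustained for the stimulation epoch; on imagery trials the cue-epoch gain
#' applies during the cue-delay and the imagery gain after the go beep; null
#' and actual-hand trials are unmodulated. Conditions are pseudorandomly
#' interleaved in blocks (each condition once per block).
#'
#' @param pop A `population_truth` from [make_population()].
#' @param task A `task_spec` from [make_task_spec()].
#' @param seed Integer seed (required).
#' @param session_id Session identifier.
#' @return A validated `session_recording`; the ground truth is attached as
#'   attribute `"truth"` (see [session_truth()]).
#' @export
simulate_session <- function(pop, task, seed, session_id = NULL) {
  stopifnot(inherits(pop, "population_truth"), inherits(task, "task_spec"))
  if (missing(seed)) stop("simulate_session: 'seed' is required")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (is.null(session_id))
    session_id <- sprintf("%s-%d", task$task, seed)

  ep <- task$epochs
  cue_onset <- ep$pre_cue
  go_onset <- cue_onset + ep$cue + ep$delay
  stim_end <- go_onset + ep$stim
  duration <- stim_end + ep$iti

  nc <- nrow(task$conditions)
  # pseudorandom interleaving: every condition once per block
  order_idx <- unlist(lapply(seq_len(task$trials_per_condition),
                             function(b) sample.int(nc)))
  trials <- task$conditions[order_idx, , drop = FALSE]
  ntr <- nrow(trials)
  trials$trial_id <- seq_len(ntr)
  trials$cue_onset <- cue_onset
  trials$go_onset <- go_onset
  trials$duration <- duration
  trials$contact_time <- NA_real_
  if (!is.null(task$contact_jitter)) {
    stim_trial <- trials$format != "null"
    trials$contact_time[stim_trial] <-
      go_onset + stats::runif(sum(stim_trial), 0, task$contact_jitter)
  }
  rownames(trials) <- NULL
  trials <- trials[, c("trial_id", "body_part", "side", "format",
                       "cue_onset", "go_onset", "contact_time", "duration")]

  n <- length(pop$unit_id)
  key <- paste(trials$body_part, trials$side, sep = ".")
  sp_u <- vector("list", n)
  for (i in seq_len(n)) {
    b <- pop$baseline[i]
    L <- pop$latency[i]
    ramp <- pop$ramp_rise[i]
    sp_t <- vector("list", ntr)
    for (j in seq_len(ntr)) {
      fmt <- trials$format[j]
      G_stim <- 0; G_cue <- 0
      onset <- trials$go_onset[j]
      if (fmt == "actual") {
        G_stim <- unname(pop$gains[i, key[j]])
        if (!is.na(trials$contact_time[j])) onset <- trials$contact_time[j]
      } else if (fmt == "imagery") {
        G_stim <- unname(pop$imagery_gains[i, trials$body_part[j]])
        G_cue <- unname(pop$cue_gains[i, trials$body_part[j]])
      }
      lam_max <- b + max(G_stim, G_cue, 0)
      if (lam_max <= 0) { sp_t[[j]] <- numeric(0); next }
      n_cand <- stats::rpois(1L, lam_max * duration)
      if (n_cand == 0L) { sp_t[[j]] <- numeric(0); next }
      tt <- sort(stats::runif(n_cand, 0, duration))
      lam <- unit_trial_rate(tt, b, G_stim, G_cue, onset, stim_end,
                             trials$cue_onset[j], trials$go_onset[j], L, ramp)
      keep <- stats::runif(n_cand) < lam / lam_max
      sp_t[[j]] <- tt[keep]
    }
    cnt <- lengths(sp_t)
    sp_u[[i]] <- data.frame(unit_id = rep(pop$unit_id[i], sum(cnt)),
                            trial_id = rep(trials$trial_id, cnt),
                            time = if (sum(cnt)) unlist(sp_t) else numeric(0),
                            stringsAsFactors = FALSE)
  }
  spikes <- do.call(rbind, sp_u)
  rownames(spikes) <- NULL

  units <- data.frame(unit_id = pop$unit_id,
                      channel = seq_along(pop$unit_id),
                      snr = pop$snr,
                      mean_rate = pop$mean_rate_nominal,
                      isolation = pop$isolation, stringsAsFactors = FALSE)
  s <- session_recording(session_id, task$task, units, trials, spikes)
  attr(s, "truth") <- pop
  s
}

#' Retrieve the ground truth attached to a simulated session
#'
#' @param session A session returned by [simulate_session()].
#' @return The `population_truth`, or `NULL` for sessions read from disk.
#' @export
session_truth <- function(session) attr(session, "truth")
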