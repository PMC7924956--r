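# Population response latency. The population time course is summarised by
# the first principal component of the units x (time * condition * trial)
# matrix of 2 ms binned counts; the averaged PC1 trace is fit with a
# continuous two-breakpoint (three segment) piecewise-linear function, and
# latency is read off where the fit crosses the 95th percentile of the
# pre-contact baseline values.

#' Population PC1 time series
#'
#' Builds the units x (bins * trials) matrix from an event-aligned tensor
#' (optionally restricted to a condition subset), removes each unit's mean,
#' and extracts the first principal component by singular value
#' decomposition. PC1 scores are averaged across conditions and repetitions
#' into a single time series; the sign is oriented so that the
#' post-event mean exceeds the pre-event mean. Single-trial PC1 traces (the
#' per-trial score time courses) are retained for bootstrap resampling.
#'
#' @param binned A `binned_tensor` (typically 2 ms bins aligned to
#'   `contact_time`).
#' @param conditions Optional character vector of condition identifiers to
#'   include (default: all non-null conditions).
#' @return Object of class `population_timeseries`: `values` (mean PC1 per
#'   bin), `bin_centers`, `single_trial` (bins x trials matrix), `loadings`,
#'   `var_explained`, `conditions`.
#' @export
population_pc1 <- function(binned, conditions = NULL) {
  stopifnot(inherits(binned, "binned_tensor"))
  lab <- binned$labels$condition
  keep <- if (is.null(conditions)) binned$labels$format != "null"
          else lab %in% conditions
  if (!any(keep)) stop("no trials selected")
  cnt <- binned$counts[, keep, , drop = FALSE]
  n <- dim(cnt)[1L]; ntr <- dim(cnt)[2L]; nb <- dim(cnt)[3L]
  if (n < 2L) stop("need at least 2 units")
  # units x (trial,bin) matrix; columns ordered trial-major
  D <- matrix(aperm(cnt, c(1L, 3L, 2L)), n, ntr * nb)
  mu <- rowMeans(D)
  Dc <- D - mu
  sv <- svd(Dc, nu = 1L, nv = 0L)
  w <- sv$u[, 1L]
  scores <- drop(crossprod(w, Dc))             # length nb*ntr, bin-major runs
  single <- matrix(scores, nb, ntr)            # bins x trials
  vals <- rowMeans(single)
  post <- binned$bin_centers >= 0
  if (any(post) && any(!post) &&
      mean(vals[post]) < mean(vals[!post])) {
    w <- -w; single <- -single; vals <- -vals
  }
  structure(list(values = vals, bin_centers = binned$bin_centers,
                 single_trial = single, loadings = w,
                 var_explained = sv$d[1L]^2 / sum(sv$d^2),
                 conditions = unique(lab[keep])),
            class = "population_timeseries")
}

#' Continuous piecewise-linear fit with two breakpoints
#'
#' Least-squares fit of a continuous three-segment piecewise-linear function
#' (initial baseline, rise, plateau — though segment slopes are
#' unconstrained) to a time series. Breakpoints are located by exhaustive
#' search over a grid of bin positions (full bin resolution for series up to
#' 64 bins, coarsened beyond that) followed by local continuous refinement
#' (Nelder-Mead), so the reported solution is never worse than the best grid
#' solution.
#'
#' @param ts A `population_timeseries`, or a list with `values` and
#'   `bin_centers`.
#' @param n_breakpoints Number of breakpoints; only 2 is supported.
#' @return Object of class `piecewise_fit`: `breakpoints` (tau1 < tau2),
#'   `coef` (intercept, base slope, slope changes at the breakpoints),
#'   `sse`, `fitted`, `degenerate` flag.
#' @export
fit_piecewise_linear <- function(ts, n_breakpoints = 2L) {
  if (n_breakpoints != 2L) stop("only two breakpoints are supported")
  t <- ts$bin_centers; y <- ts$values
  nb <- length(t)
  if (nb < 10L) stop("need at least 10 bins")
  degenerate <- stats::var(y) < 1e-24
  Xb <- cbind(1, t, 0, 0)
  sse_at <- function(tau) {
    Xb[, 3L] <- pmax(t - tau[1L], 0)
    Xb[, 4L] <- pmax(t - tau[2L], 0)
    f <- stats::.lm.fit(Xb, y)
    sum(f$residuals^2)
  }
  step <- max(1L, ceiling((nb - 4L) / 60L))
  cand <- t[seq(2L, nb - 1L, by = step)]
  best <- c(cand[1L], cand[2L]); best_sse <- Inf
  for (i in seq_len(length(cand) - 1L)) {
    for (j in seq(i + 1L, length(cand))) {
      s <- sse_at(c(cand[i], cand[j]))
      if (s < best_sse) { best_sse <- s; best <- c(cand[i], cand[j]) }
    }
  }
  pen <- function(tau) {
    if (tau[1L] >= tau[2L] || tau[1L] <= t[1L] || tau[2L] >= t[nb]) return(Inf)
    sse_at(tau)
  }
  opt <- stats::optim(best, pen, method = "Nelder-Mead")
  tau <- if (opt$value <= best_sse) opt$par else best
  X <- cbind(1, t, pmax(t - tau[1L], 0), pmax(t - tau[2L], 0))
  f <- stats::.lm.fit(X, y)
  co <- f$coefficients
  co[is.na(co)] <- 0
  structure(list(breakpoints = tau, coef = co,
                 sse = sum(f$residuals^2), fitted = drop(X %*% co),
                 t_range = range(t), degenerate = degenerate),
            class = "piecewise_fit")
}

#' Evaluate a piecewise-linear fit
#'
#' @param object A `piecewise_fit`.
#' @param t Times at which to evaluate.
#' @param ... Unused.
#' @return Fitted values.
#' @export
predict.piecewise_fit <- function(object, t, ...) {
  co <- object$coef; bp <- object$breakpoints
  co[1L] + co[2L] * t + co[3L] * pmax(t - bp[1L], 0) +
    co[4L] * pmax(t - bp[2L], 0)
}

#' Latency from a piecewise fit and a baseline percentile
#'
#' The response latency is the earliest time at or after the start of the
#' baseline window where the fitted piecewise-linear function exceeds the
#' 95th (by default) percentile of the raw series values inside the baseline
#' window. If the fit never exceeds the threshold the estimate is flagged
#' undefined rather than raising an error.
#'
#' @param ts The `population_timeseries` that was fit.
#' @param fit The corresponding `piecewise_fit`.
#' @param baseline_window Two times (s) bounding the baseline, default
#'   \[-0.150, 0).
#' @param percentile Baseline percentile (default 95).
#' @return Object of class `latency_estimate`: `latency` (s, `NA` if
#'   undefined), `defined`, `threshold`, `fit`.
#' @export
estimate_latency <- function(ts, fit, baseline_window = c(-0.150, 0),
                             percentile = 95) {
  bl <- ts$bin_centers >= baseline_window[1L] &
    ts$bin_centers < baseline_window[2L]
  if (!any(bl)) stop("baseline window contains no bins")
  thr <- stats::quantile(ts$values[bl], percentile / 100, names = FALSE)
  # scale-aware guard so a fit that merely equals the threshold (to within
  # float error) does not register as a crossing
  thr <- thr + 1e-8 * max(diff(range(ts$values)), 1e-300)
  t_lo <- baseline_window[1L]
  t_hi <- fit$t_range[2L]
  knots <- sort(unique(c(t_lo, fit$breakpoints[fit$breakpoints > t_lo &
                                                 fit$breakpoints < t_hi],
                         t_hi)))
  lat <- NA_real_
  for (i in seq_len(length(knots) - 1L)) {
    a <- knots[i]; b <- knots[i + 1L]
    fa <- predict(fit, a); fb <- predict(fit, b)
    if (fa > thr) { lat <- a; break }
    slope <- (fb - fa) / (b - a)
    if (fb > thr && slope > 0) {
      lat <- a + (thr - fa) / slope
      break
    }
  }
  structure(list(latency = lat, defined = !is.na(lat), threshold = thr,
                 fit = fit, baseline_window = baseline_window,
                 percentile = percentile),
            class = "latency_estimate")
}

#' Bootstrap distribution of the latency estimate
#'
#' Resamples single-trial PC1 traces with replacement, re-averages, re-fits
#' the piecewise-linear model and re-estimates latency `n_boot` times;
#' reports the sample distribution and its interquartile range. A warning is
#' issued if more than 20% of resamples yield undefined latencies.
#'
#' @param binned A `binned_tensor` aligned to contact time.
#' @param conditions Condition subset passed to [population_pc1()].
#' @param n_boot Number of resamples (default 1000).
#' @param seed Integer seed.
#' @param baseline_window,percentile Passed to [estimate_latency()].
#' @return List of class `latency_bootstrap`: `point` (the full-data
#'   `latency_estimate`), `samples`, `iqr` (25th/75th percentiles),
#'   `prop_undefined`.
#' @export
bootstrap_latency <- function(binned, conditions = NULL, n_boot = 1000L,
                              seed = 1L, baseline_window = c(-0.150, 0),
                              percentile = 95) {
  pc1 <- population_pc1(binned, conditions)
  fit0 <- fit_piecewise_linear(pc1)
  point <- estimate_latency(pc1, fit0, baseline_window, percentile)
  ntr <- ncol(pc1$single_trial)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  samples <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(ntr, ntr, replace = TRUE)
    ts_b <- list(values = rowMeans(pc1$single_trial[, idx, drop = FALSE]),
                 bin_centers = pc1$bin_centers)
    fit_b <- fit_piecewise_linear(ts_b)
    est_b <- estimate_latency(ts_b, fit_b, baseline_window, percentile)
    samples[b] <- est_b$latency
  }
  prop_na <- mean(is.na(samples))
  if (prop_na > 0.2)
    warning(sprintf("%.0f%% of bootstrap resamples had undefined latency",
                    100 * prop_na))
  structure(list(point = point, samples = samples,
                 iqr = stats::quantile(samples, c(0.25, 0.75), na.rm = TRUE,
                                       names = FALSE),
                 prop_undefined = prop_na),
            class = "latency_bootstrap")
}

#' Permutation test for a latency difference between body sides
#'
#' Two-sided label-shuffling test of the difference in mean latency between
#' two sets of latency samples (e.g. bootstrap draws for left- and
#' right-side stimulation).
#'
#' @param samplesL,samplesR Numeric latency samples (`NA`s dropped).
#' @param n_perm Number of shuffles (default 2000).
#' @param seed Integer seed.
#' @return Two-sided permutation p-value.
#' @export
latency_side_test <- function(samplesL, samplesR, n_perm = 2000L, seed = 1L) {
  correlation_contrast_test(samplesL[!is.na(samplesL)],
                            samplesR[!is.na(samplesR)], n_perm, seed)
}
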