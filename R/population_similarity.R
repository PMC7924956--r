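# Cross-validated split-half condition similarity. Each condition's trials
# are repeatedly partitioned 50-50; condition-mean population vectors from
# independent halves are compared pairwise, so the diagonal (a condition
# against itself across halves) estimates the noise ceiling that bounds all
# between-condition similarities.

#' Cross-validated condition-correlation matrix
#'
#' For each of `n_splits` random 50-50 partitions of every condition's
#' trials, computes condition-mean population vectors for the two halves and
#' the chosen similarity between half-A of condition i and half-B of
#' condition j for all pairs, including i = j (within-condition noise
#' ceiling). The i-to-j and j-to-i comparisons are computed independently
#' and averaged into a symmetric matrix; with odd trial counts the extra
#' trial joins half A. Results are averaged over splits.
#'
#' Each unit's response is taken relative to its baseline when a baseline
#' matrix is supplied (recommended): if the baseline matrix covers the same
#' trials, every trial's own pre-cue baseline rate is subtracted (so the
#' correction is cross-validated along with the trial splits); otherwise the
#' per-unit mean baseline rate is subtracted. Without the correction,
#' conditions without systematic responses (e.g. the null condition)
#' correlate well above zero purely through shared per-unit rate offsets.
#'
#' @param rates A `firing_rate_matrix`; every condition needs >= 2 trials.
#' @param n_splits Number of split resamples (default 250).
#' @param metric `"pearson"`, `"cosine"` or `"euclidean"` (distance; smaller
#'   means more similar, unbounded).
#' @param seed Integer seed.
#' @param baseline Optional baseline-window `firing_rate_matrix` over the
#'   same units; per-unit mean baseline rates are subtracted.
#' @return Object of class `correlation_matrix`: `mean_corr`
#'   (condition x condition), `split_samples` (condition x condition x
#'   n_splits array), `metric`, `conditions`.
#' @export
cv_condition_correlation <- function(rates, n_splits = 250L,
                                     metric = c("pearson", "cosine",
                                                "euclidean"),
                                     seed = 1L, baseline = NULL) {
  metric <- match.arg(metric)
  stopifnot(inherits(rates, "firing_rate_matrix"), n_splits >= 1L)
  labels <- rates$labels$condition
  lev <- unique(labels)
  idx_by_cond <- split(seq_along(labels), factor(labels, levels = lev))
  if (any(lengths(idx_by_cond) < 2L))
    stop("condition with fewer than 2 trials")
  Y <- rates$rates                      # units x trials
  if (!is.null(baseline)) {
    stopifnot(identical(baseline$unit_ids, rates$unit_ids))
    if (identical(baseline$labels$trial_id, rates$labels$trial_id))
      Y <- Y - baseline$rates
    else Y <- Y - rowMeans(baseline$rates)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  k <- length(lev)
  samples <- array(NA_real_, c(k, k, n_splits),
                   dimnames = list(lev, lev, NULL))
  for (s in seq_len(n_splits)) {
    A <- matrix(0, nrow(Y), k)
    B <- matrix(0, nrow(Y), k)
    for (ci in seq_len(k)) {
      id <- idx_by_cond[[ci]]
      nh <- ceiling(length(id) / 2)      # extra trial goes to half A
      a <- sample(id, nh)
      b <- setdiff(id, a)
      A[, ci] <- rowMeans(Y[, a, drop = FALSE])
      B[, ci] <- rowMeans(Y[, b, drop = FALSE])
    }
    samples[, , s] <- similarity_matrix(A, B, metric)
  }
  mc <- apply(samples, c(1L, 2L), mean)
  structure(list(mean_corr = (mc + t(mc)) / 2,
                 split_samples = samples, metric = metric, conditions = lev),
            class = "correlation_matrix")
}

similarity_matrix <- function(A, B, metric) {
  if (metric == "pearson") {
    stats::cor(A, B)
  } else if (metric == "cosine") {
    An <- sweep(A, 2L, sqrt(colSums(A^2)), "/")
    Bn <- sweep(B, 2L, sqrt(colSums(B^2)), "/")
    t(An) %*% Bn
  } else {
    a2 <- colSums(A^2); b2 <- colSums(B^2)
    d2 <- outer(a2, b2, "+") - 2 * t(A) %*% B
    sqrt(pmax(d2, 0))
  }
}

#' Two-sided permutation test for a difference in mean similarity
#'
#' Tests whether two sets of per-split similarity samples have different
#' means, by pooling and randomly re-splitting them `n_shuffles` times.
#' The p-value is `(1 + #\{|null diff| >= |observed diff|\}) /
#' (1 + n_shuffles)`.
#'
#' @param samplesA,samplesB Numeric vectors (e.g. per-split correlations).
#' @param n_shuffles Number of shuffles (default 2000); fewer than 100
#'   triggers a warning.
#' @param seed Integer seed.
#' @return Two-sided permutation p-value.
#' @export
correlation_contrast_test <- function(samplesA, samplesB, n_shuffles = 2000L,
                                      seed = 1L) {
  stopifnot(length(samplesA) >= 1L, length(samplesB) >= 1L)
  if (n_shuffles < 100L)
    warning("fewer than 100 shuffles; p-value resolution is coarse")
  obs <- mean(samplesA) - mean(samplesB)
  pool <- c(samplesA, samplesB)
  nA <- length(samplesA)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  tot <- sum(pool); n <- length(pool); nB <- n - nA
  null_diff <- vapply(seq_len(n_shuffles), function(i) {
    sa <- sum(pool[sample.int(n, nA)])
    sa / nA - (tot - sa) / nB
  }, 0)
  (1 + sum(abs(null_diff) >= abs(obs))) / (1 + n_shuffles)
}

#' Mirror-symmetry contrast between left and right body sides
#'
#' For each left/right condition pair, tests whether the left-right
#' cross-correlation falls below the within-condition noise ceiling. The
#' statistic is the mean within-condition split-half correlation minus the
#' mean left-right cross correlation (over `n_splits` random 50-50 trial
#' splits). Its null distribution is built by randomly re-assigning the
#' pair's trials to the two sides (`n_shuffles` times) and recomputing the
#' statistic: under mirror-symmetric coding the side labels are exchangeable,
#' so the permutation is exact. A pair whose two-sided p-value exceeds
#' `alpha` is statistically indistinguishable from the ceiling, the
#' signature of mirror-symmetric bilateral coding.
#'
#' (The split-sample permutation of [correlation_contrast_test()] is not
#' used here: re-split samples of the same trials are pseudo-replicated, so
#' near the noise ceiling that test flags negligible data-level fluctuations.)
#'
#' @param rates A `firing_rate_matrix` containing both conditions of every
#'   pair.
#' @param lateral_pairs Data frame or 2-column matrix of (left condition,
#'   right condition) identifiers.
#' @param baseline Optional baseline `firing_rate_matrix` (as in
#'   [cv_condition_correlation()]).
#' @param n_splits Random splits per statistic evaluation (default 50).
#' @param n_shuffles Side-relabelling permutations (default 500).
#' @param seed Integer seed.
#' @param alpha Level for the indistinguishability call (default 0.05).
#' @return Data frame with one row per pair: `left`, `right`, `lr_corr`,
#'   `ceiling_corr`, `p`, `at_ceiling`.
#' @export
mirror_symmetry_contrast <- function(rates, lateral_pairs, baseline = NULL,
                                     n_splits = 50L, n_shuffles = 500L,
                                     seed = 1L, alpha = 0.05) {
  stopifnot(inherits(rates, "firing_rate_matrix"))
  lp <- as.matrix(lateral_pairs)
  miss <- setdiff(unique(as.vector(lp)), rates$labels$condition)
  if (length(miss))
    stop("conditions absent from rates: ", paste(miss, collapse = ", "))
  Y <- rates$rates
  if (!is.null(baseline)) {
    stopifnot(identical(baseline$unit_ids, rates$unit_ids))
    if (identical(baseline$labels$trial_id, rates$labels$trial_id))
      Y <- Y - baseline$rates
    else Y <- Y - rowMeans(baseline$rates)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  col_cor <- function(X, Z) {
    Xc <- sweep(X, 2L, colMeans(X))
    Zc <- sweep(Z, 2L, colMeans(Z))
    colSums(Xc * Zc) / sqrt(colSums(Xc^2) * colSums(Zc^2))
  }
  half_means <- function(Yc) {
    n <- ncol(Yc)
    nh <- ceiling(n / 2)
    SelA <- matrix(0, n, n_splits)
    for (s in seq_len(n_splits)) SelA[sample.int(n, nh), s] <- 1
    list(A = (Yc %*% SelA) / nh, B = (Yc %*% (1 - SelA)) / (n - nh))
  }
  # statistic: mean within-side ceiling minus mean cross-side correlation,
  # over n_splits random 50-50 splits (vectorised across splits)
  stat <- function(Yl, Yr) {
    hl <- half_means(Yl); hr <- half_means(Yr)
    w <- c(col_cor(hl$A, hl$B), col_cor(hr$A, hr$B))
    x <- c(col_cor(hl$A, hr$B), col_cor(hr$A, hl$B))
    c(diff = mean(w) - mean(x), within = mean(w), cross = mean(x))
  }
  out <- data.frame(left = lp[, 1L], right = lp[, 2L], lr_corr = NA_real_,
                    ceiling_corr = NA_real_, p = NA_real_,
                    at_ceiling = NA, stringsAsFactors = FALSE)
  cond <- rates$labels$condition
  for (i in seq_len(nrow(lp))) {
    il <- which(cond == lp[i, 1L]); ir <- which(cond == lp[i, 2L])
    obs <- stat(Y[, il, drop = FALSE], Y[, ir, drop = FALSE])
    pool <- c(il, ir)
    null_diff <- vapply(seq_len(n_shuffles), function(b) {
      pl <- sample(pool, length(il))
      stat(Y[, pl, drop = FALSE],
           Y[, setdiff(pool, pl), drop = FALSE])[1L]
    }, 0)
    p <- (1 + sum(abs(null_diff) >= abs(obs[1L]))) / (1 + n_shuffles)
    out$lr_corr[i] <- obs[3L]
    out$ceiling_corr[i] <- obs[2L]
    out$p[i] <- p
    out$at_ceiling[i] <- p > alpha
  }
  out
}
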