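# Sliding-window cross-temporal analyses for the cue-delay/imagery paradigm:
# generalization matrices of diagonal-LDA accuracy across all pairs of
# training/testing windows (population or per unit), cross-validated
# Mahalanobis (crossnobis) separation from a post-cue reference window, PCA
# over per-unit generalization matrices, and cross-format (actual vs
# imagined touch) dynamic pattern correlation.

window_onsets <- function(binned, window, step) {
  on <- seq(binned$t_start, binned$t_end - window + 1e-9, by = step)
  if (!length(on)) stop("window wider than the binned range")
  on
}

# units x trials x n_windows array of mean rates per sliding window
window_features <- function(binned, window, step, trial_idx = NULL) {
  on <- window_onsets(binned, window, step)
  cnt <- binned$counts
  if (!is.null(trial_idx)) cnt <- cnt[, trial_idx, , drop = FALSE]
  d <- dim(cnt)
  W <- array(NA_real_, c(d[1L], d[2L], length(on)))
  for (w in seq_along(on)) {
    inb <- binned$bin_centers >= on[w] &
      binned$bin_centers < on[w] + window
    W[, , w] <- rowSums(cnt[, , inb, drop = FALSE], dims = 2L) /
      (sum(inb) * binned$bin_size)
  }
  list(W = W, onsets = on)
}

# leave-one-out generalization accuracy for one feature tensor
# (units x trials x windows) with class labels g; the identical trial
# partition is reused at every window pair, and the within-window model
# matches fit_lda_diag exactly (pooled floored variance, first-level ties).
dyn_class_core <- function(W, g) {
  d <- dim(W)
  N <- d[1L]; ntr <- d[2L]; nw <- d[3L]
  lev <- levels(g)
  k <- length(lev)
  gi <- as.integer(g)
  nk <- tabulate(gi, k)
  correct <- matrix(0, nw, nw)
  E <- diag(k)
  for (i in seq_len(nw)) {
    X <- matrix(W[, , i], N, ntr)              # units x trials
    S <- rowsum(t(X), g)                       # k x N class sums
    Q <- rowSums(X^2)                          # per-unit sum of squares
    for (tr in seq_len(ntr)) {
      c0 <- gi[tr]
      x <- X[, tr]
      Sp <- S - outer(E[c0, ], x)
      np <- nk - E[c0, ]
      ss <- (Q - x^2) - colSums(Sp^2 / np)
      v <- pmax(ss / (ntr - 1L - k), VAR_FLOOR)
      Mw <- Sp / np / rep(v, each = k)         # k x N, means / var
      const <- 0.5 * rowSums((Sp / np) * Mw)
      Xall <- t(matrix(W[, tr, ], N, nw))      # nw x N held-out features
      D <- Xall %*% t(Mw) - rep(const, each = nw)
      pred <- max.col(D, ties.method = "first")
      correct[i, ] <- correct[i, ] + (pred == c0)
    }
  }
  correct / ntr
}

#' Cross-temporal generalization matrix of classification accuracy
#'
#' Averages neural activity in sliding windows (default 500 ms stepped at
#' 100 ms), trains a diagonal-covariance LDA classifier on each training
#' window and tests it on every window, under leave-one-out cross-validation
#' with one trial partition reused at every window pair so that all entries
#' use the same amount of training and test data. The diagonal is the
#' within-window cross-validated accuracy; off-diagonal entries measure how
#' decision boundaries generalize across task epochs.
#'
#' @param binned A `binned_tensor` aligned to the cue.
#' @param conditions Condition identifiers to classify (default: all imagery
#'   conditions in the tensor).
#' @param window Window width (s), default 0.5.
#' @param step Step between window onsets (s), default 0.1.
#' @param scope `"population"` (one matrix) or `"single_unit"` (a list of
#'   matrices, one per unit, from the identical procedure on 1-dimensional
#'   features).
#' @return For population scope, an object of class `dyn_class_matrix`:
#'   `accuracy` (train x test window), `window_onsets`, `window`, `step`,
#'   `chance`, `scope`. For single-unit scope, a named list of such objects.
#' @export
dynamic_classification <- function(binned, conditions = NULL, window = 0.5,
                                   step = 0.1,
                                   scope = c("population", "single_unit")) {
  scope <- match.arg(scope)
  stopifnot(inherits(binned, "binned_tensor"))
  lab <- binned$labels$condition
  if (is.null(conditions))
    conditions <- unique(lab[binned$labels$format == "imagery"])
  keep <- which(lab %in% conditions)
  if (length(unique(lab[keep])) < 2L) stop("need at least 2 conditions")
  wf <- window_features(binned, window, step, keep)
  g <- factor(lab[keep], levels = sort(unique(lab[keep])))
  if (any(table(g) < 2L)) stop("condition with fewer than 2 trials")
  wrap <- function(acc, sc)
    structure(list(accuracy = acc, window_onsets = wf$onsets,
                   window = window, step = step,
                   chance = 1 / nlevels(g), scope = sc),
              class = "dyn_class_matrix")
  if (scope == "population") return(wrap(dyn_class_core(wf$W, g),
                                         "population"))
  out <- lapply(seq_along(binned$unit_ids), function(u)
    wrap(dyn_class_core(wf$W[u, , , drop = FALSE], g), "single_unit"))
  names(out) <- binned$unit_ids
  out
}

#' Crossnobis distance time course from a post-cue reference
#'
#' Cross-validated (unbiased) squared Mahalanobis distance between the
#' population activity in each sliding window and a reference window
#' immediately following the cue (default 0.25-0.75 s post-cue). Trials of
#' each condition are split into two independent folds; the estimate is the
#' inner product of the fold-1 and fold-2 (window minus reference) mean
#' difference vectors under a diagonal noise covariance pooled from
#' reference-window residuals (with a df/(df-2) inverse-variance
#' unbiasedness correction and the decoder's variance floor), averaged over
#' random fold assignments. The expectation is zero when a window's
#' distribution equals the reference's; estimates may be negative.
#'
#' @param binned A `binned_tensor` aligned to the cue.
#' @param conditions Condition identifiers (default: imagery conditions).
#' @param reference_window Reference interval (s, relative to cue).
#' @param window,step Sliding-window parameters.
#' @param n_splits Number of random fold assignments (default 20).
#' @param seed Integer seed.
#' @return Object of class `crossnobis_series`: `distance` (condition x
#'   window), `mean` (per window, averaged over conditions),
#'   `window_onsets`, `reference_window`.
#' @export
crossnobis_timecourse <- function(binned, conditions = NULL,
                                  reference_window = c(0.25, 0.75),
                                  window = 0.5, step = 0.1,
                                  n_splits = 20L, seed = 1L) {
  stopifnot(inherits(binned, "binned_tensor"))
  lab <- binned$labels$condition
  if (is.null(conditions))
    conditions <- unique(lab[binned$labels$format == "imagery"])
  keep <- which(lab %in% conditions)
  g <- factor(lab[keep], levels = unique(lab[keep]))
  if (any(table(g) < 4L))
    stop("need at least 4 trials per condition for two folds")
  wf <- window_features(binned, window, step, keep)
  N <- dim(wf$W)[1L]; nw <- dim(wf$W)[3L]
  inb <- binned$bin_centers >= reference_window[1L] &
    binned$bin_centers < reference_window[2L]
  if (!any(inb)) stop("reference window contains no bins")
  Ref <- rowSums(binned$counts[, keep, inb, drop = FALSE], dims = 2L) /
    (sum(inb) * binned$bin_size)               # units x trials
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  k <- nlevels(g)
  dist_acc <- matrix(0, k, nw, dimnames = list(levels(g), NULL))
  idx_by_c <- split(seq_along(g), g)
  for (s in seq_len(n_splits)) {
    f1 <- lapply(idx_by_c, function(id) sort(sample(id, floor(length(id) / 2))))
    f2 <- mapply(setdiff, idx_by_c, f1, SIMPLIFY = FALSE)
    # pooled diagonal covariance from reference residuals in both folds
    ssq <- numeric(N); df <- 0L
    for (ci in seq_len(k)) for (fold in list(f1[[ci]], f2[[ci]])) {
      R <- Ref[, fold, drop = FALSE]
      ssq <- ssq + rowSums((R - rowMeans(R))^2)
      df <- df + length(fold) - 1L
    }
    v <- ssq / df
    if (df > 2L) v <- v * df / (df - 2L)       # unbiased inverse variance
    v <- pmax(v, VAR_FLOOR)
    for (ci in seq_len(k)) {
      d1ref <- rowMeans(Ref[, f1[[ci]], drop = FALSE])
      d2ref <- rowMeans(Ref[, f2[[ci]], drop = FALSE])
      M1 <- apply(wf$W[, f1[[ci]], , drop = FALSE], c(1L, 3L), mean) - d1ref
      M2 <- apply(wf$W[, f2[[ci]], , drop = FALSE], c(1L, 3L), mean) - d2ref
      dist_acc[ci, ] <- dist_acc[ci, ] + colSums(M1 * M2 / v)
    }
  }
  dist <- dist_acc / n_splits
  structure(list(distance = dist, mean = colMeans(dist),
                 window_onsets = wf$onsets,
                 reference_window = reference_window),
            class = "crossnobis_series")
}

#' PCA over per-unit dynamic classification matrices
#'
#' Flattens each unit's generalization matrix to a vector, treats units as
#' observations, and applies mean-centred PCA. Components are reshaped back
#' to window x window matrices; variance-explained fractions sum to 1.
#'
#' @param per_unit List of `dyn_class_matrix` objects of identical shape
#'   (>= 3 units).
#' @param n_components Number of components to return (default 3).
#' @return List of class `dyn_class_pca`: `components` (window x window x
#'   component array), `var_explained` (all components), `mean_matrix`,
#'   `degenerate` flag (all units identical).
#' @export
unit_dynamic_pca <- function(per_unit, n_components = 3L) {
  stopifnot(length(per_unit) >= 3L)
  dims <- dim(per_unit[[1L]]$accuracy)
  X <- t(vapply(per_unit, function(m) {
    stopifnot(identical(dim(m$accuracy), dims))
    as.vector(m$accuracy)
  }, numeric(prod(dims))))
  Xc <- sweep(X, 2L, colMeans(X))
  sv <- svd(Xc)
  tot <- sum(sv$d^2)
  if (tot < 1e-20)
    return(structure(list(components = NULL, var_explained = numeric(0),
                          mean_matrix = matrix(colMeans(X), dims[1L]),
                          degenerate = TRUE),
                     class = "dyn_class_pca"))
  nc <- min(n_components, ncol(sv$v), nrow(X) - 1L)
  comps <- array(sv$v[, seq_len(nc)], c(dims[1L], dims[2L], nc))
  structure(list(components = comps, var_explained = sv$d^2 / tot,
                 mean_matrix = matrix(colMeans(X), dims[1L]),
                 degenerate = FALSE),
            class = "dyn_class_pca")
}

#' Cross-format dynamic pattern correlation
#'
#' Compares, across all pairs of time windows, the population pattern of
#' body-site selectivity within and across the actual-touch and imagery
#' formats. For each of `n_splits` random 50-50 trial splits and each
#' window, a (2N) x 2 matrix is formed per split half (rows: units stacked
#' over the two body sites; columns: formats) of trial-averaged rates; each
#' unit's mean over its two site entries within a column is subtracted, so
#' the correlations reflect site-preference patterns rather than per-unit
#' rate offsets; train and test columns are then Pearson-correlated for all
#' window pairs and format pairs, and averaged over splits. The two
#' cross-format directions (train actual/test imagery and the reverse) are
#' averaged into one matrix.
#'
#' @param binned_actual,binned_imagery `binned_tensor` objects over the same
#'   units and bin grid, containing the two actual-touch and the two
#'   matching imagery conditions respectively (>= 4 trials per condition).
#' @param window,step Sliding-window parameters.
#' @param n_splits Number of random splits (default 50).
#' @param seed Integer seed.
#' @return Object of class `dyn_format_corr`: `corr` (list of train x test
#'   matrices `actual_actual`, `imagery_imagery`, `actual_imagery`),
#'   `window_onsets`, `n_splits`.
#' @export
dynamic_format_correlation <- function(binned_actual, binned_imagery,
                                       window = 0.5, step = 0.1,
                                       n_splits = 50L, seed = 1L) {
  stopifnot(inherits(binned_actual, "binned_tensor"),
            inherits(binned_imagery, "binned_tensor"))
  if (!identical(binned_actual$unit_ids, binned_imagery$unit_ids))
    stop("unmatched units across formats")
  if (!isTRUE(all.equal(binned_actual$bin_centers,
                        binned_imagery$bin_centers)))
    stop("formats binned on different time grids")
  parts <- sort(unique(binned_actual$labels$body_part[
    binned_actual$labels$format != "null"]))
  if (length(parts) != 2L)
    stop("expected exactly 2 body sites per format, got: ",
         paste(parts, collapse = ", "))
  if (!setequal(parts, unique(binned_imagery$labels$body_part[
    binned_imagery$labels$format != "null"])))
    stop("formats cover different body sites")

  prep <- function(binned) {
    keep <- which(binned$labels$body_part %in% parts)
    wf <- window_features(binned, window, step, keep)
    list(W = wf$W, onsets = wf$onsets,
         part = binned$labels$body_part[keep])
  }
  A <- prep(binned_actual)
  I <- prep(binned_imagery)
  nw <- length(A$onsets)
  N <- dim(A$W)[1L]
  if (any(table(A$part) < 4L) || any(table(I$part) < 4L))
    stop("need at least 4 trials per condition")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  # centred, stacked (2N x nw) site-pattern matrix for a set of trials
  col_mat <- function(W, part, idx) {
    x1 <- apply(W[, intersect(idx, which(part == parts[1L])), , drop = FALSE],
                c(1L, 3L), mean)
    x2 <- apply(W[, intersect(idx, which(part == parts[2L])), , drop = FALSE],
                c(1L, 3L), mean)
    m <- (x1 + x2) / 2
    rbind(x1 - m, x2 - m)
  }
  acc <- list(aa = matrix(0, nw, nw), ii = matrix(0, nw, nw),
              ai = matrix(0, nw, nw))
  for (s in seq_len(n_splits)) {
    sp <- function(part) {
      tr <- unlist(lapply(parts, function(p) {
        id <- which(part == p)
        sample(id, ceiling(length(id) / 2))
      }))
      list(train = tr)
    }
    spA <- sp(A$part); spI <- sp(I$part)
    TrA <- col_mat(A$W, A$part, spA$train)
    TeA <- col_mat(A$W, A$part, setdiff(seq_along(A$part), spA$train))
    TrI <- col_mat(I$W, I$part, spI$train)
    TeI <- col_mat(I$W, I$part, setdiff(seq_along(I$part), spI$train))
    acc$aa <- acc$aa + stats::cor(TrA, TeA)
    acc$ii <- acc$ii + stats::cor(TrI, TeI)
    acc$ai <- acc$ai + (stats::cor(TrA, TeI) + stats::cor(TrI, TeA)) / 2
  }
  structure(list(corr = list(actual_actual = acc$aa / n_splits,
                             imagery_imagery = acc$ii / n_splits,
                             actual_imagery = acc$ai / n_splits),
                 window_onsets = A$onsets, n_splits = n_splits),
            class = "dyn_format_corr")
}
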