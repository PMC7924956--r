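# Diagonal-covariance linear discriminant decoding. The model assumes (1)
# conditions differ only in their mean firing-rate vectors (one shared
# covariance) and (2) units are independent (the shared covariance is
# diagonal), so training reduces to per-condition means and one pooled
# within-condition variance per unit.

VAR_FLOOR <- 1e-6  # Hz^2, floor for zero-variance units

#' Fit a diagonal-covariance LDA decoder
#'
#' @param rates A `firing_rate_matrix` with at least two conditions and two
#'   trials per condition.
#' @return Object of class `lda_diag`: per-condition mean matrix
#'   (conditions x units), pooled per-unit variance (floored at `1e-6`),
#'   condition labels in training order.
#' @export
fit_lda_diag <- function(rates) {
  stopifnot(inherits(rates, "firing_rate_matrix"))
  fit_lda_diag_mat(t(rates$rates), rates$labels$condition)
}

# core fit on a samples x units matrix; condition order (and hence the
# deterministic tie-break) is alphabetical
fit_lda_diag_mat <- function(Y, labels) {
  g <- factor(labels, levels = sort(unique(labels)))
  if (nlevels(g) < 2L) stop("need at least 2 conditions")
  nk <- table(g)
  if (any(nk < 2L)) stop("condition with fewer than 2 trials")
  means <- rowsum(Y, g) / as.vector(nk)
  res <- Y - means[as.integer(g), , drop = FALSE]
  pooled_var <- colSums(res^2) / (nrow(Y) - nlevels(g))
  pooled_var <- pmax(pooled_var, VAR_FLOOR)
  structure(list(means = means, var = pooled_var, levels = levels(g)),
            class = "lda_diag")
}

#' Predict conditions with a fitted diagonal LDA
#'
#' Assigns each sample to the condition maximising the Gaussian discriminant
#' `-0.5 * sum_u (x_u - mu_cu)^2 / var_u` (equal priors). Ties are broken
#' deterministically in favour of the condition earlier in training order.
#'
#' @param object An `lda_diag` model.
#' @param newdata Matrix of samples x units (or a `firing_rate_matrix`).
#' @param ... Unused.
#' @return Character vector of predicted condition labels.
#' @export
predict.lda_diag <- function(object, newdata, ...) {
  if (inherits(newdata, "firing_rate_matrix")) newdata <- t(newdata$rates)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  w <- 1 / object$var
  # discriminant: x' diag(w) mu - 0.5 mu' diag(w) mu (linear, shared cov)
  Mw <- object$means * rep(w, each = nrow(object$means))
  lin <- newdata %*% t(Mw)
  const <- 0.5 * rowSums(object$means * Mw)
  D <- sweep(lin, 2L, const)
  object$levels[max.col(D, ties.method = "first")]
}

#' Leave-one-out confusion matrix
#'
#' Predicts every trial from a decoder trained on all remaining trials
#' (leave-one-out is inherently stratified) and aggregates the results into
#' a row-normalised confusion matrix. All supplied units are used, not only
#' significantly modulated ones. Folds iterate trials in stored order, so
#' results are exactly reproducible.
#'
#' @param rates A `firing_rate_matrix`.
#' @return Object of class `confusion_matrix`: `accuracy` (true x predicted,
#'   rows sum to 1), `n_trials` per condition, `overall_accuracy`.
#' @export
loo_confusion <- function(rates) {
  stopifnot(inherits(rates, "firing_rate_matrix"))
  Y <- t(rates$rates)
  labels <- rates$labels$condition
  lev <- sort(unique(labels))
  n <- nrow(Y)
  pred <- character(n)
  for (i in seq_len(n)) {
    m <- fit_lda_diag_mat(Y[-i, , drop = FALSE], labels[-i])
    pred[i] <- predict(m, Y[i, , drop = FALSE])
  }
  confusion_from_predictions(labels, pred, lev)
}

confusion_from_predictions <- function(truth, pred, lev) {
  tab <- table(factor(truth, levels = lev), factor(pred, levels = lev))
  n_trials <- rowSums(tab)
  acc <- sweep(unclass(tab), 1L, n_trials, "/")
  dimnames(acc) <- list(lev, lev)
  structure(list(accuracy = acc, n_trials = n_trials,
                 overall_accuracy = sum(diag(unclass(tab))) / sum(tab)),
            class = "confusion_matrix")
}

#' Average confusion matrices across sessions
#'
#' Element-wise mean of confusion matrices sharing a condition set (e.g. one
#' per recording day); row-stochasticity is preserved and re-checked.
#'
#' @param confusions List of `confusion_matrix` objects.
#' @return A `confusion_matrix` with the averaged accuracies.
#' @export
average_confusions <- function(confusions) {
  stopifnot(length(confusions) >= 1L)
  lev <- rownames(confusions[[1L]]$accuracy)
  for (cm in confusions) {
    stopifnot(inherits(cm, "confusion_matrix"))
    if (!identical(rownames(cm$accuracy), lev))
      stop("confusion matrices have mismatched condition sets")
  }
  acc <- Reduce(`+`, lapply(confusions, `[[`, "accuracy")) /
    length(confusions)
  if (any(abs(rowSums(acc) - 1) > 1e-9))
    stop("averaged confusion rows do not sum to 1")
  structure(list(accuracy = acc,
                 n_trials = Reduce(`+`, lapply(confusions, `[[`, "n_trials")),
                 overall_accuracy = mean(vapply(confusions, `[[`, 0,
                                                "overall_accuracy"))),
            class = "confusion_matrix")
}
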