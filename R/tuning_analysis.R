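# Per-unit indicator-variable linear tuning model. Firing rate is modelled
# as FR = beta0 + sum_c beta_c X_c with one indicator per condition;
# baseline-window samples enter with all indicators 0, pooling baseline data
# across conditions. Per-condition significance comes from the t statistic
# of beta_c, overall discrimination from the F test of all beta_c jointly,
# both FDR-corrected (Benjamini-Hochberg) across the whole unit x condition
# family of one analysis.

#' Fit the per-unit linear tuning model
#'
#' Ordinary least squares on stacked stimulus-window and (optional) pooled
#' baseline samples, fitted for all units against the shared design matrix.
#' When baseline samples are omitted the intercept absorbs one condition via
#' pivoting and the overall F test reduces exactly to the one-way ANOVA of
#' [anova_discrimination()].
#'
#' @param rates Stimulus-window `firing_rate_matrix`.
#' @param baseline Baseline-window `firing_rate_matrix` over the same units,
#'   or `NULL` to fit without a pooled reference.
#' @param q FDR level for the responsiveness/tuning flags (default 0.05).
#' @return Object of class `tuning_result`: list with `unit_ids`,
#'   `conditions`, `beta0`, `beta` (units x conditions, Hz), `tstat`, `pval`,
#'   `F`, `p_F`, `responsive` (post-FDR logical matrix), `tuned` (post-FDR
#'   logical), `q`.
#' @export
fit_linear_tuning <- function(rates, baseline = NULL, q = 0.05) {
  stopifnot(inherits(rates, "firing_rate_matrix"))
  conds <- unique(rates$labels$condition)
  tabn <- table(rates$labels$condition)
  if (any(tabn < 2L))
    stop("condition with fewer than 2 samples: ",
         names(tabn)[which(tabn < 2L)[1L]])
  Y <- t(rates$rates)                       # samples x units
  X <- stats::model.matrix(~ 0 + factor(rates$labels$condition,
                                        levels = conds))
  colnames(X) <- conds
  if (!is.null(baseline)) {
    stopifnot(identical(baseline$unit_ids, rates$unit_ids))
    Y <- rbind(Y, t(baseline$rates))
    X <- rbind(X, matrix(0, ncol(baseline$rates), length(conds)))
  }
  X <- cbind(`(Intercept)` = 1, X)
  fit <- ols_multi(X, Y)
  beta <- t(fit$coef[-1L, , drop = FALSE])  # units x conditions
  tstat <- t(fit$tstat[-1L, , drop = FALSE])
  pval <- t(fit$pval[-1L, , drop = FALSE])
  dimnames(beta) <- dimnames(tstat) <- dimnames(pval) <-
    list(rates$unit_ids, conds)
  fdr_all <- fdr_correct(as.vector(pval), q)
  responsive <- matrix(fdr_all$reject, nrow(beta), ncol(beta),
                       dimnames = dimnames(beta))
  tuned <- fdr_correct(fit$p_F, q)$reject
  structure(list(unit_ids = rates$unit_ids, conditions = conds,
                 beta0 = unname(fit$coef[1L, ]), beta = beta, tstat = tstat,
                 pval = pval, F = fit$F, p_F = fit$p_F,
                 responsive = responsive, tuned = tuned, q = q),
            class = "tuning_result")
}

# OLS of a common design on many response columns; rank-deficient designs
# are handled by QR pivoting (aliased coefficients are NA and excluded from
# the t/F machinery).
ols_multi <- function(X, Y) {
  n <- nrow(X)
  qrX <- qr(X)
  r <- qrX$rank
  coef <- qr.coef(qrX, Y)
  res <- Y - qr.fitted(qrX, Y)
  rss <- colSums(res^2)
  df <- n - r
  sigma2 <- if (df > 0) rss / df else rep(NA_real_, ncol(Y))
  piv <- qrX$pivot[seq_len(r)]
  Rm <- qr.R(qrX)[seq_len(r), seq_len(r), drop = FALSE]
  xtxinv_diag <- rep(NA_real_, ncol(X))
  xtxinv_diag[piv] <- diag(chol2inv(Rm))
  se <- sqrt(outer(xtxinv_diag, sigma2))
  tstat <- coef / se
  pval <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  # overall F: full model vs intercept-only
  tss <- colSums(sweep(Y, 2L, colMeans(Y))^2)
  mss <- tss - rss
  df1 <- r - 1L
  eps <- 1e-12 * (n + colMeans(Y)^2 * n)
  Fstat <- (mss / df1) / sigma2
  p_F <- stats::pf(Fstat, df1, df, lower.tail = FALSE)
  deg0 <- rss <= eps & mss <= eps    # no variance at all
  degI <- rss <= eps & mss > eps     # perfect separation
  Fstat[deg0] <- 0;   p_F[deg0] <- 1
  Fstat[degI] <- Inf; p_F[degI] <- 0
  pval[, rss <= eps & mss <= eps] <- 1
  list(coef = coef, tstat = tstat, pval = pval, F = Fstat, p_F = p_F,
       sigma2 = sigma2, df = df, rank = r)
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up procedure: with sorted p-values p(1) <= ... <= p(m), rejects all
#' hypotheses up to the largest k with p(k) <= k q / m, and reports monotone
#' adjusted p-values.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\] (`NA` allowed; never
#'   rejected, adjusted to `NA`).
#' @param q FDR level.
#' @return List with `reject` (logical) and `p_adj` (numeric).
#' @export
fdr_correct <- function(pvals, q = 0.05) {
  m <- sum(!is.na(pvals))
  if (m == 0L)
    return(list(reject = logical(length(pvals)),
                p_adj = rep(NA_real_, length(pvals))))
  p_adj <- rep(NA_real_, length(pvals))
  ok <- !is.na(pvals)
  p <- pvals[ok]
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(pmin(ranked, 1))))
  tmp <- numeric(m)
  tmp[o] <- adj
  p_adj[ok] <- tmp
  reject <- !is.na(p_adj) & p_adj <= q
  list(reject = reject, p_adj = p_adj)
}

#' Per-unit one-way ANOVA across touch locations
#'
#' Tests, for each unit, whether stimulus-window firing rates differ across
#' conditions (no baseline samples).
#'
#' @param rates A `firing_rate_matrix` restricted to the conditions of
#'   interest.
#' @return Data frame with `unit_id`, `F`, `p`.
#' @export
anova_discrimination <- function(rates) {
  stopifnot(inherits(rates, "firing_rate_matrix"))
  g <- factor(rates$labels$condition)
  if (nlevels(g) < 2L) stop("need at least 2 conditions")
  if (any(table(g) < 2L)) stop("condition with fewer than 2 samples")
  Y <- t(rates$rates)
  n <- nrow(Y); k <- nlevels(g)
  gm <- rowsum(Y, g) / as.vector(table(g))
  fitted <- gm[as.integer(g), , drop = FALSE]
  rss <- colSums((Y - fitted)^2)
  tss <- colSums(sweep(Y, 2L, colMeans(Y))^2)
  mss <- tss - rss
  Fstat <- (mss / (k - 1L)) / (rss / (n - k))
  p <- stats::pf(Fstat, k - 1L, n - k, lower.tail = FALSE)
  eps <- 1e-12 * n
  deg0 <- rss <= eps & mss <= eps
  degI <- rss <= eps & mss > eps
  Fstat[deg0] <- 0;   p[deg0] <- 1
  Fstat[degI] <- Inf; p[degI] <- 0
  data.frame(unit_id = rates$unit_ids, F = unname(Fstat), p = unname(p),
             stringsAsFactors = FALSE)
}

#' Population tuning summary
#'
#' Per-condition fraction of responsive units with percentile bootstrap 95%
#' confidence intervals (resampling units with replacement), counts of
#' responsive and tuned units, and a chi-squared goodness-of-fit test
#' (df = 1) of the observed number of responsive units against the
#' `alpha * N` expected by chance over the \{responsive, not responsive\}
#' cells.
#'
#' @param results A `tuning_result`.
#' @param alpha Nominal per-test level used for the chance expectation.
#' @param n_boot Bootstrap resamples.
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return List of class `population_summary` with `fraction_responsive`
#'   (data frame: condition, fraction, lo, hi), `n_responsive`, `n_tuned`,
#'   `chi2`, `chi2_p`.
#' @export
population_summary <- function(results, alpha = 0.05, n_boot = 1000L, seed = 1L,
                               conf = 0.95) {
  stopifnot(inherits(results, "tuning_result"))
  R <- results$responsive
  N <- nrow(R)
  if (N < 2L) stop("need at least 2 units")
  frac <- colMeans(R)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  idx <- matrix(sample.int(N, N * n_boot, replace = TRUE), N)
  boots <- apply(R, 2L, function(col)
    colMeans(matrix(col[idx], N)))
  qs <- apply(boots, 2L, stats::quantile,
              probs = c((1 - conf) / 2, 1 - (1 - conf) / 2))
  fr <- data.frame(condition = colnames(R), fraction = unname(frac),
                   lo = unname(pmin(qs[1L, ], frac)),
                   hi = unname(pmax(qs[2L, ], frac)),
                   stringsAsFactors = FALSE)
  n_resp <- sum(rowSums(R) > 0)
  expd <- c(alpha * N, (1 - alpha) * N)
  obs <- c(n_resp, N - n_resp)
  chi2 <- sum((obs - expd)^2 / expd)
  structure(list(fraction_responsive = fr, n_responsive = n_resp,
                 n_tuned = sum(results$tuned), chi2 = chi2,
                 chi2_p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE)),
            class = "population_summary")
}
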