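# Receptive-field characterisation: per-side field counts over lateralized
# sites, single- vs multi-peak classification along collinear sites,
# fixed-centre Gaussian field-size fits (FWHM), and single-unit
# mirror-symmetry R^2 (left-from-left vs left-from-right prediction).

RF_LATERAL_PARTS <- c("back_head", "cheek", "neck", "shoulder")

#' Left/right receptive-field count matrix
#'
#' For each unit, counts the FDR-significant lateralized touch sites (back of
#' head, cheek, neck, shoulder) on the left and on the right side, and
#' tallies units into a 5 x 5 matrix indexed by (number of left fields,
#' number of right fields). Mirror-symmetric populations concentrate on the
#' diagonal.
#'
#' @param tuning A `tuning_result` from a touch-mapping session.
#' @return Object of class `field_count_matrix`: 5 x 5 integer matrix
#'   (rows = left field count 0..4, columns = right field count 0..4).
#' @export
field_count_matrix <- function(tuning) {
  stopifnot(inherits(tuning, "tuning_result"))
  lc <- condition_id(RF_LATERAL_PARTS, "left", "actual")
  rc <- condition_id(RF_LATERAL_PARTS, "right", "actual")
  miss <- setdiff(c(lc, rc), tuning$conditions)
  if (length(miss))
    stop("missing lateralized conditions: ", paste(miss, collapse = ", "))
  nl <- rowSums(tuning$responsive[, lc, drop = FALSE])
  nr <- rowSums(tuning$responsive[, rc, drop = FALSE])
  counts <- table(factor(nl, levels = 0:4), factor(nr, levels = 0:4))
  m <- matrix(as.integer(counts), 5L, 5L,
              dimnames = list(left = 0:4, right = 0:4))
  structure(m, class = c("field_count_matrix", "matrix"))
}

#' Classify macroscale receptive-field peak structure
#'
#' Along four approximately collinear sites (ordered from one end to the
#' other), units with significant differential responses (one-way ANOVA,
#' FDR-corrected across units) are classified by walking outward from the
#' preferred (argmax mean rate; ties broken toward the earlier site) site:
#' each adjacent pair is tested one-tailed for a reversal (rate at the
#' farther site exceeding the nearer site). With
#' `criterion = "significant_reversal"` (default) a unit is multi-peak if
#' any reversal is significant after Benjamini-Hochberg correction over its
#' pair tests; `criterion = "nonsignificant_decrease"` instead calls
#' multi-peak whenever the one-tailed test of the expected decrease
#' (nearer > farther) fails to reach significance.
#'
#' @param rates A `firing_rate_matrix` containing the four sites.
#' @param ordered_sites Character vector of 4 condition identifiers in
#'   spatial order.
#' @param alpha Significance level (default 0.05).
#' @param criterion Multi-peak criterion, see above.
#' @return Data frame with `unit_id`, `preferred` (site index or `NA`),
#'   `class` in `{"single_peak", "multi_peak", "not_selective"}`.
#' @export
classify_peak_structure <- function(rates, ordered_sites, alpha = 0.05,
                                    criterion = c("significant_reversal",
                                                  "nonsignificant_decrease")) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(rates, "firing_rate_matrix"),
            length(ordered_sites) == 4L)
  keep <- rates$labels$condition %in% ordered_sites
  if (!any(keep)) stop("ordered sites not present in rates")
  sub <- rates
  sub$rates <- rates$rates[, keep, drop = FALSE]
  sub$labels <- rates$labels[keep, , drop = FALSE]
  if (any(table(sub$labels$condition) < 2L))
    stop("each site needs at least 2 trials")
  aov <- anova_discrimination(sub)
  selective <- fdr_correct(aov$p, alpha)$reject
  cond <- factor(sub$labels$condition, levels = ordered_sites)
  out <- data.frame(unit_id = rates$unit_ids, preferred = NA_integer_,
                    class = "not_selective", stringsAsFactors = FALSE)
  for (ui in which(selective)) {
    y <- sub$rates[ui, ]
    mns <- tapply(y, cond, mean)
    pref <- which.max(mns)           # which.max takes the earlier site on ties
    out$preferred[ui] <- pref
    # adjacent pairs walking outward from the peak: (nearer, farther)
    pairs <- list()
    if (pref > 2L) for (j in seq(pref - 1L, 2L))
      pairs[[length(pairs) + 1L]] <- c(j, j - 1L)
    if (pref < 3L) for (j in seq(pref + 1L, 3L))
      pairs[[length(pairs) + 1L]] <- c(j, j + 1L)
    pv <- vapply(pairs, function(pr) {
      nearer <- y[cond == ordered_sites[pr[1L]]]
      farther <- y[cond == ordered_sites[pr[2L]]]
      alt <- if (criterion == "significant_reversal") "greater" else "less"
      # one-tailed pooled-variance t-test: reversal means farther > nearer
      tt <- tryCatch(stats::t.test(farther, nearer, alternative = alt,
                                   var.equal = TRUE)$p.value,
                     error = function(e) 1)
      if (is.na(tt)) 1 else tt
    }, 0)
    multi <- if (criterion == "significant_reversal")
      any(fdr_correct(pv, alpha)$reject)
    else length(pv) > 0L && any(!fdr_correct(pv, alpha)$reject)
    out$class[ui] <- if (multi) "multi_peak" else "single_peak"
  }
  out
}

#' Fixed-centre Gaussian receptive-field fit
#'
#' Fits `G(x) = A exp(-((x - mu)/sigma)^2 / 2) + c` to a 9-site mean-rate
#' profile by nonlinear least squares, with the centre `mu` fixed at the
#' preferred (peak) site coordinate. Sites are spaced `site_spacing` cm
#' apart. Field size is reported as the full width at half maximum,
#' `FWHM = 2 sqrt(2 ln 2) sigma`.
#'
#' @param profile Numeric vector of 9 mean rates (Hz), site 1..9.
#' @param preferred Index of the preferred site (default: argmax).
#' @param site_spacing Spacing between adjacent sites in cm (default 2).
#' @return Object of class `gaussian_rf`: `A`, `sigma`, `c`, `mu`, `fwhm`
#'   (cm), `flagged` (`TRUE` when the profile is flat or no positive-width
#'   fit was found, in which case `sigma`/`fwhm` are `NA`).
#' @export
fit_rf_gaussian <- function(profile, preferred = which.max(profile),
                            site_spacing = 2) {
  stopifnot(length(profile) == 9L)
  x <- (seq_len(9L) - 1L) * site_spacing
  mu <- x[preferred]
  if (diff(range(profile)) < 1e-9 * (1 + max(abs(profile))))
    return(structure(list(A = 0, sigma = NA_real_, c = mean(profile),
                          mu = mu, fwhm = NA_real_, flagged = TRUE),
                     class = "gaussian_rf"))
  df <- data.frame(x = x, y = profile)
  starts <- c(2, 1, 4, 8) * site_spacing / 2
  fit <- NULL
  for (s0 in starts) {
    f <- tryCatch(
      minpack.lm::nlsLM(y ~ A * exp(-0.5 * ((x - mu) / sigma)^2) + c0,
                        data = df,
                        start = list(A = max(profile) - min(profile),
                                     sigma = s0, c0 = min(profile)),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(f) && abs(stats::coef(f)[["sigma"]]) > 1e-8) { fit <- f; break }
  }
  if (is.null(fit))
    return(structure(list(A = NA_real_, sigma = NA_real_, c = NA_real_,
                          mu = mu, fwhm = NA_real_, flagged = TRUE),
                     class = "gaussian_rf"))
  co <- stats::coef(fit)
  sigma <- abs(co[["sigma"]])  # sign-symmetric in the model
  structure(list(A = co[["A"]], sigma = sigma, c = co[["c0"]], mu = mu,
                 fwhm = 2 * sqrt(2 * log(2)) * sigma, flagged = FALSE),
            class = "gaussian_rf")
}

#' Single-unit mirror-symmetry R-squared
#'
#' For each unit, quantifies how well the pattern of responses across the
#' four lateralized body sites on the left is predicted (a) from the left
#' side itself and (b) from the right side, both with leave-one-out
#' cross-validation so the two measures use the same amount of training
#' data. For each left-out left trial, `r2_within` trains condition means on
#' the remaining left trials; `r2_across` trains on the right-side trials
#' with one (seeded) random trial of the matching condition removed.
#' `R^2 = 1 - SS_res / SS_tot` over held-out predictions; values can be
#' negative.
#'
#' @param rates_left,rates_right `firing_rate_matrix` objects over the same
#'   units covering the lateralized sites of each body side; >= 3 trials
#'   per condition.
#' @param seed Integer seed for the training-size-matching trial drop.
#' @return Data frame with `unit_id`, `r2_within`, `r2_across`.
#' @export
mirror_symmetry_r2 <- function(rates_left, rates_right, seed = 1L) {
  stopifnot(identical(rates_left$unit_ids, rates_right$unit_ids))
  partL <- rates_left$labels$body_part
  partR <- rates_right$labels$body_part
  parts <- sort(unique(partL))
  if (!setequal(parts, unique(partR)))
    stop("left and right sides cover different body parts")
  if (any(table(partL) < 3L) || any(table(partR) < 3L))
    stop("need at least 3 trials per condition on each side")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  YL <- rates_left$rates; YR <- rates_right$rates
  nL <- ncol(YL)
  drop_choice <- vapply(seq_len(nL), function(i) {
    cand <- which(partR == partL[i])
    cand[sample.int(length(cand), 1L)]
  }, 0L)
  out <- data.frame(unit_id = rates_left$unit_ids, r2_within = NA_real_,
                    r2_across = NA_real_, stringsAsFactors = FALSE)
  for (ui in seq_along(rates_left$unit_ids)) {
    yl <- YL[ui, ]; yr <- YR[ui, ]
    pw <- pa <- numeric(nL)
    for (i in seq_len(nL)) {
      p <- partL[i]
      idxw <- which(partL == p); idxw <- setdiff(idxw, i)
      pw[i] <- mean(yl[idxw])
      idxa <- setdiff(which(partR == p), drop_choice[i])
      pa[i] <- mean(yr[idxa])
    }
    sst <- sum((yl - mean(yl))^2)
    out$r2_within[ui] <- 1 - sum((yl - pw)^2) / sst
    out$r2_across[ui] <- 1 - sum((yl - pa)^2) / sst
  }
  out
}
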