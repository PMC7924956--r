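lateral_conds <- function(side)
  condition_id(c("back_head", "cheek", "neck", "shoulder"), side, "actual")

test_that("field count matrix tallies hand-flagged units exactly", {
  conds <- c(lateral_conds("left"), lateral_conds("right"))
  resp <- matrix(FALSE, 3, 8, dimnames = list(NULL, conds))
  resp[1, ] <- FALSE                           # (0, 0)
  resp[2, c(1, 2, 5, 6, 7)] <- TRUE            # 2 left, 3 right
  resp[3, 5:8] <- TRUE                         # 0 left, 4 right
  fc <- field_count_matrix(toy_tuning(resp))
  expect_equal(sum(fc), 3)
  expect_equal(fc["0", "0"], 1L, ignore_attr = TRUE)
  expect_equal(fc["2", "3"], 1L, ignore_attr = TRUE)
  expect_equal(fc["0", "4"], 1L, ignore_attr = TRUE)
  # missing lateralized conditions are an error
  expect_error(field_count_matrix(toy_tuning(resp[, 1:4, drop = FALSE])),
               "missing lateralized")
})

test_that("mirror-symmetric generators concentrate field counts on the diagonal", {
  pop <- make_population(population_spec(n_units = 80, mirror_sigma = 0,
                                         seed = 81))
  s <- simulate_session(pop, make_task_spec("touch_map"), seed = 82)
  sel <- select_units(s)
  stim <- window_rates(sel, "go_onset", 0.5, 2.5)
  base <- window_rates(sel, "cue_onset", -1.5, 0)
  fc <- field_count_matrix(fit_linear_tuning(stim, base))
  off_mass <- 1 - sum(diag(unclass(fc))) / sum(fc)
  expect_lt(off_mass, 0.2)
})

test_that("peak-structure classification separates clean profiles", {
  sites <- condition_id(c("forehead", "cheek", "neck", "shoulder"), "right",
                        "actual")
  mk <- function(means, sd = 0.2, ntr = 10, n_units = 1, seed = 1) {
    set.seed(seed)
    Y <- do.call(cbind, lapply(means, function(m)
      matrix(rnorm(n_units * ntr, m, sd), n_units)))
    make_rates(Y, rep(sites, each = ntr))
  }
  mono <- classify_peak_structure(mk(c(10, 7, 4, 1)), sites)
  expect_equal(mono$class, "single_peak")
  expect_equal(mono$preferred, 1L)
  w <- classify_peak_structure(mk(c(10, 1, 1, 9)), sites)
  expect_equal(w$class, "multi_peak")
  flat <- classify_peak_structure(mk(c(5, 5, 5, 5), sd = 1), sites)
  expect_equal(flat$class, "not_selective")
})

test_that("borderline classification equals the manual t-and-BH oracle", {
  sites <- condition_id(c("forehead", "cheek", "neck", "shoulder"), "right",
                        "actual")
  set.seed(83)
  for (rep in 1:10) {
    means <- sample(c(2, 4, 6, 8))
    Y <- matrix(rnorm(40, rep(means, each = 10), 2), nrow = 1)
    rates <- make_rates(Y, rep(sites, each = 10))
    got <- classify_peak_structure(rates, sites, alpha = 0.05)
    # oracle: same selection + walk computed from first principles
    y <- drop(Y); g <- rep(1:4, each = 10)
    pa <- stats::oneway.test(y ~ factor(g), var.equal = TRUE)$p.value
    if (!fdr_correct(pa, 0.05)$reject) {
      expect_equal(got$class, "not_selective")
      next
    }
    mns <- tapply(y, g, mean)
    pref <- which.max(mns)
    pairs <- list()
    if (pref > 2) for (j in seq(pref - 1, 2)) pairs <- c(pairs, list(c(j, j - 1)))
    if (pref < 3) for (j in seq(pref + 1, 3)) pairs <- c(pairs, list(c(j, j + 1)))
    pv <- vapply(pairs, function(pr)
      stats::t.test(y[g == pr[2]], y[g == pr[1]], alternative = "greater",
                    var.equal = TRUE)$p.value, 0)
    want <- if (any(fdr_correct(pv, 0.05)$reject)) "multi_peak"
            else "single_peak"
    expect_equal(got$class, want)
  }
})

test_that("monotone noiseless profiles are never multi-peak", {
  sites <- condition_id(c("forehead", "cheek", "neck", "shoulder"), "right",
                        "actual")
  set.seed(84)
  for (rep in 1:20) {
    means <- sort(runif(4, 1, 10))
    if (runif(1) < 0.5) means <- rev(means)
    Y <- matrix(rep(means, each = 5), nrow = 1) +
      matrix(rnorm(20, 0, 1e-6), nrow = 1)
    got <- classify_peak_structure(make_rates(Y, rep(sites, each = 5)), sites)
    expect_true(got$class %in% c("single_peak", "not_selective"))
  }
})

test_that("Gaussian field fits recover sigma and satisfy the FWHM identity", {
  x <- (0:8) * 2
  prof <- 8 * exp(-0.5 * ((x - 8) / 2)^2) + 1
  fit <- fit_rf_gaussian(prof)
  expect_false(fit$flagged)
  expect_equal(fit$sigma, 2, tolerance = 1e-6)
  expect_equal(fit$fwhm, 2 * sqrt(2 * log(2)) * 2, tolerance = 1e-6)
  expect_equal(fit$fwhm / fit$sigma, 2 * sqrt(2 * log(2)), tolerance = 1e-12)
  flat <- fit_rf_gaussian(rep(3, 9))
  expect_true(flat$flagged)
})

test_that("noisy Gaussian fits match a fine grid-search oracle in the median", {
  set.seed(85)
  x <- (0:8) * 2
  errs <- replicate(20, {
    prof <- 10 * exp(-0.5 * ((x - 8) / 3)^2) + 2 + rnorm(9, 0, 0.5)
    fit <- fit_rf_gaussian(prof, preferred = 5)
    # oracle: profile over sigma grid, A and c solved by linear LS
    sse_at <- function(sg) {
      basis <- exp(-0.5 * ((x - 8) / sg)^2)
      sum(stats::lm.fit(cbind(1, basis), prof)$residuals^2)
    }
    sgrid <- seq(0.5, 10, by = 0.01)
    s_star <- sgrid[which.min(vapply(sgrid, sse_at, 0))]
    expect_equal(fit$sigma, s_star, tolerance = 0.02)
    fit$sigma - 3
  })
  expect_lt(abs(median(errs)), 0.5)
})

test_that("mirror R2 is exact for mirrored noiseless tuning", {
  parts <- c("back_head", "cheek", "neck", "shoulder")
  pat <- c(2, 8, 5, 3)
  Y <- matrix(rep(rep(pat, each = 3), each = 1), nrow = 1)
  lab_l <- rep(condition_id(parts, "left", "actual"), each = 3)
  lab_r <- rep(condition_id(parts, "right", "actual"), each = 3)
  rl <- make_rates(Y, lab_l)
  rr <- make_rates(Y, lab_r)
  res <- mirror_symmetry_r2(rl, rr, seed = 1)
  expect_equal(res$r2_within, 1)
  expect_equal(res$r2_across, 1)
})

test_that("mirror R2 equals a brute-force LOO loop on a deterministic toy", {
  parts <- c("back_head", "cheek", "neck", "shoulder")
  lab_l <- rep(condition_id(parts, "left", "actual"), each = 3)
  lab_r <- rep(condition_id(parts, "right", "actual"), each = 3)
  set.seed(86)
  yl <- rnorm(12, rep(c(2, 8, 5, 3), each = 3), 1)
  # right-side trials identical within condition so the seeded trial drop
  # cannot change the training means
  yr <- rep(c(3, 7, 6, 2), each = 3)
  res <- mirror_symmetry_r2(make_rates(matrix(yl, 1), lab_l),
                            make_rates(matrix(yr, 1), lab_r), seed = 2)
  gl <- rep(1:4, each = 3)
  predw <- preda <- numeric(12)
  for (i in 1:12) {
    idx <- setdiff(which(gl == gl[i]), i)
    predw[i] <- mean(yl[idx])
    preda[i] <- c(3, 7, 6, 2)[gl[i]]
  }
  sst <- sum((yl - mean(yl))^2)
  expect_equal(res$r2_within, 1 - sum((yl - predw)^2) / sst)
  expect_equal(res$r2_across, 1 - sum((yl - preda)^2) / sst)
})

test_that("independent right-side tuning drives cross-side R2 to zero or below", {
  set.seed(87)
  parts <- c("back_head", "cheek", "neck", "shoulder")
  lab_l <- rep(condition_id(parts, "left", "actual"), each = 6)
  lab_r <- rep(condition_id(parts, "right", "actual"), each = 6)
  n <- 30
  YL <- YR <- matrix(0, n, 24)
  for (u in 1:n) {
    gl <- rnorm(4, 0, 5); gr <- rnorm(4, 0, 5)   # unrelated patterns
    YL[u, ] <- rnorm(24, rep(10 + gl, each = 6), 1)
    YR[u, ] <- rnorm(24, rep(10 + gr, each = 6), 1)
  }
  res <- mirror_symmetry_r2(make_rates(YL, lab_l), make_rates(YR, lab_r),
                            seed = 3)
  expect_gt(mean(res$r2_within), 0.5)
  expect_lte(mean(res$r2_across), 0)
})
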