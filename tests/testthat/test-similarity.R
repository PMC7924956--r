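test_that("noiseless patterns give exact within and cross correlations", {
  set.seed(61)
  N <- 6
  pat <- list(a = rnorm(N), b = rnorm(N), c = rnorm(N))
  conds <- c("actual.cheek.right", "actual.neck.right", "actual.vertex.midline")
  Y <- cbind(pat$a, pat$a, pat$a, pat$b, pat$b, pat$b, pat$c, pat$c, pat$c)
  rates <- make_rates(Y, rep(conds, each = 3))
  cc <- cv_condition_correlation(rates, n_splits = 5, seed = 2)
  expect_equal(unname(diag(cc$mean_corr)), rep(1, 3), tolerance = 1e-12)
  expect_equal(cc$mean_corr[1, 2], cor(pat$a, pat$b), tolerance = 1e-12)
  expect_equal(cc$mean_corr[1, 3], cor(pat$a, pat$c), tolerance = 1e-12)
  # symmetric by construction
  expect_equal(cc$mean_corr, t(cc$mean_corr))
})

test_that("cosine and euclidean metrics behave on noiseless patterns", {
  N <- 5
  set.seed(62)
  p1 <- abs(rnorm(N)); p2 <- abs(rnorm(N))
  Y <- cbind(p1, p1, p2, p2)
  rates <- make_rates(Y, rep(c("actual.cheek.right", "actual.neck.right"),
                             each = 2))
  cs <- cv_condition_correlation(rates, n_splits = 2, metric = "cosine",
                                 seed = 1)
  expect_equal(unname(diag(cs$mean_corr)), c(1, 1), tolerance = 1e-12)
  expect_equal(cs$mean_corr[1, 2],
               sum(p1 * p2) / sqrt(sum(p1^2) * sum(p2^2)), tolerance = 1e-12)
  eu <- cv_condition_correlation(rates, n_splits = 2, metric = "euclidean",
                                 seed = 1)
  expect_equal(unname(diag(eu$mean_corr)), c(0, 0), tolerance = 1e-10)
  expect_equal(eu$mean_corr[1, 2], sqrt(sum((p1 - p2)^2)), tolerance = 1e-10)
})

test_that("untuned conditions correlate around zero after baseline correction", {
  set.seed(63)
  N <- 40; ntr <- 10
  b <- rgamma(N, 2, 0.4)                      # heterogeneous baselines
  conds <- rep(c("actual.cheek.right", "null.null.none"), each = ntr)
  pat <- rnorm(N, 0, 4)
  Y <- sapply(seq_len(2 * ntr), function(i)
    rnorm(N, b + if (i <= ntr) pat else 0, 1))
  B <- sapply(seq_len(2 * ntr), function(i) rnorm(N, b, 1))
  rates <- make_rates(Y, conds)
  base <- make_rates(B, conds)
  cc <- cv_condition_correlation(rates, n_splits = 100, seed = 3,
                                 baseline = base)
  nullself <- cc$split_samples["null.null.none", "null.null.none", ]
  se <- sd(nullself) / sqrt(length(nullself))
  # mean split-sample correlation of the null with itself is near zero
  expect_lt(abs(mean(nullself)), max(3 * se, 0.1))
  crossnull <- cc$split_samples["actual.cheek.right", "null.null.none", ]
  expect_lt(abs(mean(crossnull)), max(3 * sd(crossnull) /
                                        sqrt(length(crossnull)), 0.1))
  # tuned condition keeps a high ceiling
  expect_gt(cc$mean_corr["actual.cheek.right", "actual.cheek.right"], 0.8)
  # without baseline correction, shared offsets dominate the null ceiling
  cc0 <- cv_condition_correlation(rates, n_splits = 100, seed = 3)
  expect_gt(cc0$mean_corr["null.null.none", "null.null.none"], 0.5)
})

test_that("unit permutation leaves the correlation matrix unchanged", {
  set.seed(64)
  Y <- matrix(rnorm(8 * 12, 5), nrow = 8)
  conds <- rep(c("actual.cheek.right", "actual.neck.right"), each = 6)
  cc1 <- cv_condition_correlation(make_rates(Y, conds), n_splits = 20,
                                  seed = 9)
  perm <- sample(8)
  cc2 <- cv_condition_correlation(make_rates(Y[perm, ], conds), n_splits = 20,
                                  seed = 9)
  expect_equal(cc1$mean_corr, cc2$mean_corr, tolerance = 1e-12)
})

test_that("pearson entries are invariant to a global additive offset", {
  set.seed(65)
  Y <- matrix(rnorm(5 * 8, 10), nrow = 5)
  conds <- rep(c("actual.cheek.right", "actual.neck.right"), each = 4)
  cc1 <- cv_condition_correlation(make_rates(Y, conds), n_splits = 10,
                                  seed = 4)
  cc2 <- cv_condition_correlation(make_rates(Y + 100, conds), n_splits = 10,
                                  seed = 4)
  expect_equal(cc1$mean_corr, cc2$mean_corr, tolerance = 1e-9)
})

test_that("within-condition ceiling rises toward 1 with trial count", {
  set.seed(66)
  N <- 20; pat <- rnorm(N, 0, 2)
  ceiling_at <- function(ntr) {
    Y <- sapply(seq_len(ntr), function(i) pat + rnorm(N, 0, 2))
    rates <- make_rates(Y, rep("actual.cheek.right", ntr))
    # need 2 conditions for the container; add an independent one
    Y2 <- sapply(seq_len(ntr), function(i) rnorm(N, 0, 2))
    all <- make_rates(cbind(Y, Y2),
                      rep(c("actual.cheek.right", "actual.neck.right"),
                          each = ntr))
    cc <- cv_condition_correlation(all, n_splits = 40, seed = 5)
    cc$mean_corr["actual.cheek.right", "actual.cheek.right"]
  }
  ladder <- c(ceiling_at(4), ceiling_at(16), ceiling_at(64))
  expect_true(all(diff(ladder) > 0))
  expect_true(all(ladder < 1))
  expect_gt(ladder[3], 0.9)
})

test_that("permutation contrast behaves at the null and at full separation", {
  a <- c(0.5, 0.6, 0.7, 0.8)
  expect_gte(correlation_contrast_test(a, a, 2000, seed = 1), 0.9)
  p <- correlation_contrast_test(c(1, 1, 1, 1), c(0, 0, 0, 0), 2000,
                                 seed = 2)
  # exhaustive null: 2 of the 70 partitions of 8 items reach |diff| = 1
  expect_lt(p, 0.06)
  expect_gt(p, 1 / 2001)
  expect_warning(correlation_contrast_test(a, a, 50, seed = 1), "shuffles")
})

test_that("permutation p-values are calibrated under the null", {
  set.seed(67)
  ps <- replicate(200, {
    a <- rnorm(15); b <- rnorm(15)
    correlation_contrast_test(a, b, 200, seed = sample.int(1e6, 1))
  })
  # break the 1/201 granularity ties before the KS comparison
  ps_j <- ps + runif(length(ps), -1 / 402, 1 / 402)
  expect_gt(stats::ks.test(ps_j, "punif")$p.value, 0.01)
})

test_that("mirror contrast flags identical and separated pairs correctly", {
  k <- c("actual.cheek.left", "actual.cheek.right")
  N <- 12
  set.seed(68)
  pat <- rnorm(N, 0, 3)
  # identical coding on the two sides, noiseless: observed and null
  # statistics are all zero, p is the maximum
  Y_same <- cbind(matrix(pat, N, 6), matrix(pat, N, 6))
  rates_same <- make_rates(Y_same, rep(k, each = 6))
  res <- mirror_symmetry_contrast(rates_same, cbind(k[1], k[2]),
                                  n_shuffles = 200, seed = 1)
  expect_gte(res$p, 0.9)
  expect_true(res$at_ceiling)
  # unrelated side patterns with low noise: clearly below ceiling
  patR <- rnorm(N, 0, 3)
  Y_apart <- cbind(matrix(pat, N, 6) + rnorm(N * 6, 0, 0.3),
                   matrix(patR, N, 6) + rnorm(N * 6, 0, 0.3))
  res2 <- mirror_symmetry_contrast(make_rates(Y_apart, rep(k, each = 6)),
                                   cbind(k[1], k[2]), n_shuffles = 200,
                                   seed = 1)
  expect_lt(res2$p, 0.05)
  expect_false(res2$at_ceiling)
  expect_gt(res2$ceiling_corr, res2$lr_corr)
  expect_error(mirror_symmetry_contrast(rates_same, cbind("a", "b")),
               "absent")
})

test_that("mirror contrast p-values are calibrated under exchangeable sides", {
  k <- c("actual.neck.left", "actual.neck.right")
  set.seed(69)
  N <- 15
  ps <- replicate(40, {
    pat <- rnorm(N, 0, 2)
    Y <- matrix(pat, N, 12) + rnorm(N * 12, 0, 1)
    res <- mirror_symmetry_contrast(make_rates(Y, rep(k, each = 6)),
                                    cbind(k[1], k[2]), n_splits = 20,
                                    n_shuffles = 60,
                                    seed = sample.int(1e6, 1))
    res$p
  })
  # under the symmetric null about 5% of pairs should be called asymmetric
  expect_lte(mean(ps <= 0.05), 0.2)
  expect_gt(mean(ps > 0.3), 0.4)
})
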