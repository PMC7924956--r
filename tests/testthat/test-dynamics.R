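# small imagery-like tensor helper: N units, 3 conditions x ntr trials,
# Gaussian "rates" injected directly into the bins
dyn_tensor <- function(N = 8, ntr = 6, nb = 20, bin_size = 0.1,
                       t_start = -0.5, pattern_fun, seed = 1) {
  set.seed(seed)
  conds <- rep(sprintf("imagery.%s.right", c("cheek", "shoulder", "hand")),
               each = ntr)
  counts <- array(0, c(N, 3 * ntr, nb))
  tcent <- t_start + (seq_len(nb) - 0.5) * bin_size
  for (tr in seq_len(3 * ntr)) {
    cls <- (tr - 1) %/% ntr + 1
    counts[, tr, ] <- pattern_fun(cls, tcent) +
      matrix(rnorm(N * nb, 0, 0.3), N, nb)
  }
  make_tensor(counts, conds, t_start, bin_size, format = "imagery")
}

test_that("diagonal of the generalization matrix equals plain LOO accuracy", {
  set.seed(91)
  pat <- matrix(rnorm(8 * 3, 0, 2), 8, 3)
  b <- dyn_tensor(pattern_fun = function(cls, tc)
    matrix(rep(pat[, cls], length(tc)), 8), seed = 91)
  dm <- dynamic_classification(b, window = 0.5, step = 0.5)
  w1 <- b$bin_centers >= dm$window_onsets[1] &
    b$bin_centers < dm$window_onsets[1] + 0.5
  feats <- rowSums(b$counts[, , w1, drop = FALSE], dims = 2) /
    (sum(w1) * b$bin_size)
  rates <- make_rates(feats, b$labels$condition)
  cm <- loo_confusion(rates)
  expect_equal(dm$accuracy[1, 1], cm$overall_accuracy, tolerance = 1e-12)
  expect_true(all(dm$accuracy >= 0 & dm$accuracy <= 1))
  expect_equal(nrow(dm$accuracy), length(dm$window_onsets))
})

test_that("time-constant coding yields a uniform generalization matrix", {
  set.seed(92)
  pat <- matrix(rnorm(10 * 3, 0, 3), 10, 3)
  b <- dyn_tensor(N = 10, ntr = 8, pattern_fun = function(cls, tc)
    matrix(rep(pat[, cls], length(tc)), 10), seed = 92)
  dm <- dynamic_classification(b, window = 0.5, step = 0.2)
  # strong constant patterns: every entry near the diagonal level
  expect_gt(min(dm$accuracy), 0.9)
})

test_that("orthogonal epoch coding confines accuracy to within-epoch blocks", {
  set.seed(93)
  N <- 20
  pat1 <- matrix(rnorm(N * 3, 0, 3), N, 3)   # early-epoch patterns
  pat2 <- matrix(rnorm(N * 3, 0, 3), N, 3)   # late-epoch patterns
  b <- dyn_tensor(N = N, ntr = 8, nb = 20, pattern_fun = function(cls, tc) {
    early <- tc < 0.5
    outer(pat1[, cls], as.numeric(early)) +
      outer(pat2[, cls], as.numeric(!early))
  }, seed = 93)
  dm <- dynamic_classification(b, window = 0.5, step = 0.5)
  on <- dm$window_onsets
  early_w <- which(on + 0.5 <= 0.5)
  late_w <- which(on >= 0.5)
  within <- c(dm$accuracy[early_w, early_w], dm$accuracy[late_w, late_w])
  across <- c(dm$accuracy[early_w, late_w], dm$accuracy[late_w, early_w])
  expect_gt(mean(within), 0.8)
  expect_lt(abs(mean(across) - 1 / 3), 0.15)
})

test_that("label-free features decode at chance across all window pairs", {
  # features carry no class information at all, so every entry of the
  # generalization matrix is a draw near 1/3 (leave-one-out keeps a small
  # pessimistic bias, hence the band is checked on the matrix mean)
  set.seed(94)
  b <- dyn_tensor(ntr = 8, pattern_fun = function(cls, tc)
    matrix(0, 8, length(tc)), seed = 94)
  dm <- dynamic_classification(b, window = 0.5, step = 0.5)
  n <- 24
  band <- qbinom(c(0.005, 0.995), n, 1 / 3) / n
  expect_gte(mean(dm$accuracy), band[1])
  expect_lte(mean(dm$accuracy), band[2])
  expect_true(all(dm$accuracy <= band[2]))
})

test_that("single-unit scope runs the identical procedure per unit", {
  set.seed(95)
  pat <- matrix(rnorm(4 * 3, 0, 3), 4, 3)
  b <- dyn_tensor(N = 4, ntr = 4, nb = 10, pattern_fun = function(cls, tc)
    matrix(rep(pat[, cls], length(tc)), 4), seed = 95)
  per_unit <- dynamic_classification(b, window = 0.5, step = 0.5,
                                     scope = "single_unit")
  expect_length(per_unit, 4)
  # a tensor reduced to one unit reproduces that unit's matrix
  b1 <- b; b1$counts <- b$counts[1, , , drop = FALSE]; b1$unit_ids <- b$unit_ids[1]
  dm1 <- dynamic_classification(b1, window = 0.5, step = 0.5,
                                scope = "single_unit")
  expect_equal(per_unit[[1]]$accuracy, dm1[[1]]$accuracy)
})

test_that("crossnobis is exact for deterministic shifted data", {
  # constant reference, one shifted window, zero variance -> floored
  N <- 3; ntr <- 12; nb <- 6; bs <- 0.25
  delta <- c(0.5, -1, 2) * 1e-3
  counts <- array(0, c(N, ntr, nb))
  base_lvl <- c(1, 2, 3)
  for (tr in seq_len(ntr)) {
    counts[, tr, ] <- matrix(rep(base_lvl * bs, nb), N)
    counts[, tr, 5:6] <- (base_lvl + delta) * bs
  }
  b <- make_tensor(counts, rep(sprintf("imagery.%s.right",
                                       c("cheek", "shoulder", "hand")),
                               each = 4), t_start = 0, bin_size = bs,
                   format = "imagery")
  cs <- crossnobis_timecourse(b, reference_window = c(0.25, 0.75),
                              window = 0.5, step = 0.5, n_splits = 3,
                              seed = 1)
  # window 3 covers bins 5:6 (onset 1.0); variances floored at 1e-6
  expect_equal(unname(cs$mean[3]), sum(delta^2) / 1e-6, tolerance = 1e-6)
  expect_equal(unname(cs$mean[1]), 0, tolerance = 1e-9)
})

test_that("crossnobis is unbiased at the null and under a known shift", {
  set.seed(96)
  N <- 4; ntr_pc <- 8
  one_rep <- function(shift) {
    counts <- array(0, c(N, 3 * ntr_pc, 6))
    for (tr in seq_len(3 * ntr_pc)) {
      x_ref <- rnorm(N)                    # reference feature, sd 1
      x_win <- rnorm(N) + shift            # test window feature
      counts[tr %% N + 1, tr, ] <- 0       # keep array shape
      counts[, tr, 2:3] <- x_ref * 0.25    # reference window bins
      counts[, tr, 5:6] <- x_win * 0.25    # test window bins
      counts[, tr, 1] <- rnorm(N) * 0.25
      counts[, tr, 4] <- rnorm(N) * 0.25
    }
    b <- make_tensor(counts, rep(sprintf("imagery.%s.right",
                                         c("cheek", "shoulder", "hand")),
                                 each = ntr_pc), 0, 0.25, format = "imagery")
    cs <- crossnobis_timecourse(b, reference_window = c(0.25, 0.75),
                                window = 0.5, step = 0.5, n_splits = 4,
                                seed = sample.int(1e6, 1))
    cs$mean[3]
  }
  nulls <- replicate(60, one_rep(0))
  se <- sd(nulls) / sqrt(length(nulls))
  expect_lt(abs(mean(nulls)), 3 * se)
  shifted <- replicate(60, one_rep(1))
  se2 <- sd(shifted) / sqrt(length(shifted))
  expect_lt(abs(mean(shifted) - N), 3 * se2)
})

test_that("unit-matrix PCA matches prcomp and its identities", {
  set.seed(97)
  mats <- lapply(1:6, function(i)
    structure(list(accuracy = matrix(runif(25), 5, 5)),
              class = "dyn_class_matrix"))
  pca <- unit_dynamic_pca(mats, n_components = 3)
  expect_equal(sum(pca$var_explained), 1, tolerance = 1e-9)
  X <- t(sapply(mats, function(m) as.vector(m$accuracy)))
  pr <- prcomp(X, center = TRUE, scale. = FALSE)
  ve <- pr$sdev^2 / sum(pr$sdev^2)
  expect_equal(pca$var_explained[1:3], ve[1:3], tolerance = 1e-9)
  agree <- min(sum((as.vector(pca$components[, , 1]) - pr$rotation[, 1])^2),
               sum((as.vector(pca$components[, , 1]) + pr$rotation[, 1])^2))
  expect_lt(agree, 1e-18)
})

test_that("a two-archetype mixture loads entirely on PC1", {
  a1 <- matrix(1:25 / 25, 5, 5); a2 <- matrix(25:1 / 25, 5, 5)
  mats <- lapply(rep(list(a1, a2), 3), function(m)
    structure(list(accuracy = m), class = "dyn_class_matrix"))
  pca <- unit_dynamic_pca(mats)
  expect_equal(pca$var_explained[1], 1, tolerance = 1e-12)
  # identical units are degenerate
  same <- lapply(1:4, function(i)
    structure(list(accuracy = a1), class = "dyn_class_matrix"))
  expect_true(unit_dynamic_pca(same)$degenerate)
})

test_that("cross-format correlation is exact for identical noiseless patterns", {
  N <- 4; ntr <- 4; nb <- 10; bs <- 0.5
  d <- c(1, -2, 0.5, 3)          # site-preference pattern, both formats
  mk <- function(fmt) {
    conds <- rep(sprintf("%s.%s.right", fmt, c("cheek", "shoulder")),
                 each = ntr)
    counts <- array(0, c(N, 2 * ntr, nb))
    for (tr in seq_len(2 * ntr)) {
      site1 <- tr <= ntr
      counts[, tr, ] <- matrix(rep((5 + if (site1) d / 2 else -d / 2) * bs,
                                   nb), N)
    }
    make_tensor(counts, conds, 0, bs, format = fmt)
  }
  fc <- dynamic_format_correlation(mk("actual"), mk("imagery"),
                                   window = 1, step = 1, n_splits = 2,
                                   seed = 1)
  expect_true(all(abs(fc$corr$actual_actual - 1) < 1e-9))
  expect_true(all(abs(fc$corr$actual_imagery - 1) < 1e-9))
  expect_true(all(abs(fc$corr$imagery_imagery - 1) < 1e-9))
})

test_that("cross-format correlation matches hand arithmetic on a 2-unit toy", {
  N <- 2; ntr <- 4; nb <- 4; bs <- 0.5
  da <- c(2, -1); di <- c(1, 3)  # distinct site-preference patterns
  mk <- function(fmt, d) {
    conds <- rep(sprintf("%s.%s.right", fmt, c("cheek", "shoulder")),
                 each = ntr)
    counts <- array(0, c(N, 2 * ntr, nb))
    for (tr in seq_len(2 * ntr)) {
      site1 <- tr <= ntr
      counts[, tr, ] <- matrix(rep((10 + if (site1) d / 2 else -d / 2) * bs,
                                   nb), N)
    }
    make_tensor(counts, conds, 0, bs, format = fmt)
  }
  fc <- dynamic_format_correlation(mk("actual", da), mk("imagery", di),
                                   window = 2, step = 2, n_splits = 1,
                                   seed = 1)
  va <- c(da / 2, -da / 2)
  vi <- c(di / 2, -di / 2)
  expect_equal(fc$corr$actual_imagery[1, 1], cor(va, vi), tolerance = 1e-9)
  expect_equal(fc$corr$actual_actual[1, 1], 1, tolerance = 1e-9)
})

test_that("format mismatches are rejected", {
  b <- dyn_tensor(N = 3, ntr = 4, nb = 4, pattern_fun = function(cls, tc)
    matrix(1, 3, length(tc)), seed = 99)
  b2 <- b; b2$unit_ids <- paste0("x", b2$unit_ids)
  expect_error(dynamic_format_correlation(b, b2), "unmatched units")
})
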