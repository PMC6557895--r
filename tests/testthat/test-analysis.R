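test_that("separation statistics follow their closed form", {
  set.seed(40)
  x <- rnorm(300)
  s <- separation_stats(x, x)
  expect_equal(s$t, 0)
  expect_equal(s$gaussian_p12, 0.5)
  # mu_i = 2, mu_sc = 1, sigma = 1 each -> t = 1/sqrt(2)
  a <- rnorm(2000); a <- (a - mean(a)) / sd(a) + 2
  b <- rnorm(2000); b <- (b - mean(b)) / sd(b) + 1
  s2 <- separation_stats(a, b)
  expect_equal(s2$t, 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(s2$n_i, 2000L)
  expect_equal(s2$se_i, s2$sigma_i / sqrt(2000))
  # monotone overlap probability
  expect_true(all(diff(gaussian_p12(seq(-2, 2, 0.1))) > 0))
  expect_error(separation_stats(1, c(1, 2)), "at least 2")
})

test_that("empirical overlap probability matches symmetry, separation and the Gaussian law", {
  set.seed(41)
  x <- rnorm(500)
  expect_equal(empirical_p12(x, x), 0.5)
  expect_equal(empirical_p12(1:10 / 10, 2 + 1:10 / 10), 1.0)
  # ties count one half
  expect_equal(empirical_p12(c(1, 1), c(1, 1)), 0.5)
  # Gaussian sets engineered to separation t = 0.82: p12 ~ pnorm(0.82)
  n <- 20000
  same <- rnorm(n); same <- (same - mean(same)) / sd(same)
  diff <- rnorm(n); diff <- (diff - mean(diff)) / sd(diff) + 0.82 * sqrt(2)
  expect_equal(empirical_p12(same, diff, n_samples = 1e5),
               gaussian_p12(0.82), tolerance = 0.01)
})

test_that("the one-vector-per-subject bootstrap recovers planted correlation structure", {
  set.seed(42)
  S <- 200
  # subjects with y2 == y1 planted: perfect correlation
  base <- default_schema()$reference
  subj_vec <- t(replicate(S, {
    e <- rnorm(11, 0, 0.02)
    e[3] <- e[2]  # d_1 and d_2 move together
    base + e
  }))
  recs <- pops_to_records(lapply(seq_len(S), function(s)
    subj_vec[s, , drop = FALSE]), sprintf("s%03d", 1:S), rep(1, S))
  cr <- bootstrap_correlation(recs, B = 200)
  expect_equal(max(abs(cr$C - t(cr$C))), 0)
  expect_equal(unname(diag(cr$C)), rep(1, 11), tolerance = 1e-9)
  expect_gt(cr$C["d_1", "d_2"], 1 - 3 * max(cr$sd["d_1", "d_2"], 0.01))
  # independent coordinates stay within the sampling-theory bound
  expect_lt(abs(cr$C["d_6", "d_7"]), 3 / sqrt(S))
  expect_true(all(cr$p >= 0 & cr$p <= 1))
})

test_that("PCA of the correlation matrix is ordered, signed and diagonalizing", {
  # diagonal input: coordinate axes, ascending eigenvalues
  Cd <- diag(c(3, 1, 2))
  pd <- pca_decompose(Cd)
  expect_equal(pd$values, c(1, 2, 3))
  expect_equal(abs(pd$E), rbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0)),
               ignore_attr = TRUE)
  # closed-form 2x2
  p2 <- pca_decompose(matrix(c(1, 1, 1, 1), 2, 2))
  expect_equal(p2$values, c(0, 2))
  expect_equal(unname(p2$E[2, ]), c(1, 1) / sqrt(2))
  # deterministic sign convention: largest entry positive
  expect_true(all(apply(pd$E, 1, function(r) r[which.max(abs(r))] > 0)))
  expect_error(pca_decompose(matrix(c(1, 2, 3, 4), 2, 2)), "symmetric")
  # the h = 1 constraint shows up as a null coordinate combination
  set.seed(43)
  F <- random_population(300)
  C <- cov(F)
  pc <- pca_decompose(C)
  expect_lt(pc$values[1], 1e-12)
  null_axis <- pc$E[1, ]
  expect_equal(unname(abs(null_axis)), c(0, rep(0.5, 4), rep(0, 6)),
               tolerance = 1e-6)
  # projections of the fitting data decorrelate with variances lambda
  Yc <- sweep(F, 2, colMeans(F))
  proj <- pca_project(pc, Yc)
  G <- crossprod(proj) / (nrow(F) - 1)
  expect_equal(G, diag(pc$values), ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("group tests are antisymmetric, calibrated and sensitive to planted offsets", {
  set.seed(44)
  base <- default_schema()$reference
  mkgrp <- function(S, offset = rep(0, 11), sd = 0.03) {
    pops <- lapply(seq_len(S), function(s) {
      att <- base + offset + rnorm(11, 0, sd)
      t(replicate(5, att + rnorm(11, 0, 0.01)))
    })
    pops_to_records(pops, sprintf("g%03d", seq_len(S)), rep(1, S))
  }
  A <- mkgrp(12)
  off <- rep(0, 11); off[10] <- 0.06  # d_9 shifted by ~2 group sd
  B <- mkgrp(12, offset = off)
  gt <- group_coordinate_test(A, B)
  gt_rev <- group_coordinate_test(B, A)
  expect_equal(gt$t, -gt_rev$t, tolerance = 1e-9)
  expect_lt(gt$p[gt$coordinate == "d_9"], 0.05)
  expect_equal(sign(gt$t[gt$coordinate == "d_9"]), -1)
  # null coordinates are not flooded with discoveries
  expect_lte(sum(gt$p[gt$coordinate != "d_9"] < 0.01), 1)
  # same-population split behaves as a null
  set.seed(45)
  AB <- mkgrp(24)
  ids <- unique(AB$subject_id)
  ps <- c()
  for (r in 1:10) {
    pick <- sample(ids, 12)
    g <- group_coordinate_test(AB[AB$subject_id %in% pick, ],
                               AB[!AB$subject_id %in% pick, ])
    ps <- c(ps, g$p)
  }
  expect_lt(mean(ps < 0.05), 0.12)
  # per-PC variant runs on the same dataset
  pc <- pca_decompose(cov(standardize(AB)$y))
  gpc <- group_coordinate_test(A, B, per = "pc", pca = pc)
  expect_equal(nrow(gpc), 11L)
})

test_that("cross-experiment offsets recover planted shifts with scaling errors", {
  set.seed(46)
  base <- default_schema()$reference
  mkexp <- function(S, shift = rep(0, 11)) {
    pops <- lapply(seq_len(S), function(s) {
      att <- base + shift + rnorm(11, 0, 0.02)
      t(replicate(5, att + rnorm(11, 0, 0.01)))
    })
    pops_to_records(pops, sprintf("e%03d", seq_len(S)), rep(1, S))
  }
  A <- mkexp(20)
  expect_true(all(abs(cross_experiment_offset(A, A)$offset) < 1e-12))
  shift <- rep(0, 11); shift[3] <- 0.02  # planted +0.02 on d_2
  B <- mkexp(20, shift)
  co <- cross_experiment_offset(A, B)
  expect_lt(abs(co$offset[co$coordinate == "d_2"] - (-0.02)),
            3 * co$se[co$coordinate == "d_2"])
  # standard error halves when both cohort sizes quadruple
  seS <- mean(replicate(5, {
    co1 <- cross_experiment_offset(mkexp(10), mkexp(10))
    co1$se[3]
  }))
  se4S <- mean(replicate(5, {
    co1 <- cross_experiment_offset(mkexp(40), mkexp(40))
    co1$se[3]
  }))
  expect_equal(seS / se4S, 2, tolerance = 0.5)
})
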