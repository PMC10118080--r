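test_that("Pareto scaling centres and divides by the root of the SD", {
  ps <- pareto_scale(cbind(a = c(1, 2, 3)))
  expect_equal(drop(ps$X), c(-1, 0, 1))
  ps2 <- pareto_scale(cbind(a = c(0, 0, 4, 4)))
  expect_equal(drop(ps2$X), c(-2, -2, 2, 2) / sqrt(sd(c(0, 0, 4, 4))))
  expect_equal(colMeans(ps2$X), c(a = 0), tolerance = 1e-12)
  expect_warning(ps3 <- pareto_scale(cbind(a = c(1, 2, 3), b = c(5, 5, 5))),
                 "zero-variance")
  expect_equal(ps3$dropped, "b")
  expect_equal(ncol(ps3$X), 1)
})

test_that("NIPALS PCA matches the singular value decomposition", {
  set.seed(42)
  X <- matrix(rnorm(80), 10, 8)
  p <- fit_pca(X, 3, scale = "center")
  sv <- svd(scale(X, scale = FALSE))
  for (a in 1:3) {
    expect_lt(max(abs(abs(p$scores[, a]) - abs(sv$u[, a] * sv$d[a]))), 1e-6)
    expect_lt(max(abs(abs(p$loadings[, a]) - abs(sv$v[, a]))), 1e-6)
  }
  expect_equal(p$r2x, sv$d[1:3]^2 / sum(sv$d^2), tolerance = 1e-9)
  # orthonormal loadings, orthogonal scores
  expect_equal(crossprod(p$loadings), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  off <- crossprod(p$scores)
  expect_lt(max(abs(off[upper.tri(off)])), 1e-6)
})

test_that("a rank-1 matrix is fully explained by one component", {
  X <- outer(c(1, 2, 3, 4), c(2, -1, 0.5))
  p <- fit_pca(X, 1, scale = "center")
  expect_equal(p$r2x[1], 1.0, tolerance = 1e-10)
})

test_that("PCA separates the species in the synthetic dataset", {
  ds <- simulate_dataset(simulation_design(n_background = 100, seed = 21))
  fm <- align_features(ds$features, ds$samples) %>%
    filter_flags() %>%
    subtract_blanks()
  X <- as_sample_matrix(fm)
  oil <- attr(X, "classes") %in% c("sunflower", "rapeseed", "sesame", "flax")
  suppressWarnings(p <- fit_pca(X[oil, ], 3))
  expect_gt(silhouette_mean(p$scores[, 1:2], attr(X, "classes")[oil]), 0)
})

test_that("OPLS-DA with zero orthogonal components equals NIPALS PLS2", {
  set.seed(1)
  X <- matrix(rnorm(60), 12, 5)
  cls <- rep(c("a", "b", "c"), each = 4)
  m <- fit_oplsda(X, cls, n_predictive = 2, n_orthogonal = 0,
                  scale = "center", n_folds = NA)
  Y <- outer(cls, sort(unique(cls)), `==`) * 1
  oracle_scores <- pls2_oracle(X, Y, 2)
  expect_lt(max(abs(m$scores - oracle_scores)), 1e-6)
})

test_that("perfect class separation gives R2Y and Q2 near one", {
  set.seed(2)
  base <- matrix(rnorm(16 * 6, sd = 0.01), 16, 6)
  base[1:8, 1] <- base[1:8, 1] + 10
  base[9:16, 2] <- base[9:16, 2] + 10
  cls <- rep(c("a", "b"), each = 8)
  m <- fit_oplsda(base, cls, n_predictive = 1, scale = "center")
  expect_gt(m$r2y, 0.999)
  expect_gt(m$q2, 0.99)
})

test_that("model invariants hold across random fits", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- 18
    X <- matrix(rnorm(n * 8), n, 8)
    cls <- rep(c("a", "b", "c"), each = 6)
    # plant separation so the model is meaningful
    X[cls == "a", 1] <- X[cls == "a", 1] + 3
    X[cls == "b", 2] <- X[cls == "b", 2] + 3
    m <- suppressWarnings(
      fit_oplsda(X, cls, n_predictive = 2, n_orthogonal = 2,
                 scale = "center"))
    Y <- outer(cls, m$levels, `==`) * 1
    # orthogonal scores exactly uncorrelated with every class column
    expect_lt(max(abs(cor(m$scores_orth, Y))), 1e-8)
    # Q2 never beats R2Y on the same data
    expect_lte(m$q2, m$r2y + 1e-9)
    expect_true(all(m$r2x >= 0), info = seed)
    # deflation conserves variance: explained + residual = total
    ctr <- scale(X, scale = FALSE)
    E <- ctr
    for (j in seq_len(m$n_orthogonal)) {
      E <- E - tcrossprod(drop(E %*% m$weights_orth[, j]),
                          m$loadings_orth[, j])
    }
    for (a in seq_len(m$n_predictive)) {
      E <- E - tcrossprod(m$scores[, a], m$loadings[, a])
    }
    expect_equal(sum(E^2) / sum(ctr^2) + m$r2x_cum, 1, tolerance = 1e-8)
  }
})

test_that("orthogonal components never decrease cumulative R2X", {
  set.seed(10)
  X <- matrix(rnorm(20 * 10), 20, 10)
  cls <- rep(c("a", "b"), each = 10)
  X[cls == "a", 1] <- X[cls == "a", 1] + 2
  cums <- vapply(0:3, function(no) {
    suppressWarnings(fit_oplsda(X, cls, n_predictive = 1, n_orthogonal = no,
                                scale = "center", n_folds = NA)$r2x_cum)
  }, numeric(1))
  expect_true(all(diff(cums) >= -1e-10))
})

test_that("degenerate requests are rejected", {
  X <- matrix(rnorm(40), 8, 5)
  expect_error(fit_oplsda(X, rep("a", 8)), "two classes")
  expect_error(fit_oplsda(X, rep(c("a", "b"), 4), n_predictive = 6,
                          n_orthogonal = 3, scale = "center", n_folds = NA),
               "rank")
})

test_that("leave-one-out Q2 agrees with brute-force refits", {
  set.seed(3)
  X <- matrix(rnorm(60), 12, 5)
  colnames(X) <- paste0("v", 1:5)
  cls <- rep(c("a", "b", "c"), each = 4)
  X[cls == "a", 1] <- X[cls == "a", 1] + 2
  q_loo <- cross_validate_q2(X, cls, n_predictive = 2, n_orthogonal = 0,
                             n_folds = 12, scale = "center")
  lev <- sort(unique(cls))
  Y <- outer(cls, lev, `==`) * 1
  press <- 0; ss <- 0
  for (i in seq_len(nrow(X))) {
    tr <- setdiff(seq_len(nrow(X)), i)
    fit <- oilmarkr:::oplsda_core(X[tr, , drop = FALSE], cls[tr], lev, 2, 0,
                                  "center")
    pr <- oilmarkr:::oplsda_project(fit, X[i, , drop = FALSE])
    press <- press + sum((Y[i, ] - pr$y_hat)^2)
    ss <- ss + sum((Y[i, ] - colMeans(Y[tr, , drop = FALSE]))^2)
  }
  expect_equal(q_loo, 1 - press / ss, tolerance = 1e-12)
})

test_that("pure-noise labels give non-positive Q2 on average", {
  set.seed(4)
  q2s <- vapply(1:30, function(i) {
    X <- matrix(rnorm(24 * 6), 24, 6)
    cls <- sample(rep(c("a", "b"), each = 12))
    cross_validate_q2(X, cls, n_predictive = 1, n_orthogonal = 0,
                      scale = "center")
  }, numeric(1))
  expect_lt(mean(q2s), 0)
})

test_that("permutation test bounds and orders as expected", {
  set.seed(6)
  X <- matrix(rnorm(24 * 8, sd = 0.3), 24, 8)
  cls <- rep(c("a", "b", "c"), each = 8)
  X[cls == "a", 1] <- X[cls == "a", 1] + 4
  X[cls == "b", 2] <- X[cls == "b", 2] + 4
  pt <- permutation_test(X, cls, n_predictive = 2, n_orthogonal = 0,
                         n_perm = 39, seed = 9, scale = "center")
  expect_equal(pt$p_q2, 1 / 40)
  expect_gt(pt$observed$q2, mean(pt$permutations$q2, na.rm = TRUE))
  expect_gte(pt$p_q2, 1 / (39 + 1))
  expect_lte(pt$p_q2, 1)
})

test_that("class predictions assign new samples by largest membership", {
  set.seed(8)
  X <- matrix(rnorm(24 * 5, sd = 0.2), 24, 5)
  cls <- rep(c("a", "b"), each = 12)
  X[cls == "a", 1] <- X[cls == "a", 1] + 3
  m <- fit_oplsda(X, cls, n_predictive = 1, scale = "center", n_folds = NA)
  Xnew <- matrix(rnorm(10 * 5, sd = 0.2), 10, 5)
  Xnew[1:5, 1] <- Xnew[1:5, 1] + 3
  pred <- predict(m, Xnew)
  expect_equal(pred$.class, rep(c("a", "b"), each = 5))
})

test_that("variable contributions rank class-exclusive variables on top", {
  set.seed(5)
  n <- 24
  X <- matrix(abs(rnorm(n * 6, 1, 0.05)), n, 6)
  cls <- rep(c("a", "b", "c"), each = 8)
  X[, 6] <- 1  # equal everywhere, constant: no contribution
  X[, 1] <- ifelse(cls == "b", 5, 0) + rnorm(n, 0, 0.05)
  m <- suppressWarnings(fit_oplsda(X, cls, n_predictive = 2,
                                   scale = "center", n_folds = NA))
  ct <- variable_contributions(m, "b")
  expect_equal(ct$variable[1], "v1")
  near_const <- ct[ct$variable == "v6", ]
  expect_true(nrow(near_const) == 0 || abs(near_const$contribution) < 1e-6)
  expect_error(variable_contributions(m, "zzz"), "not in the model")
})
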