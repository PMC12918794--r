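test_that("conditional down-sampling caps the class ratio deterministically", {
  labels <- rep(c("a", "b"), c(40, 10))
  idx <- downsample_condition(labels, 3, seed = 5L)
  expect_equal(sum(labels[idx] == "a"), 30L)
  expect_equal(sum(labels[idx] == "b"), 10L)
  expect_identical(idx, downsample_condition(labels, 3, seed = 5L))
  expect_false(identical(idx, downsample_condition(labels, 3, seed = 6L)))

  # under the cap: identity
  labels2 <- rep(c("a", "b"), c(34, 17))
  expect_identical(downsample_condition(labels2, 3, seed = 1L),
                   seq_along(labels2))
  expect_error(downsample_condition(rep("a", 5), 3), "two nonempty")
})

test_that("NIPALS PLS matches the SIMPLS oracle and basic limits", {
  set.seed(13)
  X <- scale(matrix(rnorm(60), 10, 6))
  y <- rnorm(10); y <- y - mean(y)
  fit <- fit_pls(X, y, 2)
  oracle <- simpls_coef(X, y, 2)
  expect_equal(as.numeric(X %*% oracle), predict_pls(fit, X),
               tolerance = 1e-8)

  # score orthogonality and unit-norm weights
  expect_lt(abs(sum(fit$Tm[, 1] * fit$Tm[, 2])), 1e-8)
  expect_equal(colSums(fit$W^2), rep(1, 2), tolerance = 1e-12)

  # single informative feature: LV1 weight concentrates on it, training AUC 1
  y2 <- c(rep(-0.5, 5), rep(0.5, 5))
  X2 <- scale(cbind(sig = y2 + rnorm(10, 0, 1e-8),
                    matrix(rnorm(40), 10, 4) * 0 + rnorm(40)))
  fit2 <- fit_pls(X2[, 1, drop = FALSE], y2, 1)
  expect_equal(abs(fit2$W[1, 1]), 1)
  expect_equal(roc_auc(predict_pls(fit2, X2[, 1, drop = FALSE]), y2 > 0), 1)

  # X orthogonal to y: explained y-variance ~ 0
  X3 <- scale(matrix(rep(c(-1, 1), 5), 10, 3))
  y3 <- rep(c(-1, -1, 1, 1, -1, 1, 1, -1, 1, -1) * 0.5)
  expect_error(fit_pls(X3 * 0, y3, 1))  # zero-variance features
})

test_that("AUC is rank-based and monotone-invariant", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  set.seed(23)
  s <- rnorm(40); lab <- rbinom(40, 1, 0.5)
  if (sum(lab) %in% c(0, 40)) lab[1] <- 1 - lab[1]
  expect_equal(roc_auc(s, lab), roc_auc(exp(s), lab))
  # agrees with the Mann-Whitney construction
  pos <- s[lab == 1]; neg <- s[lab == 0]
  mw <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
  expect_equal(roc_auc(s, lab), mw)
})

test_that("CV selection finds separable structure and is honest under permutation", {
  set.seed(33)
  n <- 50
  y <- rep(c(0, 1), each = n / 2)
  X <- cbind(matrix(rnorm(n * 10), n, 10), signal = y * 4 + rnorm(n, 0, 0.5))
  cv <- cv_select_k(X, y, k_grid = 1:4, folds = 5L, seed = 3L)
  expect_equal(max(cv$mean_auc), 1)

  yperm <- sample(y)
  cvp <- cv_select_k(X, yperm, k_grid = 1:4, folds = 5L, seed = 3L)
  expect_lt(abs(max(cvp$mean_auc) - 0.5), 0.25)

  small <- c(1:3, 26:28)
  expect_error(cv_select_k(X[small, ], y[small], folds = 5L),
               "fewer members")
  expect_error(cv_select_k(X[1:6, ], y[1:6], folds = 5L), "two classes")
})

test_that("VIP satisfies its algebraic identity and matches a direct formula oracle", {
  set.seed(43)
  X <- scale(matrix(rnorm(60), 10, 6))
  y <- rnorm(10); y <- y - mean(y)
  fit <- fit_pls(X, y, 2)
  v <- vip(fit, 2)
  expect_equal(mean(v^2), 1, tolerance = 1e-6)

  # direct evaluation of the formula from the fit components
  ssy <- fit$ssy[1:2]
  oracle <- sqrt(6 * ((fit$W[, 1]^2 / sum(fit$W[, 1]^2)) * ssy[1] +
                        (fit$W[, 2]^2 / sum(fit$W[, 2]^2)) * ssy[2]) /
                   sum(ssy))
  expect_equal(unname(v), unname(oracle), tolerance = 1e-12)

  # single-feature model: VIP = 1
  f1 <- fit_pls(X[, 1, drop = FALSE], y, 1)
  expect_equal(unname(vip(f1, 2)), 1, tolerance = 1e-12)
})

test_that("signed VIP direction follows class association and flips with coding", {
  set.seed(53)
  n <- 40
  y <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(up_in_1 = y * 2 + rnorm(n, 0, 0.5),
             down_in_1 = -y * 2 + rnorm(n, 0, 0.5),
             noise = rnorm(n))
  Xs <- scale(X)
  fit <- fit_pls(Xs, y - mean(y), 2)
  sv <- sign_vip(vip(fit, 2), Xs, y)
  expect_gt(sv[["up_in_1"]], 0)
  expect_lt(sv[["down_in_1"]], 0)

  sv_flip <- sign_vip(vip(fit, 2), Xs, 1L - y)
  expect_equal(unname(abs(sv)), unname(abs(sv_flip)))
  expect_equal(unname(sign(sv[1:2])), -unname(sign(sv_flip[1:2])))
})

test_that("iterated PLS-DA recovers informative features and reproduces under a seed", {
  set.seed(63)
  n <- 40; p <- 60; n_info <- 10
  y <- rep(c(0L, 1L), c(28, 12))
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  X[, 1:n_info] <- X[, 1:n_info] + 2 * y  # 2-sd shift
  cfg <- chromdep_config(n_plsda_iterations = 10L, rng_seed = 7L)
  res <- run_plsda_iterations(X, y, cfg, k_grid = 1:3)
  expect_gte(res$mean_auc, 0.95)
  ranks <- rank(-abs(res$vip_table$mean_signed_vip))
  expect_lt(median(ranks[1:n_info]), median(ranks[(n_info + 1):p]))
  expect_true(all(res$vip_table$mean_signed_vip[1:n_info] > 0))

  res2 <- run_plsda_iterations(X, y, cfg, k_grid = 1:3)
  expect_identical(res$vip_table, res2$vip_table)

  # null features: signed VIP roughly symmetric about zero
  X0 <- matrix(rnorm(n * 30), n, 30,
               dimnames = list(NULL, paste0("n", 1:30)))
  res0 <- run_plsda_iterations(X0, y, cfg, k_grid = 1:2)
  expect_lt(abs(mean(sign(res0$vip_table$mean_signed_vip))), 0.6)
})
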