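test_that("one-vs-rest logFC follows the stated group-mean arithmetic", {
  m <- rbind(g1 = c(0.8, 0.8, 0.2, 0.2, 0.4, 0.4))
  lin <- c("A", "A", "B", "B", "C", "C")
  fit <- fit_one_vs_rest(m, lin)
  expect_equal(fit$logFC["g1", "A"], 0.8 - mean(c(0.2, 0.4)))
  expect_equal(fit$logFC["g1", "B"], 0.2 - mean(c(0.8, 0.4)))

  # constant matrix: logFC 0, s2 0
  m0 <- rbind(g1 = rep(0.5, 6))
  fit0 <- fit_one_vs_rest(m0, lin)
  expect_equal(unname(fit0$logFC["g1", ]), rep(0, 3))
  expect_equal(unname(fit0$s2), 0)

  # singleton lineage rejected
  expect_error(fit_one_vs_rest(m, c("A", "A", "B", "B", "C", "D")),
               "at least 2")
})

test_that("fit matches an independent normal-equations oracle to 1e-10", {
  set.seed(21)
  lin <- rep(c("A", "B", "C"), each = 4)
  m <- matrix(rnorm(50 * 12), 50, 12,
              dimnames = list(paste0("g", 1:50), NULL))
  fit <- fit_one_vs_rest(m, lin)
  X <- stats::model.matrix(~ 0 + factor(lin))
  for (g in c(1, 17, 50)) {
    b <- solve(crossprod(X), crossprod(X, m[g, ]))
    expect_equal(unname(fit$group_means[g, ]), as.numeric(b),
                 tolerance = 1e-10)
    res <- m[g, ] - X %*% b
    expect_equal(unname(fit$s2[g]), sum(res^2) / (12 - 3), tolerance = 1e-10)
  }
  # contrast variance multiplier from the contrast weights: c'(X'X)^-1 c
  cvec <- c(1, -0.5, -0.5)
  v_oracle <- as.numeric(t(cvec) %*% solve(crossprod(X)) %*% cvec)
  expect_equal(unname(fit$v["A"]), v_oracle, tolerance = 1e-12)
})

test_that("the whole moderated pipeline agrees with limma", {
  set.seed(31)
  lin <- rep(c("A", "B", "C", "D"), times = c(5, 6, 4, 7))
  m <- matrix(rnorm(200 * length(lin), sd = runif(200, 0.5, 2)),
              200, length(lin), dimnames = list(paste0("g", 1:200), NULL))
  fit <- fit_one_vs_rest(m, lin)
  mod <- moderate_variances(fit$s2, fit$df)
  tab <- moderated_t(fit, mod)

  library(limma)
  design <- stats::model.matrix(~ 0 + factor(lin))
  colnames(design) <- levels(factor(lin))
  contr <- limma::makeContrasts(A - (B + C + D) / 3, levels = design)
  lfit <- limma::eBayes(limma::contrasts.fit(limma::lmFit(m, design), contr))
  ours <- tab[tab$lineage == "A", ]
  expect_equal(ours$logFC, unname(lfit$coefficients[, 1]), tolerance = 1e-10)
  expect_equal(mod$d0, lfit$df.prior, tolerance = 0.05)
  expect_equal(mod$s0_2, lfit$s2.prior, tolerance = 1e-3)
  expect_equal(ours$t, unname(lfit$t[, 1]), tolerance = 1e-6)
  expect_equal(ours$p, unname(lfit$p.value[, 1]), tolerance = 1e-6)
})

test_that("moderation limits behave as stated", {
  set.seed(41)
  s2 <- rchisq(100, 8) / 8
  # d0 = 0 limit: posterior equals observed (construct directly)
  post0 <- (0 * 1 + 8 * s2) / (0 + 8)
  expect_equal(post0, s2)
  # d0 = Inf: all posteriors equal s0^2 (homogeneous variances trigger it)
  mv <- moderate_variances(rep(2, 50), 10)
  expect_true(is.infinite(mv$d0))
  expect_equal(unname(mv$s2_post), rep(mv$s0_2, 50))
  expect_error(moderate_variances(rep(0, 20), 5), "zero")
})

test_that("moderation recovers prior parameters from hierarchical simulation", {
  set.seed(51)
  d0 <- 8; s0 <- 1; d <- 8
  sigma2 <- s0 * d0 / rchisq(5000, d0)          # scaled inverse-chi-square prior
  s2 <- sigma2 * rchisq(5000, d) / d            # observed residual variances
  mv <- moderate_variances(s2, d)
  expect_gt(mv$s0_2, 0.9); expect_lt(mv$s0_2, 1.1)
  expect_gt(mv$d0, 6); expect_lt(mv$d0, 10)
})

test_that("unmoderated t equals the classical contrast t-test on a 2-lineage toy", {
  set.seed(61)
  lin <- rep(c("A", "B"), each = 6)
  m <- matrix(rnorm(20 * 12), 20, 12, dimnames = list(paste0("g", 1:20), NULL))
  fit <- fit_one_vs_rest(m, lin)
  tab <- moderated_t(fit, NULL)  # d0 = 0: ordinary t
  for (g in c(3, 11)) {
    tt <- stats::t.test(m[g, lin == "A"], m[g, lin == "B"], var.equal = TRUE)
    row <- tab[tab$feature == paste0("g", g) & tab$lineage == "A", ]
    expect_equal(row$t, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(row$p, tt$p.value, tolerance = 1e-10)
  }
  # logFC 0 gives t 0, p 1
  m1 <- rbind(g1 = rep(c(1, 2), 6))
  tab1 <- moderated_t(fit_one_vs_rest(m1, lin), NULL)
  expect_equal(tab1$t[1], 0)
  expect_equal(tab1$p[1], 1)
})

test_that("BH adjustment matches the hand formula and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  set.seed(71)
  p <- runif(200)^2
  expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"))
  expect_true(all(bh_adjust(p) >= p & bh_adjust(p) <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")
})

test_that("enrichment calls follow the level-specific rules", {
  tab <- data.frame(feature = "f", lineage = "l",
                    logFC = c(0.15, 0.09, 0.02, -0.5),
                    fdr = c(0.01, 0.001, 0.08, 0.0001))
  gene <- call_enriched(tab, "gene")
  expect_identical(gene$enriched, c(TRUE, FALSE, FALSE, FALSE))
  cx <- call_enriched(tab, "complex")
  expect_identical(cx$enriched, c(TRUE, TRUE, TRUE, FALSE))
  expect_error(call_enriched(tab, "protein"))
})

test_that("row z-scoring yields exact moments and drops constant rows", {
  expect_equal(unname(zscore_rows(rbind(c(1, 2, 3)))[1, ]), c(-1, 0, 1))
  set.seed(81)
  m <- matrix(rnorm(60), 6, 10)
  z <- zscore_rows(m)
  expect_true(all(abs(rowMeans(z)) < 1e-12))
  expect_true(all(abs(apply(z, 1, sd) - 1) < 1e-12))
  m2 <- rbind(m, const = rep(2, 10))
  expect_warning(z2 <- zscore_rows(m2), "constant")
  expect_equal(nrow(z2), 6L)
})

test_that("Ward clustering reproduces the hand Lance-Williams result and hclust", {
  cl <- ward_cluster(matrix(c(0, 1, 10), ncol = 1))
  expect_equal(cl$height[1], 1)
  expect_equal(cl$height[2], sqrt(361 / 3), tolerance = 1e-12)

  # identical points merge at height 0
  cl0 <- ward_cluster(matrix(c(3, 3), ncol = 1))
  expect_equal(cl0$height, 0)

  # agrees with hclust ward.D2 heights on random data
  set.seed(91)
  m <- matrix(rnorm(14 * 3), 14, 3)
  cl <- ward_cluster(m)
  hc <- stats::hclust(stats::dist(m), method = "ward.D2")
  expect_equal(sort(cl$height), sort(hc$height), tolerance = 1e-10)

  # permutation invariance of heights
  perm <- sample(14)
  cl_p <- ward_cluster(m[perm, , drop = FALSE])
  expect_equal(sort(cl_p$height), sort(cl$height), tolerance = 1e-10)

  expect_error(ward_cluster(matrix(c(1, NA), ncol = 1)), "finite")
})

test_that("rank-sum comparison: exact enumeration, symmetry, and wilcox.test agreement", {
  r <- rank_sum_compare(c(1, 2), c(3, 4))
  expect_equal(r$p, 1 / 3)
  expect_identical(r$method, "exact")

  expect_equal(rank_sum_compare(c(1, 2, 3), c(1, 2, 3))$p, 1)

  set.seed(101)
  x <- rnorm(10); y <- rnorm(12)
  ours <- rank_sum_compare(x, y)
  ref <- stats::wilcox.test(x, y, exact = TRUE)
  expect_equal(ours$W, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)

  # large-sample branch with ties matches wilcox.test's corrected normal
  x <- round(rnorm(40), 1); y <- round(rnorm(35, 0.2), 1)
  ours <- rank_sum_compare(x, y)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)

  # strong shift
  expect_lt(rank_sum_compare(rnorm(40), rnorm(40, 5))$p, 1e-6)
  expect_error(rank_sum_compare(numeric(0), 1), "nonempty")
})

test_that("planted lineage shift is recovered with small bias", {
  set.seed(111)
  deltas <- replicate(50, {
    gen <- gen_dependency_matrix(n_lineages = 4L, lines_per_lineage = 10L,
                                 n_genes = 5L,
                                 planted_genes = data.frame(
                                   gene = "g0001", lineage = "lineage_01",
                                   delta = 0.3),
                                 noise_sd = 0.05,
                                 seed = sample.int(1e6, 1))
    fit <- fit_one_vs_rest(t(gen$dep), gen$annotation$lineage)
    fit$logFC["g0001", "lineage_01"]
  })
  expect_lt(abs(mean(deltas) - 0.3), 0.02)
})
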