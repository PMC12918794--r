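sc_fixture <- function(seed = 3L, coupling = 1, high = c(si_NTC = 0.85,
                                                         si_CXXC1 = 0.25)) {
  gen_singlecell_intensities(high_fraction = high, coupling = coupling,
                             n_cells = 1500L, seed = seed)
}

test_that("pooled gating recovers the symmetric lognormal-mixture midpoint", {
  set.seed(19)
  lx <- c(rnorm(2500, 1, 0.15), rnorm(2500, 2, 0.15))
  tab <- data.frame(cell_id = seq_along(lx), cell_line = "CL",
                    condition = rep(c("a", "b"), 2500),
                    replicate = 1L, marker = "M", intensity = 10^lx)
  gate <- pool_and_gate(tab, "M", "CL")
  expect_lt(abs(gate$threshold - 1.5), 0.05)
  # pooled across conditions: same gate whichever condition is queried
  gate_a <- pool_and_gate(tab[order(tab$condition), ], "M", "CL")
  expect_equal(gate$threshold, gate_a$threshold)
  # weighted densities equal at the threshold
  f <- gate$fit
  expect_lt(abs(f$pi[1] * dnorm(gate$threshold, f$mu[1], f$sigma[1]) -
                  f$pi[2] * dnorm(gate$threshold, f$mu[2], f$sigma[2])),
            1e-10)
  expect_error(pool_and_gate(tab[1:10, ], "M", "CL"), "fewer than 50")
})

test_that("fraction-high counts strictly above the threshold and aggregates by replicate", {
  gate <- list(threshold = 1.0, log_base = 10)
  tab <- data.frame(cell_id = 1:4, cell_line = "CL", condition = "c1",
                    replicate = c(1, 1, 2, 2), marker = "M",
                    intensity = 10^c(0.5, 1.5, 2.0, 0.8))
  fh <- fraction_high(tab, gate, "M", "CL")
  expect_equal(fh$by_condition$pct_high, 50)
  expect_equal(fh$by_replicate$pct_high, c(50, 50))

  # exactly at threshold counts low
  tab$intensity <- 10^c(1, 1, 1, 1)
  expect_equal(fraction_high(tab, gate, "M", "CL")$by_condition$pct_high, 0)

  # pooled fraction equals the cell-count-weighted mean of replicate fractions
  gen <- sc_fixture()
  g <- pool_and_gate(gen$table, "CXXC1", "MALME3M_syn")
  fh <- fraction_high(gen$table, g, "CXXC1", "MALME3M_syn")
  for (cond in fh$by_condition$condition) {
    reps <- fh$by_replicate[fh$by_replicate$condition == cond, ]
    pooled <- sum(reps$pct_high * reps$n_cells) / sum(reps$n_cells)
    expect_equal(fh$by_condition$pct_high[
      fh$by_condition$condition == cond], pooled, tolerance = 1e-9)
  }
})

test_that("planted condition shift in fraction-high is recovered within binomial tolerance", {
  gen <- sc_fixture(seed = 29L)
  g <- pool_and_gate(gen$table, "CXXC1", "MALME3M_syn")
  fh <- fraction_high(gen$table, g, "CXXC1", "MALME3M_syn")$by_condition
  expect_lt(abs(fh$pct_high[fh$condition == "si_NTC"] - 85), 3)
  expect_lt(abs(fh$pct_high[fh$condition == "si_CXXC1"] - 25), 3)
})

test_that("quadrant fractions partition to 100 and respect full coupling", {
  gen <- sc_fixture(seed = 39L, coupling = 1)
  gx <- pool_and_gate(gen$table, "CXXC1", "MALME3M_syn")
  gy <- pool_and_gate(gen$table, "H3K4me3", "MALME3M_syn")
  q <- quadrant_fractions(gen$table, "CXXC1", "H3K4me3", gx, gy,
                          "MALME3M_syn")
  sums <- tapply(q$pct, q$condition, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  # full coupling: off-diagonal quadrants nearly empty (gate misclassification
  # at ~0.15 log-sd separation is the only leakage)
  off <- q$pct[q$quadrant %in% c("high_low", "low_high")]
  expect_true(all(off < 2))

  # 4 cells, one per quadrant
  tab <- data.frame(cell_id = rep(1:4, 2), cell_line = "CL",
                    condition = "c1", replicate = 1L,
                    marker = rep(c("X", "Y"), each = 4),
                    intensity = 10^c(0, 2, 0, 2, 0, 0, 2, 2))
  g0 <- list(threshold = 1, log_base = 10)
  q4 <- quadrant_fractions(tab, "X", "Y", g0, g0, "CL")
  expect_equal(sort(q4$pct), rep(25, 4))
})

test_that("Welch test matches the Welch-Satterthwaite oracle and guards degeneracy", {
  set.seed(49)
  for (rep_ in 1:10) {
    x <- rnorm(3); y <- rnorm(3, 1)
    ours <- welch_test(x, y)
    ref <- t.test(x, y)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }
  expect_equal(welch_test(c(1, 1, 1), c(1, 1, 1))$p, 1)
  expect_lt(welch_test(c(1, 1, 1), c(2, 2, 2))$p, 0.01)
  expect_error(welch_test(1, c(1, 2)), "replicates")
})

test_that("normalized cell counts scale by the mean control count", {
  counts <- data.frame(cell_line = "CL",
                       condition = rep(c("ctrl", "kd"), c(3, 1)),
                       replicate = c(1, 2, 3, 1),
                       n_cells = c(900, 1000, 1100, 500))
  norm <- normalized_cell_count(counts, "ctrl")
  expect_equal(norm$normalized_count[norm$condition == "kd"], 0.5)
  expect_equal(mean(norm$normalized_count[norm$condition == "ctrl"]), 1)
  # scale invariance
  counts2 <- counts; counts2$n_cells <- counts2$n_cells * 2
  expect_equal(normalized_cell_count(counts2, "ctrl")$normalized_count,
               norm$normalized_count)
  expect_error(normalized_cell_count(
    data.frame(cell_line = "CL", condition = "kd", replicate = 1,
               n_cells = 5), "ctrl"), "control")
})

test_that("delta regression matches the closed-form normal equations", {
  r <- delta_regression(c(1, 2, 3), c(2, 4, 6))
  expect_equal(r$r_squared, 1)
  expect_equal(r$slope, 2)

  expect_equal(delta_regression(c(1, 2, 3), c(5, 5, 5))$r_squared, 0)

  set.seed(59)
  dx <- rnorm(5); dy <- rnorm(5)
  r <- delta_regression(dx, dy)
  slope <- cov(dx, dy) / var(dx)
  intercept <- mean(dy) - slope * mean(dx)
  expect_equal(r$slope, slope, tolerance = 1e-12)
  expect_equal(r$intercept, intercept, tolerance = 1e-12)
  r2 <- cor(dx, dy)^2
  expect_equal(r$r_squared, r2, tolerance = 1e-12)
  expect_error(delta_regression(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})
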