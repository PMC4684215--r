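test_that("F test matches hand computation and base R", {
  res <- f_test(c(2, 4, 6, 8), c(1, 2, 3, 4))
  expect_equal(res$statistic, 4)   # sample variances 20/3 and 5/3
  expect_equal(res$df1, 3)
  expect_equal(res$df2, 3)

  same <- f_test(c(1, 2, 5), c(1, 2, 5))
  expect_equal(same$statistic, 1)
  expect_equal(same$p_value, 1)

  set.seed(11)
  d <- rnorm(9, sd = 1.7); n <- rnorm(14)
  vt <- var.test(d, n)
  mine <- f_test(d, n)
  expect_equal(mine$statistic, unname(vt$statistic), tolerance = 1e-12)
  expect_equal(mine$p_value, vt$p.value, tolerance = 1e-12)

  expect_error(f_test(1, c(1, 2)), "at least 2")
  degen <- f_test(c(3, 3, 3), c(5, 5))
  expect_true(degen$degenerate)
  expect_equal(degen$p_value, 1)
})

test_that("F test keeps nominal level under a normal null (Monte Carlo)", {
  set.seed(101)
  B <- 10000
  xd <- matrix(rnorm(B * 20), B)
  xn <- matrix(rnorm(B * 20), B)
  mm <- methyl_matrix(cbind(xd, xn), rep(c(1L, 0L), each = 20))
  rate <- rejection_rate(run_test(mm, "F")$p_value, 0.05)
  se <- sqrt(0.05 * 0.95 / B)
  expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("Bartlett statistic matches stats::bartlett.test", {
  set.seed(3)
  g2 <- list(rnorm(10), rnorm(12, sd = 2))
  g3 <- list(rnorm(8), rnorm(9, sd = 1.4), rchisq(7, df = 3))
  for (g in list(g2, g3)) {
    mine <- bartlett_test(g)
    ref <- bartlett.test(g)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(mine$df1, length(g) - 1)
  }
  eqvar <- bartlett_test(list(c(0, 2), c(5, 7)))  # identical variances
  expect_equal(eqvar$statistic, 0)
  expect_equal(eqvar$p_value, 1)
  degen <- bartlett_test(list(c(1, 1), c(2, 2)))
  expect_true(degen$degenerate)
  expect_equal(degen$p_value, 1)
})

test_that("deviation transform centers within group", {
  vals <- rbind(c(1, 2, 3, 1, 2, 100), c(0, 0, 0, 5, 5, 5))
  mm <- methyl_matrix(vals, c(1, 1, 1, 0, 0, 0))
  z_mean <- center_deviations(mm, "abs", "group_mean")
  expect_equal(unname(z_mean$z_values[1, 1:3]), c(1, 0, 1))
  z_med <- center_deviations(mm, "abs", "group_median")
  expect_equal(unname(z_med$z_values[1, 4:6]), c(1, 0, 98))
  z_sq <- center_deviations(mm, "square", "group_mean")
  expect_equal(z_sq$z_values, z_mean$z_values^2)
  expect_true(all(z_mean$z_values >= 0))
})

test_that("trimmed mean removes floor(trim * n) values per tail", {
  expect_equal(trimmed_mean(1:10, 0.1), 5.5)    # mean of 2..9
  expect_equal(trimmed_mean(c(4, 1, 9), 0), mean(c(4, 1, 9)))
  expect_equal(trimmed_mean(c(-3, -1, 0, 1, 3), 0.2), 0)  # symmetric
  expect_error(trimmed_mean(numeric(0), 0.1), "non-empty")
  expect_error(trimmed_mean(1:5, 0.5), "0.5")
})

test_that("ANOVA F on deviations equals squared pooled t and car oracle", {
  mm <- rand_mm(n_sites = 8, n_d = 9, n_n = 11, seed = 5)
  z <- center_deviations(mm, "abs", "group_mean")
  res <- anova_f_on_deviations(z)
  # t^2 = F identity against an explicit per-site t test
  tt <- vapply(seq_len(8), function(i) {
    unname(t.test(z$z_values[i, z$labels == 1],
                  z$z_values[i, z$labels == 0],
                  var.equal = TRUE)$statistic)
  }, numeric(1))
  expect_equal(res$statistic, tt^2, tolerance = 1e-10)
  expect_equal(res$p_value, pooled_t_p(z), tolerance = 1e-10)
  # Levene and BF against car::leveneTest at one site
  skip_if_not_installed("car")
  gfac <- factor(mm$labels)
  lev <- run_test(mm, "Levene")
  bf <- run_test(mm, "BF")
  expect_equal(lev$p_value[4],
               car::leveneTest(mm$values[4, ], gfac, center = mean)[1, 3],
               tolerance = 1e-10)
  expect_equal(bf$p_value[4],
               car::leveneTest(mm$values[4, ], gfac, center = median)[1, 3],
               tolerance = 1e-10)
  # identical z across groups -> F = 0, p = 1
  flat <- methyl_matrix(rbind(rep(c(1, 2), 4)), rep(c(1, 0), each = 4))
  zf <- center_deviations(flat, "abs", "group_mean")
  rf <- anova_f_on_deviations(zf)
  expect_equal(rf$statistic, 0)
  expect_equal(rf$p_value, 1)
})

test_that("run_test dispatches the canonical compositions", {
  mm <- rand_mm(n_sites = 12, seed = 9)
  bf <- run_test(mm, "BF")
  by_hand <- anova_f_on_deviations(
    center_deviations(mm, "abs", "group_median"), test = "BF")
  expect_equal(bf, by_hand)
  expect_error(run_test(mm, "nope"), "unknown test")
  for (te in varhom_tests()) {
    res <- run_test(mm, te)
    expect_identical(nrow(res), 12L)
    expect_true(all(res$p_value >= 0 & res$p_value <= 1), info = te)
    expect_identical(res$test[1], te)
  }
})

test_that("F and Bartlett p-values are rank-identical on two equal groups", {
  mm <- rand_mm(n_sites = 100, n_d = 15, n_n = 15, seed = 21)
  pf_ <- run_test(mm, "F")$p_value
  pb <- run_test(mm, "Bartlett")$p_value
  expect_identical(rank(pf_), rank(pb))
})

test_that("statistics are scale-equivariant and location-invariant", {
  mm <- rand_mm(n_sites = 15, n_d = 8, n_n = 12, seed = 33)
  scaled <- methyl_matrix(mm$values * 3.7, mm$labels)
  shifted <- mm$values
  shifted[, mm$labels == 1L] <- shifted[, mm$labels == 1L] + 11.3
  shifted <- methyl_matrix(shifted, mm$labels)
  for (te in c("F", "Bartlett", "Levene", "L.trim", "BF")) {
    base <- run_test(mm, te)
    sc <- run_test(scaled, te)
    expect_equal(sc$statistic, base$statistic, tolerance = 1e-10, info = te)
    expect_equal(sc$p_value, base$p_value, tolerance = 1e-10, info = te)
  }
  for (te in c("Levene", "L.trim", "BF", "PO.AD", "PO.SQ")) {
    base <- run_test(mm, te)
    sh <- run_test(shifted, te)
    expect_equal(sh$statistic, base$statistic, tolerance = 1e-10, info = te)
  }
})

test_that("null calibration holds for F, Bartlett, L.trim and BF at n = 200", {
  # 20 replicates of 1000 normal equal-variance sites per group size 200
  tests <- c("F", "Bartlett", "L.trim", "BF")
  perf <- run_comparison(scenario_spec("normal", "eqM_eqV", 200),
                         tests = tests, n_datasets = 20, root_seed = 2024)
  se <- sqrt(0.05 * 0.95 / (20 * 1000))
  for (te in tests)
    expect_lt(abs(perf$mean_rate[te] - 0.05), 3 * se, label = te)
})
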