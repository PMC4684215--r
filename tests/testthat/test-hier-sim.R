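# Printed (mean, var) annotations of the fixed-distribution table, checked
# against the closed-form non-central moment formulas.
printed_moments <- list(
  chisq = list(non_d = c(2, 4), eqM_eqV = c(2, 4), diffM_eqV = c(1.5, 4),
               eqM_diffV = c(2, 7), diffM_diffV = c(4, 8)),
  t = list(non_d = c(0, 1.25), eqM_eqV = c(0, 1.25),
           diffM_eqV = c(1.57, 1.25), eqM_diffV = c(0, 2.5),
           diffM_diffV = c(2.75, 2.5)),
  normal = list(non_d = c(0, 1), eqM_eqV = c(0, 1), diffM_eqV = c(1.5, 1),
                eqM_diffV = c(0, 2), diffM_diffV = c(1.5, 2))
)

test_that("scenario table entries match their printed moment annotations", {
  p <- scenario_distributions("chisq", "eqM_diffV")
  expect_equal(p$d$df, 0.5)
  expect_equal(p$d$ncp, 1.5)
  p <- scenario_distributions("t", "diffM_eqV")
  expect_equal(p$d$df, 15)
  expect_equal(p$d$ncp, 1.489)
  p <- scenario_distributions("normal", "eqM_eqV")
  expect_equal(p$d, p$non_d)
  expect_error(scenario_distributions("gamma", "eqM_eqV"))

  for (fam in c("chisq", "t", "normal")) {
    for (reg in c("eqM_eqV", "diffM_eqV", "eqM_diffV", "diffM_diffV")) {
      par <- scenario_distributions(fam, reg)
      mom_n <- dist_moments(par$non_d)
      mom_d <- dist_moments(par$d)
      ref_n <- printed_moments[[fam]]$non_d
      ref_d <- printed_moments[[fam]][[reg]]
      lbl <- paste(fam, reg)
      expect_lt(abs(mom_n$mean - ref_n[1]), 0.006, label = lbl)
      expect_lt(abs(mom_n$var - ref_n[2]), 0.006, label = lbl)
      expect_lt(abs(mom_d$mean - ref_d[1]), 0.006, label = lbl)
      expect_lt(abs(mom_d$var - ref_d[2]), 0.006, label = lbl)
    }
  }
})

test_that("fixed-distribution draws reproduce their moments (Monte Carlo)", {
  spec <- scenario_spec("chisq", "eqM_eqV", n_per_group = 2,
                        n_sites = 5e5, seed = 61)
  ds <- simulate_study1(spec)
  x <- ds$matrix$values[, ds$matrix$labels == 0L]  # 1e6 chisq_2 draws
  expect_lt(abs(mean(x) - 2), 3 * sd(x) / sqrt(length(x)))
  expect_lt(abs(var(as.vector(x)) - 4) / 4, 0.01)

  spec_t <- scenario_spec("t", "diffM_diffV", n_per_group = 2,
                          n_sites = 5e5, seed = 62)
  xd <- simulate_study1(spec_t)$matrix$values[, 1:2]
  mom <- dist_moments(scenario_distributions("t", "diffM_diffV")$d)
  expect_lt(abs(mean(xd) - mom$mean), 3 * sd(xd) / sqrt(length(xd)))
  expect_lt(abs(var(as.vector(xd)) - mom$var) / mom$var, 0.02)
})

test_that("generators are deterministic under a fixed seed", {
  s1 <- scenario_spec("t", "eqM_diffV", 10, n_sites = 30, seed = 99)
  expect_identical(simulate_study1(s1)$matrix$values,
                   simulate_study1(s1)$matrix$values)
  s2 <- hier_spec(10, n_sites = 30, seed = 99, emission = "chisq")
  expect_identical(simulate_study2(s2)$matrix$values,
                   simulate_study2(s2)$matrix$values)
  pair <- make_discovery_validation_pair(50, 5, 10, seed = 99)
  pair2 <- make_discovery_validation_pair(50, 5, 10, seed = 99)
  expect_identical(pair$discovery$matrix$values,
                   pair2$discovery$matrix$values)
})

test_that("scaled inverse chi-squared draws have the closed-form mean", {
  set.seed(71)
  v <- r_scaled_inv_chisq(1e6, d0 = 20, s0_sq = 0.64)
  expect_true(all(v > 0))
  expect_lt(abs(mean(v) - 20 * 0.64 / 18) / (20 * 0.64 / 18), 0.01)
  # large d0: distribution concentrates at s0^2
  w <- r_scaled_inv_chisq(1e4, d0 = 1e6, s0_sq = 0.64, seed = 72)
  expect_lt(sd(w), 0.01 * 0.64 * sqrt(2) * 1e3)
  expect_lt(abs(mean(w) - 0.64), 0.001)
})

test_that("hierarchical null variances follow the scaled-F law", {
  spec <- hier_spec(50, n_sites = 10000, seed = 81)
  ds <- simulate_study2(spec)
  s2 <- apply(ds$matrix$values[, ds$matrix$labels == 1L], 1, var)
  ks <- suppressWarnings(
    ks.test(s2 / 0.64, pf, df1 = 49, df2 = 20)$statistic)
  expect_lt(unname(ks), 0.02)
})

test_that("chi-squared emission is literal unless recentered", {
  spec <- hier_spec(100, n_sites = 2000, seed = 82, emission = "chisq")
  ds <- simulate_study2(spec)
  expect_true(all(ds$matrix$values >= 0))
  # recenter shifts each group to the configured means
  spec_rc <- hier_spec(100, n_sites = 2000, seed = 82, emission = "chisq",
                       recenter = TRUE)
  ds_rc <- simulate_study2(spec_rc)
  xd <- ds_rc$matrix$values[, ds_rc$matrix$labels == 1L]
  expect_lt(abs(mean(xd) - 2), 0.1)
})

test_that("outlier injection replaces one diseased value per site", {
  spec <- scenario_spec("normal", "eqM_eqV", 10, n_sites = 200, seed = 91)
  clean <- simulate_study1(spec)
  gmax <- max(clean$matrix$values)
  out <- inject_outlier(clean)
  d_block <- out$matrix$values[, out$matrix$labels == 1L]
  expect_equal(unname(apply(d_block, 1, max)), rep(gmax, 200))
  expect_lte(sum(out$matrix$values != clean$matrix$values), 200)
  again <- inject_outlier(out)
  expect_identical(again$matrix$values, out$matrix$values)
  # outlier flag in the spec routes through the same injection
  spec_o <- scenario_spec("normal", "eqM_eqV", 10, n_sites = 200,
                          outlier = TRUE, seed = 91)
  expect_identical(simulate_study1(spec_o)$matrix$values,
                   out$matrix$values)
})

test_that("cohort pairs share truth and support the null edge case", {
  pair <- make_discovery_validation_pair(100, 0, 10, seed = 101)
  expect_false(any(pair$truth))
  expect_identical(pair$discovery$truth, pair$validation$truth)
  pair2 <- make_discovery_validation_pair(100, 20, c(10, 15), effect = 4,
                                          seed = 102)
  expect_identical(sum(pair2$truth), 20L)
  expect_identical(ncol(pair2$validation$matrix$values), 30L)
})
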