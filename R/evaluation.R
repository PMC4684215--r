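# Performance evaluation: type I error and power over replicate datasets,
# the one-sided bound test on the type I error rate, and the rank summary
# (median rank m, n_reject) that condenses the whole scenario grid.

#' Proportion of significant p-values
#'
#' @param p_values Non-empty vector of p-values in [0, 1].
#' @param alpha Significance level; a test is significant when its p-value
#'   is strictly below \code{alpha}.
#' @return Proportion in [0, 1].
#' @export
rejection_rate <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0L) stop("'p_values' must be non-empty")
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("'p_values' must lie in [0, 1]")
  mean(p_values < alpha)
}

simulate_spec <- function(spec) {
  if (inherits(spec, "scenario_spec")) return(simulate_study1(spec))
  if (inherits(spec, "hier_spec")) return(simulate_study2(spec))
  stop("'spec' must be a scenario_spec or hier_spec")
}

#' Rejection rates of several tests over replicate simulated datasets
#'
#' For each replicate, one dataset is simulated from \code{spec} (seeded
#' \code{root_seed}, \code{root_seed + 1}, ...) and every test in
#' \code{tests} is run on the same matrix, so per-dataset rates are paired
#' across tests. When the spec is a null scenario the rates estimate type I
#' error; otherwise they estimate power.
#'
#' @param spec A \code{\link{scenario_spec}} or \code{\link{hier_spec}}
#'   (its own \code{seed} field is ignored here).
#' @param tests Character vector of test names (default all seven).
#' @param n_datasets Number of replicate datasets (the study used 100).
#' @param root_seed Seed of the first replicate.
#' @param alpha Per-site significance level.
#' @return An object of class \code{"performance"}: list with \code{rates}
#'   (matrix, datasets x tests), \code{mean_rate} (per test),
#'   \code{is_null} (flag), \code{spec}, \code{alpha}.
#' @export
run_comparison <- function(spec, tests = varhom_tests(), n_datasets = 100,
                           root_seed = 1, alpha = 0.05) {
  stopifnot(n_datasets >= 1, all(tests %in% varhom_tests()))
  rates <- matrix(NA_real_, nrow = n_datasets, ncol = length(tests),
                  dimnames = list(NULL, tests))
  for (j in seq_len(n_datasets)) {
    spec$seed <- root_seed + j - 1L
    ds <- simulate_spec(spec)
    for (te in tests) {
      res <- run_test(ds$matrix, te)
      rates[j, te] <- rejection_rate(res$p_value, alpha)
    }
  }
  structure(
    list(rates = rates, mean_rate = colMeans(rates),
         is_null = !any(ds$truth), spec = spec, alpha = alpha),
    class = "performance"
  )
}

#' @export
print.performance <- function(x, ...) {
  cat("performance over ", nrow(x$rates), " datasets (",
      if (x$is_null) "null" else "alternative", " scenario); mean ",
      if (x$is_null) "type I error" else "power", ":\n", sep = "")
  print(round(x$mean_rate, 4))
  invisible(x)
}

#' One-sided test of the type I error bound
#'
#' Tests H0: mean type I error rate <= nominal against the one-sided
#' alternative that it exceeds the nominal level, using a one-sample t test
#' on the per-dataset rejection rates (default), or an exact binomial test
#' on the pooled rejection count.
#'
#' @param per_dataset_rates Vector of >= 2 per-dataset rejection rates.
#' @param nominal Nominal level (default 0.05).
#' @param method \code{"t"} or \code{"binomial"}.
#' @param n_sites Sites per dataset, required for the binomial method.
#' @return The p-value. Constant rates give the exact decision: p = 0 when
#'   the constant exceeds the nominal level, p = 1 otherwise.
#' @export
test_type1_bound <- function(per_dataset_rates, nominal = 0.05,
                             method = c("t", "binomial"), n_sites = NULL) {
  method <- match.arg(method)
  r <- per_dataset_rates
  if (length(r) < 2L) stop("need at least 2 per-dataset rates")
  if (method == "binomial") {
    if (is.null(n_sites)) stop("'n_sites' is required for method='binomial'")
    x <- round(sum(r) * n_sites)
    return(stats::binom.test(x, length(r) * n_sites, p = nominal,
                             alternative = "greater")$p.value)
  }
  if (stats::sd(r) == 0)
    return(if (mean(r) > nominal) 0 else 1)
  stats::t.test(r, mu = nominal, alternative = "greater")$p.value
}

#' Rank tests by power, masking those with inflated type I error
#'
#' Tests whose type-I bound was rejected receive a missing rank; the
#' remaining tests are ranked by mean power in ascending order (rank 1 =
#' least powerful), with average ranks for ties.
#'
#' @param mean_powers Named vector of mean powers, one per test.
#' @param rejected_type1 Logical vector aligned with \code{mean_powers}.
#' @return Numeric vector of ranks with \code{NA} for masked tests.
#' @examples
#' rank_powers(c(a = 0.3, b = 0.3, c = 0.5), c(FALSE, FALSE, FALSE))
#' # a and b tie at 1.5, c gets 3
#' @export
rank_powers <- function(mean_powers, rejected_type1) {
  stopifnot(length(mean_powers) == length(rejected_type1))
  ranks <- rep(NA_real_, length(mean_powers))
  names(ranks) <- names(mean_powers)
  keep <- !rejected_type1
  ranks[keep] <- rank(mean_powers[keep], ties.method = "average")
  ranks
}

#' Median rank and rejection count over scenarios
#'
#' Condenses a scenarios x tests rank matrix into the per-test summary:
#' m, the median of the non-missing ranks, and n_reject, the number of
#' scenarios in which the test's type-I bound was rejected.
#'
#' @param ranks Matrix (scenarios x tests) of ranks with \code{NA} where
#'   the type-I bound was rejected.
#' @param rejected Logical matrix of the same shape marking those
#'   rejections (defaults to \code{is.na(ranks)}).
#' @return Data frame with columns \code{test}, \code{m} (NA when ranked
#'   in no scenario) and \code{n_reject}.
#' @export
summarize_ranks <- function(ranks, rejected = is.na(ranks)) {
  ranks <- as.matrix(ranks)
  rejected <- as.matrix(rejected)
  stopifnot(identical(dim(ranks), dim(rejected)))
  m <- apply(ranks, 2L, function(r)
    if (all(is.na(r))) NA_real_ else stats::median(r, na.rm = TRUE))
  data.frame(test = colnames(ranks) %||% paste0("test_", seq_along(m)),
             m = unname(m), n_reject = unname(colSums(rejected)),
             stringsAsFactors = FALSE)
}

#' The full scenario grid of the comparison study
#'
#' 36 fixed-distribution scenarios (3 families x equal/different means x
#' with/without outlier x sample sizes) plus 12 hierarchical scenarios
#' (2 emissions x with/without outlier x sample sizes) = 48 at the default
#' sizes. Each scenario pairs a null spec (equal variances; type I error)
#' with an alternative spec (different variances; power).
#'
#' @param sample_sizes Per-group sample sizes of the grid
#'   (default c(20, 50, 200)).
#' @param n_sites Sites per dataset (default 1000).
#' @return List of scenarios; each has \code{id}, \code{null} and
#'   \code{alt} specs.
#' @export
study_scenarios <- function(sample_sizes = c(20, 50, 200), n_sites = 1000) {
  out <- list()
  for (n in sample_sizes) {
    for (fam in FAMILIES) {
      for (diffM in c(FALSE, TRUE)) {
        for (outl in c(FALSE, TRUE)) {
          id <- sprintf("S1_%s_%s_n%d%s", fam,
                        if (diffM) "diffM" else "eqM", n,
                        if (outl) "_outlier" else "")
          out[[id]] <- list(
            id = id,
            null = scenario_spec(fam, if (diffM) "diffM_eqV" else "eqM_eqV",
                                 n, n_sites = n_sites, outlier = outl),
            alt = scenario_spec(fam, if (diffM) "diffM_diffV" else "eqM_diffV",
                                n, n_sites = n_sites, outlier = outl))
        }
      }
    }
    for (emis in c("normal", "chisq")) {
      for (outl in c(FALSE, TRUE)) {
        id <- sprintf("S2_%s_n%d%s", emis, n,
                      if (outl) "_outlier" else "")
        out[[id]] <- list(
          id = id,
          null = hier_spec(n, emission = emis, s0_sq_case = 0.64,
                           n_sites = n_sites, outlier = outl),
          alt = hier_spec(n, emission = emis, s0_sq_case = 1.5,
                          n_sites = n_sites, outlier = outl))
      }
    }
  }
  out
}

#' Evaluate a scenario grid and summarise test performance
#'
#' For every scenario, estimates type I error (null spec) and power
#' (alternative spec) for each test over replicate datasets, applies the
#' type-I bound test, ranks the surviving tests by power, and condenses the
#' grid into the (m, n_reject) summary.
#'
#' @param scenarios List from \code{\link{study_scenarios}} (or a subset).
#' @param tests Character vector of test names.
#' @param n_datasets Replicate datasets per spec (the study used 100).
#' @param root_seed Base seed; each scenario/spec gets a distinct offset.
#' @param alpha Per-site significance level.
#' @param nominal Nominal type I error level for the bound test.
#' @return List with \code{summary} (the per-test m/n_reject data frame),
#'   \code{ranks} and \code{rejected} matrices (scenarios x tests), and
#'   \code{performance}, a long data frame of per-scenario mean rates.
#' @export
evaluate_grid <- function(scenarios, tests = varhom_tests(),
                          n_datasets = 100, root_seed = 1, alpha = 0.05,
                          nominal = 0.05) {
  ns <- length(scenarios)
  ranks <- matrix(NA_real_, ns, length(tests),
                  dimnames = list(names(scenarios), tests))
  rejected <- matrix(FALSE, ns, length(tests),
                     dimnames = list(names(scenarios), tests))
  perf <- vector("list", ns)
  for (i in seq_len(ns)) {
    sc <- scenarios[[i]]
    seed_i <- root_seed + (i - 1L) * 2L * n_datasets
    null_perf <- run_comparison(sc$null, tests, n_datasets,
                                root_seed = seed_i, alpha = alpha)
    alt_perf <- run_comparison(sc$alt, tests, n_datasets,
                               root_seed = seed_i + n_datasets,
                               alpha = alpha)
    pvals <- apply(null_perf$rates, 2L, test_type1_bound, nominal = nominal)
    rejected[i, ] <- pvals < 0.05
    ranks[i, ] <- rank_powers(alt_perf$mean_rate, rejected[i, ])
    perf[[i]] <- data.frame(
      scenario = sc$id, test = tests,
      type1 = unname(null_perf$mean_rate),
      type1_sd = unname(apply(null_perf$rates, 2L, stats::sd)),
      power = unname(alt_perf$mean_rate),
      power_sd = unname(apply(alt_perf$rates, 2L, stats::sd)),
      type1_bound_p = unname(pvals),
      n_datasets = n_datasets,
      stringsAsFactors = FALSE)
  }
  list(summary = summarize_ranks(ranks, rejected),
       ranks = ranks, rejected = rejected,
       performance = do.call(rbind, perf))
}

#' Scatter of n_reject versus median power rank
#'
#' Base-graphics reproduction of the grid summary plot: each test is a
#' labelled point at (m, n_reject); good tests sit low (few type-I
#' rejections) and right (high median power rank).
#'
#' @param summary Data frame from \code{\link{summarize_ranks}} or the
#'   \code{summary} element of \code{\link{evaluate_grid}}.
#' @param ... Passed to \code{plot}.
#' @return Invisibly, the summary.
#' @export
plot_rank_summary <- function(summary, ...) {
  plot(summary$m, summary$n_reject, xlab = "median power rank m",
       ylab = expression(n[reject]), pch = 19, ...)
  graphics::text(summary$m, summary$n_reject, labels = summary$test,
                 pos = 3, cex = 0.8)
  invisible(summary)
}
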