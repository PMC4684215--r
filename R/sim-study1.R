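# Simulation engine, part I: fixed-distribution two-group scenarios.
#
# Each scenario draws i.i.d. methylation levels for every site from one of
# three families (normal, t, chi-squared), with the diseased-group
# distribution shifted in mean and/or variance according to the regime.
# Non-central t and chi-squared members are used so that a mean shift can
# be imposed without (or together with) a variance shift.

REGIMES <- c("eqM_eqV", "diffM_eqV", "eqM_diffV", "diffM_diffV")
FAMILIES <- c("normal", "t", "chisq")

dist_desc <- function(dist, df = NULL, ncp = 0, mean = NULL, var = NULL) {
  list(dist = dist, df = df, ncp = ncp, mean = mean, var = var)
}

#' Closed-form moments of the generating distributions
#'
#' Mean and variance of a (possibly non-central) t or chi-squared
#' distribution, or a normal. For non-central t with df nu and
#' non-centrality delta, mean = delta sqrt(nu/2) Gamma((nu-1)/2) /
#' Gamma(nu/2) and variance = nu (1 + delta^2) / (nu - 2) - mean^2. For
#' non-central chi-squared, mean = df + ncp and variance = 2 (df + 2 ncp).
#'
#' @param desc A distribution descriptor as returned inside
#'   \code{\link{scenario_distributions}}.
#' @return List with \code{mean} and \code{var}.
#' @export
dist_moments <- function(desc) {
  switch(desc$dist,
    normal = list(mean = desc$mean, var = desc$var),
    t = {
      nu <- desc$df; ncp <- desc$ncp
      m <- if (ncp == 0) 0 else
        ncp * sqrt(nu / 2) * gamma((nu - 1) / 2) / gamma(nu / 2)
      v <- nu * (1 + ncp^2) / (nu - 2) - m^2
      list(mean = m, var = v)
    },
    chisq = list(mean = desc$df + desc$ncp,
                 var = 2 * (desc$df + 2 * desc$ncp)),
    stop("unknown distribution '", desc$dist, "'")
  )
}

draw_dist <- function(n, desc) {
  switch(desc$dist,
    normal = stats::rnorm(n, mean = desc$mean, sd = sqrt(desc$var)),
    t = if (desc$ncp == 0) stats::rt(n, df = desc$df) else
      stats::rt(n, df = desc$df, ncp = desc$ncp),
    chisq = if (desc$ncp == 0) stats::rchisq(n, df = desc$df) else
      stats::rchisq(n, df = desc$df, ncp = desc$ncp)
  )
}

#' Per-group generating distributions for a fixed-distribution scenario
#'
#' Returns the exact distribution pair used for a given family and regime:
#' the non-diseased group keeps the family's reference distribution
#' (chi-squared with 2 df, t with 10 df, or N(0,1)) while the diseased
#' group is modified in mean and/or variance. Regimes: \code{eqM_eqV}
#' (null in both mean and variance), \code{diffM_eqV} (mean shift only),
#' \code{eqM_diffV} (variance shift only), \code{diffM_diffV} (both).
#'
#' @param family \code{"normal"}, \code{"t"} or \code{"chisq"}.
#' @param regime One of the four regimes above.
#' @return List with elements \code{non_d} and \code{d}, each a descriptor
#'   with \code{dist}, \code{df}, \code{ncp}, \code{mean}, \code{var}.
#' @examples
#' p <- scenario_distributions("chisq", "eqM_diffV")
#' dist_moments(p$d)  # mean 2, variance 7
#' @export
scenario_distributions <- function(family = FAMILIES, regime = REGIMES) {
  family <- match.arg(family)
  regime <- match.arg(regime)
  non_d <- switch(family,
    chisq = dist_desc("chisq", df = 2),
    t = dist_desc("t", df = 10),
    normal = dist_desc("normal", mean = 0, var = 1))
  d <- switch(family,
    chisq = switch(regime,
      eqM_eqV = dist_desc("chisq", df = 2),
      diffM_eqV = dist_desc("chisq", df = 1, ncp = 0.5),
      eqM_diffV = dist_desc("chisq", df = 0.5, ncp = 1.5),
      diffM_diffV = dist_desc("chisq", df = 4)),
    t = switch(regime,
      eqM_eqV = dist_desc("t", df = 10),
      diffM_eqV = dist_desc("t", df = 15, ncp = 1.489),
      eqM_diffV = dist_desc("t", df = 10 / 3),
      diffM_diffV = dist_desc("t", df = 6, ncp = 2.393)),
    normal = switch(regime,
      eqM_eqV = dist_desc("normal", mean = 0, var = 1),
      diffM_eqV = dist_desc("normal", mean = 1.5, var = 1),
      eqM_diffV = dist_desc("normal", mean = 0, var = 2),
      diffM_diffV = dist_desc("normal", mean = 1.5, var = 2)))
  list(non_d = non_d, d = d)
}

#' Specify a fixed-distribution simulation scenario
#'
#' @param family,regime Passed to \code{\link{scenario_distributions}}.
#' @param n_per_group Subjects per group (>= 2); the study grid uses
#'   20, 50 and 200.
#' @param n_sites Number of CpG sites per dataset (default 1000).
#' @param outlier If \code{TRUE}, one diseased subject per site is replaced
#'   by the global pre-injection maximum (see \code{\link{inject_outlier}}).
#' @param seed Integer seed; \code{NULL} leaves the RNG state alone.
#' @return An object of class \code{"scenario_spec"}.
#' @export
scenario_spec <- function(family, regime, n_per_group, n_sites = 1000,
                          outlier = FALSE, seed = NULL) {
  family <- match.arg(family, FAMILIES)
  regime <- match.arg(regime, REGIMES)
  stopifnot(n_per_group >= 2, n_sites >= 1)
  structure(
    list(family = family, regime = regime,
         n_per_group = as.integer(n_per_group),
         n_sites = as.integer(n_sites),
         outlier = isTRUE(outlier), seed = seed,
         truth = regime %in% c("eqM_diffV", "diffM_diffV")),
    class = "scenario_spec"
  )
}

new_sim_dataset <- function(values, labels, truth, spec) {
  mm <- methyl_matrix(
    values, labels,
    site_ids = paste0("site_", seq_len(nrow(values))),
    subject_ids = c(paste0("case_", seq_len(sum(labels == 1L))),
                    paste0("ctrl_", seq_len(sum(labels == 0L))))
  )
  structure(list(matrix = mm, truth = truth, spec = spec),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("sim_dataset: ", nrow(x$matrix$values), " sites x ",
      ncol(x$matrix$values), " subjects; ",
      sum(x$truth), " differentially variable\n", sep = "")
  invisible(x)
}

#' Simulate a fixed-distribution dataset
#'
#' Draws every site x subject value i.i.d. from the group's scenario
#' distribution; sites are independent. The per-site truth flag is set for
#' the different-variance regimes. Values are generated in site-major
#' order (diseased block first), so a fixed seed yields identical matrices.
#'
#' @param spec A \code{\link{scenario_spec}}.
#' @return A \code{sim_dataset}: list with \code{matrix}
#'   (a \code{\link{methyl_matrix}} whose diseased columns come first),
#'   \code{truth} (per-site logical) and the generating \code{spec}.
#' @export
simulate_study1 <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  par <- scenario_distributions(spec$family, spec$regime)
  n <- spec$n_per_group; s <- spec$n_sites
  xd <- matrix(draw_dist(s * n, par$d), nrow = s, byrow = TRUE)
  xn <- matrix(draw_dist(s * n, par$non_d), nrow = s, byrow = TRUE)
  out <- new_sim_dataset(cbind(xd, xn), rep(c(1L, 0L), each = n),
                         truth = rep(spec$truth, s), spec = spec)
  if (spec$outlier) out <- inject_outlier(out)
  out
}
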