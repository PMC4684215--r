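# Simulation engine, part II: hierarchical variance model on the M-value
# scale. Each site's group variance is drawn from a scaled inverse
# chi-squared prior scale-inv-chisq(d0, s0^2); given the variance, subject
# values are conditionally normal (means +2 for cases, -2 for controls) or
# conditionally chi-squared with the latent value as real-valued degrees of
# freedom. Sites are marginally correlated through the shared prior but
# conditionally independent.

#' Draw from a scaled inverse chi-squared distribution
#'
#' scale-inv-chisq(d0, s0^2) is the law of d0 s0^2 / X with X ~ chisq_{d0};
#' its mean is d0 s0^2 / (d0 - 2) for d0 > 2.
#'
#' @param n Number of draws.
#' @param d0 Degrees of freedom (> 0).
#' @param s0_sq Scale factor (> 0).
#' @param seed Optional integer seed.
#' @return Vector of n positive values.
#' @export
r_scaled_inv_chisq <- function(n, d0, s0_sq, seed = NULL) {
  stopifnot(n >= 1, d0 > 0, s0_sq > 0)
  if (!is.null(seed)) set.seed(seed)
  d0 * s0_sq / stats::rchisq(n, df = d0)
}

#' Specify a hierarchical-variance simulation scenario
#'
#' Defaults follow the comparison study: prior degrees of freedom d0 = 20
#' and control scale s0^2 = 0.64; the null keeps the case scale at 0.64 and
#' the alternative raises it to 1.5; group mean M-values are +2 (cases) and
#' -2 (controls) under the conditional-normal emission.
#'
#' @param n_per_group Subjects per group (>= 2).
#' @param d0 Prior degrees of freedom of the variance prior.
#' @param s0_sq_control,s0_sq_case Prior scale factors per group; unequal
#'   scales make every site differentially variable.
#' @param emission \code{"normal"} (conditional normal with the latent
#'   variance) or \code{"chisq"} (conditional chi-squared with the latent
#'   value as real-valued degrees of freedom).
#' @param mean_case,mean_control Group means for the normal emission.
#' @param recenter For the chi-squared emission only: shift each group to
#'   the normal-emission means (off by default; the conditional chi-squared
#'   variant is generated literally, with its own mean equal to the latent
#'   degrees of freedom).
#' @param n_sites Number of CpG sites (default 1000).
#' @param outlier If \code{TRUE}, apply \code{\link{inject_outlier}}.
#' @param seed Integer seed; \code{NULL} leaves the RNG state alone.
#' @return An object of class \code{"hier_spec"}.
#' @export
hier_spec <- function(n_per_group, d0 = 20, s0_sq_control = 0.64,
                      s0_sq_case = 0.64,
                      emission = c("normal", "chisq"),
                      mean_case = 2, mean_control = -2,
                      recenter = FALSE, n_sites = 1000,
                      outlier = FALSE, seed = NULL) {
  emission <- match.arg(emission)
  stopifnot(n_per_group >= 2, n_sites >= 1, d0 > 0,
            s0_sq_control > 0, s0_sq_case > 0)
  structure(
    list(n_per_group = as.integer(n_per_group), d0 = d0,
         s0_sq_control = s0_sq_control, s0_sq_case = s0_sq_case,
         emission = emission, mean_case = mean_case,
         mean_control = mean_control, recenter = isTRUE(recenter),
         n_sites = as.integer(n_sites), outlier = isTRUE(outlier),
         seed = seed,
         truth = s0_sq_case != s0_sq_control),
    class = "hier_spec"
  )
}

# One group block: latent per-site variances, then conditional emission.
hier_group_block <- function(n_sites, n, d0, s0_sq, emission, mu, recenter) {
  v <- r_scaled_inv_chisq(n_sites, d0, s0_sq)
  if (emission == "normal") {
    x <- matrix(stats::rnorm(n_sites * n, mean = mu,
                             sd = rep(sqrt(v), each = n)),
                nrow = n_sites, byrow = TRUE)
  } else {
    # chi-squared with real-valued df v via gamma(shape = v/2, scale = 2)
    x <- matrix(stats::rgamma(n_sites * n, shape = rep(v / 2, each = n),
                              scale = 2),
                nrow = n_sites, byrow = TRUE)
    if (recenter) x <- x - v + mu
  }
  x
}

#' Simulate a hierarchical-variance dataset
#'
#' Per site, one latent variance per group is drawn from the group's scaled
#' inverse chi-squared prior; subject values are then emitted conditionally
#' (normal or chi-squared). The per-site truth flag is set when the two
#' groups have different prior scale factors. Deterministic under a fixed
#' seed (case block generated first, site-major).
#'
#' @param spec A \code{\link{hier_spec}}.
#' @return A \code{sim_dataset} as in \code{\link{simulate_study1}}.
#' @export
simulate_study2 <- function(spec) {
  stopifnot(inherits(spec, "hier_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  s <- spec$n_sites; n <- spec$n_per_group
  xd <- hier_group_block(s, n, spec$d0, spec$s0_sq_case, spec$emission,
                         spec$mean_case, spec$recenter)
  xn <- hier_group_block(s, n, spec$d0, spec$s0_sq_control, spec$emission,
                         spec$mean_control, spec$recenter)
  out <- new_sim_dataset(cbind(xd, xn), rep(c(1L, 0L), each = n),
                         truth = rep(spec$truth, s), spec = spec)
  if (spec$outlier) out <- inject_outlier(out)
  out
}

#' Inject one outlier per site into the diseased group
#'
#' The global maximum of the whole pre-injection matrix is computed once;
#' at every site the value of one diseased subject is replaced by that
#' maximum. All other entries are unchanged. Idempotent when the same
#' subject is targeted, since the maximum is retained.
#'
#' @param dataset A \code{sim_dataset}.
#' @param subject_index Which diseased subject receives the outlier: a
#'   fixed index within the diseased group (default 1, for
#'   reproducibility), or \code{"random"} for a uniform choice per site
#'   (consumes the RNG stream).
#' @return The modified \code{sim_dataset}.
#' @export
inject_outlier <- function(dataset, subject_index = 1L) {
  stopifnot(inherits(dataset, "sim_dataset"))
  mm <- dataset$matrix
  d_cols <- which(mm$labels == 1L)
  if (length(d_cols) == 0L) stop("diseased group is empty")
  gmax <- max(mm$values)
  n_sites <- nrow(mm$values)
  if (identical(subject_index, "random")) {
    pick <- d_cols[sample.int(length(d_cols), n_sites, replace = TRUE)]
  } else {
    stopifnot(subject_index >= 1L, subject_index <= length(d_cols))
    pick <- rep(d_cols[as.integer(subject_index)], n_sites)
  }
  mm$values[cbind(seq_len(n_sites), pick)] <- gmax
  dataset$matrix <- mm
  dataset
}

#' Paired discovery/validation cohorts with shared truth
#'
#' Emulates a two-cohort replication design: two independently generated
#' cohorts share site identities, and the same subset of sites is
#' differentially variable in both. Control values are N(0, 1) everywhere;
#' case values are N(0, effect) at the differentially variable sites and
#' N(0, 1) otherwise.
#'
#' @param n_sites Total sites per cohort.
#' @param n_dv_sites Number of truly differentially variable sites
#'   (the first \code{n_dv_sites} site ids; <= \code{n_sites}).
#' @param n_per_group Subjects per group in each cohort (one number, or a
#'   length-2 vector for discovery/validation).
#' @param effect Case/control variance ratio at the differentially
#'   variable sites.
#' @param seed Integer seed; \code{NULL} leaves the RNG state alone.
#' @return List with \code{discovery} and \code{validation}
#'   (\code{sim_dataset}s) and the shared logical \code{truth}.
#' @export
make_discovery_validation_pair <- function(n_sites, n_dv_sites, n_per_group,
                                           effect = 4, seed = NULL) {
  stopifnot(n_dv_sites >= 0, n_dv_sites <= n_sites, effect > 0)
  n_per_group <- rep(as.integer(n_per_group), length.out = 2L)
  stopifnot(all(n_per_group >= 2L))
  if (!is.null(seed)) set.seed(seed)
  truth <- seq_len(n_sites) <= n_dv_sites
  sds <- ifelse(truth, sqrt(effect), 1)
  one_cohort <- function(n) {
    xd <- matrix(stats::rnorm(n_sites * n, sd = rep(sds, each = n)),
                 nrow = n_sites, byrow = TRUE)
    xn <- matrix(stats::rnorm(n_sites * n), nrow = n_sites, byrow = TRUE)
    new_sim_dataset(cbind(xd, xn), rep(c(1L, 0L), each = n),
                    truth = truth, spec = NULL)
  }
  list(discovery = one_cohort(n_per_group[1L]),
       validation = one_cohort(n_per_group[2L]),
       truth = truth)
}
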