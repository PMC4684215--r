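# Two-cohort workflow: FDR discovery in one cohort, validation of the
# discovered sites at unadjusted p < alpha in an independent cohort, and an
# IQR fence rule flagging sites whose groups contain outlying subjects.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: sorted ascending, each p-value is multiplied by
#' m/rank, monotonicity is enforced from the largest down, values are
#' capped at 1, and the original order is restored.
#'
#' @param p_values Vector of p-values in [0, 1].
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("'p_values' must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Discover differentially variable sites at a target FDR
#'
#' Runs one equal-variance test over the matrix, BH-adjusts its p-values,
#' and returns the sites with adjusted p below the FDR level.
#'
#' @param mm A \code{\link{methyl_matrix}}.
#' @param test Test name (see \code{\link{run_test}}).
#' @param fdr_level Target false discovery rate (default 0.05).
#' @param ... Passed to \code{\link{run_test}}.
#' @return List with \code{sites} (character ids of significant sites) and
#'   \code{table} (the full result table with a \code{p_adj} column).
#' @export
discover <- function(mm, test, fdr_level = 0.05, ...) {
  res <- run_test(mm, test, ...)
  res$p_adj <- bh_adjust(res$p_value)
  list(sites = res$site_id[res$p_adj < fdr_level], table = res)
}

#' Validate discovered sites in an independent cohort
#'
#' The same test is run over the full validation matrix (the moderated-t
#' tests borrow information across all sites, so the test is never
#' restricted to the discovered subset); a discovered site is validated
#' when its unadjusted p-value in the validation cohort is below alpha.
#'
#' @param sites Character ids of the discovered sites; all must be present
#'   in the validation matrix.
#' @param validation_mm The validation \code{\link{methyl_matrix}}.
#' @param test Test name.
#' @param alpha Unadjusted significance level (default 0.05).
#' @param ... Passed to \code{\link{run_test}}.
#' @return List with \code{validated_sites}, \code{n_validated}, and
#'   \code{proportion} (\code{NA} when no sites were discovered).
#' @export
validate_discoveries <- function(sites, validation_mm, test, alpha = 0.05,
                                 ...) {
  stopifnot(inherits(validation_mm, "methyl_matrix"))
  missing <- setdiff(sites, validation_mm$site_ids)
  if (length(missing))
    stop("sites absent from validation matrix: ",
         paste(missing, collapse = ", "))
  if (length(sites) == 0L)
    return(list(validated_sites = character(0), n_validated = 0L,
                proportion = NA_real_))
  res <- run_test(validation_mm, test, ...)
  p <- res$p_value[match(sites, res$site_id)]
  validated <- sites[p < alpha]
  list(validated_sites = validated, n_validated = length(validated),
       proportion = length(validated) / length(sites))
}

#' Flag sites containing IQR-rule outliers
#'
#' A site is flagged when any subject's value lies strictly outside
#' [Q1 - fence*IQR, Q3 + fence*IQR] computed within its own group, in
#' either group.
#'
#' @param mm A \code{\link{methyl_matrix}}.
#' @param fence Fence multiplier (default 1.5).
#' @param quantile_type Quartile convention passed to
#'   \code{\link[stats]{quantile}} (default 7, linear interpolation).
#' @return Named logical vector, one flag per site.
#' @export
iqr_outlier_sites <- function(mm, fence = 1.5, quantile_type = 7) {
  stopifnot(inherits(mm, "methyl_matrix"))
  flag <- rep(FALSE, nrow(mm$values))
  for (g in c(0L, 1L)) {
    x <- mm$values[, mm$labels == g, drop = FALSE]
    q <- apply(x, 1L, stats::quantile, probs = c(0.25, 0.75),
               type = quantile_type, names = FALSE)
    iqr <- q[2L, ] - q[1L, ]
    lo <- q[1L, ] - fence * iqr
    hi <- q[2L, ] + fence * iqr
    flag <- flag | rowSums(x < lo | x > hi) > 0L
  }
  names(flag) <- mm$site_ids
  flag
}

#' Outlier overlap of significant sites across two cohorts
#'
#' Among the given sites, counts how many contain IQR-rule outliers in the
#' discovery cohort, and how many of those also contain outliers in the
#' validation cohort.
#'
#' @param discovery_mm,validation_mm \code{\link{methyl_matrix}} cohorts;
#'   every site in \code{sites} must be present in both.
#' @param sites Character site ids (typically the significant sites).
#' @param ... Passed to \code{\link{iqr_outlier_sites}}.
#' @return List with \code{n_discovery} and \code{n_both}.
#' @export
outlier_overlap <- function(discovery_mm, validation_mm, sites, ...) {
  missing <- c(setdiff(sites, discovery_mm$site_ids),
               setdiff(sites, validation_mm$site_ids))
  if (length(missing))
    stop("sites absent from a cohort: ",
         paste(unique(missing), collapse = ", "))
  if (length(sites) == 0L)
    return(list(n_discovery = 0L, n_both = 0L))
  f_disc <- iqr_outlier_sites(discovery_mm, ...)[sites]
  f_val <- iqr_outlier_sites(validation_mm, ...)[sites]
  list(n_discovery = sum(f_disc), n_both = sum(f_disc & f_val))
}

#' Full two-cohort discovery/validation report
#'
#' For each test: the number of FDR-significant sites in the discovery
#' cohort, the number and proportion validated at unadjusted p < alpha in
#' the validation cohort, and the outlier-site counts among the significant
#' sites (in the discovery cohort, and in both cohorts).
#'
#' @param discovery_mm,validation_mm \code{\link{methyl_matrix}} cohorts
#'   sharing site ids.
#' @param tests Character vector of test names (default all seven).
#' @param fdr_level Discovery FDR level.
#' @param alpha Validation significance level.
#' @param fence,quantile_type Passed to \code{\link{iqr_outlier_sites}}.
#' @return Data frame with one row per test and columns \code{test},
#'   \code{n_significant}, \code{n_validated}, \code{proportion_validated},
#'   \code{n_outlier_discovery}, \code{prop_outlier_discovery},
#'   \code{n_outlier_both}, \code{prop_outlier_both}.
#' @export
discovery_report <- function(discovery_mm, validation_mm,
                             tests = varhom_tests(), fdr_level = 0.05,
                             alpha = 0.05, fence = 1.5, quantile_type = 7) {
  rows <- lapply(tests, function(te) {
    disc <- discover(discovery_mm, te, fdr_level = fdr_level)
    val <- validate_discoveries(disc$sites, validation_mm, te, alpha = alpha)
    ov <- outlier_overlap(discovery_mm, validation_mm, disc$sites,
                          fence = fence, quantile_type = quantile_type)
    n_sig <- length(disc$sites)
    data.frame(
      test = te, n_significant = n_sig, n_validated = val$n_validated,
      proportion_validated = val$proportion,
      n_outlier_discovery = ov$n_discovery,
      prop_outlier_discovery = if (n_sig > 0) ov$n_discovery / n_sig
                               else NA_real_,
      n_outlier_both = ov$n_both,
      prop_outlier_both = if (ov$n_discovery > 0) ov$n_both / ov$n_discovery
                          else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
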