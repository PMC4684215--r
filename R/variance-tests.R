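# Classical equal-variance tests, vectorised over sites.
#
# All tests address H0: sigma^2_d = sigma^2_n for two groups of subjects at
# each CpG site. Two-sided p-values throughout. Degenerate sites (no
# within-group spread anywhere) are reported as statistic 0, p = 1 with the
# degenerate flag set: such data carry no evidence against equal variances,
# and a defined p-value keeps rejection-rate estimates free of NaNs.

TEST_NAMES <- c("F", "Bartlett", "Levene", "L.trim", "BF", "PO.AD", "PO.SQ")

result_table <- function(site_ids, test, statistic, df1, df2, p_value,
                         degenerate) {
  out <- data.frame(
    site_id = site_ids,
    test = test,
    statistic = statistic,
    df1 = df1,
    df2 = df2,
    p_value = p_value,
    degenerate = degenerate,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  class(out) <- c("varhom_result", "data.frame")
  out
}

row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}

# Two-sided p from an F-distributed statistic by doubling the smaller tail,
# capped at 1.
two_sided_f_p <- function(stat, df1, df2) {
  lo <- stats::pf(stat, df1, df2)
  hi <- stats::pf(stat, df1, df2, lower.tail = FALSE)
  pmin(1, 2 * pmin(lo, hi))
}

f_test_rows <- function(xd, xn, site_ids) {
  md <- ncol(xd); mn <- ncol(xn)
  vd <- row_vars(xd); vn <- row_vars(xn)
  stat <- vd / vn
  degen <- vd == 0 & vn == 0
  p <- two_sided_f_p(stat, md - 1, mn - 1)
  # one-sided degeneracies: a zero variance in one group only is maximal
  # evidence of inequality
  p[vn == 0 & vd > 0] <- 0
  stat[vn == 0 & vd > 0] <- Inf
  p[vd == 0 & vn > 0] <- 0
  stat[degen] <- 0; p[degen] <- 1
  result_table(site_ids, "F", stat, md - 1, mn - 1, p, degen)
}

bartlett_rows <- function(blocks, site_ids) {
  k <- length(blocks)
  ni <- vapply(blocks, ncol, integer(1))
  N <- sum(ni)
  vi <- lapply(blocks, row_vars)
  ss <- Reduce(`+`, Map(function(v, n) (n - 1) * v, vi, as.list(ni)))
  sp2 <- ss / (N - k)
  num <- (N - k) * log(sp2) -
    Reduce(`+`, Map(function(v, n) (n - 1) * log(v), vi, as.list(ni)))
  C <- 1 + (sum(1 / (ni - 1)) - 1 / (N - k)) / (3 * (k - 1))
  stat <- num / C
  degen <- sp2 == 0
  p <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
  one_zero <- !degen & Reduce(`|`, lapply(vi, function(v) v == 0))
  stat[one_zero] <- Inf; p[one_zero] <- 0
  stat[degen] <- 0; p[degen] <- 1
  result_table(site_ids, "Bartlett", stat, k - 1, Inf, p, degen)
}

#' F test for equality of two variances
#'
#' Ratio of the unbiased sample variances, diseased group in the numerator.
#' The two-sided p-value doubles the smaller F tail (capped at 1), so the
#' orientation does not affect the p-value.
#'
#' @param group_d,group_n Numeric vectors of length >= 2: diseased and
#'   non-diseased group values at one site.
#' @return A one-row result data frame with columns \code{site_id},
#'   \code{test}, \code{statistic}, \code{df1}, \code{df2}, \code{p_value},
#'   \code{degenerate}.
#' @examples
#' f_test(c(2, 4, 6, 8), c(1, 2, 3, 4))  # statistic 4, df (3, 3)
#' @export
f_test <- function(group_d, group_n) {
  if (length(group_d) < 2L || length(group_n) < 2L)
    stop("each group must have at least 2 values")
  f_test_rows(matrix(group_d, nrow = 1L), matrix(group_n, nrow = 1L), "site_1")
}

#' Bartlett's test for homogeneity of variances
#'
#' Classical Bartlett chi-squared statistic over k >= 2 groups with k - 1
#' degrees of freedom and an upper-tail p-value.
#'
#' @param groups List of numeric vectors, each of length >= 2.
#' @return A one-row result data frame (see \code{\link{f_test}}).
#' @export
bartlett_test <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("'groups' must be a list of at least 2 vectors")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("each group must have at least 2 values")
  blocks <- lapply(groups, function(g) matrix(g, nrow = 1L))
  bartlett_rows(blocks, "site_1")
}

#' One-way ANOVA F on a deviation matrix
#'
#' Per site, the two-group one-way ANOVA F statistic on the transformed
#' values, with degrees of freedom (1, m_d + m_n - 2) and an upper-tail
#' p-value. Composed with \code{\link{center_deviations}} using the
#' group mean, trimmed mean, or median this yields the Levene, L.trim, and
#' Brown-Forsythe tests respectively.
#'
#' @param z A \code{\link{center_deviations}} result.
#' @param test Label recorded in the \code{test} column.
#' @return A result data frame, one row per site.
#' @export
anova_f_on_deviations <- function(z, test = "Levene") {
  stopifnot(inherits(z, "deviation_matrix"))
  zd <- z$z_values[, z$labels == 1L, drop = FALSE]
  zn <- z$z_values[, z$labels == 0L, drop = FALSE]
  md <- ncol(zd); mn <- ncol(zn)
  if (md < 2L || mn < 2L) stop("each group must have at least 2 subjects")
  df2 <- md + mn - 2
  sp2 <- ((md - 1) * row_vars(zd) + (mn - 1) * row_vars(zn)) / df2
  diff <- rowMeans(zd) - rowMeans(zn)
  stat <- diff^2 / (sp2 * (1 / md + 1 / mn))
  degen <- sp2 == 0
  p <- stats::pf(stat, 1, df2, lower.tail = FALSE)
  sep <- degen & abs(diff) > 0   # zero residual spread, separated means
  stat[sep] <- Inf; p[sep] <- 0
  zero <- degen & diff == 0
  stat[zero] <- 0; p[zero] <- 1
  result_table(z$site_ids, test, stat, 1, df2, p, degen & !sep)
}

#' Run one of the seven equal-variance tests over a methylation matrix
#'
#' Single dispatch point. \code{"F"} and \code{"Bartlett"} act on the raw
#' values; \code{"Levene"}, \code{"L.trim"} and \code{"BF"} are ANOVA F
#' tests on absolute deviations from the within-group mean, trimmed mean,
#' and median; \code{"PO.AD"} and \code{"PO.SQ"} are empirical-Bayes
#' moderated t tests on absolute and squared deviations from the
#' within-group mean (see \code{\link{po_test}}).
#'
#' @param mm A \code{\link{methyl_matrix}}.
#' @param test One of \code{"F"}, \code{"Bartlett"}, \code{"Levene"},
#'   \code{"L.trim"}, \code{"BF"}, \code{"PO.AD"}, \code{"PO.SQ"}.
#' @param trim_fraction Per-tail trim fraction for \code{"L.trim"}
#'   (default 0.10, the classical choice).
#' @param po_center Centering for the PO tests; the published construction
#'   uses the within-group mean.
#' @return A result data frame, one row per site, with columns
#'   \code{site_id}, \code{test}, \code{statistic}, \code{df1}, \code{df2},
#'   \code{p_value}, \code{degenerate}.
#' @examples
#' mm <- simulate_study1(scenario_spec("normal", "eqM_diffV", 20,
#'                                     n_sites = 50, seed = 1))$matrix
#' head(run_test(mm, "BF"))
#' @export
run_test <- function(mm, test, trim_fraction = 0.1,
                     po_center = "group_mean") {
  stopifnot(inherits(mm, "methyl_matrix"))
  if (!is.character(test) || length(test) != 1L || !test %in% TEST_NAMES)
    stop("unknown test '", paste(test, collapse = ","),
         "'; must be one of: ", paste(TEST_NAMES, collapse = ", "))
  g <- group_split(mm)
  if (ncol(g$d) < 2L || ncol(g$n) < 2L)
    stop("each group must have at least 2 subjects")
  switch(test,
    "F" = f_test_rows(g$d, g$n, mm$site_ids),
    "Bartlett" = bartlett_rows(list(g$d, g$n), mm$site_ids),
    "Levene" = anova_f_on_deviations(
      center_deviations(mm, "abs", "group_mean"), test = "Levene"),
    "L.trim" = anova_f_on_deviations(
      center_deviations(mm, "abs", "group_trimmed_mean",
                        trim_fraction = trim_fraction), test = "L.trim"),
    "BF" = anova_f_on_deviations(
      center_deviations(mm, "abs", "group_median"), test = "BF"),
    "PO.AD" = po_test(mm, "AD", center = po_center),
    "PO.SQ" = po_test(mm, "SQ", center = po_center)
  )
}

#' All seven test names
#'
#' @return Character vector of the test identifiers accepted by
#'   \code{\link{run_test}}.
#' @export
varhom_tests <- function() TEST_NAMES
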