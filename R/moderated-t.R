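# Empirical-Bayes moderated t on deviation scores: the machinery behind the
# PO.AD and PO.SQ equal-variance tests. Per-site residual variances are
# assumed to follow s_g^2 | sigma_g^2 ~ sigma_g^2 * chisq_d / d with a
# scaled-inverse-chi-squared prior sigma_g^2 ~ d0 s0^2 / chisq_{d0}, so that
# marginally s_g^2 / s0^2 ~ F(d, d0). The prior (d0, s0^2) is estimated
# across sites and each site's variance is shrunk toward s0^2 before
# forming the t statistic.

#' Invert the trigamma function
#'
#' Solves trigamma(y) = x by Newton iteration on the monotone decreasing
#' trigamma, to relative tolerance 1e-8 within 100 iterations.
#'
#' @param x Positive values.
#' @return y with \code{trigamma(y) = x}; \code{Inf} maps to 0-variance
#'   behaviour and very small x to the asymptote \code{1/sqrt(x)}.
#' @keywords internal
trigamma_inverse <- function(x) {
  out <- x
  ok <- is.finite(x) & x > 0
  out[!ok & !is.na(x) & x <= 0] <- Inf
  big <- ok & x > 1e7      # trigamma(y) ~ 1/y as y -> 0
  out[big] <- 1 / sqrt(x[big])
  small <- ok & x < 1e-6   # trigamma(y) ~ 1/y for large y
  out[small] <- 1 / x[small]
  mid <- ok & !big & !small
  if (any(mid)) {
    xm <- x[mid]
    y <- 0.5 + 1 / xm
    for (iter in 1:100) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xm) / psigamma(y, deriv = 2L)
      y <- y + dif
      if (max(-dif / y) < 1e-8) break
    }
    out[mid] <- y
  }
  out
}

#' Fit the scaled-F prior of the moderated t by moment matching
#'
#' Given per-site sample variances with common residual degrees of freedom
#' d, estimates the prior degrees of freedom d0 and prior variance s0^2 of
#' the scaled-inverse-chi-squared variance prior. Moment matching is on the
#' log scale: with e_g = log(s_g^2) - digamma(d/2) + log(d/2), the method
#' solves trigamma(d0/2) = var(e_g) - trigamma(d/2) (clamped at zero, which
#' yields d0 = Inf) and sets s0^2 = exp(mean(e_g) + digamma(d0/2) -
#' log(d0/2)).
#'
#' @param sample_variances Vector of >= 2 positive variances.
#' @param residual_df Residual degrees of freedom d (> 0) shared by all
#'   variances.
#' @return List with \code{d0} (> 0, possibly \code{Inf}) and \code{s0_sq}.
#' @export
fit_fdist <- function(sample_variances, residual_df) {
  s2 <- sample_variances
  if (length(s2) < 2L) stop("need at least 2 sample variances")
  if (any(!is.finite(s2)) || any(s2 <= 0))
    stop("'sample_variances' must be positive and finite")
  if (!is.numeric(residual_df) || residual_df <= 0)
    stop("'residual_df' must be > 0")
  d <- residual_df
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  disp <- stats::var(e)
  if (disp == 0) {
    # no dispersion at all: the prior is the common variance itself
    return(list(d0 = Inf, s0_sq = s2[1L]))
  }
  evar <- disp - trigamma(d / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Shrink a sample variance toward the prior variance
#'
#' Posterior (squeezed) variance of the moderated-t model: the
#' precision-weighted compromise (d0 s0^2 + d s^2) / (d0 + d). With
#' d0 = 0 there is no shrinkage; with d0 = Inf the prior dominates.
#'
#' @param s_g_sq Sample variance(s), >= 0.
#' @param d_g Residual degrees of freedom, > 0.
#' @param hyper List with \code{d0} and \code{s0_sq}
#'   (see \code{\link{fit_fdist}}).
#' @return Squeezed variance(s).
#' @export
squeeze_var <- function(s_g_sq, d_g, hyper) {
  stopifnot(is.numeric(s_g_sq), all(s_g_sq >= 0), d_g > 0,
            hyper$d0 >= 0, hyper$s0_sq > 0)
  if (is.infinite(hyper$d0)) return(rep(hyper$s0_sq, length(s_g_sq)))
  (hyper$d0 * hyper$s0_sq + d_g * s_g_sq) / (hyper$d0 + d_g)
}

#' Moderated t table on a deviation matrix
#'
#' Per site, the two-group difference of mean deviations divided by the
#' standard error built from the squeezed pooled variance; p-values are
#' two-sided from a t distribution with d_g + d0 degrees of freedom (the
#' normal law when d0 is infinite). Hyperparameters are fitted across all
#' sites, so at least 2 sites are required.
#'
#' @param z A \code{\link{center_deviations}} result.
#' @param test Label recorded in the \code{test} column.
#' @param d0 Optional fixed prior degrees of freedom, bypassing
#'   \code{\link{fit_fdist}} (\code{d0 = 0} reproduces the ordinary pooled
#'   two-sample t per site).
#' @return A result data frame, one row per site; \code{df2} is the total
#'   degrees of freedom d_g + d0.
#' @export
moderated_t_table <- function(z, test = "PO.AD", d0 = NULL) {
  stopifnot(inherits(z, "deviation_matrix"))
  if (nrow(z$z_values) < 2L)
    stop("moderated t needs >= 2 sites to fit hyperparameters")
  zd <- z$z_values[, z$labels == 1L, drop = FALSE]
  zn <- z$z_values[, z$labels == 0L, drop = FALSE]
  md <- ncol(zd); mn <- ncol(zn)
  if (md < 2L || mn < 2L) stop("each group must have at least 2 subjects")
  dg <- md + mn - 2
  sp2 <- ((md - 1) * row_vars(zd) + (mn - 1) * row_vars(zn)) / dg
  if (is.null(d0)) {
    pos <- sp2 > 0
    if (sum(pos) < 2L)
      stop("fewer than 2 sites with positive residual variance")
    hyper <- fit_fdist(sp2[pos], dg)
  } else {
    s0 <- if (d0 > 0 && any(sp2 > 0)) mean(sp2[sp2 > 0]) else 1
    hyper <- list(d0 = d0, s0_sq = s0)
  }
  s2post <- squeeze_var(sp2, dg, hyper)
  diff <- rowMeans(zd) - rowMeans(zn)
  se <- sqrt(s2post * (1 / md + 1 / mn))
  stat <- diff / se
  df_total <- dg + hyper$d0
  p <- 2 * stats::pt(-abs(stat), df = df_total)
  degen <- se == 0
  stat[degen & diff == 0] <- 0
  p[degen & diff == 0] <- 1
  stat[degen & diff != 0] <- Inf * sign(diff[degen & diff != 0])
  p[degen & diff != 0] <- 0
  out <- result_table(z$site_ids, test, stat, 1, df_total, p,
                      degen & diff == 0)
  attr(out, "hyper") <- hyper
  out
}

#' Phipson-Oshlack moderated-t equal-variance tests (PO.AD, PO.SQ)
#'
#' Transforms each value to its absolute (AD) or squared (SQ) deviation
#' from the within-group mean and applies the empirical-Bayes moderated t
#' to the transformed matrix: a group difference in mean deviation size is
#' evidence of unequal variances.
#'
#' @param mm A \code{\link{methyl_matrix}} with >= 2 sites.
#' @param mode \code{"AD"} (absolute deviations) or \code{"SQ"} (squared).
#' @param center Centrality measure for the deviations; default the
#'   within-group mean as in the published construction.
#' @return A result data frame, one row per site, with the fitted
#'   hyperparameters in \code{attr(, "hyper")}.
#' @export
po_test <- function(mm, mode = c("AD", "SQ"), center = "group_mean") {
  stopifnot(inherits(mm, "methyl_matrix"))
  mode <- match.arg(mode)
  z <- center_deviations(mm, mode = if (mode == "AD") "abs" else "square",
                         center = center)
  moderated_t_table(z, test = paste0("PO.", mode))
}
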