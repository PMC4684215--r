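#' Trimmed mean
#'
#' Mean after removing \code{floor(trim_fraction * n)} smallest and largest
#' values, the centering used by the trimmed-mean Levene (L.trim) test.
#'
#' @param values Non-empty numeric vector.
#' @param trim_fraction Fraction trimmed from each tail, in [0, 0.5).
#' @return The trimmed mean (ordinary mean when \code{trim_fraction = 0}).
#' @examples
#' trimmed_mean(1:10, 0.1)  # mean of 2..9 = 5.5
#' @export
trimmed_mean <- function(values, trim_fraction = 0.1) {
  if (length(values) == 0L) stop("'values' must be non-empty")
  check_trim(trim_fraction)
  n <- length(values)
  if (n - 2L * floor(trim_fraction * n) < 1L)
    stop("trimming leaves no values")
  mean(values, trim = trim_fraction)
}

check_trim <- function(trim_fraction) {
  if (!is.numeric(trim_fraction) || length(trim_fraction) != 1L ||
      trim_fraction < 0 || trim_fraction >= 0.5)
    stop("'trim_fraction' must be a single value in [0, 0.5)")
}

# Row-sort a matrix with one global radix sort; much faster than per-row
# sort() calls for the thousands of short rows typical here.
row_sorted <- function(x) {
  matrix(x[order(row(x), x)], nrow = nrow(x), byrow = TRUE)
}

# Row-wise centering statistics over a group block. Medians are midpoint
# medians for even n; trimmed means drop floor(trim * n) values per tail,
# matching mean(x, trim = ).
row_center <- function(x, center, trim_fraction) {
  n <- ncol(x)
  switch(center,
    group_mean = rowMeans(x),
    group_median = {
      xs <- row_sorted(x)
      if (n %% 2L) xs[, (n + 1L) / 2L]
      else (xs[, n / 2L] + xs[, n / 2L + 1L]) / 2
    },
    group_trimmed_mean = {
      lo <- floor(trim_fraction * n)
      if (lo == 0L) rowMeans(x)
      else rowMeans(row_sorted(x)[, (lo + 1L):(n - lo), drop = FALSE])
    },
    stop("unknown center '", center, "'")
  )
}

#' Group-centered deviation transform
#'
#' Replaces each methylation value by its absolute or squared deviation from
#' a within-group centrality measure of its site. The Levene-family and
#' moderated-t tests are one-way tests of group mean differences on this
#' transformed matrix.
#'
#' @param mm A \code{\link{methyl_matrix}}.
#' @param mode \code{"abs"} for |x - c| or \code{"square"} for (x - c)^2.
#' @param center Within-group centrality: \code{"group_mean"},
#'   \code{"group_median"} (Brown-Forsythe) or \code{"group_trimmed_mean"}.
#' @param trim_fraction Per-tail trim fraction when
#'   \code{center = "group_trimmed_mean"}.
#' @return An object of class \code{"deviation_matrix"}: list with the
#'   non-negative matrix \code{z_values} (same shape and dimnames as the
#'   input), the \code{labels}, and the transform settings.
#' @export
center_deviations <- function(mm,
                              mode = c("abs", "square"),
                              center = c("group_mean", "group_median",
                                         "group_trimmed_mean"),
                              trim_fraction = 0.1) {
  stopifnot(inherits(mm, "methyl_matrix"))
  mode <- match.arg(mode)
  center <- match.arg(center)
  check_trim(trim_fraction)
  z <- mm$values
  for (g in c(0L, 1L)) {
    cols <- mm$labels == g
    c_g <- row_center(mm$values[, cols, drop = FALSE], center, trim_fraction)
    z[, cols] <- mm$values[, cols, drop = FALSE] - c_g
  }
  z <- if (mode == "abs") abs(z) else z * z
  structure(
    list(z_values = z, labels = mm$labels, site_ids = mm$site_ids,
         mode = mode, center = center,
         trim_fraction = if (center == "group_trimmed_mean") trim_fraction else NA_real_),
    class = "deviation_matrix"
  )
}

#' @export
print.deviation_matrix <- function(x, ...) {
  cat("deviation_matrix: ", nrow(x$z_values), " sites x ", ncol(x$z_values),
      " subjects; mode=", x$mode, ", center=", x$center, "\n", sep = "")
  invisible(x)
}
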