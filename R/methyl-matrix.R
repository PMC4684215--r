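#' Sites-by-subjects methylation matrix with binary group labels
#'
#' The universal input of all seven equal-variance tests: a numeric matrix
#' of methylation levels (rows are CpG sites, columns are subjects; M-values
#' or simulated units) together with a binary case/control label per subject.
#'
#' @param values Numeric matrix, sites in rows, subjects in columns. No
#'   missing values are allowed.
#' @param labels Binary group membership per subject, one per column:
#'   1 (or \code{TRUE}, or the second factor level) marks diseased/case
#'   subjects, 0 marks non-diseased/control subjects. Both groups must be
#'   non-empty.
#' @param site_ids Optional character vector of unique site identifiers;
#'   defaults to existing rownames or \code{site_1 ... site_n}.
#' @param subject_ids Optional character vector of subject identifiers;
#'   defaults to existing colnames or \code{subj_1 ...}.
#'
#' @return An object of class \code{"methyl_matrix"}: a list with elements
#'   \code{values} (the matrix, dimnames set), \code{labels} (integer 0/1)
#'   and the two id vectors.
#'
#' @examples
#' x <- matrix(rnorm(40), nrow = 4)
#' mm <- methyl_matrix(x, labels = rep(c(0, 1), each = 5))
#' mm
#' @export
methyl_matrix <- function(values, labels, site_ids = NULL, subject_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (sites x subjects)")
  if (anyNA(values))
    stop("'values' must not contain missing values")
  labels <- normalize_labels(labels)
  if (length(labels) != ncol(values))
    stop("number of labels (", length(labels), ") must equal number of ",
         "subject columns (", ncol(values), ")")
  if (sum(labels == 1L) < 1L || sum(labels == 0L) < 1L)
    stop("both groups must be non-empty")
  if (is.null(site_ids))
    site_ids <- rownames(values) %||% paste0("site_", seq_len(nrow(values)))
  if (is.null(subject_ids))
    subject_ids <- colnames(values) %||% paste0("subj_", seq_len(ncol(values)))
  site_ids <- as.character(site_ids)
  subject_ids <- as.character(subject_ids)
  if (length(site_ids) != nrow(values))
    stop("'site_ids' must have one entry per row")
  if (anyDuplicated(site_ids))
    stop("'site_ids' must be unique")
  if (length(subject_ids) != ncol(values))
    stop("'subject_ids' must have one entry per column")
  dimnames(values) <- list(site_ids, subject_ids)
  structure(
    list(values = values, labels = labels,
         site_ids = site_ids, subject_ids = subject_ids),
    class = "methyl_matrix"
  )
}

# Coerce assorted label encodings (0/1 numeric, logical, 2-level factor or
# character) to integer 0/1 with 1 = diseased.
normalize_labels <- function(labels) {
  if (is.factor(labels) || is.character(labels)) {
    f <- as.factor(labels)
    if (nlevels(f) != 2L)
      stop("'labels' must have exactly two levels, got ", nlevels(f))
    return(as.integer(f) - 1L)
  }
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1)))
      stop("numeric 'labels' must be 0/1")
    return(as.integer(labels))
  }
  stop("unsupported 'labels' type")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.methyl_matrix <- function(x, ...) {
  cat("methyl_matrix: ", nrow(x$values), " sites x ", ncol(x$values),
      " subjects (", sum(x$labels == 1L), " diseased, ",
      sum(x$labels == 0L), " non-diseased)\n", sep = "")
  invisible(x)
}

#' @export
dim.methyl_matrix <- function(x) dim(x$values)

#' Subset a methylation matrix by site
#'
#' @param mm A \code{\link{methyl_matrix}}.
#' @param sites Character vector of site ids (all must be present) or a
#'   logical/integer row index.
#' @return A \code{methyl_matrix} restricted to the requested sites.
#' @export
subset_sites <- function(mm, sites) {
  stopifnot(inherits(mm, "methyl_matrix"))
  if (is.character(sites)) {
    missing <- setdiff(sites, mm$site_ids)
    if (length(missing))
      stop("sites absent from matrix: ", paste(missing, collapse = ", "))
    idx <- match(sites, mm$site_ids)
  } else {
    idx <- sites
  }
  methyl_matrix(mm$values[idx, , drop = FALSE], mm$labels,
                site_ids = mm$site_ids[idx], subject_ids = mm$subject_ids)
}

# Split the value matrix into the diseased (label 1) and non-diseased
# (label 0) column blocks; used by every vectorised test.
group_split <- function(mm) {
  list(d = mm$values[, mm$labels == 1L, drop = FALSE],
       n = mm$values[, mm$labels == 0L, drop = FALSE])
}
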