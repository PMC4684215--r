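# Readers and writers for the delimited matrix + phenotype format, the
# beta/M transform, and the result-table serialisation.

sniff_sep <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl("\t", line)) "\t" else ","
}

#' Read a methylation matrix and its phenotype file
#'
#' The matrix file is delimited text with a site-id first column and a
#' subject-id header; the phenotype file has columns \code{subject_id} and
#' \code{group} (binary). Tab and comma delimiters are auto-detected.
#' Sites containing any missing value are dropped with a reported count.
#'
#' @param path Matrix file path.
#' @param phenotype_path Phenotype file path.
#' @param sep Field separator; \code{NULL} (default) sniffs tab vs comma.
#' @return A \code{\link{methyl_matrix}}; the number of dropped sites is
#'   attached as \code{attr(, "n_dropped")}.
#' @export
read_methyl_matrix <- function(path, phenotype_path, sep = NULL) {
  sep <- sep %||% sniff_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("matrix file needs a site-id column plus data")
  site_ids <- as.character(tab[[1L]])
  if (anyDuplicated(site_ids))
    stop("duplicate site ids in matrix file: ",
         paste(unique(site_ids[duplicated(site_ids)]), collapse = ", "))
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric cells in matrix file")
  keep <- !apply(is.na(vals), 1L, any)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L)
    message("dropped ", n_dropped, " site(s) with missing values")
  vals <- vals[keep, , drop = FALSE]
  site_ids <- site_ids[keep]

  phen_sep <- sep %||% sniff_sep(phenotype_path)
  phen <- utils::read.table(phenotype_path, header = TRUE, sep = phen_sep,
                            stringsAsFactors = FALSE)
  if (!all(c("subject_id", "group") %in% names(phen)))
    stop("phenotype file must have columns 'subject_id' and 'group'")
  subj <- colnames(vals)
  missing_m <- setdiff(phen$subject_id, subj)
  if (length(missing_m))
    stop("phenotype subject(s) absent from matrix: ",
         paste(missing_m, collapse = ", "))
  missing_p <- setdiff(subj, phen$subject_id)
  if (length(missing_p))
    stop("matrix subject(s) absent from phenotype: ",
         paste(missing_p, collapse = ", "))
  labels <- phen$group[match(subj, phen$subject_id)]
  mm <- methyl_matrix(vals, labels, site_ids = site_ids, subject_ids = subj)
  attr(mm, "n_dropped") <- n_dropped
  mm
}

#' Write a methylation matrix and phenotype file
#'
#' @param mm A \code{\link{methyl_matrix}}.
#' @param path Matrix output path (site_id first column, subject header).
#' @param phenotype_path Phenotype output path (subject_id, group).
#' @param sep Field separator (default tab).
#' @return Invisibly, \code{mm}.
#' @export
write_methyl_matrix <- function(mm, path, phenotype_path, sep = "\t") {
  stopifnot(inherits(mm, "methyl_matrix"))
  tab <- data.frame(site_id = mm$site_ids, mm$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  phen <- data.frame(subject_id = mm$subject_ids, group = mm$labels)
  utils::write.table(phen, phenotype_path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(mm)
}

#' Write a result table as tab-separated text
#'
#' Columns: site_id, test, statistic, df1, df2, p_value, degenerate (and
#' p_adj if present).
#'
#' @param res A result data frame from \code{\link{run_test}}.
#' @param path Output path.
#' @return Invisibly, \code{res}.
#' @export
write_result_table <- function(res, path) {
  utils::write.table(res, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(res)
}

#' Logit (M-value) transform of methylation beta-values
#'
#' M = log2(beta / (1 - beta)); the analysis scale of the hierarchical
#' simulation model.
#'
#' @param beta Values strictly in (0, 1), unless \code{clip} is given.
#' @param clip Optional small positive bound: betas are clipped into
#'   [clip, 1 - clip] before transforming (off by default; boundary values
#'   are an error).
#' @return M-values.
#' @examples
#' beta_to_m(0.8)  # 2
#' @export
beta_to_m <- function(beta, clip = NULL) {
  if (!is.null(clip)) {
    stopifnot(clip > 0, clip < 0.5)
    beta <- pmin(pmax(beta, clip), 1 - clip)
  } else if (any(beta <= 0 | beta >= 1)) {
    stop("'beta' must lie strictly in (0, 1); use 'clip' for boundary values")
  }
  log2(beta / (1 - beta))
}

#' Inverse of \code{\link{beta_to_m}}
#'
#' @param m M-values.
#' @return Beta-values in (0, 1).
#' @export
m_to_beta <- function(m) {
  2^m / (1 + 2^m)
}
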