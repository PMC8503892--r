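#' Read an expression matrix TSV
#'
#' Reads a probes-by-samples tab-separated matrix: an optional metadata
#' line \code{#scale=log2} (or \code{#scale=linear}), then a header row of
#' sample ids, then one row per probe (probe id in the first column).
#' An optional two-column label file (sample id, entity) attaches entity
#' labels to the samples.
#'
#' @param path path to the matrix TSV.
#' @param labelsPath optional path to a two-column (sample, entity) TSV.
#' @param scale scale to assume when the file carries no metadata line.
#' @return an \linkS4class{ExpressionCohort}.
#' @export
readExpressionMatrix <- function(path, labelsPath = NULL,
                                 scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  first <- readLines(path, n = 1L)
  skip <- 0L
  if (startsWith(first, "#")) {
    skip <- 1L
    m <- regmatches(first, regexec("^#\\s*scale\\s*=\\s*(linear|log2)", first))[[1L]]
    if (length(m) == 2L) scale <- m[2L]
  }
  df <- utils::read.delim(path, skip = skip, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  probes <- as.character(df[[1L]])
  if (anyDuplicated(probes)) {
    stop("duplicate probe id: ", probes[duplicated(probes)][1L])
  }
  values <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(values)) stop("non-numeric expression values in ", path)
  rownames(values) <- probes
  labels <- NULL
  if (!is.null(labelsPath)) {
    lab <- utils::read.delim(labelsPath, header = FALSE,
                             stringsAsFactors = FALSE)
    labels <- stats::setNames(as.character(lab[[2L]]), as.character(lab[[1L]]))
  }
  ExpressionCohort(values, scale = scale, labels = labels)
}

#' Write an expression matrix TSV
#'
#' @param cohort an \linkS4class{ExpressionCohort}.
#' @param path output TSV path (a \code{#scale=} metadata line is written).
#' @param labelsPath optional path for the two-column label file.
#' @return invisibly, \code{path}.
#' @export
writeExpressionMatrix <- function(cohort, path, labelsPath = NULL) {
  v <- assay(cohort, "exprs")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#scale=", exprScale(cohort)), con)
  writeLines(paste(c("probe_id", colnames(v)), collapse = "\t"), con)
  utils::write.table(v, con, sep = "\t", quote = FALSE,
                     col.names = FALSE, row.names = TRUE)
  lab <- entityLabels(cohort)
  if (!is.null(labelsPath) && !is.null(lab)) {
    utils::write.table(data.frame(names(lab), unname(lab)), labelsPath,
                       sep = "\t", quote = FALSE,
                       col.names = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read / write group-assignment reports
#'
#' Assignment reports are TSVs with columns \code{sample_id}, \code{label},
#' \code{score} and \code{evidence}, as produced by the classification
#' functions.
#'
#' @param path report path.
#' @return \code{readAssignments}: a \code{data.frame} of assignments.
#' @export
readAssignments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "label")
  if (!all(need %in% names(df))) {
    stop("assignment report must carry columns ", paste(need, collapse = ", "))
  }
  if (is.null(df$score)) df$score <- NA_real_
  if (is.null(df$evidence)) df$evidence <- ""
  df
}

#' @rdname readAssignments
#' @param assignments a \code{data.frame} of assignments.
#' @export
writeAssignments <- function(assignments, path) {
  utils::write.table(assignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
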