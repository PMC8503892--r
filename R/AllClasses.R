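#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData colData<-
NULL

.CODE_CLASSES <- c("Positive", "Negative", "Housekeeping", "Endogenous")

#' RccLane: one NanoString nCounter lane
#'
#' In-memory representation of a single RCC lane file: the code-class-tagged
#' probe counts of the \code{Code_Summary} section together with the
#' instrument attributes (header, sample and lane attribute sections).
#'
#' @slot laneId character(1), lane identifier (cartridge/lane).
#' @slot sampleName character(1), sample identifier of the lane.
#' @slot codeSummary \code{data.frame} with columns \code{codeClass}
#'   (one of Positive, Negative, Housekeeping, Endogenous), \code{name},
#'   \code{accession} and integer \code{count}.
#' @slot attributes named character vector of instrument attributes; names
#'   are prefixed with their RCC section (e.g. \code{Lane_Attributes.ID}),
#'   order preserved from the file.
#'
#' @seealso [readRcc()], [writeRcc()], [positiveControlNormalize()]
#' @export
setClass("RccLane",
  representation(
    laneId = "character",
    sampleName = "character",
    codeSummary = "data.frame",
    attributes = "character"
  )
)

setValidity("RccLane", function(object) {
  cs <- object@codeSummary
  msg <- character()
  need <- c("codeClass", "name", "accession", "count")
  if (!all(need %in% names(cs))) {
    return(paste("codeSummary must have columns", paste(need, collapse = ", ")))
  }
  if (length(object@laneId) != 1L || length(object@sampleName) != 1L) {
    msg <- c(msg, "laneId and sampleName must be length 1")
  }
  if (!all(cs$codeClass %in% .CODE_CLASSES)) {
    msg <- c(msg, paste("unknown code class:",
                        paste(setdiff(unique(cs$codeClass), .CODE_CLASSES), collapse = ", ")))
  }
  bad <- !is.finite(cs$count) | cs$count < 0 | cs$count != round(cs$count)
  if (any(bad)) {
    msg <- c(msg, paste0("counts must be non-negative integers (offending gene: ",
                         cs$name[which(bad)[1L]], ")"))
  }
  if (anyDuplicated(cs$name)) {
    msg <- c(msg, paste0("duplicated gene name: ", cs$name[duplicated(cs$name)][1L]))
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' @describeIn RccLane construct an RccLane from its parts
#' @param laneId,sampleName,codeSummary,attributes see slots.
#' @export
RccLane <- function(laneId, sampleName, codeSummary,
                    attributes = character()) {
  codeSummary$count <- as.integer(codeSummary$count)
  rownames(codeSummary) <- NULL
  if (is.null(names(attributes))) names(attributes) <- character(length(attributes))
  new("RccLane", laneId = as.character(laneId),
      sampleName = as.character(sampleName),
      codeSummary = codeSummary,
      attributes = attributes)
}

#' @describeIn RccLane lane identifier
#' @param object,x an \code{RccLane}
#' @export
setGeneric("laneId", function(object) standardGeneric("laneId"))
#' @rdname RccLane
#' @export
setMethod("laneId", "RccLane", function(object) object@laneId)

#' @describeIn RccLane sample name
#' @export
setGeneric("sampleName", function(object) standardGeneric("sampleName"))
#' @rdname RccLane
#' @export
setMethod("sampleName", "RccLane", function(object) object@sampleName)

#' @describeIn RccLane the Code_Summary table (codeClass, name, accession, count)
#' @export
setGeneric("codeSummary", function(object) standardGeneric("codeSummary"))
#' @rdname RccLane
#' @export
setMethod("codeSummary", "RccLane", function(object) object@codeSummary)

#' @describeIn RccLane instrument attributes (named character vector)
#' @export
setGeneric("rccAttributes", function(object) standardGeneric("rccAttributes"))
#' @rdname RccLane
#' @export
setMethod("rccAttributes", "RccLane", function(object) object@attributes)

setMethod("show", "RccLane", function(object) {
  cs <- object@codeSummary
  cat("RccLane", object@laneId, "sample:", object@sampleName, "\n")
  tab <- table(factor(cs$codeClass, levels = .CODE_CLASSES))
  cat(" ", paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
})

#' ExpressionCohort: a labelled probes-by-samples expression matrix
#'
#' A \linkS4class{SummarizedExperiment} carrying one assay \code{"exprs"}
#' (probes in rows, samples in columns), a scale flag (\code{"linear"} or
#' \code{"log2"}), and optional per-sample entity labels in
#' \code{colData()$entity} (e.g. \code{"EPN_RELA"}, \code{"ATRT"}).
#'
#' @slot scale character(1), \code{"linear"} or \code{"log2"}.
#' @export
setClass("ExpressionCohort",
  contains = "SummarizedExperiment",
  representation(scale = "character")
)

setValidity("ExpressionCohort", function(object) {
  msg <- character()
  if (!identical(length(object@scale), 1L) ||
      !object@scale %in% c("linear", "log2")) {
    msg <- c(msg, "scale must be \"linear\" or \"log2\"")
  }
  if (!"exprs" %in% names(assays(object))) {
    msg <- c(msg, "assay \"exprs\" is required")
  } else {
    v <- assay(object, "exprs")
    if (anyNA(v)) msg <- c(msg, "expression values must not contain NA")
    else if (identical(object@scale, "log2") && any(!is.finite(v))) {
      msg <- c(msg, "log2-scale values must be finite")
    }
  }
  ent <- colData(object)$entity
  if (!is.null(ent) && anyNA(ent)) {
    msg <- c(msg, "entity labels must cover every sample or be absent entirely")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' @describeIn ExpressionCohort construct from a matrix
#' @param values numeric matrix, probes x samples, with dimnames.
#' @param scale \code{"linear"} or \code{"log2"}.
#' @param labels optional named character vector sample -> entity, or NULL.
#' @export
ExpressionCohort <- function(values, scale = c("linear", "log2"),
                             labels = NULL) {
  scale <- match.arg(scale)
  cd <- DataFrame(row.names = colnames(values))
  if (!is.null(labels)) {
    unknown <- setdiff(names(labels), colnames(values))
    if (length(unknown)) {
      stop("labels refer to unknown samples: ", paste(unknown, collapse = ", "))
    }
    if (!all(colnames(values) %in% names(labels))) {
      stop("labels must cover every sample or be absent entirely")
    }
    cd$entity <- unname(labels[colnames(values)])
  }
  se <- SummarizedExperiment(assays = list(exprs = values), colData = cd)
  new("ExpressionCohort", se, scale = scale)
}

#' @describeIn ExpressionCohort the scale flag
#' @param object an \code{ExpressionCohort}
#' @export
setGeneric("exprScale", function(object) standardGeneric("exprScale"))
#' @rdname ExpressionCohort
#' @export
setMethod("exprScale", "ExpressionCohort", function(object) object@scale)

#' @describeIn ExpressionCohort per-sample entity labels (or NULL)
#' @export
setGeneric("entityLabels", function(object) standardGeneric("entityLabels"))
#' @rdname ExpressionCohort
#' @export
setMethod("entityLabels", "ExpressionCohort", function(object) {
  ent <- colData(object)$entity
  if (is.null(ent)) return(NULL)
  stats::setNames(as.character(ent), colnames(object))
})

setMethod("show", "ExpressionCohort", function(object) {
  cat("ExpressionCohort:", nrow(object), "probes x", ncol(object),
      "samples [", object@scale, "]\n")
  ent <- colData(object)$entity
  if (!is.null(ent)) {
    tab <- table(ent)
    cat("  entities:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
})

#' NormalizedCounts: normalized log2 NanoString signature matrix
#'
#' A \linkS4class{SummarizedExperiment} holding the endogenous genes only,
#' after technical (positive-control) and biological (housekeeping)
#' normalization: assay \code{"log2"} is \code{log2(count + 1)} on the
#' normalized scale. Per-sample technical and biological scaling factors
#' and QC flags live in \code{colData()}.
#'
#' @seealso [housekeepingNormalize()], [normalizeNanostring()]
#' @export
setClass("NormalizedCounts", contains = "SummarizedExperiment")

setValidity("NormalizedCounts", function(object) {
  msg <- character()
  cd <- colData(object)
  for (f in c("techFactor", "bioFactor")) {
    if (!f %in% names(cd)) msg <- c(msg, paste("colData column", f, "is required"))
    else if (any(!is.finite(cd[[f]]) | cd[[f]] <= 0)) {
      msg <- c(msg, paste(f, "must be strictly positive"))
    }
  }
  if (!"log2" %in% names(assays(object))) {
    msg <- c(msg, "assay \"log2\" is required")
  } else if (any(!is.finite(assay(object, "log2")))) {
    msg <- c(msg, "log2 values must be finite")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' @describeIn NormalizedCounts per-sample technical normalization factors
#' @param object a \code{NormalizedCounts}
#' @export
setGeneric("techFactors", function(object) standardGeneric("techFactors"))
#' @rdname NormalizedCounts
#' @export
setMethod("techFactors", "NormalizedCounts", function(object) {
  stats::setNames(colData(object)$techFactor, colnames(object))
})

#' @describeIn NormalizedCounts per-sample biological (housekeeping) factors
#' @export
setGeneric("bioFactors", function(object) standardGeneric("bioFactors"))
#' @rdname NormalizedCounts
#' @export
setMethod("bioFactors", "NormalizedCounts", function(object) {
  stats::setNames(colData(object)$bioFactor, colnames(object))
})

#' @describeIn NormalizedCounts per-sample QC flags (";"-separated, "" = clean)
#' @export
setGeneric("qcFlags", function(object) standardGeneric("qcFlags"))
#' @rdname NormalizedCounts
#' @export
setMethod("qcFlags", "NormalizedCounts", function(object) {
  stats::setNames(colData(object)$qcFlags, colnames(object))
})

setMethod("show", "NormalizedCounts", function(object) {
  cat("NormalizedCounts:", nrow(object), "endogenous genes x",
      ncol(object), "samples (log2)\n")
  fl <- colData(object)$qcFlags
  n <- sum(nzchar(fl))
  if (n) cat("  QC-flagged lanes:", n, "\n")
})

#' DendrogramCut: an average-linkage clustering of samples
#'
#' Wraps the \code{\link[stats]{hclust}} merge tree built on Euclidean
#' distances over a gene subset of a normalized matrix, together with the
#' genes and settings used, so that group-assignment functions can cut it
#' reproducibly.
#'
#' @slot tree an \code{hclust} object over the samples.
#' @slot genes character, the genes the distances were computed on.
#' @slot metric,linkage character(1), distance metric and linkage method.
#' @export
setClass("DendrogramCut",
  representation(tree = "ANY", genes = "character",
                 metric = "character", linkage = "character")
)

setValidity("DendrogramCut", function(object) {
  if (!inherits(object@tree, "hclust")) return("tree must be an hclust object")
  TRUE
})

#' @describeIn DendrogramCut cluster membership at k clusters
#' @param object a \code{DendrogramCut}
#' @param k integer number of clusters
#' @export
setGeneric("cutClusters", function(object, k) standardGeneric("cutClusters"))
#' @rdname DendrogramCut
#' @export
setMethod("cutClusters", "DendrogramCut", function(object, k) {
  stats::cutree(object@tree, k = k)
})

setMethod("show", "DendrogramCut", function(object) {
  cat("DendrogramCut:", length(object@tree$labels), "samples,",
      length(object@genes), "genes (", object@metric, "/", object@linkage, ")\n")
})
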