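# assemble a lane batch into one counts matrix (genes x lanes)
.laneBatchMatrix <- function(lanes) {
  stopifnot(length(lanes) >= 1L, all(vapply(lanes, is, TRUE, "RccLane")))
  ref <- codeSummary(lanes[[1L]])
  genes <- ref$name
  counts <- vapply(lanes, function(l) {
    cs <- codeSummary(l)
    if (!setequal(cs$name, genes)) {
      stop("lane ", laneId(l), " does not share the batch codeset")
    }
    cs$count[match(genes, cs$name)]
  }, numeric(length(genes)))
  counts <- matrix(counts, nrow = length(genes),
                   dimnames = list(genes,
                                   vapply(lanes, sampleName, "")))
  list(counts = counts,
       codeClass = stats::setNames(ref$codeClass, genes),
       accession = stats::setNames(ref$accession, genes))
}

# geometric-mean scaling to the batch mean over the `use` gene rows;
# returns scaled counts, per-lane factors and QC flags
.geoMeanScale <- function(counts, use, what, factorBounds = c(0.3, 3)) {
  flags <- rep("", ncol(counts))
  gm <- vapply(seq_len(ncol(counts)), function(j) {
    x <- counts[use, j]
    if (any(x <= 0)) {
      flags[j] <<- paste0("zero-", what)
      x <- x[x > 0]
      if (!length(x)) stop("lane ", colnames(counts)[j],
                           ": all ", what, " counts are zero")
    }
    geomMean(x)
  }, 0)
  factors <- mean(gm) / gm
  flagged <- factors < factorBounds[1] | factors > factorBounds[2]
  flags[flagged] <- trimws(paste(flags[flagged],
                                 paste0(what, "-factor-out-of-range")))
  list(counts = sweep(counts, 2, factors, `*`),
       factors = stats::setNames(factors, colnames(counts)),
       flags = stats::setNames(flags, colnames(counts)))
}

#' Positive-control (technical) normalization
#'
#' Scales every lane so the geometric means of its positive-control counts
#' agree across the batch: lane factor = (arithmetic mean over lanes of the
#' per-lane geometric mean of positive controls) / (this lane's geometric
#' mean); all counts in the lane are multiplied by the factor. Lanes with a
#' zero positive control are QC-flagged and their factor computed from the
#' nonzero positives; factors outside \code{factorBounds} flag the lane
#' (flag, not drop).
#'
#' @param lanes a list of \linkS4class{RccLane} sharing one codeset; every
#'   lane needs at least two positive-control records.
#' @param factorBounds conventional QC bounds on the technical factor.
#' @return a list with \code{counts} (genes x lanes, technically
#'   normalized, all code classes), \code{codeClass}, \code{techFactors}
#'   and \code{qcFlags}.
#' @seealso [housekeepingNormalize()], [normalizeNanostring()]
#' @export
positiveControlNormalize <- function(lanes, factorBounds = c(0.3, 3)) {
  batch <- .laneBatchMatrix(lanes)
  pos <- batch$codeClass == "Positive"
  if (sum(pos) < 2L) stop("normalization needs >= 2 positive-control probes")
  sc <- .geoMeanScale(batch$counts, pos, "positive-control", factorBounds)
  list(counts = sc$counts, codeClass = batch$codeClass,
       techFactors = sc$factors, qcFlags = sc$flags)
}

#' Housekeeping (biological) normalization
#'
#' Applies the same geometric-mean scaling using the housekeeping genes to
#' technically normalized counts, then drops control and housekeeping
#' records and log2-transforms the endogenous genes with pseudocount 1.
#'
#' @param pcNorm output of [positiveControlNormalize()].
#' @param hkGenes housekeeping gene names; all must be present with
#'   positive counts in every lane.
#' @param factorBounds QC bounds on the biological factor.
#' @return a \linkS4class{NormalizedCounts}.
#' @export
housekeepingNormalize <- function(pcNorm, hkGenes = c("ACTB", "GAPDH", "TBP"),
                                  factorBounds = c(0.3, 3)) {
  counts <- pcNorm$counts
  miss <- setdiff(hkGenes, rownames(counts))
  if (length(miss)) {
    stop("housekeeping gene(s) missing from the codeset: ",
         paste(miss, collapse = ", "))
  }
  zero <- colSums(counts[hkGenes, , drop = FALSE] <= 0) > 0
  if (any(zero)) {
    stop("non-positive housekeeping count in lane ",
         colnames(counts)[which(zero)[1L]])
  }
  sc <- .geoMeanScale(counts, rownames(counts) %in% hkGenes,
                      "housekeeping", factorBounds)
  endo <- pcNorm$codeClass[rownames(counts)] == "Endogenous"
  log2v <- log2(sc$counts[endo, , drop = FALSE] + 1)
  flags <- trimws(paste(pcNorm$qcFlags, sc$flags))
  cd <- DataFrame(techFactor = unname(pcNorm$techFactors),
                  bioFactor = unname(sc$factors),
                  qcFlags = unname(flags),
                  row.names = colnames(counts))
  new("NormalizedCounts",
      SummarizedExperiment(assays = list(log2 = log2v), colData = cd))
}

#' One-step NanoString normalization
#'
#' Composes [positiveControlNormalize()] and [housekeepingNormalize()]:
#' the technical/biological normalization applied to a batch of RCC lanes
#' before clustering.
#'
#' @inheritParams positiveControlNormalize
#' @inheritParams housekeepingNormalize
#' @return a \linkS4class{NormalizedCounts}.
#' @examples
#' lanes <- simulateNanostringRun(nanoDesign(c(PFA = 4, PFB = 3), seed = 5))
#' norm <- normalizeNanostring(lanes)
#' techFactors(norm)
#' @export
normalizeNanostring <- function(lanes, hkGenes = c("ACTB", "GAPDH", "TBP"),
                                factorBounds = c(0.3, 3)) {
  housekeepingNormalize(positiveControlNormalize(lanes, factorBounds),
                        hkGenes = hkGenes, factorBounds = factorBounds)
}
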