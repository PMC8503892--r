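#' Signature gene panels
#'
#' The marker-gene panels used for group assignment, after probe-level QC
#' (DRD1, uniformly low, and ANGPTL6, nonspecific between the reference
#' samples, are excluded). Supratentorial ("ST"): RELA+ and YAP1+;
#' posterior fossa ("PF"): PFA and PFB; PFA subgrouping ("PFA_SUB"): PFA1
#' and PFA2. The six-gene CNS HGNET-MN1 panel is not published and ships
#' empty; supply it via \code{mn1Genes} when needed.
#'
#' @param compartment which panel to return: \code{"ST"}, \code{"PF"},
#'   \code{"PFA_SUB"} or \code{"ALL"}.
#' @param mn1Genes optional character vector of CNS HGNET-MN1 signature
#'   genes to include in the supratentorial panel.
#' @return named list, group -> character vector of signature genes. No
#'   gene appears in two groups of the same compartment.
#' @export
signaturePanel <- function(compartment = c("ALL", "ST", "PF", "PFA_SUB"),
                           mn1Genes = character()) {
  compartment <- match.arg(compartment)
  st <- list(
    "RELA+" = c("RELA", "ELL3", "FBP2", "PCP4L1", "MYO3A"),
    "YAP1+" = c("MRAP", "IGF1", "CAPS", "WWC1")
  )
  if (length(mn1Genes)) st[["MN1"]] <- mn1Genes
  pf <- list(
    PFA = c("LAMA2", "ALDH1L1", "SLC6A13", "IGSF1", "CXorf67"),
    PFB = c("NELL2", "DNAH1", "CEP83", "C9orf72", "NXNL2")
  )
  sub <- list(
    PFA1 = c("SKAP2", "WIF1"),
    PFA2 = c("EN2", "CNPY1")
  )
  switch(compartment,
         ST = st, PF = pf, PFA_SUB = sub,
         ALL = c(st, pf, sub))
}

# per-gene z-scores across the batch (log2 scale); constant genes get z = 0
.batchZ <- function(log2v) {
  m <- rowMeans(log2v)
  s <- sqrt(rowVars(log2v))
  s[s == 0] <- Inf
  (log2v - m) / s
}

# mean z-score of a gene set per sample
.signatureZ <- function(log2v, genes) {
  miss <- setdiff(genes, rownames(log2v))
  if (length(miss)) {
    stop("signature gene(s) absent from the matrix: ",
         paste(miss, collapse = ", "))
  }
  colMeans(.batchZ(log2v)[genes, , drop = FALSE])
}

# mean log2 expression of a gene set per sample
.signatureMean <- function(log2v, genes) {
  miss <- setdiff(genes, rownames(log2v))
  if (length(miss)) {
    stop("signature gene(s) absent from the matrix: ",
         paste(miss, collapse = ", "))
  }
  colMeans(log2v[genes, , drop = FALSE])
}

.assignmentFrame <- function(sample_id, label, score, evidence) {
  data.frame(sample_id = sample_id, label = label,
             score = unname(score), evidence = evidence,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Hierarchical clustering of samples over a gene subset
#'
#' Agglomerative average-linkage clustering on Euclidean distances between
#' samples, computed on the log2 normalized values of the given genes —
#' the clustering settings used throughout the group assignment.
#'
#' @param norm a \linkS4class{NormalizedCounts} (>= 2 samples).
#' @param genes genes to compute distances on; all must be present.
#' @return a \linkS4class{DendrogramCut}.
#' @export
clusterSamples <- function(norm, genes = rownames(norm)) {
  stopifnot(is(norm, "NormalizedCounts"), ncol(norm) >= 2L)
  v <- assay(norm, "log2")
  miss <- setdiff(genes, rownames(v))
  if (length(miss)) {
    stop("gene(s) absent from the matrix: ", paste(miss, collapse = ", "))
  }
  tree <- stats::hclust(stats::dist(t(v[genes, , drop = FALSE]),
                                    method = "euclidean"),
                        method = "average")
  new("DendrogramCut", tree = tree, genes = genes,
      metric = "euclidean", linkage = "average")
}

#' Reference-anchored group assignment (supratentorial workflow)
#'
#' Cuts the dendrogram into \code{k} clusters and labels each cluster by
#' the molecularly confirmed reference sample(s) it contains: a cluster
#' whose references all share one group takes that group's label; clusters
#' with conflicting references are not classified (NC). Clusters without a
#' reference are rescued by signature score: if the cluster's mean
#' signature z-score exceeds \code{zMin} for exactly the panel's strongest
#' group (the YAP1+ singleton case), it takes that label, otherwise NC.
#'
#' @param cut a \linkS4class{DendrogramCut} from [clusterSamples()].
#' @param norm the \linkS4class{NormalizedCounts} the cut was built on.
#' @param references named character vector, sample id -> group label
#'   (use \code{"NC"} for a fusion-negative reference).
#' @param k number of clusters; default = number of distinct non-NC
#'   reference groups + 2 (one NC cluster, one potential singleton).
#' @param panel signature panel for the score rescue.
#' @param zMin z-score threshold for labelling an unreferenced cluster.
#' @return a \code{data.frame} of assignments (\code{sample_id},
#'   \code{label}, \code{score} = mean signature z of the assigned group
#'   (NA for NC), \code{evidence}).
#' @export
assignByReference <- function(cut, norm, references, k = NULL,
                              panel = signaturePanel("ST"), zMin = 2) {
  stopifnot(is(cut, "DendrogramCut"), is(norm, "NormalizedCounts"))
  samples <- cut@tree$labels
  miss <- setdiff(names(references), samples)
  if (length(miss)) {
    stop("reference sample(s) not in the batch: ", paste(miss, collapse = ", "))
  }
  if (is.null(k)) {
    k <- length(setdiff(unique(references), "NC")) + 2L
  }
  k <- min(k, length(samples))
  v <- assay(norm, "log2")
  z <- lapply(panel, function(g) .signatureZ(v, g))

  member <- cutClusters(cut, k)
  labels <- scores <- evid <- stats::setNames(rep(NA_character_, length(samples)), samples)
  scores <- stats::setNames(rep(NA_real_, length(samples)), samples)

  for (cl in unique(member)) {
    inCl <- samples[member == cl]
    refs <- references[intersect(names(references), inCl)]
    refGroups <- unique(refs)
    if (length(refGroups) == 1L) {
      labels[inCl] <- refGroups
      evid[inCl] <- paste0("co-clustered with reference ",
                           paste(names(refs), collapse = ","))
    } else if (length(refGroups) > 1L) {
      labels[inCl] <- "NC"
      evid[inCl] <- paste0("conflicting references: ",
                           paste(refGroups, collapse = ","))
    } else {
      zCl <- vapply(z, function(zz) mean(zz[inCl]), 0)
      best <- which.max(zCl)
      if (length(zCl) && zCl[best] > zMin) {
        labels[inCl] <- names(z)[best]
        evid[inCl] <- "score-rule"
      } else {
        labels[inCl] <- "NC"
        evid[inCl] <- "no reference, no signature"
      }
    }
    lab <- labels[inCl][1L]
    if (lab %in% names(z)) scores[inCl] <- z[[lab]][inCl]
  }
  .assignmentFrame(samples, unname(labels[samples]), scores[samples],
                   unname(evid[samples]))
}

#' PFA/PFB assignment with outlier detection
#'
#' Posterior-fossa workflow: per-sample PFA and PFB signature scores (mean
#' log2 of each group's genes) are each dichotomized by an exact two-level
#' variance-minimizing split (accepted only when the split gap is at least
#' \code{minGap} log2 units, so homogeneous batches are not split on
#' noise). Samples negative for both signatures are outliers and are set
#' aside; the remaining samples are cut into two average-linkage clusters
#' over the ten signature genes and the cluster with the higher mean
#' PFA-minus-PFB score is labelled PFA, the other PFB.
#'
#' @param norm a \linkS4class{NormalizedCounts} with >= 3 samples.
#' @param panel posterior-fossa signature panel (groups PFA and PFB).
#' @param minGap minimum accepted split gap (log2 units).
#' @return assignments with labels \code{PFA}, \code{PFB} or
#'   \code{outlier}; \code{score} is the mean signature z of the assigned
#'   group.
#' @export
assignPf <- function(norm, panel = signaturePanel("PF"), minGap = 1) {
  stopifnot(is(norm, "NormalizedCounts"), ncol(norm) >= 3L,
            all(c("PFA", "PFB") %in% names(panel)))
  v <- assay(norm, "log2")
  samples <- colnames(v)
  genes <- c(panel$PFA, panel$PFB)
  miss <- setdiff(genes, rownames(v))
  if (length(miss)) {
    stop("signature gene(s) absent from the matrix: ",
         paste(miss, collapse = ", "))
  }
  if (all(rowVars(v[genes, , drop = FALSE]) == 0)) {
    warning("degenerate (all-equal) matrix; every sample is an outlier")
    return(.assignmentFrame(samples, "outlier", NA_real_, "degenerate matrix"))
  }
  sA <- .signatureMean(v, panel$PFA)
  sB <- .signatureMean(v, panel$PFB)
  zA <- .signatureZ(v, panel$PFA)
  zB <- .signatureZ(v, panel$PFB)

  posFor <- function(s) {
    sp <- splitTwoLevels(s)
    if (is.null(sp) || sp$gap < minGap) rep(TRUE, length(s)) else sp$high
  }
  outlier <- !posFor(sA) & !posFor(sB)

  labels <- stats::setNames(rep("outlier", length(samples)), samples)
  keep <- samples[!outlier]
  if (length(keep) >= 2L) {
    cutK <- clusterSamples(norm[, keep], genes)
    member <- cutClusters(cutK, k = 2L)
    diffByCl <- tapply((sA - sB)[keep], member[keep], mean)
    pfaCl <- names(diffByCl)[which.max(diffByCl)]
    labels[keep] <- ifelse(member[keep] == as.integer(pfaCl), "PFA", "PFB")
  } else if (length(keep) == 1L) {
    labels[keep] <- if (sA[keep] >= sB[keep]) "PFA" else "PFB"
  }
  score <- ifelse(labels == "PFA", zA, ifelse(labels == "PFB", zB, NA_real_))
  .assignmentFrame(samples, unname(labels), score[samples], "score-rule")
}

#' PFA1/PFA2 subgrouping
#'
#' Re-clusters PFA-labelled samples on the four subgroup genes (SKAP2/WIF1
#' versus EN2/CNPY1) into two clusters, labelled by the higher mean
#' PFA1-minus-PFA2 score. If fewer than three PFA samples are supplied, or
#' the subgroup genes carry no usable contrast (cluster separation below
#' \code{minGap}), the assignment is refused and samples stay PFA.
#'
#' @param norm a \linkS4class{NormalizedCounts} restricted to PFA samples.
#' @param panel subgroup panel (groups PFA1 and PFA2).
#' @param minGap minimum separation (log2 units) between the two clusters'
#'   mean score difference for the subdivision to be accepted.
#' @return assignments with labels \code{PFA1}/\code{PFA2} (or \code{PFA}
#'   when refused).
#' @export
assignPfaSubgroup <- function(norm, panel = signaturePanel("PFA_SUB"),
                              minGap = 1) {
  stopifnot(is(norm, "NormalizedCounts"),
            all(c("PFA1", "PFA2") %in% names(panel)))
  v <- assay(norm, "log2")
  samples <- colnames(v)
  if (length(samples) < 3L) {
    warning("fewer than 3 PFA samples; subgrouping refused")
    return(.assignmentFrame(samples, "PFA", NA_real_, "too few samples"))
  }
  genes <- c(panel$PFA1, panel$PFA2)
  d <- .signatureMean(v, panel$PFA1) - .signatureMean(v, panel$PFA2)
  cutK <- clusterSamples(norm, genes)
  member <- cutClusters(cutK, k = 2L)
  dByCl <- tapply(d, member, mean)
  if (length(dByCl) < 2L || abs(diff(range(dByCl))) < minGap) {
    warning("no usable PFA1/PFA2 contrast; samples stay PFA")
    return(.assignmentFrame(samples, "PFA", NA_real_, "no contrast"))
  }
  pfa1Cl <- names(dByCl)[which.max(dByCl)]
  labels <- ifelse(member == as.integer(pfa1Cl), "PFA1", "PFA2")
  z1 <- .signatureZ(v, panel$PFA1)
  z2 <- .signatureZ(v, panel$PFA2)
  score <- ifelse(labels == "PFA1", z1, z2)
  .assignmentFrame(samples, labels, score, "score-rule")
}

#' NELL2/LAMA2 expression trichotomy
#'
#' Dichotomizes each of the two marker genes into positive/negative by an
#' exact two-level variance-minimizing split of its log2 values and
#' composes the labels: \code{NELL2+/LAMA2-}, \code{NELL2+/LAMA2+} and
#' \code{NELL2-/LAMA2+}; the double-negative combination is an
#' \code{outlier}.
#'
#' @param norm a \linkS4class{NormalizedCounts} carrying both genes.
#' @param genes the two genes, in (NELL2, LAMA2) order.
#' @return assignments; \code{score} is the mean of the two genes'
#'   batch z-scores.
#' @export
classifyNell2Lama2 <- function(norm, genes = c("NELL2", "LAMA2")) {
  stopifnot(is(norm, "NormalizedCounts"), length(genes) == 2L)
  v <- assay(norm, "log2")
  miss <- setdiff(genes, rownames(v))
  if (length(miss)) {
    stop("gene(s) absent from the matrix: ", paste(miss, collapse = ", "))
  }
  split <- lapply(genes, function(g) {
    sp <- splitTwoLevels(v[g, ])
    if (is.null(sp)) stop("gene ", g, " has all-equal values; no split")
    sp$high
  })
  nell2 <- split[[1L]]
  lama2 <- split[[2L]]
  labels <- ifelse(nell2 & !lama2, "NELL2+/LAMA2-",
            ifelse(nell2 & lama2, "NELL2+/LAMA2+",
            ifelse(!nell2 & lama2, "NELL2-/LAMA2+", "outlier")))
  z <- .batchZ(v)[genes, , drop = FALSE]
  .assignmentFrame(colnames(v), labels, colMeans(z), "score-rule")
}
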