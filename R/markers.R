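#' Quantile normalization
#'
#' Forces every sample column to the same value distribution: each column's
#' rank r is replaced by the mean over columns of the r-th smallest value;
#' ties within a column receive the mean of their ranks' reference values.
#' Delegates to \code{limma::normalizeQuantiles(ties = TRUE)}.
#'
#' @param cohort an \linkS4class{ExpressionCohort} (any scale).
#' @return an \linkS4class{ExpressionCohort} on the same scale; with a
#'   single sample the input is returned unchanged with a warning.
#' @export
quantileNormalize <- function(cohort) {
  stopifnot(is(cohort, "ExpressionCohort"))
  if (ncol(cohort) < 2L) {
    warning("quantile normalization needs >= 2 samples; returning input")
    return(cohort)
  }
  v <- limma::normalizeQuantiles(assay(cohort, "exprs"), ties = TRUE)
  dimnames(v) <- dimnames(assay(cohort, "exprs"))
  ExpressionCohort(v, scale = exprScale(cohort),
                   labels = entityLabels(cohort))
}

#' Log2-transform a linear-scale cohort
#'
#' @param cohort a linear-scale \linkS4class{ExpressionCohort}.
#' @param pseudocount added before taking logs (default 0; microarray
#'   intensities are strictly positive).
#' @return the cohort on the log2 scale.
#' @export
log2Transform <- function(cohort, pseudocount = 0) {
  stopifnot(is(cohort, "ExpressionCohort"))
  if (identical(exprScale(cohort), "log2")) return(cohort)
  ExpressionCohort(log2(assay(cohort, "exprs") + pseudocount),
                   scale = "log2", labels = entityLabels(cohort))
}

#' Variance filter
#'
#' Removes the least variable probes: retains exactly the probes whose
#' sample variance is at or above \code{threshold}, preserving order.
#'
#' @param cohort a log2-scale \linkS4class{ExpressionCohort}.
#' @param threshold variance threshold (log2 units squared).
#' @return the filtered cohort.
#' @export
varianceFilter <- function(cohort, threshold = 0.25) {
  stopifnot(is(cohort, "ExpressionCohort"))
  if (!identical(exprScale(cohort), "log2")) {
    stop("variance filtering operates on log2-scale data")
  }
  keep <- rowVars(assay(cohort, "exprs")) >= threshold
  if (!any(keep)) {
    stop("variance filter removed every probe; lower the threshold (",
         threshold, ")")
  }
  cohort[keep, ]
}

#' Resampled Student t-test marker scores
#'
#' The marker-discovery statistic: the target entity's samples are compared
#' \code{nIterations} times against an equal-sized set drawn without
#' replacement from the pooled samples of all other entities. Per probe and
#' iteration a two-sided Student (equal-variance) t-test p-value and a
#' linear fold change \code{2^(mean_target - mean_drawn)} are computed; the
#' per-probe arithmetic means of p and fold over iterations (and the
#' maximum fold) are reported, with \code{significance_rank} ordering
#' probes by ascending mean p (ties broken by larger mean fold, then probe
#' id).
#'
#' @param cohort a log2-scale, entity-labelled
#'   \linkS4class{ExpressionCohort}.
#' @param targetEntity the entity whose markers are sought (>= 2 samples).
#' @param nIterations number of resampled comparisons (default 100).
#' @param seed integer seed for the draws.
#' @param welch use Welch's unequal-variance t-test instead of Student's.
#' @return a \code{data.frame} with columns \code{probe_id}, \code{mean_p},
#'   \code{mean_fold}, \code{max_fold}, \code{significance_rank}, ordered
#'   by rank.
#' @seealso [selectMarkers()]
#' @export
resampledTTestScores <- function(cohort, targetEntity, nIterations = 100L,
                                 seed = 1L, welch = FALSE) {
  stopifnot(is(cohort, "ExpressionCohort"))
  if (!identical(exprScale(cohort), "log2")) {
    stop("marker scoring operates on log2-scale data")
  }
  labels <- entityLabels(cohort)
  if (is.null(labels)) stop("cohort carries no entity labels")
  v <- assay(cohort, "exprs")
  # canonical sample order so scores are invariant to input permutations
  v <- v[, order(colnames(v)), drop = FALSE]
  labels <- labels[colnames(v)]
  tgt <- which(labels == targetEntity)
  pool <- which(labels != targetEntity)
  t_ <- length(tgt)
  if (t_ < 2L) stop("target entity needs >= 2 samples, has ", t_)
  if (length(pool) < t_) {
    stop("pooled non-target samples (", length(pool),
         ") fewer than target size (", t_, "); no replacement fallback")
  }
  x <- v[, tgt, drop = FALSE]
  mx <- rowMeans(x)
  vx <- rowVars(x)

  pSum <- foldSum <- numeric(nrow(v))
  foldMax <- rep(-Inf, nrow(v))
  withSeed(seed, {
    for (it in seq_len(nIterations)) {
      y <- v[, sample(pool, t_), drop = FALSE]
      my <- rowMeans(y)
      vy <- rowVars(y)
      if (welch) {
        se2 <- vx / t_ + vy / t_
        df <- se2^2 / ((vx / t_)^2 / (t_ - 1) + (vy / t_)^2 / (t_ - 1))
      } else {
        se2 <- (vx + vy) * ((t_ - 1) / (2 * t_ - 2)) * (2 / t_)
        df <- 2 * t_ - 2
      }
      tstat <- (mx - my) / sqrt(se2)
      p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
      p[!is.finite(tstat)] <- 1   # zero-variance, equal-mean probes
      fold <- 2^(mx - my)
      pSum <- pSum + p
      foldSum <- foldSum + fold
      foldMax <- pmax(foldMax, fold)
    }
  })
  scores <- data.frame(
    probe_id = rownames(v),
    mean_p = pSum / nIterations,
    mean_fold = foldSum / nIterations,
    max_fold = foldMax,
    stringsAsFactors = FALSE
  )
  o <- order(scores$mean_p, -scores$mean_fold, scores$probe_id)
  scores <- scores[o, ]
  scores$significance_rank <- seq_len(nrow(scores))
  rownames(scores) <- NULL
  scores
}

#' Marker selection rule
#'
#' Selects candidate marker probes from resampled t-test scores: at least a
#' \code{minFold}-fold mean increase and a significance rank within the top
#' \code{maxRank} positions, ordered by descending mean fold.
#'
#' @param scores a score table from [resampledTTestScores()].
#' @param minFold minimum mean linear fold change (default 5).
#' @param maxRank maximum significance rank (default 20).
#' @return character vector of selected probe ids (possibly empty).
#' @export
selectMarkers <- function(scores, minFold = 5, maxRank = 20L) {
  stopifnot(all(c("probe_id", "mean_fold", "significance_rank") %in%
                  names(scores)), minFold > 0, maxRank >= 1)
  sel <- scores[scores$mean_fold >= minFold &
                  scores$significance_rank <= maxRank, , drop = FALSE]
  sel$probe_id[order(-sel$mean_fold)]
}
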