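test_that("quantile normalization matches the rank-mean oracle and its defining properties", {
  v <- cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
  rownames(v) <- paste0("p", 1:3)
  qn <- quantileNormalize(ExpressionCohort(v, scale = "linear"))
  expect_equal(unname(SummarizedExperiment::assay(qn)),
               cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))

  # already-identical columns are a fixed point
  w <- cbind(a = c(5, 1, 9), b = c(5, 1, 9))
  rownames(w) <- paste0("p", 1:3)
  qw <- quantileNormalize(ExpressionCohort(w, scale = "linear"))
  expect_equal(SummarizedExperiment::assay(qw), w)

  # any input: sorted columns identical afterwards; idempotent; rank order kept
  set.seed(42)
  r <- matrix(rexp(60), nrow = 10,
              dimnames = list(paste0("p", 1:10), paste0("s", 1:6)))
  q <- quantileNormalize(ExpressionCohort(r, scale = "linear"))
  qv <- SummarizedExperiment::assay(q)
  sorted <- apply(qv, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  expect_equal(SummarizedExperiment::assay(quantileNormalize(q)), qv)
  expect_equal(apply(qv, 2, rank), apply(r, 2, rank))

  expect_warning(quantileNormalize(
    ExpressionCohort(r[, 1, drop = FALSE], scale = "linear")), ">= 2 samples")
})

test_that("variance filter keeps exactly the probes at or above threshold", {
  v <- rbind(const = c(3, 3, 3, 3),
             lowvar = c(0, 0.5, 0, 0.5),
             half = c(0, 1, 0, 1),     # variance 1/3
             big = c(0, 4, 0, 4))
  colnames(v) <- paste0("s", 1:4)
  co <- ExpressionCohort(v, scale = "log2")
  kept <- rownames(varianceFilter(co, 0.25))
  expect_equal(kept, c("half", "big"))

  # two-sample probe with values {0,1}: variance 0.5, retained at 0.25
  v2 <- rbind(p = c(0, 1))
  colnames(v2) <- c("a", "b")
  expect_equal(nrow(varianceFilter(ExpressionCohort(v2, scale = "log2"),
                                   0.25)), 1L)

  expect_equal(rownames(varianceFilter(co, 0)), rownames(v))  # identity
  expect_error(varianceFilter(co, 1e6), "lower the threshold")
  expect_error(varianceFilter(ExpressionCohort(2^v, scale = "linear"), 0.25),
               "log2")
})

test_that("degenerate resampling equals a plain Student t-test", {
  set.seed(3)
  v <- matrix(rnorm(30 * 8, 6), nrow = 30,
              dimnames = list(sprintf("p%02d", 1:30), sprintf("s%d", 1:8)))
  labels <- stats::setNames(rep(c("T", "O"), each = 4), colnames(v))
  co <- ExpressionCohort(v, scale = "log2", labels = labels)
  sc <- resampledTTestScores(co, "T", nIterations = 1, seed = 1)
  ref <- apply(v, 1, function(x) {
    stats::t.test(x[1:4], x[5:8], var.equal = TRUE)$p.value
  })
  expect_equal(sc$mean_p[match(names(ref), sc$probe_id)], unname(ref),
               tolerance = 1e-12)
  expect_equal(sc$mean_fold[match(names(ref), sc$probe_id)],
               unname(2^(rowMeans(v[, 1:4]) - rowMeans(v[, 5:8]))),
               tolerance = 1e-12)
})

test_that("scores are invariant to sample order and monotone in planted fold", {
  d <- cohortDesign(c(T = 6, O = 12), nProbes = 40,
                    markers = data.frame(probe = 1, entity = "T", fold = 4),
                    noiseSd = 0.3, seed = 2)
  co <- log2Transform(simulateMicroarrayCohort(d))
  sc1 <- resampledTTestScores(co, "T", nIterations = 25, seed = 7)
  perm <- sample(ncol(co))
  sc2 <- resampledTTestScores(co[, perm], "T", nIterations = 25, seed = 7)
  expect_equal(sc1, sc2)

  # raising the planted fold (same seeds throughout) can only help its p
  meanP <- vapply(c(2, 4, 8), function(fold) {
    dd <- cohortDesign(c(T = 6, O = 12), nProbes = 40,
                       markers = data.frame(probe = 1, entity = "T",
                                            fold = fold),
                       noiseSd = 0.3, seed = 2)
    s <- resampledTTestScores(log2Transform(simulateMicroarrayCohort(dd)),
                              "T", nIterations = 25, seed = 7)
    s$mean_p[s$probe_id == "probe_0001"]
  }, 0)
  expect_true(all(diff(meanP) <= 0))
})

test_that("label-free data yield approximately uniform p-values", {
  d <- cohortDesign(c(T = 10, O = 20), nProbes = 500, noiseSd = 0.5, seed = 8)
  co <- log2Transform(simulateMicroarrayCohort(d))
  # a single resampled comparison under the null: p is uniform
  sc1 <- resampledTTestScores(co, "T", nIterations = 1, seed = 8)
  ks1 <- suppressWarnings(stats::ks.test(sc1$mean_p, "punif"))
  expect_lt(unname(ks1$statistic), 0.1)
  # averaging dependent p-values pulls mass off the extremes; the
  # aggregate stays near-uniform (generous band) and centred
  sc <- resampledTTestScores(co, "T", nIterations = 20, seed = 8)
  ks <- suppressWarnings(stats::ks.test(sc$mean_p, "punif"))
  expect_lt(unname(ks$statistic), 0.3)
  expect_equal(mean(sc$mean_p), 0.5, tolerance = 0.05)
  expect_true(all(sc$mean_p > 0 & sc$mean_p <= 1))
  # ranks are a permutation of 1..n
  expect_equal(sort(sc$significance_rank), seq_len(nrow(sc)))
})

test_that("the fold/rank selection rule keeps and drops the right probes", {
  scores <- data.frame(
    probe_id = c("FBP2_probe", "borderline_fold", "late_rank", "good2"),
    mean_p = c(1e-6, 1e-9, 1e-4, 1e-5),
    mean_fold = c(716.4, 4.9, 50, 12),
    significance_rank = c(13L, 1L, 21L, 5L),
    stringsAsFactors = FALSE
  )
  sel <- selectMarkers(scores, minFold = 5, maxRank = 20)
  expect_equal(sel, c("FBP2_probe", "good2"))  # descending mean fold
})

test_that("marker recovery on a planted cohort returns exactly the planted set", {
  d <- cohortDesign(c(EPN = 20, OTHER = 20), nProbes = 500,
                    markers = data.frame(probe = 1:10, entity = "EPN",
                                         fold = 8),
                    noiseSd = 0.5, seed = 21)
  co <- varianceFilter(log2Transform(simulateMicroarrayCohort(d)), 0.25)
  sc <- resampledTTestScores(co, "EPN", nIterations = 100, seed = 22)
  expect_setequal(selectMarkers(sc), sprintf("probe_%04d", 1:10))
})
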