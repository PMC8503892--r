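test_that("average-linkage clustering behaves as its contract requires", {
  v <- cbind(a = c(1, 1), b = c(1, 1), c = c(9, 9))
  rownames(v) <- c("g1", "g2")
  cut <- clusterSamples(normFromMatrix(v), c("g1", "g2"))
  h <- cut@tree$height
  expect_equal(h[1], 0)                      # identical samples merge at 0
  expect_true(all(diff(h) >= 0))             # monotone merge heights
  expect_equal(sort(cut@tree$labels[cut@tree$merge[1, ] * -1]), c("a", "b"))

  # three samples with pairwise distances 1,1,10-ish: the close pair first
  v2 <- cbind(a = 0, b = 1, c = 10)
  v2 <- rbind(g1 = as.numeric(v2))
  colnames(v2) <- c("a", "b", "c")
  cut2 <- clusterSamples(normFromMatrix(v2), "g1")
  expect_equal(sort(cut2@tree$labels[-cut2@tree$merge[1, ]]), c("a", "b"))

  expect_error(clusterSamples(normFromMatrix(v), c("g1", "nope")), "nope")
})

test_that("reference-anchored assignment recovers planted supratentorial groups", {
  st <- signaturePanel("ST")
  lanes <- simulateNanostringRun(nanoDesign(
    groups = c("RELA+" = 10, NC = 6, "YAP1+" = 1),
    signatureSets = list("RELA+" = st[["RELA+"]], "YAP1+" = st[["YAP1+"]]),
    signatureFold = 6, seed = 13))
  norm <- normalizeNanostring(lanes)
  cut <- clusterSamples(norm, unlist(st, use.names = FALSE))
  refs <- c("RELA+_01" = "RELA+", "NC_01" = "NC")
  a <- assignByReference(cut, norm, refs)
  truth <- laneTruth(lanes)
  expect_equal(stats::setNames(a$label, a$sample_id),
               stats::setNames(truth, a$sample_id))
  expect_equal(sum(a$label == "RELA+"), 10L)
  expect_equal(sum(a$label == "NC"), 6L)
  expect_equal(sum(a$label == "YAP1+"), 1L)

  # references always carry their own group
  expect_equal(a$label[a$sample_id == "RELA+_01"], "RELA+")
  expect_match(a$evidence[a$sample_id == "RELA+_02"], "reference")
  expect_match(a$evidence[a$sample_id == "YAP1+_01"], "score-rule")
})

test_that("reference-only batches and signature-free batches label sensibly", {
  st <- signaturePanel("ST")
  lanes <- simulateNanostringRun(nanoDesign(
    groups = c("RELA+" = 1, NC = 1),
    signatureSets = st,
    seed = 3))
  norm <- normalizeNanostring(lanes)
  cut <- clusterSamples(norm, unlist(st, use.names = FALSE))
  a <- assignByReference(cut, norm,
                         c("RELA+_01" = "RELA+", "NC_01" = "NC"), k = 2)
  expect_equal(a$label[a$sample_id == "RELA+_01"], "RELA+")
  expect_equal(a$label[a$sample_id == "NC_01"], "NC")

  # all-flat lanes with no references: everything NC
  flat <- simulateNanostringRun(nanoDesign(
    groups = c(NC = 8),
    signatureSets = list(NC = unlist(st, use.names = FALSE)),
    signatureFold = 1, seed = 5))
  nf <- normalizeNanostring(flat)
  cutF <- clusterSamples(nf, unlist(st, use.names = FALSE))
  af <- assignByReference(cutF, nf, character(0), k = 2)
  expect_true(all(af$label == "NC"))
})

test_that("PFA/PFB assignment recovers the planted structure with outlier detection", {
  lanes <- simulateNanostringRun(nanoDesign(
    groups = c(PFA = 42, PFB = 7, FLAT = 1), signatureFold = 6, seed = 1))
  a <- assignPf(normalizeNanostring(lanes))
  truth <- laneTruth(lanes)
  expect_equal(sum(a$label == "PFA"), 42L)
  expect_equal(sum(a$label == "PFB"), 7L)
  expect_equal(a$sample_id[a$label == "outlier"], "FLAT_01")
  expect_equal(a$label[truth == "PFA"], rep("PFA", 42))
  expect_equal(a$label[truth == "PFB"], rep("PFB", 7))
})

test_that("PFA/PFB labels swap under signature swap and survive class imbalance", {
  pf <- signaturePanel("PF")
  swapped <- list(PFA = pf$PFB, PFB = pf$PFA)
  lanes <- simulateNanostringRun(nanoDesign(
    groups = c(PFA = 10, PFB = 10), seed = 2))
  norm <- normalizeNanostring(lanes)
  a <- assignPf(norm, pf)
  b <- assignPf(norm, swapped)
  expect_equal(b$label, ifelse(a$label == "PFA", "PFB",
                        ifelse(a$label == "PFB", "PFA", a$label)))

  # a single PFB-like lane among PFA-like lanes is still called PFB
  one <- simulateNanostringRun(nanoDesign(
    groups = c(PFA = 15, PFB = 1), seed = 4))
  ao <- assignPf(normalizeNanostring(one))
  expect_equal(ao$label[ao$sample_id == "PFB_01"], "PFB")
  expect_true(all(ao$label[ao$sample_id != "PFB_01"] == "PFA"))
})

test_that("degenerate PF input is refused gracefully", {
  pf <- signaturePanel("PF")
  v <- matrix(5, nrow = 10, ncol = 4,
              dimnames = list(unlist(pf, use.names = FALSE),
                              paste0("s", 1:4)))
  expect_warning(a <- assignPf(normFromMatrix(v)), "degenerate")
  expect_true(all(a$label == "outlier"))
})

test_that("PFA1/PFA2 subgrouping recovers planted subgroups and refuses flat input", {
  sub <- signaturePanel("PFA_SUB")
  lanes <- simulateNanostringRun(nanoDesign(
    groups = c(PFA1 = 33, PFA2 = 9),
    signatureSets = sub, signatureFold = 6, seed = 17))
  norm <- normalizeNanostring(lanes)
  a <- assignPfaSubgroup(norm)
  truth <- laneTruth(lanes)
  expect_equal(stats::setNames(a$label, a$sample_id),
               stats::setNames(truth, a$sample_id))
  expect_equal(sum(a$label == "PFA1"), 33L)
  expect_equal(sum(a$label == "PFA2"), 9L)

  # gene-set swap swaps the labels
  b <- assignPfaSubgroup(norm, list(PFA1 = sub$PFA2, PFA2 = sub$PFA1))
  expect_equal(b$label, ifelse(a$label == "PFA1", "PFA2", "PFA1"))

  # flat subgroup genes: assignment refused, samples stay PFA
  v <- matrix(rnorm(4 * 12, 7, 0.1), nrow = 4,
              dimnames = list(unlist(sub, use.names = FALSE),
                              sprintf("PFA_%02d", 1:12)))
  expect_warning(r <- assignPfaSubgroup(normFromMatrix(v)), "contrast")
  expect_true(all(r$label == "PFA"))

  expect_warning(r2 <- assignPfaSubgroup(normFromMatrix(v[, 1:2])),
                 "fewer than 3")
  expect_true(all(r2$label == "PFA"))
})

test_that("the NELL2/LAMA2 trichotomy follows the per-gene splits", {
  # planted bimodality at log2 4 vs 10 for both genes
  v <- rbind(
    NELL2 = c(10, 10, 10, 4, 4, 4, 10, 4),
    LAMA2 = c(4, 4, 4, 10, 10, 10, 10, 4)
  ) + matrix(rnorm(16, 0, 0.2), nrow = 2)
  colnames(v) <- paste0("s", 1:8)
  a <- classifyNell2Lama2(normFromMatrix(v))
  expect_equal(a$label,
               c(rep("NELL2+/LAMA2-", 3), rep("NELL2-/LAMA2+", 3),
                 "NELL2+/LAMA2+", "outlier"))

  # a gene with all-equal values cannot be split
  v2 <- rbind(NELL2 = rep(5, 4), LAMA2 = c(1, 1, 9, 9))
  colnames(v2) <- paste0("s", 1:4)
  expect_error(classifyNell2Lama2(normFromMatrix(v2)), "NELL2")
})

test_that("the NELL2+/LAMA2- stratum coincides with planted PFB lanes", {
  lanes <- simulateNanostringRun(nanoDesign(
    groups = c(PFA = 12, PFB = 6), signatureFold = 6, seed = 23))
  norm <- normalizeNanostring(lanes)
  nl <- classifyNell2Lama2(norm)
  truth <- laneTruth(lanes)
  expect_equal(nl$sample_id[nl$label == "NELL2+/LAMA2-"],
               nl$sample_id[truth == "PFB"])
})

test_that("assignments are invariant to sample order and per-lane rescaling", {
  lanes <- simulateNanostringRun(nanoDesign(
    groups = c(PFA = 8, PFB = 5), seed = 31))
  a <- assignPf(normalizeNanostring(lanes))
  aRev <- assignPf(normalizeNanostring(rev(lanes)))
  o <- match(a$sample_id, aRev$sample_id)
  expect_equal(aRev$label[o], a$label)

  # uniform positive rescaling of one lane before normalization
  lanes[[3]] <- scaleLane(lanes[[3]], 3L)
  a2 <- assignPf(normalizeNanostring(lanes))
  expect_equal(a2$label, a$label)
})
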