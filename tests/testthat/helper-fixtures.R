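# in-code fixtures shared across test files

# a small hand-built lane: 3 positives, 3 housekeeping, `nEndo` endogenous
makeLane <- function(sampleName = "S1", posCounts = c(8000, 2000, 500),
                     hkCounts = c(ACTB = 2000, GAPDH = 1500, TBP = 500),
                     endoCounts = NULL, nEndo = 19, laneId = "C1_01") {
  if (is.null(endoCounts)) {
    endoCounts <- stats::setNames(rep(200L, nEndo),
                                  sprintf("GENE%02d", seq_len(nEndo)))
  }
  cs <- data.frame(
    codeClass = c(rep("Positive", length(posCounts)),
                  rep("Housekeeping", length(hkCounts)),
                  rep("Endogenous", length(endoCounts))),
    name = c(paste0("POS_", LETTERS[seq_along(posCounts)]),
             names(hkCounts), names(endoCounts)),
    accession = paste0("NM_", seq_len(length(posCounts) + length(hkCounts) +
                                        length(endoCounts))),
    count = as.integer(c(posCounts, hkCounts, endoCounts)),
    stringsAsFactors = FALSE
  )
  RccLane(laneId = laneId, sampleName = sampleName, codeSummary = cs,
          attributes = c("Sample_Attributes.ID" = sampleName,
                         "Lane_Attributes.ID" = sub(".*_", "", laneId),
                         "Lane_Attributes.CartridgeID" = sub("_.*", "", laneId)))
}

# multiply every count in a lane by an integer factor
scaleLane <- function(lane, factor, newName = NULL) {
  if (is.null(newName)) newName <- sampleName(lane)
  cs <- codeSummary(lane)
  cs$count <- as.integer(cs$count * factor)
  at <- rccAttributes(lane)
  at["Sample_Attributes.ID"] <- newName
  RccLane(laneId = laneId(lane), sampleName = newName,
          codeSummary = cs, attributes = at)
}

# NormalizedCounts straight from a log2 matrix (unit factors)
normFromMatrix <- function(log2v) {
  cd <- S4Vectors::DataFrame(techFactor = rep(1, ncol(log2v)),
                             bioFactor = rep(1, ncol(log2v)),
                             qcFlags = rep("", ncol(log2v)),
                             row.names = colnames(log2v))
  new("NormalizedCounts",
      SummarizedExperiment::SummarizedExperiment(
        assays = list(log2 = log2v), colData = cd))
}

# planted truth of a simulated NanoString batch
laneTruth <- function(lanes) {
  vapply(lanes, function(l) rccAttributes(l)[["Sample_Attributes.SampleGroup"]], "")
}

# independent brute-force two-sided Fisher oracle: enumerate every table
# with the observed margins via the factorial formula
fisherOracle <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b
  c1 <- a + c
  aa <- 0:min(r1, c1)
  aa <- aa[c1 - aa <= n - r1]
  pr <- choose(r1, aa) * choose(n - r1, c1 - aa) / choose(n, c1)
  pObs <- pr[aa == a]
  min(1, sum(pr[pr <= pObs * (1 + 1e-7)]))
}
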