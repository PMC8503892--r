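#' Design of a synthetic multi-entity microarray cohort
#'
#' Describes a labelled expression cohort with planted group-specific
#' markers, emulating a multi-entity CNS-tumour compendium: every probe has
#' a lognormal baseline, planted marker probes are elevated by a fixed
#' linear fold change in their target entity, and every value carries
#' multiplicative lognormal noise on the log2 scale.
#'
#' @param entities named integer vector, entity name -> number of samples.
#' @param nProbes total number of probes.
#' @param markers \code{data.frame} with columns \code{probe} (id in
#'   \code{1..nProbes} or a probe name), \code{entity} (target entity) and
#'   \code{fold} (linear fold change, > 1).
#' @param baselineLog2Mean,baselineLog2Sd mean and sd of the per-probe
#'   baseline on the log2 scale.
#' @param noiseSd per-value log2 noise sd (0 = noise free).
#' @param seed integer seed; generation is a pure function of the design.
#' @return a \code{list} of class \code{"CohortDesign"}.
#' @export
cohortDesign <- function(entities, nProbes = 500L, markers = NULL,
                         baselineLog2Mean = 6, baselineLog2Sd = 1,
                         noiseSd = 0.5, seed = 1L) {
  stopifnot(length(entities) >= 1L, !is.null(names(entities)),
            !anyDuplicated(names(entities)), all(entities >= 1L),
            baselineLog2Sd > 0, noiseSd >= 0)
  if (is.null(markers)) {
    markers <- data.frame(probe = integer(), entity = character(),
                          fold = numeric())
  }
  stopifnot(all(c("probe", "entity", "fold") %in% names(markers)))
  if (nrow(markers)) {
    stopifnot(all(markers$fold > 1),
              all(markers$entity %in% names(entities)))
  }
  structure(list(entities = entities, nProbes = as.integer(nProbes),
                 markers = markers, baselineLog2Mean = baselineLog2Mean,
                 baselineLog2Sd = baselineLog2Sd, noiseSd = noiseSd,
                 seed = as.integer(seed)),
            class = "CohortDesign")
}

#' Simulate a labelled microarray cohort
#'
#' @param design a [cohortDesign()].
#' @return a linear-scale \linkS4class{ExpressionCohort} with entity labels;
#'   deterministic under the design's seed. Probe ids are \code{probe_0001}
#'   style; marker rows of the design address probes by index or name.
#' @examples
#' d <- cohortDesign(c(EPN_RELA = 5, OTHER = 5), nProbes = 50,
#'                   markers = data.frame(probe = 1:2, entity = "EPN_RELA",
#'                                        fold = 8), seed = 7)
#' simulateMicroarrayCohort(d)
#' @export
simulateMicroarrayCohort <- function(design) {
  stopifnot(inherits(design, "CohortDesign"))
  withSeed(design$seed, {
    nP <- design$nProbes
    probes <- sprintf("probe_%04d", seq_len(nP))
    sampleEntity <- rep(names(design$entities), design$entities)
    samples <- sprintf("%s_%02d", sampleEntity,
                       unlist(lapply(design$entities, seq_len)))
    baseline <- stats::rnorm(nP, design$baselineLog2Mean,
                             design$baselineLog2Sd)
    log2v <- matrix(baseline, nrow = nP, ncol = length(samples))
    if (nrow(design$markers)) {
      idx <- design$markers$probe
      if (!is.numeric(idx)) idx <- match(as.character(idx), probes)
      stopifnot(all(idx >= 1 & idx <= nP))
      for (j in seq_len(nrow(design$markers))) {
        cols <- sampleEntity == design$markers$entity[j]
        log2v[idx[j], cols] <- log2v[idx[j], cols] +
          log2(design$markers$fold[j])
      }
    }
    if (design$noiseSd > 0) {
      log2v <- log2v + stats::rnorm(length(log2v), 0, design$noiseSd)
    }
    values <- 2^log2v
    dimnames(values) <- list(probes, samples)
    ExpressionCohort(values, scale = "linear",
                     labels = stats::setNames(sampleEntity, samples))
  })
}

.DEFAULT_POS_LADDER <- c(POS_A = 25600L, POS_B = 6400L, POS_C = 1600L,
                         POS_D = 400L, POS_E = 100L, POS_F = 25L)

#' Design of a synthetic NanoString run
#'
#' Describes a batch of nCounter lanes over a custom codeset: endogenous
#' signature genes (elevated by \code{signatureFold} in lanes of their
#' group), housekeeping genes, a six-point geometric positive-control
#' ladder (relative concentrations 128, 32, 8, 2, 0.5, 0.125) and negative
#' controls. Counts are negative binomial around means scaled by a
#' per-lane lognormal technical factor.
#'
#' @param groups named integer vector, group name -> number of lanes.
#' @param signatureSets named list, group name -> character vector of its
#'   signature genes; groups absent from the list are flat (no signature).
#'   Defaults to the posterior-fossa panel of [signaturePanel()].
#' @param signatureFold linear fold elevation of a group's signature genes
#'   in its own lanes.
#' @param hkGenes named numeric vector of housekeeping mean counts.
#' @param posControls named integer vector of expected positive-control
#'   counts (the geometric ladder).
#' @param negControls number of negative-control probes (mean count 2).
#' @param baselineMean mean count of an unelevated endogenous gene.
#' @param laneScaleSd sd of the per-lane lognormal technical factor
#'   (0 = technically uniform lanes).
#' @param dispersion negative-binomial size parameter (larger = closer to
#'   Poisson; \code{Inf} = deterministic rounded means).
#' @param seed integer seed.
#' @return a \code{list} of class \code{"NanoDesign"}.
#' @export
nanoDesign <- function(groups,
                       signatureSets = NULL,
                       signatureFold = 6,
                       hkGenes = c(ACTB = 2000, GAPDH = 1500, TBP = 500),
                       posControls = .DEFAULT_POS_LADDER,
                       negControls = 6L,
                       baselineMean = 200,
                       laneScaleSd = 0.25,
                       dispersion = 20,
                       seed = 1L) {
  stopifnot(length(groups) >= 1L, !is.null(names(groups)),
            all(groups >= 1L), signatureFold >= 1, laneScaleSd >= 0,
            dispersion > 0)
  if (is.null(signatureSets)) {
    pf <- signaturePanel("PF")
    signatureSets <- pf[intersect(names(pf), names(groups))]
  }
  # sets for groups absent from the batch still define codeset genes,
  # they are just never elevated
  sigGenes <- unlist(signatureSets, use.names = FALSE)
  stopifnot(!any(sigGenes %in% names(hkGenes)))
  structure(list(groups = groups, signatureSets = signatureSets,
                 signatureFold = signatureFold, hkGenes = hkGenes,
                 posControls = posControls, negControls = as.integer(negControls),
                 baselineMean = baselineMean, laneScaleSd = laneScaleSd,
                 dispersion = dispersion, seed = as.integer(seed)),
            class = "NanoDesign")
}

#' Simulate a NanoString lane batch
#'
#' @param design a [nanoDesign()].
#' @return a list of \linkS4class{RccLane}, one per lane, deterministic
#'   under the design's seed. Each lane's planted group is recorded in its
#'   \code{Sample_Attributes.SampleGroup} attribute (synthetic truth).
#' @examples
#' lanes <- simulateNanostringRun(nanoDesign(c(PFA = 3, PFB = 2), seed = 3))
#' sapply(lanes, sampleName)
#' @export
simulateNanostringRun <- function(design) {
  stopifnot(inherits(design, "NanoDesign"))
  endoGenes <- unique(unlist(design$signatureSets, use.names = FALSE))
  if (!length(endoGenes)) stop("design has no endogenous signature genes")
  withSeed(design$seed, {
    laneGroup <- rep(names(design$groups), design$groups)
    n <- length(laneGroup)
    laneNames <- sprintf("%s_%02d", laneGroup,
                         unlist(lapply(design$groups, seq_len)))
    f <- if (design$laneScaleSd > 0) {
      exp(stats::rnorm(n, 0, design$laneScaleSd))
    } else rep(1, n)
    draw <- function(mu) {
      if (is.finite(design$dispersion)) {
        stats::rnbinom(length(mu), mu = mu, size = design$dispersion)
      } else as.integer(round(mu))
    }
    lapply(seq_len(n), function(i) {
      sig <- design$signatureSets[[laneGroup[i]]]
      endoMu <- rep(design$baselineMean, length(endoGenes))
      names(endoMu) <- endoGenes
      if (!is.null(sig)) endoMu[sig] <- endoMu[sig] * design$signatureFold
      mus <- c(design$posControls,
               stats::setNames(rep(2, design$negControls),
                               sprintf("NEG_%s", LETTERS[seq_len(design$negControls)])),
               design$hkGenes, endoMu) * f[i]
      cls <- c(rep("Positive", length(design$posControls)),
               rep("Negative", design$negControls),
               rep("Housekeeping", length(design$hkGenes)),
               rep("Endogenous", length(endoGenes)))
      cs <- data.frame(codeClass = cls, name = names(mus),
                       accession = paste0("NM_", seq_along(mus)),
                       count = as.integer(draw(mus)),
                       stringsAsFactors = FALSE)
      RccLane(
        laneId = sprintf("CART01_%02d", i),
        sampleName = laneNames[i],
        codeSummary = cs,
        attributes = c(
          "Header.FileVersion" = "1.7",
          "Header.SoftwareVersion" = "4.0.1",
          "Sample_Attributes.ID" = laneNames[i],
          "Sample_Attributes.SampleGroup" = laneGroup[i],
          "Sample_Attributes.Date" = "20210101",
          "Lane_Attributes.ID" = sprintf("%02d", i),
          "Lane_Attributes.CartridgeID" = "CART01"
        )
      )
    })
  })
}

#' Design of a synthetic survival cohort
#'
#' Exponential death and progression times from constant monthly hazards,
#' with uniform administrative censoring on a window — the simplest model
#' under which Kaplan-Meier curves and the log-rank test recover a planted
#' hazard contrast.
#'
#' @param groups \code{data.frame} with columns \code{group}, \code{n},
#'   \code{hazardDeath}, \code{hazardProgression} (per month),
#'   \code{ageMean}, \code{ageSd}.
#' @param censorWindow length-2 numeric, (min, max) months of uniform
#'   administrative censoring.
#' @param seed integer seed.
#' @return a \code{list} of class \code{"SurvivalDesign"}.
#' @export
survivalDesign <- function(groups, censorWindow = c(24, 180), seed = 1L) {
  stopifnot(is.data.frame(groups),
            all(c("group", "n", "hazardDeath") %in% names(groups)),
            all(groups$hazardDeath >= 0), all(is.finite(groups$hazardDeath)),
            length(censorWindow) == 2L, all(censorWindow > 0),
            censorWindow[1] <= censorWindow[2])
  if (is.null(groups$hazardProgression)) groups$hazardProgression <- 0
  if (is.null(groups$ageMean)) groups$ageMean <- 5
  if (is.null(groups$ageSd)) groups$ageSd <- 2
  stopifnot(all(groups$hazardProgression >= 0))
  structure(list(groups = groups, censorWindow = censorWindow,
                 seed = as.integer(seed)),
            class = "SurvivalDesign")
}

#' Simulate a clinical survival table
#'
#' @param design a [survivalDesign()].
#' @return a clinical \code{data.frame} in the layout of
#'   [readClinicalTable()], deterministic under the design's seed.
#' @examples
#' d <- survivalDesign(data.frame(group = c("PFA", "PFB"), n = c(10, 5),
#'                                hazardDeath = c(0.02, 0.002)), seed = 2)
#' head(simulateSurvival(d))
#' @export
simulateSurvival <- function(design) {
  stopifnot(inherits(design, "SurvivalDesign"))
  withSeed(design$seed, {
    g <- design$groups
    out <- lapply(seq_len(nrow(g)), function(j) {
      n <- g$n[j]
      rexpSafe <- function(h) {
        if (h > 0) stats::rexp(n, h) else rep(Inf, n)
      }
      tDeath <- rexpSafe(g$hazardDeath[j])
      tProg <- rexpSafe(g$hazardProgression[j])
      cens <- stats::runif(n, design$censorWindow[1], design$censorWindow[2])
      age <- pmax(0, stats::rnorm(n, g$ageMean[j], g$ageSd[j]))
      death <- tDeath <= cens
      time <- pmin(tDeath, cens)
      prog <- tProg <= time & is.finite(tProg)
      tprog <- pmin(tProg, time)
      data.frame(
        patient_id = sprintf("%s_%03d", g$group[j], seq_len(n)),
        age_years = round(age, 1),
        sex = sample(c("M", "F"), n, replace = TRUE),
        group_label = g$group[j],
        fusion_call = NA_character_,
        diagnosis = "EPN",
        time_months = time, time_known = TRUE, event_death = death,
        time_progression_months = tprog, event_progression = prog,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, out)
  })
}
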