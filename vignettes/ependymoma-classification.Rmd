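---
title: "Molecular group classification of paediatric ependymoma from targeted expression signatures"
author: "epnsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular group classification of paediatric ependymoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epnsig)
```

## The problem

Paediatric ependymomas are molecularly heterogeneous. Supratentorial
tumours are dominated by oncogenic fusions — most commonly *ZFTA–RELA*,
more rarely *YAP1–MAMLD1* — while posterior-fossa (PF) tumours lack
recurrent mutations and divide on expression/methylation grounds into
group A (PFA, younger patients, worse prognosis) and group B (PFB).
Because each group is marked by a handful of strongly over-expressed
genes, a small targeted panel measured on degraded FFPE RNA (a NanoString
nCounter codeset) can assign tumours to RELA+, YAP1+, PFA and PFB without
genome-wide profiling.

`epnsig` implements that workflow end to end:

1. **Marker discovery** from labelled expression matrices by a resampled
   Student t-test scheme (`resampledTTestScores()`, `selectMarkers()`).
2. **Lane normalization** of nCounter RCC files — positive-control
   (technical) and housekeeping (biological) scaling
   (`normalizeNanostring()`).
3. **Group assignment** by Euclidean average-linkage clustering:
   reference-anchored labelling for the supratentorial compartment
   (`assignByReference()`), score-guided two-cluster labelling with
   outlier detection for PF (`assignPf()`), PFA1/PFA2 subgrouping
   (`assignPfaSubgroup()`), and the two-gene NELL2/LAMA2 trichotomy
   (`classifyNell2Lama2()`).
4. **Clinical statistics**: Fisher-exact fusion concordance, Kaplan–Meier
   curves, log-rank comparisons and survivor counts
   (`fisherExactTwoSided()`, `kmEstimate()`, `logrankTest()`,
   `survivorCount()`).

Synthetic-cohort generators (`simulateMicroarrayCohort()`,
`simulateNanostringRun()`, `simulateSurvival()`) make every stage testable
without external downloads.

## Marker discovery

The discovery stage assumes a probes-by-samples matrix pooled from
several diagnostic entities, with per-sample entity labels. Processing
follows the standard microarray path: quantile normalization
(`quantileNormalize()`, delegated to limma's tie-aware implementation),
log2 transformation, and removal of uninformative probes with log2-scale
variance below 0.25 (`varianceFilter()`).

The scoring statistic addresses a pooled-background instability: a single
t-test of, say, 36 RELA-fusion ependymomas against *all* other tumours is
dominated by whichever background entity is largest. Instead, the target
group of size $t$ is compared `nIterations = 100` times against an
equal-sized set drawn without replacement from the pooled non-target
samples. Per probe and draw we compute a two-sided equal-variance Student
t-test p-value and the linear fold change $2^{\bar{x}_T - \bar{x}_D}$;
the per-probe *mean* p and *mean* fold over draws are the marker scores
(the maximum fold is reported alongside). Probes rank by ascending mean p
(ties: larger mean fold, then probe id — a deterministic ordering), and a
candidate marker must show `mean_fold >= 5` and rank in the top 20.

Choices worth knowing:

* **Equal-variance Student test** by default; Welch is available via
  `welch = TRUE`.
* **No multiple-testing correction** — the mean over resampled raw
  p-values is itself the robustness device, and selection is rank-based.
* **Pooled (not per-entity-stratified) drawing** of comparison sets; each
  probe is scored independently even when several probes map to one gene.
* **Determinism**: draws are seeded, and samples are put in canonical
  (sorted-id) order first, so scores are invariant to column
  permutations of the input.

## NanoString normalization

Raw RCC counts carry a per-lane technical scale (hybridization
efficiency, imaging) and a per-sample RNA-content scale. Both are removed
by geometric-mean scaling to the batch mean, the documented nSolver
default:

$$f_\ell = \frac{\tfrac{1}{L}\sum_m g_m}{g_\ell},$$

where $g_\ell$ is lane $\ell$'s geometric mean over the six spiked
positive controls (technical step) or over the housekeeping genes ACTB,
GAPDH and TBP (biological step). After both steps the endogenous counts
are log2-transformed with pseudocount 1. Endogenous, housekeeping and
control probes are kept apart by their RCC code class; only endogenous
genes enter the output matrix.

QC follows conventional instrument guidance: a lane whose scaling factor
falls outside [0.3, 3], or with a zero positive control (factor then
computed from the nonzero positives), is *flagged, not dropped*
(`qcFlags()`). Background subtraction from negative controls is off by
default, matching the vendor default. Note that because the scaling
target is the *batch* mean, rescaling one lane moves every normalized
value by a common factor; all relative quantities (lane ratios, distances,
z-scores, assignments) are unaffected, and the test suite asserts exactly
that.

## Group assignment

All clustering uses Euclidean distance on log2 normalized values with
average linkage.

**Supratentorial (reference-anchored).** Each batch carries molecularly
confirmed reference samples (one *ZFTA–RELA*-positive, one
fusion-negative). The dendrogram over the nine supratentorial signature
genes is cut into $k$ clusters, default $k$ = (distinct non-NC reference
groups) + 2 — one cluster expected per referenced group, one for
signature-free (NC) tumours, and one potential singleton such as a lone
YAP1+ tumour. Clusters are labelled by their references; an unreferenced
cluster is rescued only if its mean signature z-score (per-gene z across
the batch, averaged over a group's genes) exceeds `zMin = 2` for some
panel group. We apply the z-rescue to *any* unreferenced cluster, not
only singletons: when a real group splits across two clusters at the
chosen $k$, the fragment without the reference still carries the
signature and should not silently become NC.

**Posterior fossa.** PF batches have no references. Per-sample PFA and
PFB scores (mean log2 over each five-gene set) are each dichotomized by
an exact 1-D two-level split minimizing within-group variance; a split is
accepted only when the gap between its level means is at least
`minGap = 1` log2 unit (a twofold separation), so a homogeneous batch is
not split on noise. Samples negative for both signatures are *outliers*
(probably not ependymomas) and are set aside; the rest are cut into two
clusters and the cluster with the higher mean PFA-minus-PFB score is PFA.
We deliberately did **not** use an absolute z-score floor for outlier
calls: in an imbalanced batch (e.g. 42 PFA, 7 PFB, 1 non-ependymoma) the
batch mean of a majority-group gene sits near the elevated level, so no
fixed z threshold separates "flat on both signatures" from "flat on one";
the split-based rule handles any group imbalance because it works on the
bimodal structure of each score separately. The reported assignment
`score` is still the familiar mean signature z.

**PFA1/PFA2 and NELL2/LAMA2.** PFA samples are re-clustered on
SKAP2/WIF1 (PFA1) versus EN2/CNPY1 (PFA2), labelled by the higher mean
score difference; the subdivision is refused (samples stay PFA) when the
two clusters' score contrast is below `minGap`. Independently, the
two-gene trichotomy dichotomizes NELL2 and LAMA2 by the same 1-D split
and composes labels — NELL2+/LAMA2− (coinciding with PFB),
NELL2+/LAMA2+, NELL2−/LAMA2+ — with double-negative samples labelled
outlier.

Default panels exclude DRD1 (uniformly low hybridization) and ANGPTL6
(nonspecific between reference samples), matching the final panel after
probe QC. The six-gene CNS HGNET-MN1 panel is not published and therefore
ships empty; supply it via `signaturePanel(mn1Genes = ...)`.

## Clinical statistics

`fisherExactTwoSided()` is an exact hypergeometric enumeration using the
minimum-likelihood two-sided convention (sum of all margin-consistent
table probabilities not exceeding the observed one, relative tolerance
1e-7); the suite verifies it against an independent factorial-formula
enumeration for every margin configuration with $n \le 40$ and against
`stats::fisher.test`. Kaplan–Meier and log-rank delegate to the survival
package; PFS takes progression or death, whichever first. For the
packaged supratentorial cohort:

```{r clinical}
clin <- supratentorialClinical()
tab <- fusionConcordance(clin)
tab
fisherExactTwoSided(tab)
epn <- clin[clin$diagnosis != "PNET", ]
survivorCount(epn, "RELA+", 60)
```

The concordance table relates the RELA+ signature to *ZFTA–RELA*
detection and excludes YAP1+ (and MN1) tumours — the question is whether
the RELA signature predicts the RELA fusion among tumours that could
plausibly carry it; any other fusion (e.g. *ZFTA–MAML2*) counts as "not
detected". "Survived at least five years" counts patients alive with
follow-up ≥ 60 months or dying at ≥ 60 months; a patient censored at 24
months has not been observed that long and is not counted. One death is
recorded without a follow-up time; that record keeps
`time_known = FALSE`, is excluded from every time-to-event computation,
and still participates in group counts.

## The synthetic generators

The generators define the conditions under which recovery is tested:

* `simulateMicroarrayCohort()`: per-probe lognormal baselines
  (log2 mean 6, sd 1), planted markers elevated by a fixed linear fold in
  their target entity, i.i.d. log2 noise (default sd 0.5 — a typical
  within-group spread for normalized arrays). It emulates *planted,
  probe-level* group structure only: no correlated co-expression blocks,
  batch effects or probe saturation.
* `simulateNanostringRun()`: negative-binomial counts (default size 20,
  i.e. ~22% extra-Poisson CV at typical counts) around group-dependent
  means — endogenous baseline 200 counts, signature genes elevated
  6-fold in their group's lanes, housekeeping means 2000/1500/500, the
  conventional six-point positive ladder at relative concentrations
  128…0.125 (25600…25 expected counts) — all scaled by a per-lane
  lognormal technical factor (sd 0.25). `dispersion = Inf` gives
  deterministic rounded means for exactness checks.
* `simulateSurvival()`: exponential event times from constant monthly
  hazards with uniform administrative censoring on 24–180 months.

Every generator is a pure function of its design (seeded), and noise-free
designs reproduce their construction exactly. Passing recovery tests on
these cohorts shows the estimators are correct and well-conditioned under
the planted model; it does not establish performance on real tumours,
where signature folds vary by gene, groups have internal substructure
(PFA minor subgroups), and FFPE RNA quality varies by block.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use desk-scale cohorts chosen
to keep the whole suite fast while leaving comfortable recovery margins:
marker discovery on 500 probes with two entities of 20 samples and 10
planted 8-fold markers (100 resampling iterations); classification on
batches of 10–50 lanes at signature fold 6, repeated over 20 seeds.
At these folds the planted effects are many standard errors wide, so
recovery failures would indicate defects rather than bad luck; at fold 1
the same pipeline sits at chance, which the suite also asserts.

Other numerical decisions: tie-aware quantile normalization (tied ranks
share the mean of their reference values); the 1-D split is exact (all
n−1 cut points scanned), deterministic, and refuses all-equal input;
hierarchical clustering inherits `stats::hclust` tie-breaking, and
assignments are invariant to input order because distances are; the
degenerate all-equal PF matrix yields all-outlier with a warning rather
than an arbitrary 2-cut.

## Known limitations

* Published fold-changes and cluster counts from the original cohorts are
  not reproducible here — they require the controlled-access expression
  data; the package reproduces the *procedures* and the printed
  patient-level statistics.
* The MN1 signature panel must be user-supplied.
* Whether the discovery comparisons were drawn pooled or per-diagnosis is
  not documented; pooled drawing is the default, stratified drawing is
  not offered.
* Normalization assumes at least two positive controls and all three
  housekeeping genes per lane; cross-cartridge batch correction is out of
  scope.
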