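#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric test with fixed margins, minimum-likelihood
#' two-sided convention: the p-value is the sum of the point probabilities
#' of all margin-consistent tables whose probability does not exceed that
#' of the observed table (within relative tolerance 1e-7).
#'
#' @param table a 2x2 matrix of non-negative integer counts, or the count
#'   \code{a} (top-left cell) when \code{b}, \code{c}, \code{d} are given.
#' @param b,c,d remaining cells (row-wise) when \code{table} is scalar.
#' @return the two-sided p-value in (0, 1].
#' @examples
#' fisherExactTwoSided(matrix(c(9, 0, 1, 4), nrow = 2))  # 0.004995005
#' @export
fisherExactTwoSided <- function(table, b = NULL, c = NULL, d = NULL) {
  if (length(table) == 1L) table <- matrix(c(table, c, b, d), nrow = 2L)
  stopifnot(is.matrix(table), all(dim(table) == 2L),
            all(table >= 0), all(table == round(table)))
  a <- table[1, 1]; bb <- table[1, 2]; cc <- table[2, 1]; dd <- table[2, 2]
  n <- a + bb + cc + dd
  if (n < 1L) stop("table must contain at least one observation")
  r1 <- a + bb
  c1 <- a + cc
  support <- max(0L, r1 + c1 - n):min(r1, c1)
  pr <- stats::dhyper(support, c1, n - c1, r1)
  pObs <- pr[support == a]
  min(1, sum(pr[pr <= pObs * (1 + 1e-7)]))
}

# Surv objects for an endpoint; records with unknown time are dropped
.survOf <- function(records, endpoint = c("OS", "PFS")) {
  endpoint <- match.arg(endpoint)
  known <- records$time_known
  if (!any(known)) stop("no record carries a known follow-up time")
  r <- records[known, , drop = FALSE]
  if (endpoint == "OS") {
    survival::Surv(r$time_months, r$event_death)
  } else {
    # PFS event = progression or death, whichever first
    time <- pmin(r$time_progression_months, r$time_months)
    event <- r$event_progression | (r$event_death &
                                      r$time_months <= r$time_progression_months)
    survival::Surv(time, event)
  }
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimator of overall survival (OS) or progression-free
#' survival (PFS; event = progression or death, whichever first) with
#' right censoring. Records whose follow-up time is unknown are excluded.
#'
#' @param records a clinical \code{data.frame} (see [readClinicalTable()]).
#' @param endpoint \code{"OS"} or \code{"PFS"}.
#' @return a \code{data.frame} with columns \code{time} (months),
#'   \code{surv}, \code{n_risk}, \code{n_event}, \code{n_censor}; the
#'   estimate is 1 before the first row's time.
#' @export
kmEstimate <- function(records, endpoint = c("OS", "PFS")) {
  s <- .survOf(records, endpoint)
  fit <- survival::survfit(s ~ 1)
  data.frame(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
             n_event = fit$n.event, n_censor = fit$n.censor)
}

#' Log-rank test between groups
#'
#' Mantel-Haenszel log-rank comparison of survival between the groups in
#' \code{records[[groupField]]}, with (g - 1) degrees of freedom.
#'
#' @inheritParams kmEstimate
#' @param groupField column holding the group labels (>= 2 groups).
#' @return list with \code{chisq}, \code{df} and \code{p}.
#' @export
logrankTest <- function(records, groupField = "group_label",
                        endpoint = c("OS", "PFS")) {
  groups <- records[[groupField]][records$time_known]
  if (length(unique(groups)) < 2L) {
    stop("log-rank comparison needs >= 2 groups")
  }
  s <- .survOf(records, endpoint)
  sd <- survival::survdiff(s ~ groups)
  df <- length(sd$n) - 1L
  list(chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE))
}

#' Count survivors beyond a horizon
#'
#' Number of patients in a group, alive or dead, whose survival time is at
#' least \code{minMonths} (no death before the horizon; a patient censored
#' earlier has not been observed that long and is not counted). Records
#' with unknown follow-up time are excluded.
#'
#' @param records a clinical \code{data.frame}.
#' @param groupLabel group to count within (must exist in the records).
#' @param minMonths survival horizon in months (60 = five years).
#' @return integer count.
#' @examples
#' clin <- supratentorialClinical()
#' epn <- clin[clin$diagnosis != "PNET", ]
#' survivorCount(epn, "RELA+", 60)  # 8
#' @export
survivorCount <- function(records, groupLabel, minMonths) {
  if (!groupLabel %in% records$group_label) {
    stop("unknown group: ", groupLabel)
  }
  r <- records[records$group_label == groupLabel & records$time_known, ,
               drop = FALSE]
  sum(r$time_months >= minMonths)
}

#' Signature / fusion concordance table
#'
#' Builds the 2x2 contingency table of the RELA+ expression signature
#' against detection of the ZFTA-RELA fusion: rows are signature class
#' (RELA+, NC), columns fusion status (detected, not detected). YAP1+ and
#' CNS HGNET-MN1 records are excluded; any other fusion (e.g. ZFTA-MAML2)
#' counts as "not detected" for ZFTA-RELA.
#'
#' @param records a clinical \code{data.frame} with \code{group_label} and
#'   \code{fusion_call}.
#' @param fusion fusion transcript of interest.
#' @return a 2x2 integer matrix with dimnames.
#' @examples
#' fusionConcordance(supratentorialClinical())
#' @export
fusionConcordance <- function(records, fusion = "ZFTA-RELA") {
  r <- records[records$group_label %in% c("RELA+", "NC"), , drop = FALSE]
  det <- !is.na(r$fusion_call) & r$fusion_call == fusion
  sig <- r$group_label == "RELA+"
  matrix(c(sum(sig & det), sum(!sig & det),
           sum(sig & !det), sum(!sig & !det)),
         nrow = 2L,
         dimnames = list(signature = c("RELA+", "NC"),
                         fusion = c("detected", "not detected")))
}

#' Two-sample Student t-test p-value
#'
#' Two-sided equal-variance Student t-test (as used for the group age
#' comparisons). Degenerate input with zero pooled variance returns p = 1
#' when the means are equal.
#'
#' @param valuesA,valuesB numeric vectors (each >= 2 values).
#' @return the two-sided p-value.
#' @export
twoSampleTTest <- function(valuesA, valuesB) {
  stopifnot(length(valuesA) >= 2L, length(valuesB) >= 2L)
  if (stats::var(valuesA) == 0 && stats::var(valuesB) == 0) {
    return(if (mean(valuesA) == mean(valuesB)) 1 else 0)
  }
  stats::t.test(valuesA, valuesB, var.equal = TRUE)$p.value
}
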