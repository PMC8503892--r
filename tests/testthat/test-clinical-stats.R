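test_that("the two-sided Fisher exact test follows the minimum-likelihood convention", {
  # frozen hand enumeration for margins (10,4)x(9,5), n = 14:
  # P(a=9) = C(10,9)C(4,0)/C(14,9) = 10/2002 = 5/1001; no other table in
  # the support {5..9} has probability <= that, so p = 5/1001
  expect_equal(fisherExactTwoSided(matrix(c(9, 0, 1, 4), 2)), 5 / 1001,
               tolerance = 1e-12)
  expect_equal(round(fisherExactTwoSided(matrix(c(9, 0, 1, 4), 2)), 3), 0.005)

  # both unit-diagonal tables have probability 0.5: both are counted
  expect_equal(fisherExactTwoSided(matrix(c(1, 0, 0, 1), 2)), 1)
  # the observed table is the mode: every table is counted
  expect_equal(fisherExactTwoSided(matrix(c(5, 5, 5, 5), 2)), 1)

  expect_error(fisherExactTwoSided(matrix(c(0, 0, 0, 0), 2)), "at least one")
})

test_that("Fisher agrees with stats::fisher.test on randomized tables", {
  set.seed(1)
  for (i in 1:200) {
    tab <- matrix(rpois(4, sample(1:8, 1)), 2)
    if (sum(tab) == 0) next
    expect_equal(fisherExactTwoSided(tab),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("Kaplan-Meier matches hand-computed product limits", {
  rec <- function(time, death, prog = FALSE, tprog = time) {
    data.frame(patient_id = paste0("p", seq_along(time)), age_years = 5,
               sex = "M", group_label = "G", fusion_call = NA,
               diagnosis = "EPN", time_months = time, time_known = TRUE,
               event_death = death, time_progression_months = tprog,
               event_progression = prog, stringsAsFactors = FALSE)
  }

  # no events: flat S(t) = 1
  km <- kmEstimate(rec(c(10, 20, 30), c(FALSE, FALSE, FALSE)), "OS")
  expect_true(all(km$surv == 1))

  # 4 deaths, no censoring: empirical survival function
  km <- kmEstimate(rec(1:4, rep(TRUE, 4)), "OS")
  expect_equal(km$surv, c(3, 2, 1, 0) / 4)

  # death@10, censored@5, death@20: S(10) = 1/2, S(20) = 0
  km <- kmEstimate(rec(c(10, 5, 20), c(TRUE, FALSE, TRUE)), "OS")
  expect_equal(km$surv[km$time == 10], 1 / 2)
  expect_equal(km$surv[km$time == 20], 0)

  # PFS: progression or death, whichever first
  r <- rec(c(30, 40), c(TRUE, FALSE), prog = c(TRUE, FALSE),
           tprog = c(12, 40))
  pfs <- kmEstimate(r, "PFS")
  expect_equal(pfs$time[pfs$n_event == 1], 12)

  expect_error(kmEstimate(rec(10, TRUE)[0, ], "OS"), "known follow-up")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(7)
  for (i in 1:5) {
    times <- sort(round(rexp(20, 0.02), 1) + 0.1)
    r <- data.frame(patient_id = paste0("p", 1:20), age_years = 5,
                    sex = "F", group_label = "G", fusion_call = NA,
                    diagnosis = "EPN", time_months = times,
                    time_known = TRUE, event_death = TRUE,
                    time_progression_months = times,
                    event_progression = FALSE, stringsAsFactors = FALSE)
    km <- kmEstimate(r, "OS")
    emp <- vapply(km$time, function(t) mean(times > t), 0)
    expect_equal(km$surv, emp, tolerance = 1e-12)
  }
})

test_that("the log-rank test is symmetric, null on identical patterns, and powered", {
  base <- simulateSurvival(survivalDesign(
    data.frame(group = "A", n = 15, hazardDeath = 0.01), seed = 2))
  dup <- base
  dup$group_label <- "B"
  dup$patient_id <- paste0(dup$patient_id, "b")
  both <- rbind(base, dup)
  lr <- logrankTest(both, "group_label", "OS")
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1, tolerance = 1e-12)

  d <- survivalDesign(data.frame(group = c("PFA", "PFB"), n = 200,
                                 hazardDeath = c(0.02, 0.002)), seed = 5)
  rec <- simulateSurvival(d)
  lr1 <- logrankTest(rec, "group_label", "OS")
  expect_lt(lr1$p, 0.01)
  swapped <- rec
  swapped$group_label <- ifelse(rec$group_label == "PFA", "PFB", "PFA")
  lr2 <- logrankTest(swapped, "group_label", "OS")
  expect_equal(lr2$chisq, lr1$chisq, tolerance = 1e-12)
  expect_gte(lr1$chisq, 0)

  expect_error(logrankTest(base, "group_label", "OS"), ">= 2 groups")
})

test_that("survivor counting applies the five-year rule of the printed cohort", {
  clin <- supratentorialClinical()
  epn <- clin[clin$diagnosis != "PNET", ]
  expect_equal(survivorCount(epn, "RELA+", 60), 8L)   # 24-month follow-up not counted
  expect_equal(survivorCount(epn, "RELA+", 0), 9L)    # group size
  # group present but with no usable follow-up time counts zero
  expect_equal(survivorCount(clin, "YAP1+", 60), 0L)
  expect_error(survivorCount(clin, "PFA", 60), "unknown group")
})

test_that("fusion concordance reconstructs the printed 2x2", {
  clin <- supratentorialClinical()
  tab <- fusionConcordance(clin)
  expect_equal(unname(tab), matrix(c(9, 0, 1, 4), 2))
  # the ZFTA-MAML2 fusion counts as not-detected for ZFTA-RELA
  maml2 <- clin[clin$fusion_call %in% "ZFTA-MAML2", ]
  expect_equal(nrow(maml2), 1L)
  expect_equal(unname(fusionConcordance(clin)["NC", "not detected"]), 4)
  # YAP1+ records are excluded from the table entirely
  expect_equal(sum(tab), 14)

  empty <- clin[0, ]
  expect_equal(unname(fusionConcordance(empty)), matrix(0L, 2, 2))
})

test_that("the two-sample Student t-test wrapper behaves at its edges", {
  expect_equal(twoSampleTTest(c(1, 1, 1), c(1, 1, 1)), 1)
  set.seed(9)
  a <- rnorm(30)
  b <- rnorm(30, 3)
  expect_lt(twoSampleTTest(a, b), 1e-6)
  # invariance under a common affine transform
  expect_equal(twoSampleTTest(2 * a + 5, 2 * b + 5), twoSampleTTest(a, b),
               tolerance = 1e-12)
})
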