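.CLINICAL_COLS <- c("patient_id", "age_years", "sex", "group_label",
                    "fusion_call", "diagnosis", "time_months", "time_known",
                    "event_death", "time_progression_months",
                    "event_progression")

#' Read a clinical table
#'
#' Reads a CSV with one row per patient, following the column roles of the
#' packaged supratentorial cohort: \code{id}, \code{age_years}, \code{sex},
#' \code{nanostring_diagnosis}, \code{ngs_fusion},
#' \code{original_diagnosis}, \code{relapse_months}, \code{dod_months}
#' (died of disease) and \code{adf_months} (alive disease free).
#'
#' Outcome encoding (right censoring):
#' \itemize{
#'   \item \code{adf_months = m} and \code{dod_months = No}: alive,
#'     censored at \code{m} months.
#'   \item \code{dod_months = m}: died of disease at \code{m} months.
#'   \item \code{dod_months = Yes} without a month: death with unknown
#'     follow-up time; the record keeps \code{time_known = FALSE} and is
#'     excluded from time-to-event computations but retained in counts.
#'   \item \code{relapse_months} of the form \code{m} or \code{m/site}:
#'     progression event at \code{m} months; otherwise progression time
#'     equals follow-up time with no event.
#' }
#'
#' @param path path to the CSV.
#' @return a \code{data.frame} with columns \code{patient_id},
#'   \code{age_years}, \code{sex}, \code{group_label}, \code{fusion_call}
#'   (\code{NA} when no fusion was detected), \code{diagnosis},
#'   \code{time_months}, \code{time_known}, \code{event_death},
#'   \code{time_progression_months}, \code{event_progression}.
#' @seealso [supratentorialClinical()] for the packaged cohort.
#' @export
readClinicalTable <- function(path) {
  empty <- data.frame(
    patient_id = character(), age_years = numeric(), sex = character(),
    group_label = character(), fusion_call = character(),
    diagnosis = character(), time_months = numeric(), time_known = logical(),
    event_death = logical(), time_progression_months = numeric(),
    event_progression = logical(), stringsAsFactors = FALSE
  )
  if (!length(readLines(path, n = 1L))) return(empty)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!nrow(raw)) return(empty)
  need <- c("id", "age_years", "sex", "nanostring_diagnosis", "ngs_fusion",
            "original_diagnosis", "relapse_months", "dod_months",
            "adf_months")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("clinical table lacks columns: ",
                         paste(miss, collapse = ", "))

  asMonths <- function(x) suppressWarnings(as.numeric(x))
  isNo <- function(x) toupper(trimws(x)) %in% c("NO", "-", "", "NA")

  out <- lapply(seq_len(nrow(raw)), function(i) {
    r <- raw[i, ]
    sex <- toupper(trimws(r$sex))
    if (!sex %in% c("M", "F")) {
      stop("row ", i, ": unknown sex code \"", r$sex, "\"")
    }
    dod <- asMonths(r$dod_months)
    adf <- asMonths(r$adf_months)
    if (!is.na(dod) && !is.na(adf)) {
      stop("row ", i, ": DOD and ADF months are mutually exclusive outcomes")
    }
    if (!is.na(dod)) {                       # died at a known time
      time <- dod; known <- TRUE; death <- TRUE
    } else if (!isNo(r$dod_months)) {        # death without a printed time
      time <- NA_real_; known <- FALSE; death <- TRUE
    } else if (!is.na(adf)) {                # alive disease free
      time <- adf; known <- TRUE; death <- FALSE
    } else {
      stop("row ", i, ": neither DOD nor ADF carries a follow-up time")
    }
    if (known && time <= 0) stop("row ", i, ": follow-up time must be positive")

    rel <- asMonths(sub("/.*$", "", r$relapse_months))
    if (!is.na(rel)) {
      if (rel <= 0) stop("row ", i, ": relapse time must be positive")
      if (known && rel > time) {
        stop("row ", i, ": progression time exceeds follow-up time")
      }
      tprog <- rel; prog <- TRUE
    } else {
      tprog <- time; prog <- FALSE
    }
    data.frame(
      patient_id = trimws(r$id), age_years = asMonths(r$age_years),
      sex = sex, group_label = trimws(r$nanostring_diagnosis),
      fusion_call = if (isNo(r$ngs_fusion) ||
                        toupper(trimws(r$ngs_fusion)) == "NOT DETECTED")
        NA_character_ else trimws(r$ngs_fusion),
      diagnosis = trimws(r$original_diagnosis),
      time_months = time, time_known = known, event_death = death,
      time_progression_months = tprog, event_progression = prog,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Packaged supratentorial clinical cohort
#'
#' The 15 supratentorial patients analysed by the classifier (nine RELA+
#' ependymomas, one RELA+ tumour originally diagnosed as PNET, one YAP1+
#' and four not-classified ependymomas), with age, sex, NanoString group,
#' NGS fusion call and follow-up.
#'
#' @return a clinical \code{data.frame}, see [readClinicalTable()].
#' @examples
#' clin <- supratentorialClinical()
#' table(clin$group_label)
#' @export
supratentorialClinical <- function() {
  readClinicalTable(system.file("extdata", "supratentorial_clinical.csv",
                                package = "epnsig", mustWork = TRUE))
}

#' Packaged supratentorial assignment report
#'
#' Final molecular labels of the 16 histopathologically diagnosed
#' supratentorial ependymomas (RELA+, YAP1+, CNS HGNET-MN1 or NC), as an
#' assignment report.
#'
#' @return a \code{data.frame} of assignments, see [readAssignments()].
#' @export
supratentorialAssignments <- function() {
  readAssignments(system.file("extdata", "supratentorial_assignments.tsv",
                              package = "epnsig", mustWork = TRUE))
}

#' Write a clinical table
#'
#' Inverse of [readClinicalTable()] for programmatically generated cohorts
#' (e.g. [simulateSurvival()]); the emitted CSV re-reads to an equal table.
#'
#' @param records a clinical \code{data.frame}.
#' @param path output CSV path.
#' @return invisibly, \code{path}.
#' @export
writeClinicalTable <- function(records, path) {
  fmt <- function(x) ifelse(is.na(x), "No", format(x, trim = TRUE))
  raw <- data.frame(
    id = records$patient_id,
    age_years = records$age_years,
    sex = records$sex,
    nanostring_diagnosis = records$group_label,
    ngs_fusion = ifelse(is.na(records$fusion_call), "Not detected",
                        records$fusion_call),
    original_diagnosis = records$diagnosis,
    relapse_months = ifelse(records$event_progression,
                            fmt(records$time_progression_months), "No"),
    dod_months = ifelse(records$event_death,
                        ifelse(records$time_known,
                               fmt(records$time_months), "Yes"), "No"),
    adf_months = ifelse(!records$event_death, fmt(records$time_months), "-"),
    stringsAsFactors = FALSE
  )
  utils::write.csv(raw, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
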