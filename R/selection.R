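#' Validate and normalise a table of HbA1c measurements
#'
#' Checks column types, removes exact duplicate rows (same patient, date and
#' value), rejects conflicting same-day values and sorts by patient and date.
#' Values are validated against the plausible assay range: values outside
#' \[3, 25\] are an error, values outside \[4, 20\] raise a warning.
#'
#' @param measurements data frame with columns `patient_id`, `date` (Date),
#'   `value` (HbA1c in percent).
#' @return the validated, sorted data frame.
#' @export
validate_measurements <- function(measurements) {
  stopifnot(is.data.frame(measurements))
  need <- c("patient_id", "date", "value")
  miss <- setdiff(need, names(measurements))
  if (length(miss)) {
    stop("measurements is missing column(s): ", paste(miss, collapse = ", "))
  }
  m <- measurements[need]
  m$patient_id <- as.character(m$patient_id)
  m$date <- as.Date(m$date)
  m$value <- as.numeric(m$value)
  if (anyNA(m$date)) stop("measurements contain unparseable dates")
  if (anyNA(m$value)) stop("measurements contain non-numeric HbA1c values")
  if (any(m$value < 3 | m$value > 25)) {
    stop("HbA1c values outside the plausible range [3, 25]%: ",
         paste(unique(m$patient_id[m$value < 3 | m$value > 25]), collapse = ", "))
  }
  if (any(m$value < 4 | m$value > 20)) {
    warning("HbA1c values outside [4, 20]% retained; check units")
  }
  dup <- duplicated(m)
  if (any(dup)) {
    warning(sum(dup), " exact duplicate measurement row(s) removed")
    m <- m[!dup, , drop = FALSE]
  }
  m <- m[order(m$patient_id, m$date, m$value), , drop = FALSE]
  clash <- duplicated(m[c("patient_id", "date")])
  if (any(clash)) {
    stop("conflicting same-day HbA1c values for patient(s): ",
         paste(unique(m$patient_id[clash]), collapse = ", "))
  }
  rownames(m) <- NULL
  m
}

#' Patients with a minimum number of HbA1c tests
#'
#' First stage of the selection funnel: a patient's evolution can only be
#' assessed with at least two recorded test results.
#'
#' @param measurements validated measurement table.
#' @param min_count minimum number of distinct measurement records (default 2).
#' @return sorted character vector of retained patient ids.
#' @export
filter_min_measurements <- function(measurements, min_count = 2) {
  if (nrow(measurements) == 0) return(character(0))
  counts <- table(measurements$patient_id)
  sort(names(counts)[counts >= min_count])
}

#' Patients free of comorbidities and diabetes-related complications
#'
#' Retains patients whose diabetes complication severity index count and
#' chronic-illness-with-complexity count are both zero. The counts are inputs
#' (precomputed from diagnosis codes upstream); missing values are an error.
#'
#' @param patients data frame with columns `patient_id`, `dcsi_count`,
#'   `cic_count`.
#' @return sorted character vector of retained patient ids.
#' @export
filter_comorbidity <- function(patients) {
  need <- c("patient_id", "dcsi_count", "cic_count")
  miss <- setdiff(need, names(patients))
  if (length(miss)) stop("patients is missing column(s): ", paste(miss, collapse = ", "))
  bad <- is.na(patients$dcsi_count) | is.na(patients$cic_count)
  if (any(bad)) {
    stop("missing comorbidity flags for patient(s): ",
         paste(patients$patient_id[bad], collapse = ", "))
  }
  keep <- patients$dcsi_count == 0 & patients$cic_count == 0
  sort(as.character(patients$patient_id[keep]))
}

#' Maximum allowed gap to the next HbA1c test
#'
#' Follow-up protocol: compensated patients (< 7%) are retested within 12
#' months, moderately decompensated patients (7--9%, inclusive) within 6
#' months, and highly decompensated patients (> 9%) within 3 months. A
#' fixed tolerance (default 4 months) is added to absorb scheduling delays
#' attributable to the health care centre rather than the patient.
#'
#' @param previous_value HbA1c value (percent) of the earlier test; vectorised.
#' @param tolerance_months scheduling tolerance added to every protocol window.
#' @return allowed gap in months.
#' @export
allowed_test_gap <- function(previous_value, tolerance_months = 4) {
  if (any(is.na(previous_value))) stop("previous_value contains NA")
  protocol <- ifelse(previous_value < 7, 12, ifelse(previous_value <= 9, 6, 3))
  protocol + tolerance_months
}

#' Patients adherent to the HbA1c testing protocol
#'
#' A patient is retained iff every consecutive inter-test gap is at most
#' [allowed_test_gap()] of the earlier test's value. Gaps are measured in
#' months (days / 30.44); the bound is inclusive. Patients with fewer than two
#' tests are excluded (they should already have been filtered out).
#'
#' @param measurements validated measurement table.
#' @param tolerance_months passed to [allowed_test_gap()].
#' @return sorted character vector of retained patient ids.
#' @export
filter_adherence <- function(measurements, tolerance_months = 4) {
  if (nrow(measurements) == 0) return(character(0))
  keep <- vapply(split(measurements, measurements$patient_id), function(m) {
    if (nrow(m) < 2) return(FALSE)
    m <- m[order(m$date), , drop = FALSE]
    gaps <- diff(as.numeric(m$date)) / MONTH_DAYS
    allowed <- allowed_test_gap(m$value[-nrow(m)], tolerance_months)
    all(gaps <= allowed + 1e-9)
  }, logical(1))
  sort(names(keep)[keep])
}

#' Define the normalised study window for one patient
#'
#' Point zero is the patient's first HbA1c measurement. The closing
#' measurement is the one whose offset from point zero is closest to
#' `center` months among offsets within `center +/- halfwidth` months; ties
#' are broken towards the earlier candidate (shorter follow-up). Patients with
#' no measurement in range are rejected.
#'
#' @param dates one patient's measurement dates: a Date vector, or a numeric
#'   vector of day offsets.
#' @param center target window length in months (default 18).
#' @param halfwidth tolerance around the target (default 8, i.e. 10--26).
#' @return list with `t0`, `t_end`, `span_months`, or `NULL` if rejected.
#' @export
define_study_window <- function(dates, center = 18, halfwidth = 8) {
  dates <- sort(if (is.numeric(dates)) dates else as.Date(dates))
  if (length(dates) < 2) return(NULL)
  t0 <- dates[1]
  off <- if (is.numeric(dates)) (dates - t0) / MONTH_DAYS
         else months_between(t0, dates)
  in_range <- which(off >= center - halfwidth & off <= center + halfwidth)
  if (!length(in_range)) return(NULL)
  score <- abs(off[in_range] - center)
  # order() is stable, so equal scores resolve to the earlier measurement
  pick <- in_range[order(score)[1]]
  list(t0 = t0, t_end = dates[pick], span_months = off[pick])
}

#' Study windows for every patient in a measurement table
#'
#' @param measurements validated measurement table.
#' @inheritParams define_study_window
#' @return list with `windows` (data frame `patient_id`, `t0`, `t_end`,
#'   `span_months`) and `rejected` (ids with no in-range closing measurement).
#' @export
define_study_windows <- function(measurements, center = 18, halfwidth = 8) {
  ids <- sort(unique(measurements$patient_id))
  rows <- list()
  rejected <- character(0)
  for (id in ids) {
    w <- define_study_window(measurements$date[measurements$patient_id == id],
                             center, halfwidth)
    if (is.null(w)) {
      rejected <- c(rejected, id)
    } else {
      rows[[id]] <- data.frame(patient_id = id, t0 = w$t0, t_end = w$t_end,
                               span_months = w$span_months)
    }
  }
  windows <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
             else data.frame(patient_id = character(0), t0 = as.Date(character(0)),
                             t_end = as.Date(character(0)), span_months = numeric(0))
  list(windows = windows, rejected = rejected)
}

#' Run the patient-selection funnel
#'
#' Applies, in order: minimum test count, comorbidity exclusion,
#' protocol-adherence check, and study-window normalisation. Each stage
#' restricts the previous stage's retained set, so stage counts are
#' non-increasing.
#'
#' @param patients patient table with comorbidity counts.
#' @param measurements validated measurement table.
#' @param min_tests minimum number of HbA1c tests (default 2).
#' @param tolerance_months adherence tolerance (default 4).
#' @param window_center,window_halfwidth study-window parameters (18 +/- 8).
#' @return object of class `selection_report`: list with `eligible` (ids),
#'   `windows` (study windows of eligible patients) and `counts` (named
#'   funnel-stage counts).
#' @export
run_funnel <- function(patients, measurements, min_tests = 2,
                       tolerance_months = 4, window_center = 18,
                       window_halfwidth = 8) {
  all_ids <- sort(unique(as.character(patients$patient_id)))
  extra <- setdiff(unique(measurements$patient_id), all_ids)
  if (length(extra)) {
    stop("measurements contain unknown patient id(s): ",
         paste(extra, collapse = ", "))
  }
  s1 <- intersect(all_ids, filter_min_measurements(measurements, min_tests))
  s2 <- intersect(s1, filter_comorbidity(patients))
  m2 <- measurements[measurements$patient_id %in% s2, , drop = FALSE]
  s3 <- intersect(s2, filter_adherence(m2, tolerance_months))
  m3 <- measurements[measurements$patient_id %in% s3, , drop = FALSE]
  ws <- define_study_windows(m3, window_center, window_halfwidth)
  s4 <- intersect(s3, ws$windows$patient_id)
  structure(list(
    eligible = s4,
    windows = ws$windows[ws$windows$patient_id %in% s4, , drop = FALSE],
    counts = c(total = length(all_ids), min_tests = length(s1),
               no_comorbidity = length(s2), adherent = length(s3),
               valid_window = length(s4))
  ), class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("Patient selection funnel\n")
  stage <- c("total", ">= min tests", "no comorbidity", "adherent",
             "valid study window")
  for (i in seq_along(x$counts)) {
    cat(sprintf("  %-20s %d\n", stage[i], x$counts[i]))
  }
  invisible(x)
}
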