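parse_dates <- function(x, path, what) {
  d <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(is.na(d) | is.na(x))
  if (length(bad)) {
    stop("unparseable ", what, " date(s) in ", path, " at data row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  d
}

#' Read a CVPA encounter extract
#'
#' Expects a CSV with header `patient_id,date,discipline` and optional
#' `appointment_type`, `next_discipline`, `next_date` columns. Dates must be
#' ISO-8601; disciplines may be given as `P`/`N`/`D` or the case-insensitive
#' synonyms physician/nurse/dietitian. Rows whose `appointment_type` is
#' present and not `CVPA` are dropped (with a message); any other discipline
#' token is an error, since only the physician--nurse--dietitian triad is
#' analysed.
#'
#' @param path CSV file path.
#' @return data frame with columns `patient_id`, `date`, `discipline` (and
#'   `next_discipline`, `next_date` when present in the file).
#' @export
read_encounters <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("patient_id", "date", "discipline")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop(path, " is missing column(s): ", paste(miss, collapse = ", "))
  }
  if ("appointment_type" %in% names(raw)) {
    keep <- !nzchar(raw$appointment_type) | is.na(raw$appointment_type) |
      toupper(raw$appointment_type) == "CVPA"
    if (any(!keep)) {
      message(sum(!keep), " non-CVPA encounter row(s) dropped")
      raw <- raw[keep, , drop = FALSE]
    }
  }
  disc <- canon_discipline(raw$discipline)
  bad <- which(is.na(disc))
  if (length(bad)) {
    stop("unknown discipline token(s) in ", path, " at data row(s): ",
         paste(utils::head(bad, 10), collapse = ", "),
         " (only the physician/nurse/dietitian triad is supported)")
  }
  out <- data.frame(patient_id = raw$patient_id,
                    date = parse_dates(raw$date, path, "encounter"),
                    discipline = disc)
  if ("next_discipline" %in% names(raw)) {
    out$next_discipline <- canon_discipline(raw$next_discipline)
  }
  if ("next_date" %in% names(raw)) {
    nd <- as.Date(raw$next_date, format = "%Y-%m-%d")
    out$next_date <- nd
  }
  dup <- duplicated(out[c("patient_id", "date", "discipline")])
  if (any(dup)) {
    warning(sum(dup), " duplicate encounter row(s) removed")
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Read an HbA1c measurement extract
#'
#' Expects a CSV with header `patient_id,date,hba1c_percent` (ISO-8601 dates,
#' dot-decimal values). The result is validated and per-patient date-sorted
#' via [validate_measurements()].
#'
#' @param path CSV file path.
#' @return validated measurement data frame (`patient_id`, `date`, `value`).
#' @export
read_measurements <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("patient_id", "date", "hba1c_percent")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop(path, " is missing column(s): ", paste(miss, collapse = ", "))
  }
  val <- suppressWarnings(as.numeric(raw$hba1c_percent))
  bad <- which(is.na(val) | val < 0)
  if (length(bad)) {
    stop("non-numeric or negative HbA1c value(s) in ", path,
         " at data row(s): ", paste(utils::head(bad, 10), collapse = ", "),
         " (use dot-decimal notation, e.g. 7.4)")
  }
  validate_measurements(data.frame(patient_id = raw$patient_id,
                                   date = parse_dates(raw$date, path, "test"),
                                   value = val))
}

#' Read a patient table
#'
#' Expects a CSV with header
#' `patient_id,age,sex,years_with_t2dm,dcsi_count,cic_count`.
#'
#' @param path CSV file path.
#' @return data frame of patient records.
#' @export
read_patients <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "dcsi_count", "cic_count")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop(path, " is missing column(s): ", paste(miss, collapse = ", "))
  }
  raw$patient_id <- as.character(raw$patient_id)
  if (any(duplicated(raw$patient_id))) {
    stop("duplicate patient_id(s) in ", path, ": ",
         paste(unique(raw$patient_id[duplicated(raw$patient_id)]), collapse = ", "))
  }
  neg <- !is.na(raw$dcsi_count) & raw$dcsi_count < 0 |
    !is.na(raw$cic_count) & raw$cic_count < 0
  if (any(neg)) {
    stop("negative comorbidity count(s) in ", path, " for patient(s): ",
         paste(raw$patient_id[neg], collapse = ", "))
  }
  raw
}

#' Write a synthetic cohort to CSV files
#'
#' Writes `encounters.csv`, `measurements.csv` and `patients.csv` in the
#' dialects the readers expect, plus `truth.csv` with the planted labels.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return named vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(encounters = file.path(dir, "encounters.csv"),
             measurements = file.path(dir, "measurements.csv"),
             patients = file.path(dir, "patients.csv"),
             truth = file.path(dir, "truth.csv"))
  write.csv(cohort$encounters, paths["encounters"], row.names = FALSE)
  m <- cohort$measurements
  names(m)[names(m) == "value"] <- "hba1c_percent"
  write.csv(m, paths["measurements"], row.names = FALSE)
  write.csv(cohort$patients, paths["patients"], row.names = FALSE)
  tr <- cohort$truth
  names(tr) <- c("patient_id", "planted_pattern", "planted_segment",
                 "adherence_violator")
  write.csv(tr, paths["truth"], row.names = FALSE)
  invisible(paths)
}

#' Read a cohort previously written with [write_cohort()]
#'
#' @param dir directory containing the CSV files.
#' @return list with `encounters`, `measurements`, `patients` (validated data
#'   frames) and, when present, `truth`.
#' @export
read_cohort <- function(dir) {
  out <- list(encounters = read_encounters(file.path(dir, "encounters.csv")),
              measurements = read_measurements(file.path(dir, "measurements.csv")),
              patients = read_patients(file.path(dir, "patients.csv")))
  truth_path <- file.path(dir, "truth.csv")
  if (file.exists(truth_path)) {
    out$truth <- read.csv(truth_path, stringsAsFactors = FALSE)
  }
  out
}
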