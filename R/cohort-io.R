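cohort_files <- c(demographics = "demographics.csv",
                  uo_records = "urine_output.csv",
                  scr_records = "creatinine.csv",
                  truth = "truth.csv")

#' Write a synthetic cohort to CSV files
#'
#' Emits `demographics.csv`, `urine_output.csv`, `creatinine.csv` and
#' `truth.csv` (comma-separated, dot decimal, ISO-8601 UTC timestamps,
#' header row always present). `truth.csv` is written alongside but is never
#' consumed by the analysis pipeline; it exists for validation only.
#'
#' @param cohort an `icu_cohort`.
#' @param directory output directory (created if absent).
#' @param overwrite overwrite existing files? Defaults to refusing.
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, directory, overwrite = FALSE) {
  stopifnot(inherits(cohort, "icu_cohort"))
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  paths <- file.path(directory, cohort_files)
  clash <- file.exists(paths)
  abort_if(any(clash) && !overwrite,
           paste0("refusing to overwrite existing file(s): ",
                  paste(basename(paths[clash]), collapse = ", "),
                  " (use overwrite = TRUE)"))
  for (nm in names(cohort_files)) {
    readr::write_csv(cohort[[nm]], file.path(directory, cohort_files[[nm]]))
  }
  invisible(directory)
}

#' Read a cohort from CSV files
#'
#' Inverse of [write_cohort()]. By default the truth table is withheld
#' (`truth = NULL`) so the pipeline cannot accidentally consume labels; set
#' `with_truth = TRUE` in validation code.
#'
#' @param directory directory containing the cohort CSVs.
#' @param with_truth also read `truth.csv`?
#' @return an `icu_cohort`.
#' @export
read_cohort <- function(directory, with_truth = FALSE) {
  need <- cohort_files[c("demographics", "uo_records", "scr_records")]
  abort_if(!all(file.exists(file.path(directory, need))),
           paste0("missing cohort files in ", directory))
  tcol <- function(...) readr::cols(...)
  demographics <- readr::read_csv(
    file.path(directory, "demographics.csv"),
    col_types = tcol(patient_id = "c", sex = "c", age_group = "c",
                     height_range = "c", admit_time = "T",
                     discharge_time = "T", died_in_hospital = "l"),
    progress = FALSE)
  uo_records <- readr::read_csv(
    file.path(directory, "urine_output.csv"),
    col_types = tcol(patient_id = "c", timestamp = "T", volume_ml = "d"),
    progress = FALSE)
  scr_records <- readr::read_csv(
    file.path(directory, "creatinine.csv"),
    col_types = tcol(patient_id = "c", timestamp = "T", value_mg_dl = "d"),
    progress = FALSE)
  truth <- NULL
  if (with_truth && file.exists(file.path(directory, "truth.csv"))) {
    truth <- readr::read_csv(
      file.path(directory, "truth.csv"),
      col_types = tcol(patient_id = "c", has_event = "l",
                       true_onset_hour = "i", phase_start_hour = "i"),
      progress = FALSE)
  }
  structure(list(demographics = demographics, uo_records = uo_records,
                 scr_records = scr_records, truth = truth, config = NULL),
            class = "icu_cohort")
}
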