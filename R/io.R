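# Plain-text interchange: gaze CSV, schedule JSON, clinical CSV.

#' Write a simulated cohort to disk
#'
#' Gaze samples as CSV (one row per sample: subject, group, task, trial, time,
#' left/right pixel coordinates and validity), the schedule as JSON (per-trial
#' onset/offset and task parameters) and the clinical table as CSV.
#'
#' @param cohort output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gz <- cohort$gaze
  sch <- cohort$schedule
  trial_of <- function(sub, task, t) {
    s <- sch[sch$subject_id == sub & sch$task_id == task, ]
    id <- rep(NA_integer_, length(t))
    for (r in seq_len(nrow(s))) {
      id[t >= s$t_on[r] & t < s$t_off[r]] <- s$trial_id[r]
    }
    id
  }
  gz$trial_id <- NA_integer_
  gz_key <- paste(gz$subject_id, gz$task_id)
  for (key in unique(gz_key)) {
    idx <- gz_key == key
    gz$trial_id[idx] <- trial_of(gz$subject_id[idx][1], gz$task_id[idx][1],
                                 gz$t_s[idx])
  }
  cols <- c("subject_id", "group", "task_id", "trial_id", "t_s",
            "lx_px", "ly_px", "l_valid", "rx_px", "ry_px", "r_valid")
  utils::write.csv(gz[, cols], file.path(dir, "gaze.csv"), row.names = FALSE)
  jsonlite::write_json(cohort$schedule, file.path(dir, "schedule.json"),
                       dataframe = "rows", digits = NA, na = "null")
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#' @param dir directory containing gaze.csv, schedule.json, clinical.csv.
#' @param spec the [cohort_spec()] the files were generated under (screen
#'   geometry and sampling rate are needed downstream).
#' @return cohort list as produced by [simulate_cohort()] (without profiles).
#' @export
read_cohort <- function(dir, spec = cohort_spec()) {
  gaze <- utils::read.csv(file.path(dir, "gaze.csv"))
  schedule <- as.data.frame(jsonlite::read_json(file.path(dir, "schedule.json"),
                                                simplifyVector = TRUE))
  clinical <- utils::read.csv(file.path(dir, "clinical.csv"))
  list(spec = spec, gaze = gaze, schedule = schedule, clinical = clinical)
}
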