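## Subject metadata tables ("cohorts") and their TSV serialization.
##
## A cohort is a plain data.frame with one row per subject and columns
##   subject_id, site, sex, course, follow_up_years
## plus a list column `history` of episode_history objects (or NULL where no
## follow-up information exists). course is always derivable from history.

COURSE_LEVELS <- c("continuous", "remitting", "excluded")
SEX_LEVELS <- c("male", "female")

#' Validate a cohort data frame
#'
#' Checks the subject-metadata contract: required columns present, unique
#' subject ids, sex/course values in their vocabularies, and (when interval
#' histories are attached) agreement between the stored `course` column and
#' [classify_illness_course()] applied to each history.
#'
#' @param cohort A data.frame of subjects.
#' @param check_history If `TRUE`, re-derive course labels from histories.
#' @return The cohort, invisibly; errors describe the offending row.
#' @export
validate_cohort <- function(cohort, check_history = TRUE) {
  req <- c("subject_id", "site", "sex", "course")
  miss <- setdiff(req, names(cohort))
  if (length(miss))
    stop("cohort is missing column(s): ", paste(miss, collapse = ", "))
  dup <- cohort$subject_id[duplicated(cohort$subject_id)]
  if (length(dup))
    stop("duplicate subject_id: ", paste(unique(dup), collapse = ", "))
  bad <- which(!cohort$sex %in% SEX_LEVELS)
  if (length(bad))
    stop(sprintf("row %d: invalid sex '%s'", bad[1L], cohort$sex[bad[1L]]))
  bad <- which(!cohort$course %in% COURSE_LEVELS)
  if (length(bad))
    stop(sprintf("row %d: invalid course '%s'", bad[1L], cohort$course[bad[1L]]))
  if (check_history && !is.null(cohort$history)) {
    for (i in seq_len(nrow(cohort))) {
      h <- cohort$history[[i]]
      if (is.null(h)) next
      lab <- classify_illness_course(h)
      if (lab != cohort$course[i])
        stop(sprintf("row %d (%s): course '%s' disagrees with history ('%s')",
                     i, cohort$subject_id[i], cohort$course[i], lab))
    }
  }
  invisible(cohort)
}

#' Restrict a cohort to the outcome-analysis subjects
#'
#' Keeps only subjects with a continuous or remitting illness-course label
#' (dropping the excluded group), optionally restricted further to males —
#' the less-heterogeneous design used when female cell counts per site are
#' too small to support a model. Input row order is preserved.
#'
#' @param cohort A validated cohort data.frame.
#' @param males_only Keep male subjects only (default `FALSE`).
#' @return The filtered cohort.
#' @export
select_outcome_cohort <- function(cohort, males_only = FALSE) {
  validate_cohort(cohort, check_history = FALSE)
  keep <- cohort$course %in% c("continuous", "remitting")
  if (males_only) keep <- keep & cohort$sex == "male"
  cohort[keep, , drop = FALSE]
}

## serialize one history to a compact JSON string (NA for absent)
history_to_json <- function(h) {
  if (is.null(h)) return(NA_character_)
  rows <- function(m) lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
  as.character(jsonlite::toJSON(list(
    episodes = rows(h$episodes),
    remissions = rows(h$remissions),
    follow_up_days = h$follow_up_days), auto_unbox = TRUE, digits = NA))
}

history_from_json <- function(s) {
  if (is.na(s) || !nzchar(s)) return(NULL)
  x <- jsonlite::fromJSON(s, simplifyVector = TRUE)
  to_mat <- function(v) {
    if (length(v) == 0L) return(NULL)
    if (is.list(v)) v <- do.call(rbind, v)
    matrix(as.numeric(v), ncol = 2L)
  }
  episode_history(to_mat(x$episodes), to_mat(x$remissions), x$follow_up_days)
}

#' Write subject metadata to a TSV file
#'
#' Columns: `subject_id, site, sex, course, follow_up_years, history_json`.
#' Episode histories are serialized as JSON strings so the file remains a
#' flat, human-readable table; [read_metadata()] inverts this losslessly.
#'
#' @param cohort A validated cohort.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(cohort, path) {
  validate_cohort(cohort, check_history = FALSE)
  hist <- if (is.null(cohort$history)) rep(NA_character_, nrow(cohort))
          else vapply(cohort$history, history_to_json, character(1L))
  fu <- if (is.null(cohort$follow_up_years)) rep(NA_real_, nrow(cohort))
        else cohort$follow_up_years
  out <- data.frame(subject_id = cohort$subject_id, site = cohort$site,
                    sex = cohort$sex, course = cohort$course,
                    follow_up_years = fu, history_json = hist,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Read subject metadata from a TSV file
#'
#' @param path A TSV written by [write_metadata()] (or matching its columns).
#' @return A validated cohort data.frame with histories reconstructed.
#' @export
read_metadata <- function(path) {
  raw <- read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
                    colClasses = "character", fileEncoding = "UTF-8")
  req <- c("subject_id", "site", "sex", "course", "follow_up_years",
           "history_json")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop("metadata file missing column(s): ", paste(miss, collapse = ", "))
  cohort <- data.frame(subject_id = raw$subject_id, site = raw$site,
                       sex = raw$sex, course = raw$course,
                       follow_up_years = suppressWarnings(
                         as.numeric(raw$follow_up_years)),
                       stringsAsFactors = FALSE)
  cohort$history <- lapply(seq_len(nrow(raw)), function(i) {
    tryCatch(history_from_json(raw$history_json[i]),
             error = function(e) stop(sprintf(
               "row %d (%s): bad history_json: %s", i, raw$subject_id[i],
               conditionMessage(e))))
  })
  if (nrow(cohort) == 0L) cohort$history <- list()
  validate_cohort(cohort)
  cohort
}
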