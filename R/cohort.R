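#' @section Cohort data model:
#' A cohort bundles three tables keyed to each other:
#' participants (one row each: `participant_id`, `status` in case/control,
#' `age_at_reference`, `sex`, `military`, `education`, `onset_year` for
#' cases, `consent_year`), jobs (up to four per participant: `job_id`,
#' `participant_id`, `slot`, `title`, `description`, `start_year`,
#' `end_year`), and long-format survey responses (`job_id`, `question_id`,
#' `response`).
#' @name cohort-model
NULL

PARTICIPANT_COLS <- c("participant_id", "status", "age_at_reference", "sex",
                      "military", "education", "onset_year", "consent_year")
JOB_COLS <- c("job_id", "participant_id", "slot", "title", "description",
              "start_year", "end_year")
RESPONSE_COLS <- c("job_id", "question_id", "response")

# Same-year jobs get a half-year floor so they still carry weight in
# duration-adjusted scores and job-years.
MIN_JOB_DURATION <- 0.5

read_table_arg <- function(x, what) {
  if (is.data.frame(x)) return(x)
  if (!is.character(x) || !file.exists(x))
    stop("cannot read ", what, " table: ", x)
  utils::read.csv(x, stringsAsFactors = FALSE)
}

require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " table missing required column(s): ",
         paste(miss, collapse = ", "))
  df
}

#' Job duration in years
#'
#' `end_year - start_year`, floored at half a year so same-year jobs do not
#' vanish from duration-weighted quantities.
#'
#' @param start_year,end_year Calendar years.
#' @return Numeric durations.
#' @export
job_duration <- function(start_year, end_year) {
  pmax(end_year - start_year, MIN_JOB_DURATION)
}

#' Load and validate a cohort
#'
#' Reads the three cohort tables (CSV paths or data frames), checks the
#' column dictionary, key uniqueness, referential integrity, and that every
#' `question_id` in the responses belongs to the schema.
#'
#' @param participants,jobs,responses CSV paths or data frames.
#' @param schema An `occx_schema` ([default_schema()] or [read_schema()]).
#' @return An object of class `occx_cohort`: list with `participants`,
#'   `jobs`, `responses`, `schema`, and `log` (loading notes).
#' @export
load_cohort <- function(participants, jobs, responses, schema = default_schema()) {
  schema <- as_schema(schema)
  p <- require_cols(read_table_arg(participants, "participants"),
                    PARTICIPANT_COLS, "participants")
  j <- require_cols(read_table_arg(jobs, "jobs"), JOB_COLS, "jobs")
  r <- require_cols(read_table_arg(responses, "responses"),
                    RESPONSE_COLS, "responses")

  p$participant_id <- as.character(p$participant_id)
  j$participant_id <- as.character(j$participant_id)
  j$job_id <- as.character(j$job_id)
  r$job_id <- as.character(r$job_id)
  for (col in c("status", "sex", "military", "education"))
    p[[col]] <- as.character(p[[col]])

  if (anyDuplicated(p$participant_id))
    stop("duplicate participant_id: ",
         paste(unique(p$participant_id[duplicated(p$participant_id)]),
               collapse = ", "))
  if (anyDuplicated(j$job_id))
    stop("duplicate job_id: ",
         paste(unique(j$job_id[duplicated(j$job_id)]), collapse = ", "))

  bad <- setdiff(j$participant_id, p$participant_id)
  if (length(bad))
    stop("jobs reference unknown participant_id: ",
         paste(bad, collapse = ", "))
  badj <- setdiff(r$job_id, j$job_id)
  if (length(badj))
    stop("responses reference unknown job_id: ", paste(badj, collapse = ", "))

  known_q <- schema_items(schema)$question_id
  badq <- setdiff(unique(r$question_id), known_q)
  if (length(badq))
    stop("responses contain question_id not in schema: ",
         paste(badq, collapse = ", "))

  if (!all(p$status %in% c("case", "control")))
    stop("participant status must be 'case' or 'control'")
  if (any(p$age_at_reference <= 18, na.rm = TRUE))
    stop("participants must be older than 18")
  njob <- table(j$participant_id)
  if (any(njob > 4))
    stop("more than 4 jobs for participant(s): ",
         paste(names(njob)[njob > 4], collapse = ", "))
  bad_span <- !is.na(j$start_year) & !is.na(j$end_year) &
    j$start_year > j$end_year
  if (any(bad_span))
    stop("job start_year after end_year at row(s): ",
         paste(which(bad_span), collapse = ", "))

  j$duration <- job_duration(j$start_year, j$end_year)
  r$response[r$response %in% c("", "NA")] <- NA_character_

  structure(
    list(participants = p, jobs = j, responses = r, schema = schema,
         log = sprintf("loaded %d participants, %d jobs, %d responses",
                       nrow(p), nrow(j), nrow(r))),
    class = "occx_cohort")
}

#' @export
print.occx_cohort <- function(x, ...) {
  st <- table(x$participants$status)
  cat("<occx_cohort> ", nrow(x$participants), " participants (",
      sum(x$participants$status == "case"), " case / ",
      sum(x$participants$status == "control"), " control), ",
      nrow(x$jobs), " jobs, ", nrow(x$responses), " responses\n", sep = "")
  invisible(x)
}

#' Reference year per participant
#'
#' Symptom-onset year for cases and consent year for controls; anchors job
#' eligibility and pre-onset time windows.
#'
#' @param cohort An `occx_cohort`.
#' @return Named numeric vector keyed by participant_id (NA for cases
#'   without an onset year).
#' @export
reference_year <- function(cohort) {
  p <- cohort$participants
  ref <- ifelse(p$status == "case", p$onset_year, p$consent_year)
  stats::setNames(as.numeric(ref), p$participant_id)
}

#' Apply job eligibility rules
#'
#' Drops jobs that began after the participant's reference year: for cases,
#' jobs starting strictly after symptom onset (and all jobs of cases with no
#' onset year on record); for controls, jobs starting strictly after survey
#' consent. Jobs beginning in the reference year itself are retained.
#'
#' @param cohort An `occx_cohort`.
#' @return The filtered cohort; attribute `"exclusion_log"` holds a data
#'   frame of dropped jobs with the reason.
#' @export
filter_eligible_jobs <- function(cohort) {
  stopifnot(inherits(cohort, "occx_cohort"))
  j <- cohort$jobs
  ref <- reference_year(cohort)[j$participant_id]
  no_ref <- is.na(ref)
  late <- !no_ref & j$start_year > ref
  drop <- no_ref | late
  reason <- ifelse(no_ref, "case without onset year",
                   "job began after reference year")
  log <- data.frame(job_id = j$job_id[drop],
                    participant_id = j$participant_id[drop],
                    reason = reason[drop], stringsAsFactors = FALSE)
  cohort$jobs <- j[!drop, , drop = FALSE]
  cohort$responses <-
    cohort$responses[cohort$responses$job_id %in% cohort$jobs$job_id, ,
                     drop = FALSE]
  attr(cohort, "exclusion_log") <- log
  cohort
}

#' Impute missing military service with the mode
#'
#' Single imputation: missing values are replaced by the modal category of
#' the observed values (ties broken by the earlier category in sorted
#' order).
#'
#' @param cohort An `occx_cohort`.
#' @return Cohort with `military` completed; attribute `"n_imputed"` gives
#'   the count.
#' @export
impute_military <- function(cohort) {
  stopifnot(inherits(cohort, "occx_cohort"))
  m <- cohort$participants$military
  miss <- is.na(m) | m == "missing"
  obs <- m[!miss]
  if (!length(obs)) stop("all military values missing; cannot impute")
  tab <- sort(table(obs), decreasing = TRUE)
  mode_cat <- names(tab)[1L]
  cohort$participants$military[miss] <- mode_cat
  attr(cohort, "n_imputed") <- sum(miss)
  cohort
}

#' Build the covariate design table
#'
#' Age quartiles are computed on the combined case+control sample
#' (empirical quartiles, linear interpolation) with half-open bins
#' \[q0,q1), \[q1,q2), \[q2,q3), \[q3,q4\]: a value exactly at an interior
#' boundary falls in the upper bin. Sex (reference female) and military
#' service (reference neither) enter as indicators. Military must be
#' imputed first.
#'
#' @param cohort An `occx_cohort` with complete `military`.
#' @return data.frame with one row per participant: `participant_id`,
#'   `age_quartile` (factor 1-4), `male` (0/1), `enlisted` (0/1).
#' @export
make_covariates <- function(cohort) {
  stopifnot(inherits(cohort, "occx_cohort"))
  p <- cohort$participants
  if (nrow(p) < 8) stop("need at least 8 participants for stable quartiles")
  if (any(is.na(p$military) | p$military == "missing"))
    stop("military has missing values; run impute_military() first")
  age <- p$age_at_reference
  qs <- stats::quantile(age, probs = c(0.25, 0.5, 0.75), names = FALSE)
  quart <- findInterval(age, qs) + 1L   # x == boundary -> upper bin
  data.frame(participant_id = p$participant_id,
             age_quartile = factor(quart, levels = 1:4),
             male = as.integer(p$sex == "male"),
             enlisted = as.integer(p$military == "enlisted"),
             stringsAsFactors = FALSE)
}

#' Adjustment covariate model matrix
#'
#' Expands the covariate table into the numeric design used by every
#' adjusted model: three age-quartile indicators (reference quartile 1),
#' sex (male = 1) and military service (enlisted = 1), row-aligned to the
#' given participant ids.
#'
#' @param covariates Output of [make_covariates()].
#' @param participant_ids Character vector ordering the rows.
#' @return Numeric matrix with rownames `participant_ids`.
#' @export
covariate_matrix <- function(covariates, participant_ids) {
  idx <- match(participant_ids, covariates$participant_id)
  if (anyNA(idx)) stop("covariates missing for some participants")
  cv <- covariates[idx, , drop = FALSE]
  m <- cbind(age_q2 = as.integer(cv$age_quartile == 2),
             age_q3 = as.integer(cv$age_quartile == 3),
             age_q4 = as.integer(cv$age_quartile == 4),
             male = cv$male, enlisted = cv$enlisted)
  rownames(m) <- participant_ids
  m
}
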