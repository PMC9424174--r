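#' Default SOC triage configuration
#'
#' Shipped defaults for the review-priority cascade: the list of job titles
#' too vague to classify without a description, the minimum information
#' threshold (token count over title + description), the per-major-group
#' base review priority encoding exposure potential (office and
#' professional groups low, service and field groups medium, trades,
#' production and military high), the high-fit threshold that lowers
#' priority when both coders agree, the low-fit threshold that triggers
#' review, and the description keywords that add an exposure-context point.
#' Expert judgment cannot be fully codified; every element is editable.
#'
#' @return Named list of configuration values.
#' @export
default_soc_config <- function() {
  list(
    insufficient_titles = c("ceo", "owner", "division controller",
                            "management", "engineering equipment officer"),
    min_info_tokens = 2L,
    high_fit = 0.8,
    low_fit = 0.3,
    agreement_digits = 6L,
    base_priority = c(
      "11" = 1L, "13" = 1L, "15" = 1L, "21" = 1L, "23" = 1L, "25" = 1L,
      "27" = 1L, "29" = 1L, "41" = 1L, "43" = 1L,
      "17" = 2L, "19" = 2L, "31" = 2L, "33" = 2L, "35" = 2L, "37" = 2L,
      "39" = 2L, "53" = 2L,
      "45" = 3L, "47" = 3L, "49" = 3L, "51" = 3L, "55" = 3L),
    default_base_priority = 2L,
    keywords = c("military", "factory", "plant", "chemical", "weld",
                 "solvent", "paint", "metal", "asbestos", "foundry",
                 "mine", "farm", "diesel", "industrial", "machine"))
}

soc_major_group <- function(code) {
  ifelse(is.na(code), NA_character_, paste0(substr(code, 1, 2), "-0000"))
}

check_soc_codes <- function(code, where) {
  bad <- !is.na(code) & !grepl("^[0-9]{2}-[0-9]{4}$", code)
  if (any(bad))
    stop(where, ": soc_code not in XX-YYYY form: ",
         paste(unique(code[bad]), collapse = ", "))
  invisible(code)
}

#' Merge dual autocoder candidate files
#'
#' Coder A supplies up to 10 ranked candidates with fit scores per job;
#' coder B supplies a single code. The merge keeps A's top candidate (by
#' rank, then fit) and B's code, and flags agreement: codes equal at 6
#' digits (or at the 2-digit major group when
#' `agreement_digits = 2`). A job present on one side only gets an NA for
#' the other side and unknown agreement.
#'
#' @param candidates_a,candidates_b data.frames with columns `job_id`,
#'   `soc_code`, and for coder A `rank` and `fit_score`.
#' @param agreement_digits 6 (default) or 2.
#' @return data.frame: `job_id`, `soc_a`, `fit_a`, `soc_b`, `agree`
#'   (logical, NA when a side is missing), `one_sided` (logical).
#' @export
merge_coders <- function(candidates_a, candidates_b, agreement_digits = 6L) {
  stopifnot(agreement_digits %in% c(2L, 6L))
  a <- candidates_a; b <- candidates_b
  for (nm in c("job_id", "soc_code"))
    if (!nm %in% names(a) || !nm %in% names(b))
      stop("coder candidate tables need columns job_id and soc_code")
  if (!"fit_score" %in% names(a)) stop("coder A candidates need fit_score")
  check_soc_codes(a$soc_code, "coder A")
  check_soc_codes(b$soc_code, "coder B")
  if (!"rank" %in% names(a)) a$rank <- stats::ave(-a$fit_score, a$job_id,
                                                  FUN = rank)
  a <- a[order(a$job_id, a$rank, -a$fit_score), , drop = FALSE]
  top_a <- a[!duplicated(a$job_id), c("job_id", "soc_code", "fit_score")]
  names(top_a) <- c("job_id", "soc_a", "fit_a")
  if (anyDuplicated(b$job_id))
    stop("coder B supplies more than one code per job")
  bb <- b[, c("job_id", "soc_code")]
  names(bb) <- c("job_id", "soc_b")
  m <- merge(top_a, bb, by = "job_id", all = TRUE)
  cmp <- function(x) if (agreement_digits == 2L) substr(x, 1, 2) else x
  m$agree <- ifelse(is.na(m$soc_a) | is.na(m$soc_b), NA,
                    cmp(m$soc_a) == cmp(m$soc_b))
  m$one_sided <- is.na(m$soc_a) | is.na(m$soc_b)
  m
}

n_tokens <- function(x) {
  x <- trimws(ifelse(is.na(x), "", x))
  lengths(strsplit(x, "\\s+")) - (x == "")
}

#' Assign review priority to coded jobs
#'
#' Rule cascade per job, producing a priority of 0 ("indeterminate"),
#' 1 ("low"), 2 ("medium") or 3 ("high"):
#' \enumerate{
#'   \item 0 when the title and description together fall below the minimum
#'     information threshold, or the title is on the insufficient-title
#'     list with no description to back it up;
#'   \item otherwise a base priority from the exposure-potential lookup on
#'     the 2-digit major group of the assigned code;
#'   \item lowered to 1 when both coders agree with fit at or above the
#'     high-fit threshold (codes consistent with high fit);
#'   \item plus one point when the description contains an exposure-context
#'     keyword, never exceeding 3.
#' }
#'
#' @param jobs Jobs table (`job_id`, `title`, `description`).
#' @param merged Output of [merge_coders()].
#' @param config See [default_soc_config()].
#' @return Integer vector of priorities aligned to `jobs` rows.
#' @export
assign_priority <- function(jobs, merged, config = default_soc_config()) {
  mi <- match(jobs$job_id, merged$job_id)
  soc <- ifelse(is.na(merged$soc_a[mi]), merged$soc_b[mi], merged$soc_a[mi])
  title <- tolower(trimws(ifelse(is.na(jobs$title), "", jobs$title)))
  descr <- tolower(trimws(ifelse(is.na(jobs$description), "",
                                 jobs$description)))
  tok <- n_tokens(jobs$title) + n_tokens(jobs$description)
  indeterminate <- tok < config$min_info_tokens |
    (title %in% config$insufficient_titles & n_tokens(jobs$description) == 0)

  grp <- substr(soc, 1, 2)
  base <- unname(config$base_priority[grp])
  base[is.na(base)] <- config$default_base_priority
  agree <- merged$agree[mi]
  fit <- merged$fit_a[mi]
  consistent <- !is.na(agree) & agree & !is.na(fit) & fit >= config$high_fit
  pri <- ifelse(consistent, 1L, base)
  kw <- paste0("\\b(", paste(config$keywords, collapse = "|"), ")")
  upgraded <- grepl(kw, descr)
  pri <- pmin(pri + as.integer(upgraded), 3L)
  pri[indeterminate] <- 0L
  as.integer(pri)
}

#' Flag jobs for manual review
#'
#' TRUE for jobs with priority 2 or 3 where the coders disagree (or
#' agreement is unknown), for jobs with priority 2 or 3 whose coder-A fit
#' score is low (below `low_fit`, or missing), and for all indeterminate
#' (priority 0) jobs. Raising a job's priority can never clear its flag.
#'
#' @param priority Integer priorities from [assign_priority()].
#' @param agree Logical agreement from [merge_coders()] (NA = unknown).
#' @param fit_a Coder A fit score (NA = unknown).
#' @param low_fit Threshold below which fit triggers review (default 0.3).
#' @return Logical vector.
#' @export
flag_for_review <- function(priority, agree, fit_a, low_fit = 0.3) {
  disagree <- is.na(agree) | !agree
  lowfit <- is.na(fit_a) | fit_a < low_fit
  (priority >= 2L & (disagree | lowfit)) | priority == 0L
}

#' Build the SOC assignment table
#'
#' Combines the merged coder output, priority cascade, review flags and any
#' manual overrides into the final per-job assignment.
#'
#' @param jobs Jobs table.
#' @param merged Output of [merge_coders()].
#' @param config See [default_soc_config()].
#' @param overrides Optional data.frame (`job_id`, `soc_code`) of manual
#'   revisions.
#' @return data.frame of class `occx_soc`: `job_id`, `final_code`,
#'   `major_group`, `priority`, `review_flag`, `source`, `fit_a`, `agree`.
#' @export
build_assignments <- function(jobs, merged, config = default_soc_config(),
                              overrides = NULL) {
  mi <- match(jobs$job_id, merged$job_id)
  final <- ifelse(is.na(merged$soc_a[mi]), merged$soc_b[mi],
                  merged$soc_a[mi])
  pri <- assign_priority(jobs, merged, config)
  flag <- flag_for_review(pri, merged$agree[mi], merged$fit_a[mi],
                          config$low_fit)
  src <- rep("auto", nrow(jobs))
  if (!is.null(overrides) && nrow(overrides)) {
    check_soc_codes(overrides$soc_code, "overrides")
    oi <- match(jobs$job_id, overrides$job_id)
    hit <- !is.na(oi)
    final[hit] <- overrides$soc_code[oi[hit]]
    src[hit] <- "manual_override"
  }
  out <- data.frame(job_id = jobs$job_id, final_code = final,
                    major_group = soc_major_group(final),
                    priority = pri, review_flag = flag, source = src,
                    fit_a = merged$fit_a[mi], agree = merged$agree[mi],
                    stringsAsFactors = FALSE)
  class(out) <- c("occx_soc", "data.frame")
  out
}

#' Draw a seeded audit sample of coded jobs
#'
#' Uniform random subset of jobs eligible for audit (manually revised and
#' indeterminate jobs excluded), for human verdicts on coding accuracy.
#'
#' @param assignments An `occx_soc` table.
#' @param n Sample size.
#' @param seed Integer seed; the same seed yields the same sample.
#' @return data.frame `job_id`, `final_code`, `priority` plus an empty
#'   `verdict` column to fill with "correct"/"incorrect".
#' @export
audit_sample <- function(assignments, n, seed) {
  eligible <- assignments[assignments$priority != 0L &
                            assignments$source != "manual_override", ,
                          drop = FALSE]
  if (n > nrow(eligible))
    stop("audit sample size ", n, " exceeds ", nrow(eligible),
         " eligible jobs")
  idx <- with_local_seed(seed, sample.int(nrow(eligible), n))
  out <- eligible[idx, c("job_id", "final_code", "priority"), drop = FALSE]
  out$verdict <- NA_character_
  rownames(out) <- NULL
  out
}

#' Misclassification rate from audit verdicts
#'
#' @param audit Audit table with a filled `verdict` column.
#' @return List: `n` audited, `n_incorrect`, `fraction` (exact), and
#'   `percent` (rounded to one decimal).
#' @export
audit_misclassification <- function(audit) {
  v <- audit$verdict[!is.na(audit$verdict)]
  n <- length(v)
  if (!n) stop("no verdicts recorded")
  bad <- sum(v == "incorrect")
  list(n = n, n_incorrect = bad, fraction = bad / n,
       percent = round(100 * bad / n, 1))
}

# run expr under a temporary RNG state seeded with `seed`
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Job-years by participant and SOC major group
#'
#' Sums job durations within each 2-digit major group per participant.
#' With `windowed = TRUE` each job's span is intersected with three windows
#' counted back from the participant's reference year r (onset for cases,
#' consent for controls): within 10 years (\[r-10, Inf), so the rare years
#' worked at or after the reference year are credited to the most recent
#' window and the three windows always sum to the total), 10-20 years
#' (\[r-20, r-10)), and more than 20 years before (-Inf, r-20). A job's
#' span is \[start, start + duration).
#'
#' @param cohort An `occx_cohort` (eligible jobs only).
#' @param assignments An `occx_soc` table covering the cohort's jobs.
#' @param windowed Split into the three pre-reference windows?
#' @return If not windowed, a numeric matrix participants x major groups.
#'   Otherwise a list of such matrices: `total`, `w0_10`, `w10_20`,
#'   `w20plus`.
#' @export
job_years_matrix <- function(cohort, assignments, windowed = FALSE) {
  j <- cohort$jobs
  grp <- assignments$major_group[match(j$job_id, assignments$job_id)]
  if (anyNA(grp))
    stop("assignments missing for job(s): ",
         paste(j$job_id[is.na(grp)], collapse = ", "))
  pids <- cohort$participants$participant_id
  groups <- sort(unique(grp))
  empty <- function() matrix(0, length(pids), length(groups),
                             dimnames = list(pids, groups))
  acc <- function(values) {
    m <- empty()
    s <- rowsum(values, paste(j$participant_id, grp, sep = "\r"))
    parts <- strsplit(rownames(s), "\r", fixed = TRUE)
    m[cbind(match(vapply(parts, `[`, "", 1L), pids),
            match(vapply(parts, `[`, "", 2L), groups))] <- as.numeric(s)
    m
  }
  if (!windowed) return(acc(j$duration))
  ref <- reference_year(cohort)[j$participant_id]
  s <- j$start_year
  e <- j$start_year + j$duration
  overlap <- function(lo, hi) pmax(0, pmin(e, hi) - pmax(s, lo))
  list(total = acc(j$duration),
       w0_10 = acc(overlap(ref - 10, Inf)),
       w10_20 = acc(overlap(ref - 20, ref - 10)),
       w20plus = acc(overlap(-Inf, ref - 20)))
}

#' One-sample enrichment test of the case proportion
#'
#' Normal-approximation z-test without continuity correction:
#' z = (phat - p0) / sqrt(p0 (1 - p0) / n) with phat the case fraction
#' among the n = n_case + n_control participants in a group and p0 the
#' reference proportion; two-sided p.
#'
#' @param n_case,n_control Participant counts in the group.
#' @param p0 Reference proportion in (0, 1), typically the overall case
#'   fraction of the cohort.
#' @return List with `z` and `p`.
#' @export
enrichment_test <- function(n_case, n_control, p0) {
  if (!is.finite(p0) || p0 <= 0 || p0 >= 1)
    stop("p0 must lie strictly between 0 and 1")
  n <- n_case + n_control
  phat <- n_case / n
  z <- (phat - p0) / sqrt(p0 * (1 - p0) / n)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Tabulate case/control counts and job-years by major group
#'
#' Per 2-digit major group: distinct case and control participants with any
#' years in the group, their summed job-years, the percentage of job-years
#' contributed by cases, the percentage of participants that are cases, and
#' the enrichment test of the case proportion against `p0` (defaulting to
#' the cohort's overall case fraction). Groups with no participants are
#' omitted; the test is reported only where at least 5 participants
#' contribute.
#'
#' @param cohort An `occx_cohort`.
#' @param jym Unwindowed matrix from [job_years_matrix()].
#' @param p0 Reference case proportion (default: overall case fraction).
#' @return data.frame: `major_group`, `n_case`, `n_control`,
#'   `jobyears_case`, `jobyears_control`, `pct_jobyears_case`, `pct_case`,
#'   `p0`, `z`, `p`.
#' @export
tabulate_group <- function(cohort, jym, p0 = NULL) {
  p <- cohort$participants
  if (is.null(p0)) p0 <- mean(p$status == "case")
  is_case <- p$status[match(rownames(jym), p$participant_id)] == "case"
  out <- list()
  for (g in colnames(jym)) {
    yrs <- jym[, g]
    has <- yrs > 0
    nc <- sum(has & is_case); nn <- sum(has & !is_case)
    if (nc + nn == 0L) next
    jc <- sum(yrs[has & is_case]); jn <- sum(yrs[has & !is_case])
    tst <- if (nc + nn >= 5L) enrichment_test(nc, nn, p0)
           else list(z = NA_real_, p = NA_real_)
    out[[length(out) + 1L]] <- data.frame(
      major_group = g, n_case = nc, n_control = nn,
      jobyears_case = jc, jobyears_control = jn,
      pct_jobyears_case = 100 * jc / (jc + jn),
      pct_case = 100 * nc / (nc + nn),
      p0 = p0, z = tst$z, p = tst$p, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
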