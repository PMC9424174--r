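#' Score one exposure factor from a job's responses
#'
#' The factor score is the sum of item contributions divided by the maximum
#' attainable sum over all items of the factor, so the attainable range is
#' \[0, 1\]. A skipped item among answered ones contributes 0; the factor is
#' missing only when every item is unanswered.
#'
#' @param responses Named character vector (question_id -> response level);
#'   absent or NA entries are missing.
#' @param factor_def A factor definition from an `occx_schema` (fields
#'   `factor_id`, `weight`, `items`).
#' @return Score in \[0, 1\], or NA if all items are missing.
#' @export
score_factor <- function(responses, factor_def) {
  max_sum <- sum(vapply(factor_def$items, function(it) max(it$map), 0))
  total <- 0
  answered <- 0L
  for (it in factor_def$items) {
    resp <- responses[it$question_id]
    if (length(resp) == 0L || is.na(resp)) next
    contrib <- it$map[as.character(resp)]
    if (is.na(contrib)) next          # unrecognised level treated as missing
    total <- total + unname(contrib)
    answered <- answered + 1L
  }
  if (answered == 0L) return(NA_real_)
  total / max_sum
}

#' Score one exposure type for a job
#'
#' Weighted mean of the factor scores, weights from the schema, taken over
#' the non-missing factors: sum(w_f * s_f) / sum(w_f). Missing only when
#' every factor is missing.
#'
#' @param responses Named character vector of responses for one job.
#' @param type_schema One type entry of an `occx_schema` (fields `type`,
#'   `factors`).
#' @return Score in \[0, 1\], or NA.
#' @export
score_job <- function(responses, type_schema) {
  s <- vapply(type_schema$factors, function(f) score_factor(responses, f), 0)
  w <- vapply(type_schema$factors, function(f) f$weight, 0)
  ok <- !is.na(s)
  if (!any(ok)) return(NA_real_)
  sum(w[ok] * s[ok]) / sum(w[ok])
}

# Vectorized job-level scoring over the whole cohort. Same semantics as
# score_factor()/score_job(), computed with rowsum() so large simulated
# cohorts score in milliseconds.
compute_job_scores <- function(cohort) {
  schema <- cohort$schema
  items <- schema_items(schema)
  fmeta <- unique(items[, c("factor_id", "type", "weight")])
  fmeta$max_sum <- vapply(fmeta$factor_id, function(fid)
    sum(items$max_contrib[items$factor_id == fid]), 0)

  r <- cohort$responses
  type_ids <- vapply(unclass(schema), `[[`, "", "type")
  grid <- expand.grid(job_id = cohort$jobs$job_id, type = type_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$score <- NA_real_
  if (!nrow(r)) return(grid)

  ctab <- schema_contrib_table(schema)
  r$contrib <- ctab$contrib[match(paste(r$question_id, r$response, sep = "\r"),
                                  paste(ctab$question_id, ctab$response,
                                        sep = "\r"))]
  fi <- match(r$question_id, items$question_id)
  r$factor_id <- items$factor_id[fi]

  ans <- !is.na(r$contrib)
  key <- paste(r$job_id, r$factor_id, sep = "\r")
  csum <- rowsum(ifelse(ans, r$contrib, 0), key)
  nans <- rowsum(as.integer(ans), key)
  parts <- strsplit(rownames(csum), "\r", fixed = TRUE)
  fs <- data.frame(job_id = vapply(parts, `[`, "", 1L),
                   factor_id = vapply(parts, `[`, "", 2L),
                   stringsAsFactors = FALSE)
  mi <- match(fs$factor_id, fmeta$factor_id)
  fs$type <- fmeta$type[mi]
  fs$weight <- fmeta$weight[mi]
  fs$score <- as.numeric(csum) / fmeta$max_sum[mi]
  fs <- fs[as.numeric(nans) > 0L, , drop = FALSE]   # all-missing factors drop

  if (nrow(fs)) {
    key2 <- paste(fs$job_id, fs$type, sep = "\r")
    num <- rowsum(fs$weight * fs$score, key2)
    den <- rowsum(fs$weight, key2)
    parts2 <- strsplit(rownames(num), "\r", fixed = TRUE)
    jt <- paste(vapply(parts2, `[`, "", 1L), vapply(parts2, `[`, "", 2L),
                sep = "\r")
    val <- as.numeric(num) / as.numeric(den)
    gi <- match(jt, paste(grid$job_id, grid$type, sep = "\r"))
    grid$score[gi] <- val
  }
  grid
}

#' Participant-level "ever exposed" score
#'
#' Summarises job scores to one value per participant and type. The default
#' is the maximum over eligible jobs (whether the participant was ever
#' exposed on any job); `method = "mean"` averages instead. Missing only
#' when every job score is missing.
#'
#' @param job_scores Numeric vector of job scores for one participant/type
#'   (NAs allowed).
#' @param method `"max"` (default) or `"mean"`.
#' @return Score in \[0, 1\], or NA.
#' @export
participant_ever_score <- function(job_scores, method = c("max", "mean")) {
  method <- match.arg(method)
  s <- job_scores[!is.na(job_scores)]
  if (!length(s)) return(NA_real_)
  if (method == "max") max(s) else mean(s)
}

#' Duration-adjusted participant score
#'
#' Duration-weighted mean of job scores: sum(s_j d_j) / sum(d_j) over
#' eligible jobs with a non-missing score. Because it is a weighted mean
#' the result stays in \[0, 1\] (dividing by total years rather than using a
#' raw score-times-years product, which would exceed 1).
#'
#' @param job_scores Numeric job scores (NAs allowed).
#' @param durations Job durations in years, positive where scored.
#' @return Score in \[0, 1\], or NA if no scored job (or total duration 0).
#' @export
duration_adjusted_score <- function(job_scores, durations) {
  stopifnot(length(job_scores) == length(durations))
  ok <- !is.na(job_scores)
  if (!any(ok)) return(NA_real_)
  d <- durations[ok]
  if (sum(d) <= 0) return(NA_real_)
  sum(job_scores[ok] * d) / sum(d)
}

#' Compute the full exposure score set for a cohort
#'
#' Runs job-level scoring for all nine types, then aggregates to
#' participant-level ever scores and duration-adjusted scores over the
#' cohort's (already filtered) jobs.
#'
#' @param cohort An `occx_cohort`, typically after [filter_eligible_jobs()].
#' @param ever_method Aggregation for the plain participant score:
#'   `"max"` (default) or `"mean"`.
#' @return An `occx_scores` object: list with long data frames `job_scores`
#'   (`job_id`, `type`, `score`), `participant_ever` and
#'   `participant_duration_adjusted` (`participant_id`, `type`, `score`).
#' @export
compute_scores <- function(cohort, ever_method = c("max", "mean")) {
  ever_method <- match.arg(ever_method)
  stopifnot(inherits(cohort, "occx_cohort"))
  js <- compute_job_scores(cohort)
  ji <- match(js$job_id, cohort$jobs$job_id)
  js$participant_id <- cohort$jobs$participant_id[ji]
  dur <- cohort$jobs$duration[ji]

  key <- paste(js$participant_id, js$type, sep = "\r")
  ukey <- unique(key)
  split_idx <- split(seq_len(nrow(js)), key)
  ever <- vapply(split_idx, function(i)
    participant_ever_score(js$score[i], ever_method), 0)
  dadj <- vapply(split_idx, function(i)
    duration_adjusted_score(js$score[i], dur[i]), 0)
  parts <- strsplit(names(split_idx), "\r", fixed = TRUE)
  pid <- vapply(parts, `[`, "", 1L)
  typ <- vapply(parts, `[`, "", 2L)
  res <- structure(
    list(job_scores = js[, c("job_id", "participant_id", "type", "score")],
         participant_ever = data.frame(participant_id = pid, type = typ,
                                       score = unname(ever),
                                       stringsAsFactors = FALSE),
         participant_duration_adjusted =
           data.frame(participant_id = pid, type = typ,
                      score = unname(dadj), stringsAsFactors = FALSE)),
    class = "occx_scores")
  res
}

#' @export
print.occx_scores <- function(x, ...) {
  cat("<occx_scores> ", length(unique(x$job_scores$job_id)), " jobs, ",
      length(unique(x$participant_ever$participant_id)),
      " participants, ", length(unique(x$job_scores$type)),
      " exposure types\n", sep = "")
  invisible(x)
}

#' Participant-by-type score matrix
#'
#' @param scores An `occx_scores` object.
#' @param which `"duration_adjusted"` (default) or `"ever"`.
#' @return Numeric matrix, rows = participants, columns = exposure types.
#' @export
score_matrix <- function(scores, which = c("duration_adjusted", "ever")) {
  which <- match.arg(which)
  df <- if (which == "ever") scores$participant_ever
        else scores$participant_duration_adjusted
  pids <- sort(unique(df$participant_id))
  types <- names(exposure_types())
  types <- types[types %in% df$type]
  if (!length(types)) types <- sort(unique(df$type))
  m <- matrix(NA_real_, length(pids), length(types),
              dimnames = list(pids, types))
  m[cbind(match(df$participant_id, pids), match(df$type, types))] <- df$score
  m
}

#' Standardize scores to z-values
#'
#' Centers by the combined-sample mean and scales by the combined-sample
#' standard deviation (denominator n-1). NAs are ignored in the moments and
#' propagate through the output.
#'
#' @param values Numeric vector with at least two distinct non-NA values.
#' @return z-scored vector.
#' @export
standardize_scores <- function(values) {
  v <- values[!is.na(values)]
  if (length(unique(v)) < 2L)
    stop("cannot standardize: fewer than 2 distinct values")
  s <- stats::sd(v)
  if (s == 0) stop("cannot standardize: zero standard deviation")
  (values - mean(v)) / s
}

#' Metal subcomponent indicators and intersections
#'
#' Derives per-job boolean indicators over the metal subcomponents (lead,
#' mercury, cadmium, arsenic, iron, welding fumes, other metals) from the
#' schema's tagged metal items, plus an upset-style tabulation of the
#' subcomponent combinations observed across jobs.
#'
#' @param cohort An `occx_cohort` whose schema tags metal items with
#'   `subcomponent`.
#' @return List with `indicators` (data frame, one row per job, logical
#'   column per subcomponent), `intersections` (data frame `pattern`,
#'   `n_jobs`, combinations sorted by count), and `margins` (named totals
#'   per subcomponent).
#' @export
metal_subcomponents <- function(cohort) {
  items <- schema_items(cohort$schema)
  mi <- items[!is.na(items$subcomponent), , drop = FALSE]
  if (!nrow(mi)) stop("schema has no items tagged with metal subcomponents")
  subs <- metal_subcomponent_levels()
  subs <- subs[subs %in% mi$subcomponent]
  r <- cohort$responses
  r <- r[r$question_id %in% mi$question_id, , drop = FALSE]
  ctab <- schema_contrib_table(cohort$schema)
  r$contrib <- ctab$contrib[match(paste(r$question_id, r$response, sep = "\r"),
                                  paste(ctab$question_id, ctab$response,
                                        sep = "\r"))]
  r$subcomponent <- mi$subcomponent[match(r$question_id, mi$question_id)]
  jobs <- cohort$jobs$job_id
  ind <- matrix(FALSE, length(jobs), length(subs),
                dimnames = list(jobs, subs))
  pos <- !is.na(r$contrib) & r$contrib > 0
  if (any(pos))
    ind[cbind(match(r$job_id[pos], jobs), match(r$subcomponent[pos], subs))] <- TRUE
  pattern <- apply(ind, 1L, function(z)
    if (!any(z)) "(none)" else paste(subs[z], collapse = "+"))
  tab <- sort(table(pattern), decreasing = TRUE)
  list(indicators = data.frame(job_id = jobs, ind,
                               stringsAsFactors = FALSE, row.names = NULL),
       intersections = data.frame(pattern = names(tab),
                                  n_jobs = as.integer(tab),
                                  stringsAsFactors = FALSE),
       margins = colSums(ind))
}

# quantiles by linear interpolation of the empirical CDF (stats type 7),
# the convention used in all score summaries
score_quantile <- function(x, probs) {
  stats::quantile(x, probs = probs, names = FALSE, type = 7, na.rm = TRUE)
}

#' Summarise exposure scores by group
#'
#' Per exposure type and group: N non-missing, mean, SD, and the 75th, 90th
#' and 95th percentiles (linear interpolation of the empirical CDF).
#'
#' @param scores An `occx_scores` object.
#' @param cohort The cohort the scores came from (for grouping variables).
#' @param which `"duration_adjusted"` (default) or `"ever"`.
#' @param group_by Participant column to stratify by (default `"status"`);
#'   NULL for an overall summary.
#' @return data.frame with columns `type`, `group`, `n`, `mean`, `sd`,
#'   `q75`, `q90`, `q95`.
#' @export
summarize_scores <- function(scores, cohort,
                             which = c("duration_adjusted", "ever"),
                             group_by = "status") {
  which <- match.arg(which)
  df <- if (which == "ever") scores$participant_ever
        else scores$participant_duration_adjusted
  p <- cohort$participants
  grp <- if (is.null(group_by)) rep("all", nrow(df))
         else p[[group_by]][match(df$participant_id, p$participant_id)]
  out <- list()
  for (ty in unique(df$type)) for (g in unique(grp)) {
    x <- df$score[df$type == ty & grp == g]
    xo <- x[!is.na(x)]
    out[[length(out) + 1L]] <- data.frame(
      type = ty, group = g, n = length(xo),
      mean = if (length(xo)) mean(xo) else NA_real_,
      sd = if (length(xo) > 1) stats::sd(xo) else NA_real_,
      q75 = if (length(xo)) score_quantile(xo, 0.75) else NA_real_,
      q90 = if (length(xo)) score_quantile(xo, 0.90) else NA_real_,
      q95 = if (length(xo)) score_quantile(xo, 0.95) else NA_real_,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Pairwise Spearman correlations between exposure types
#'
#' @param scores An `occx_scores` object.
#' @param which `"duration_adjusted"` (default) or `"ever"`.
#' @return Symmetric correlation matrix over the exposure types (pairwise
#'   complete observations).
#' @export
score_correlations <- function(scores, which = c("duration_adjusted", "ever")) {
  m <- score_matrix(scores, match.arg(which))
  stats::cor(m, method = "spearman", use = "pairwise.complete.obs")
}
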