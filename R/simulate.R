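#' Built-in SOC groups for simulation
#'
#' The occupational major groups the generator draws from, with sampling
#' frequencies, representative 6-digit codes and titles, and the per-type
#' probabilities that a job in the group carries each exposure. Shared
#' group profiles are what induce the correlation between exposure types
#' (dusty trades score high on both particulate matter and metals, offices
#' on neither), emulating the mixture structure of real occupational data.
#'
#' @return List with `groups` (data.frame: `group`, `freq`), `profiles`
#'   (matrix groups x exposure types of exposure probabilities), and
#'   `codes` (data.frame: `group`, `soc_code`, `title`, `description`,
#'   `agg_label`).
#' @export
sim_soc_groups <- function() {
  g <- c("11", "13", "15", "17", "25", "29", "31", "35", "37", "41",
         "43", "45", "47", "49", "51", "53", "55")
  freq <- c(.10, .05, .04, .05, .08, .07, .04, .06, .04, .09,
            .18, .02, .05, .05, .07, .05, .01)
  ty <- names(exposure_types())
  pr <- matrix(0.02, length(g), length(ty), dimnames = list(g, ty))
  pr["15", ] <- 0.01; pr["43", ] <- 0.01
  pr["17", c("pm", "voc", "metals", "combustion", "electromagnetic",
             "radiation", "corrosives")] <- c(.25, .20, .20, .15, .15, .10, .10)
  pr["25", "biologicals"] <- .05
  pr["29", c("biologicals", "radiation", "corrosives")] <- c(.30, .25, .10)
  pr["31", c("biologicals", "corrosives")] <- c(.25, .10)
  pr["35", c("corrosives", "biologicals", "combustion")] <- c(.15, .10, .05)
  pr["37", c("pm", "voc", "pesticides", "corrosives", "metals")] <-
    c(.30, .25, .30, .20, .15)
  pr["45", c("pesticides", "pm", "biologicals", "combustion", "metals")] <-
    c(.70, .40, .40, .30, .10)
  pr["47", c("pm", "voc", "metals", "combustion", "corrosives")] <-
    c(.60, .40, .50, .40, .20)
  pr["49", c("pm", "voc", "metals", "combustion", "electromagnetic",
             "corrosives")] <- c(.55, .45, .60, .45, .20, .25)
  pr["51", c("pm", "voc", "metals", "combustion", "corrosives",
             "radiation")] <- c(.65, .50, .65, .40, .30, .05)
  pr["53", c("pm", "combustion", "voc", "metals")] <- c(.35, .60, .20, .15)
  pr["55", c("pm", "metals", "combustion", "radiation", "voc")] <-
    c(.40, .35, .40, .15, .30)

  codes <- rbind(
    data.frame(group = "11", soc_code = c("11-1021", "11-9199"),
               title = c("general manager", "operations manager"),
               description = c("manages office staff", "oversees operations"),
               agg_label = "Manager, general"),
    data.frame(group = "13", soc_code = "13-2011",
               title = "accountant", description = "prepares accounts",
               agg_label = "Analyst, financial"),
    data.frame(group = "15", soc_code = "15-1132",
               title = "software developer", description = "writes software",
               agg_label = "Computing professional"),
    data.frame(group = "17", soc_code = c("17-2112", "17-2141"),
               title = c("industrial engineer", "mechanical engineer"),
               description = c("designs factory processes",
                               "designs machine components"),
               agg_label = "Engineer"),
    data.frame(group = "25", soc_code = "25-2021",
               title = "teacher", description = "teaches school classes",
               agg_label = "Teacher"),
    data.frame(group = "29", soc_code = c("29-1141", "29-2034"),
               title = c("registered nurse", "x-ray technician"),
               description = c("provides patient care",
                               "operates imaging equipment"),
               agg_label = "Healthcare practitioner"),
    data.frame(group = "31", soc_code = "31-1014",
               title = "nursing assistant", description = "assists patients",
               agg_label = "Healthcare support"),
    data.frame(group = "35", soc_code = "35-2014",
               title = "cook", description = "prepares food in a kitchen",
               agg_label = "Food preparation"),
    data.frame(group = "37", soc_code = "37-2011",
               title = "janitor",
               description = "cleans buildings with industrial cleaners",
               agg_label = "Cleaning and grounds"),
    data.frame(group = "41", soc_code = c("41-2031", "41-4012"),
               title = c("retail salesperson", "sales representative"),
               description = c("sells goods in a store", "sells to clients"),
               agg_label = "Sales"),
    data.frame(group = "43", soc_code = c("43-6014", "43-9061"),
               title = c("secretary", "office clerk"),
               description = c("administrative support", "files documents"),
               agg_label = "Office and administrative"),
    data.frame(group = "45", soc_code = "45-2092",
               title = "farm worker",
               description = "applies pesticides on a farm",
               agg_label = "Farming and forestry"),
    data.frame(group = "47", soc_code = c("47-2111", "47-2152"),
               title = c("electrician", "plumber"),
               description = c("installs wiring and sheet metal",
                               "installs metal piping"),
               agg_label = c("Trades, electrical and sheet metal",
                             "Trades, plumbing")),
    data.frame(group = "49", soc_code = c("49-3023", "49-9041"),
               title = c("auto mechanic", "industrial machinery mechanic"),
               description = c("repairs vehicles with welding and solvents",
                               "maintains factory machines"),
               agg_label = c("Mechanic, vehicle", "Mechanic, industrial")),
    data.frame(group = "51", soc_code = c("51-4121", "51-9011", "51-4041"),
               title = c("welder", "chemical operator", "machinist"),
               description = c("welds metal parts in a plant",
                               "operates chemical processing equipment",
                               "machines metal parts"),
               agg_label = c("Operator, welding and metals",
                             "Operator, chemical",
                             "Operator, welding and metals")),
    data.frame(group = "53", soc_code = "53-3032",
               title = "truck driver",
               description = "drives a diesel truck",
               agg_label = "Transportation"),
    data.frame(group = "55", soc_code = "55-3019",
               title = "infantry", description = "served in a military unit",
               agg_label = "Military"))
  list(groups = data.frame(group = g, freq = freq, stringsAsFactors = FALSE),
       profiles = pr, codes = codes)
}

#' Simulation configuration
#'
#' Defaults emulate the study conditions of a clinic-based ALS case-control
#' cohort: 381 cases and 272 controls, consent ages centred near 62 years,
#' a slight male excess, roughly 14% with enlisted military service (about
#' 1% missing), one to four jobs per participant with calendar-consistent
#' year spans, SOC groups drawn from realistic frequencies with sector
#' persistence across a participant's jobs, and case status generated
#' retrospectively from a logistic model on the standardized true
#' duration-adjusted scores plus age/sex/military effects. The default
#' planted signal is a per-SD metals log odds ratio of log(1.5); all other
#' types are null.
#'
#' @param n_case,n_control Target group sizes.
#' @param age_mean,age_sd,age_min,age_max Consent-age distribution
#'   (truncated normal), in years.
#' @param p_male Probability of male sex.
#' @param p_enlisted,p_military_missing Military service mix.
#' @param jobs_prob Probabilities for 1-4 reported jobs.
#' @param sector_stickiness Probability a later job stays in the previous
#'   job's SOC group.
#' @param exposure_copula_rho Gaussian-copula correlation of the latent
#'   per-job exposure propensities across types (0 = independent given
#'   the SOC group); together with the shared group profiles this sets the
#'   between-type score correlations.
#' @param exposed_item_p,unexposed_item_p Yes-probability of a binary item
#'   given the job is / is not exposed to the type.
#' @param type_missing_rate Probability a job skips all items of a type.
#' @param item_missing_rate Per-item skip probability.
#' @param planted_log_or Named per-type log ORs per SD of the
#'   duration-adjusted score (missing names = 0).
#' @param covariate_log_odds Log-odds for age_q2, age_q3, age_q4, male,
#'   enlisted.
#' @param onset_gap_range Years between consent and onset for cases
#'   (onset = consent - gap).
#' @param post_onset_job_rate Stress switch: probability of shifting a
#'   case's most recent job to start after onset.
#' @param coder_disagreement Probability coder B differs from coder A's
#'   top code.
#' @param coder_a_error Probability coder A's top code is not the true one.
#' @param fit_shape1,fit_shape2 Beta parameters for coder A's top fit score.
#' @param consent_years Calendar years consent is drawn from.
#' @param pool_factor Generation pool size relative to the target cohort.
#' @param max_attempts Pool regeneration attempts before giving up.
#' @param seed Integer seed.
#' @return List of class `occx_sim_config`.
#' @export
sim_config <- function(n_case = 381L, n_control = 272L,
                       age_mean = 62, age_sd = 10, age_min = 25,
                       age_max = 90, p_male = 0.516,
                       p_enlisted = 0.136, p_military_missing = 0.012,
                       jobs_prob = c(0.10, 0.25, 0.30, 0.35),
                       sector_stickiness = 0.6,
                       exposure_copula_rho = 0.9,
                       exposed_item_p = 0.7, unexposed_item_p = 0.005,
                       type_missing_rate = 0.01, item_missing_rate = 0.01,
                       planted_log_or = c(metals = log(1.5)),
                       covariate_log_odds = c(age_q2 = 0.1, age_q3 = 0.2,
                                              age_q4 = 0.3, male = 0.3,
                                              enlisted = 0.4),
                       onset_gap_range = 0:2,
                       post_onset_job_rate = 0,
                       coder_disagreement = 0.2, coder_a_error = 0.1,
                       fit_shape1 = 8, fit_shape2 = 2,
                       consent_years = 2010:2019,
                       pool_factor = 1.8, max_attempts = 5L, seed = 1L) {
  stopifnot(n_case >= 10L, n_control >= 10L,
            all(jobs_prob >= 0), abs(sum(jobs_prob) - 1) < 1e-8)
  cfg <- as.list(environment())
  cfg$soc <- sim_soc_groups()
  cfg$schema <- default_schema()
  class(cfg) <- "occx_sim_config"
  cfg
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm((lo - mean) / sd),
                    stats::pnorm((hi - mean) / sd))
  mean + sd * stats::qnorm(u)
}

# demographics + jobs + responses for one generation pool (no status yet)
sim_pool <- function(cfg, n, id_offset) {
  pid <- sprintf("P%05d", id_offset + seq_len(n))
  consent <- sample(cfg$consent_years, n, replace = TRUE)
  age <- round(rtruncnorm1(n, cfg$age_mean, cfg$age_sd, cfg$age_min,
                           cfg$age_max), 1)
  sex <- ifelse(stats::runif(n) < cfg$p_male, "male", "female")
  u <- stats::runif(n)
  military <- ifelse(u < cfg$p_military_missing, "missing",
                     ifelse(u < cfg$p_military_missing + cfg$p_enlisted,
                            "enlisted", "neither"))
  edu <- sample(c("hs_or_less", "some_postsecondary", "bachelor", "graduate"),
                n, replace = TRUE, prob = c(.20, .31, .26, .23))
  participants <- data.frame(
    participant_id = pid, status = "control", age_at_reference = age,
    sex = sex, military = military, education = edu,
    onset_year = NA_integer_, consent_year = consent,
    stringsAsFactors = FALSE)

  soc <- cfg$soc
  slots <- c("recent", "previous", "longest1", "longest2")
  code_rows_by_group <- split(seq_len(nrow(soc$codes)), soc$codes$group)
  cap <- 4L * n
  j_pid <- character(cap); j_k <- integer(cap)
  j_start <- integer(cap); j_end <- integer(cap)
  j_code <- integer(cap)   # row index into soc$codes
  nrec <- 0L
  for (i in seq_len(n)) {
    nj <- sample(1:4, 1L, prob = cfg$jobs_prob)
    career_start <- consent[i] - max(round(age[i]) - 20L, 5L)
    start <- career_start + sample(0:2, 1L)
    grp_prev <- NULL
    for (k in seq_len(nj)) {
      if (start >= consent[i]) break
      dur <- min(round(2 + stats::rgamma(1, shape = 2, scale = 4)),
                 consent[i] - start)
      grp <- if (!is.null(grp_prev) &&
                 stats::runif(1) < cfg$sector_stickiness) grp_prev
             else sample(soc$groups$group, 1L, prob = soc$groups$freq)
      grp_prev <- grp
      rows <- code_rows_by_group[[grp]]
      nrec <- nrec + 1L
      j_pid[nrec] <- pid[i]; j_k[nrec] <- k
      j_start[nrec] <- start; j_end[nrec] <- start + dur
      j_code[nrec] <- rows[sample.int(length(rows), 1L)]
      start <- start + dur + sample(0:2, 1L)
    }
  }
  idx <- seq_len(nrec)
  ci <- j_code[idx]
  jobs <- data.frame(
    job_id = sprintf("%s_J%d", j_pid[idx], j_k[idx]),
    participant_id = j_pid[idx], slot = slots[pmin(j_k[idx], 4L)],
    title = soc$codes$title[ci], description = soc$codes$description[ci],
    start_year = j_start[idx], end_year = j_end[idx],
    group = soc$codes$group[ci], true_code = soc$codes$soc_code[ci],
    stringsAsFactors = FALSE)
  responses <- sim_responses(cfg, jobs)
  list(participants = participants, jobs = jobs, responses = responses)
}

# vectorized per-item response generation conditional on the job's latent
# exposure indicators
sim_responses <- function(cfg, jobs) {
  schema <- cfg$schema
  items <- schema_items(schema)
  # ordinal items expose a "sometimes" level
  ctab <- schema_contrib_table(schema)
  ord_q <- unique(ctab$question_id[ctab$response == "sometimes"])
  is_ord <- items$question_id %in% ord_q
  types <- colnames(cfg$soc$profiles)
  J <- nrow(jobs)
  pexp <- cfg$soc$profiles[jobs$group, , drop = FALSE]
  # Gaussian copula across types within a job: one shared latent exposure
  # propensity per job couples the type indicators, so a dusty job tends to
  # be exposed to PM, metals and combustion together
  rho <- cfg$exposure_copula_rho
  z_job <- stats::rnorm(J)
  z <- sqrt(rho) * z_job +
    sqrt(1 - rho) * matrix(stats::rnorm(J * length(types)), J)
  E <- matrix(stats::pnorm(z) < pexp, J, length(types),
              dimnames = list(NULL, types))
  TM <- matrix(stats::runif(J * length(types)) < cfg$type_missing_rate,
               J, length(types), dimnames = list(NULL, types))

  nI <- nrow(items)
  jj <- rep(seq_len(J), each = nI)
  ii <- rep(seq_len(nI), times = J)
  t_idx <- match(items$type[ii], types)
  exposed <- E[cbind(jj, t_idx)]
  miss <- TM[cbind(jj, t_idx)] |
    (stats::runif(length(jj)) < cfg$item_missing_rate)

  resp <- character(length(jj))
  ord <- is_ord[ii]
  p_yes <- ifelse(exposed, cfg$exposed_item_p, cfg$unexposed_item_p)
  u <- stats::runif(length(jj))
  resp[!ord] <- ifelse(u[!ord] < p_yes[!ord], "yes", "no")
  # ordinal: exposed jobs report sometimes/often, unexposed almost all never
  p_lo <- ifelse(exposed, 0.2, 0.97)
  p_mid <- ifelse(exposed, 0.4, 0.02)
  resp[ord] <- ifelse(u[ord] < p_lo[ord], "never",
                      ifelse(u[ord] < (p_lo + p_mid)[ord], "sometimes",
                             "often"))
  keep <- !miss
  data.frame(job_id = jobs$job_id[jj][keep],
             question_id = items$question_id[ii][keep],
             response = resp[keep], stringsAsFactors = FALSE)
}

#' Generate a synthetic case-control cohort
#'
#' Samples demographics and calendar-consistent job histories, draws SOC
#' groups with sector persistence, generates item responses conditional on
#' the group (inducing correlated exposure types), computes the true
#' duration-adjusted scores through the package's own scoring chain,
#' assigns case/control status from the planted logistic model (with the
#' intercept calibrated so the pool's marginal case probability matches
#' the target case fraction -- a retrospective case-control emulation, not
#' incidence modelling), draws onset years for cases, and emits synthetic
#' dual-coder candidate tables with controllable disagreement and
#' fit-score noise.
#'
#' @param config An `occx_sim_config` from [sim_config()].
#' @return List of class `occx_sim`: `cohort` (an `occx_cohort`),
#'   `candidates_a`, `candidates_b`, `truth` (planted coefficients,
#'   realized linear predictor, and the post-eligibility true
#'   duration-adjusted scores -- never consumed by analysis code), and
#'   `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  cfg <- config
  with_local_seed(cfg$seed, simulate_cohort_impl(cfg))
}

simulate_cohort_impl <- function(cfg) {
  n_target <- cfg$n_case + cfg$n_control
  target_frac <- cfg$n_case / n_target
  types <- names(exposure_types())
  beta <- stats::setNames(rep(0, length(types)), types)
  beta[names(cfg$planted_log_or)] <- cfg$planted_log_or

  pool <- list(participants = NULL, jobs = NULL, responses = NULL)
  cases_idx <- integer(0)
  got <- function(p) c(sum(p$status == "case"), sum(p$status == "control"))
  for (attempt in seq_len(cfg$max_attempts)) {
    add <- sim_pool(cfg, ceiling(n_target * cfg$pool_factor),
                    id_offset = nrow(pool$participants) %||% 0L)
    pool$participants <- rbind(pool$participants, add$participants)
    pool$jobs <- rbind(pool$jobs, add$jobs)
    pool$responses <- rbind(pool$responses, add$responses)

    cohort <- load_cohort(pool$participants,
                          pool$jobs[, JOB_COLS],
                          pool$responses, cfg$schema)
    scores <- compute_scores(filter_eligible_jobs(cohort))
    m <- score_matrix(scores, "duration_adjusted")
    m <- m[pool$participants$participant_id, , drop = FALSE]
    z <- apply(m, 2, function(x) {
      x[is.na(x)] <- mean(x, na.rm = TRUE)   # truth model: missing at mean
      if (stats::sd(x) == 0) rep(0, length(x)) else standardize_scores(x)
    })
    cov <- covariate_matrix(make_covariates(impute_military(cohort)),
                            pool$participants$participant_id)
    eta <- drop(z %*% beta[colnames(z)]) +
      drop(cov %*% cfg$covariate_log_odds[colnames(cov)])
    b0 <- stats::uniroot(function(b) mean(stats::plogis(b + eta)) -
                           target_frac, c(-20, 20))$root
    pcase <- stats::plogis(b0 + eta)
    status <- ifelse(stats::runif(length(pcase)) < pcase, "case", "control")
    if (sum(status == "case") >= cfg$n_case &&
        sum(status == "control") >= cfg$n_control) {
      sel_case <- sample(which(status == "case"), cfg$n_case)
      sel_ctrl <- sample(which(status == "control"), cfg$n_control)
      sel <- sort(c(sel_case, sel_ctrl))
      p <- pool$participants[sel, , drop = FALSE]
      p$status <- status[sel]
      gap <- sample(cfg$onset_gap_range, nrow(p), replace = TRUE)
      p$onset_year <- ifelse(p$status == "case", p$consent_year - gap,
                             NA_integer_)
      jobs <- pool$jobs[pool$jobs$participant_id %in% p$participant_id, ,
                        drop = FALSE]
      # stress switch: shift some case jobs past onset to exercise exclusion
      if (cfg$post_onset_job_rate > 0) {
        case_jobs <- which(jobs$participant_id %in%
                             p$participant_id[p$status == "case"])
        hit <- case_jobs[stats::runif(length(case_jobs)) <
                           cfg$post_onset_job_rate]
        if (length(hit)) {
          on <- p$onset_year[match(jobs$participant_id[hit],
                                   p$participant_id)]
          jobs$start_year[hit] <- on + 1L
          jobs$end_year[hit] <- pmax(jobs$end_year[hit], on + 2L)
        }
      }
      resp <- pool$responses[pool$responses$job_id %in% jobs$job_id, ,
                             drop = FALSE]
      final <- load_cohort(p, jobs[, JOB_COLS], resp, cfg$schema)
      truth_scores <- compute_scores(filter_eligible_jobs(final))
      cands <- sim_coders(cfg, jobs)
      truth <- list(
        planted_log_or = as.list(beta[beta != 0]),
        intercept = b0,
        covariate_log_odds = as.list(cfg$covariate_log_odds),
        linear_predictor = stats::setNames(b0 + eta[sel],
                                           p$participant_id),
        case_probability = stats::setNames(pcase[sel], p$participant_id),
        true_job_group = stats::setNames(jobs$group, jobs$job_id),
        true_soc_code = stats::setNames(jobs$true_code, jobs$job_id),
        duration_adjusted = truth_scores$participant_duration_adjusted)
      return(structure(list(cohort = final,
                            candidates_a = cands$a, candidates_b = cands$b,
                            truth = truth, config = cfg),
                       class = "occx_sim"))
    }
  }
  stop("could not reach requested n_case/n_control after ",
       cfg$max_attempts, " pool attempts")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# synthetic dual-coder candidate tables: coder A 10 ranked candidates with
# fit scores, coder B one code disagreeing with A's top at the planted rate
sim_coders <- function(cfg, jobs) {
  all_codes <- unique(cfg$soc$codes$soc_code)
  J <- nrow(jobs)
  a_err <- stats::runif(J) < cfg$coder_a_error
  other <- function(code) {
    alt <- setdiff(all_codes, code)
    alt[sample.int(length(alt), 1L)]
  }
  top_a <- jobs$true_code
  top_a[a_err] <- vapply(top_a[a_err], other, "")
  fit1 <- stats::rbeta(J, cfg$fit_shape1, cfg$fit_shape2)
  rest <- vapply(top_a, function(code) sample(setdiff(all_codes, code), 9L),
                 character(9))                       # 9 x J
  fits <- vapply(fit1, function(f)
    sort(stats::runif(9, 0, f), decreasing = TRUE), numeric(9))
  a <- data.frame(
    job_id = rep(jobs$job_id, each = 10L), coder = "A",
    rank = rep(1:10, times = J),
    soc_code = as.vector(rbind(top_a, rest)),
    fit_score = round(as.vector(rbind(fit1, fits)), 4),
    stringsAsFactors = FALSE)
  disagree <- stats::runif(J) < cfg$coder_disagreement
  b_code <- top_a
  b_code[disagree] <- vapply(top_a[disagree], other, "")
  list(a = a,
       b = data.frame(job_id = jobs$job_id, coder = "B", rank = 1L,
                      soc_code = b_code, fit_score = NA_real_,
                      stringsAsFactors = FALSE))
}

#' Write a simulated cohort to disk
#'
#' Emits exactly the file formats [load_cohort()] and [merge_coders()]
#' read: `participants.csv`, `jobs.csv`, `responses.csv`, `coder_a.csv`,
#' `coder_b.csv`, plus a `ground_truth.json` sidecar that analysis code
#' must never consume.
#'
#' @param sim An `occx_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "occx_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) utils::write.csv(df, file.path(dir, f),
                                        row.names = FALSE, na = "")
  w(sim$cohort$participants, "participants.csv")
  w(sim$cohort$jobs[, JOB_COLS], "jobs.csv")
  w(sim$cohort$responses[, RESPONSE_COLS], "responses.csv")
  w(sim$candidates_a, "coder_a.csv")
  w(sim$candidates_b, "coder_b.csv")
  truth <- sim$truth
  truth$linear_predictor <- as.list(truth$linear_predictor)
  truth$case_probability <- as.list(truth$case_probability)
  truth$true_job_group <- as.list(truth$true_job_group)
  truth$true_soc_code <- as.list(truth$true_soc_code)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Compare simulated margins to the configured targets
#'
#' Side-by-side of key cohort margins (case fraction, sex and military
#' splits, mean jobs and mean work-years per participant) against the
#' configuration, with a flag for degenerate (zero-variance) margins.
#'
#' @param sim An `occx_sim`.
#' @return data.frame: `margin`, `configured`, `simulated`, `degenerate`.
#' @export
margins_report <- function(sim) {
  p <- sim$cohort$participants
  j <- sim$cohort$jobs
  cfg <- sim$config
  njobs <- as.numeric(table(factor(j$participant_id,
                                   levels = p$participant_id)))
  yrs <- rowsum(j$duration, j$participant_id)
  rows <- rbind(
    data.frame(margin = "case_fraction",
               configured = cfg$n_case / (cfg$n_case + cfg$n_control),
               simulated = mean(p$status == "case")),
    data.frame(margin = "p_male", configured = cfg$p_male,
               simulated = mean(p$sex == "male")),
    data.frame(margin = "p_enlisted", configured = cfg$p_enlisted,
               simulated = mean(p$military == "enlisted")),
    data.frame(margin = "mean_jobs", configured = sum(cfg$jobs_prob * 1:4),
               simulated = mean(njobs)),
    data.frame(margin = "mean_work_years", configured = NA_real_,
               simulated = mean(yrs)))
  rows$degenerate <- c(
    length(unique(p$status)) < 2L, length(unique(p$sex)) < 2L,
    length(unique(p$military)) < 2L, FALSE, FALSE)
  rows
}

#' @export
print.occx_sim <- function(x, ...) {
  cat("<occx_sim> seed ", x$config$seed, "\n", sep = "")
  print(x$cohort)
  invisible(x)
}
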