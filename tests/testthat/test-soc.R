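mk_cands <- function(df_a, df_b) {
  a <- data.frame(job_id = df_a$job_id, coder = "A",
                  rank = df_a$rank %||% 1L, soc_code = df_a$soc_code,
                  fit_score = df_a$fit_score, stringsAsFactors = FALSE)
  b <- data.frame(job_id = df_b$job_id, coder = "B", rank = 1L,
                  soc_code = df_b$soc_code, fit_score = NA_real_,
                  stringsAsFactors = FALSE)
  list(a = a, b = b)
}

test_that("coder merge keeps the top candidate and flags agreement", {
  a <- data.frame(job_id = c("j1", "j1", "j2", "j3"),
                  rank = c(2L, 1L, 1L, 1L),
                  soc_code = c("51-4122", "51-4121", "43-6014", "11-1021"),
                  fit_score = c(0.5, 0.92, 0.8, 0.6))
  b <- data.frame(job_id = c("j1", "j2", "j4"),
                  soc_code = c("51-4121", "11-1021", "49-3023"))
  c2 <- mk_cands(a, b)
  m <- merge_coders(c2$a, c2$b)
  m <- m[order(m$job_id), ]
  expect_equal(m$soc_a[m$job_id == "j1"], "51-4121")   # rank 1 wins
  expect_equal(m$fit_a[m$job_id == "j1"], 0.92)
  expect_true(m$agree[m$job_id == "j1"])
  expect_false(m$agree[m$job_id == "j2"])
  expect_true(is.na(m$agree[m$job_id == "j3"]))        # B missing
  expect_true(m$one_sided[m$job_id == "j4"])           # A missing
  # relaxed 2-digit agreement
  m2 <- merge_coders(c2$a, c2$b, agreement_digits = 2L)
  expect_true(m2$agree[m2$job_id == "j1"])
  expect_error(merge_coders(transform(c2$a, soc_code = "514121"), c2$b),
               "XX-YYYY")
})

test_that("priority cascade reproduces the triage rules", {
  jobs <- data.frame(
    job_id = c("j1", "j2", "j3", "j4"),
    title = c("CEO", "secretary", "welder", "teacher"),
    description = c("", "worked in a military facility",
                    "joins parts at a workbench", "teaches children"),
    stringsAsFactors = FALSE)
  merged <- data.frame(
    job_id = jobs$job_id,
    soc_a = c("11-1021", "43-6014", "51-4121", "25-2021"),
    fit_a = c(0.9, 0.7, 0.95, 0.5),
    soc_b = c("11-1021", "43-6014", "51-4121", "25-2021"),
    agree = c(TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  pri <- assign_priority(jobs, merged)
  expect_equal(pri[1], 0L)   # insufficient title, no description
  expect_equal(pri[2], 2L)   # base 1 (office) + exposure-context keyword
  expect_equal(pri[3], 1L)   # trades base 3, but coders agree at fit 0.95
  expect_equal(pri[4], 1L)   # education base 1, fit below high-fit bar
  # rule-cascade trace for a disagreeing trades job: stays at base 3
  merged$agree[3] <- FALSE
  expect_equal(assign_priority(jobs, merged)[3], 3L)
  # keyword upgrade caps at 3 (disagreeing trades job stays at base 3)
  jobs$description[3] <- "welds metal in a factory plant"
  expect_equal(assign_priority(jobs, merged)[3], 3L)
  # keyword upgrade applies after the high-fit lowering
  merged$agree[3] <- TRUE
  expect_equal(assign_priority(jobs, merged)[3], 2L)
})

test_that("review flags follow the priority/agreement/fit rules", {
  expect_true(flag_for_review(2L, FALSE, 0.8))
  expect_true(flag_for_review(3L, TRUE, 0.25))
  expect_false(flag_for_review(1L, FALSE, 0.1))
  expect_false(flag_for_review(2L, TRUE, 0.5))
  expect_true(flag_for_review(0L, TRUE, 0.9))    # indeterminate always
  expect_true(flag_for_review(2L, NA, 0.9))      # unknown agreement
  # monotone in priority: raising priority never clears a flag
  for (agree in c(TRUE, FALSE, NA)) for (fit in c(0.1, 0.5, NA)) {
    f <- vapply(1:3, function(p)
      flag_for_review(as.integer(p), agree, fit), TRUE)
    expect_true(all(diff(f) >= 0),
                info = sprintf("agree=%s fit=%s", agree, fit))
  }
})

test_that("audit sampling is seeded and reports exact rates", {
  sim <- shared_sim()
  m <- merge_coders(sim$candidates_a, sim$candidates_b)
  asg <- build_assignments(sim$cohort$jobs, m)
  s1 <- audit_sample(asg, 50, seed = 11)
  s2 <- audit_sample(asg, 50, seed = 11)
  expect_identical(s1, s2)
  expect_false(any(s1$priority == 0L))
  expect_error(audit_sample(asg, nrow(asg) + 1000, seed = 1), "exceeds")
  # 10 incorrect of 117: both the exact fraction and the rounded percent
  verd <- data.frame(verdict = rep(c("incorrect", "correct"),
                                   c(10, 107)))
  r <- audit_misclassification(verd)
  expect_equal(r$fraction, 10 / 117)
  expect_equal(r$percent, 8.5)
  expect_equal(audit_misclassification(
    data.frame(verdict = rep("correct", 5)))$percent, 0)
})

test_that("job-years windows intersect spans with the reference year", {
  p <- data.frame(participant_id = c("A", "B"),
                  status = c("case", "control"),
                  age_at_reference = c(60, 60), sex = "male",
                  military = "neither", education = "bachelor",
                  onset_year = c(2010, NA), consent_year = c(2012, 2012),
                  stringsAsFactors = FALSE)
  j <- data.frame(job_id = c("x1", "x2", "x3", "x4"),
                  participant_id = c("A", "A", "B", "B"),
                  slot = "recent", title = "t", description = "d",
                  start_year = c(1995, 1981, 2000, 2003),
                  end_year = c(2005, 1985, 2003, 2010),
                  stringsAsFactors = FALSE)
  co <- load_cohort(p, j, data.frame(job_id = character(0),
                                     question_id = character(0),
                                     response = character(0)))
  asg <- data.frame(job_id = j$job_id,
                    major_group = c("51-0000", "51-0000", "43-0000",
                                    "43-0000"))
  jy <- job_years_matrix(co, asg, windowed = TRUE)
  # job 1995-2005, reference 2010: 5 years in [0,10), 5 in [10,20)
  expect_equal(jy$w0_10["A", "51-0000"], 5)
  expect_equal(jy$w10_20["A", "51-0000"], 5 + 0)
  # job ending 25 years before reference, 4 years long: all in [20, Inf)
  expect_equal(jy$w20plus["A", "51-0000"], 4)
  # two jobs in one group sum; windowed entries sum to the total
  expect_equal(jy$total["B", "43-0000"], 3 + 7)
  expect_equal(jy$w0_10 + jy$w10_20 + jy$w20plus, jy$total,
               tolerance = 1e-9)
  # group totals equal the participant's summed eligible durations
  expect_equal(unname(rowSums(jy$total)),
               unname(rowsum(co$jobs$duration,
                             co$jobs$participant_id)[, 1]))
})

test_that("group tabulation reproduces percentage arithmetic", {
  # synthetic matrix with one all-zero group column
  p <- data.frame(participant_id = sprintf("p%d", 1:10),
                  status = rep(c("case", "control"), 5),
                  age_at_reference = 50 + 1:10, sex = "female",
                  military = "neither", education = "bachelor",
                  onset_year = ifelse(rep(c(TRUE, FALSE), 5), 2015, NA),
                  consent_year = 2016, stringsAsFactors = FALSE)
  co <- list(participants = p)
  class(co) <- "occx_cohort"
  jym <- matrix(0, 10, 2, dimnames = list(p$participant_id,
                                          c("51-0000", "99-0000")))
  jym[1:6, "51-0000"] <- c(10, 20, 30, 5, 2, 3)
  tab <- tabulate_group(co, jym)
  expect_equal(nrow(tab), 1L)   # zero-participant group omitted
  row <- tab[tab$major_group == "51-0000", ]
  expect_equal(row$n_case, 3L); expect_equal(row$n_control, 3L)
  expect_equal(row$pct_jobyears_case, 100 * 42 / 70)
  expect_equal(row$pct_case, 50)
})

test_that("enrichment z-test matches its formula and an exact binomial", {
  # worked example: 78 cases of 112 against the cohort case fraction
  r <- enrichment_test(78, 34, p0 = 381 / 653)
  expect_equal(r$p, 0.0153, tolerance = 0.01)
  z_direct <- (78 / 112 - 381 / 653) /
    sqrt((381 / 653) * (1 - 381 / 653) / 112)
  expect_equal(r$z, z_direct)
  expect_equal(enrichment_test(50, 50, 0.5)$z, 0)
  expect_equal(enrichment_test(50, 50, 0.5)$p, 1)
  expect_error(enrichment_test(5, 5, 1.2), "between 0 and 1")
  # decision agreement with an exact binomial oracle at alpha = 0.05
  withr::with_seed(42, {
    for (i in 1:30) {
      n <- sample(30:200, 1)
      p0 <- runif(1, 0.2, 0.8)
      k <- rbinom(1, n, runif(1, 0.2, 0.8))
      approx_p <- enrichment_test(k, n - k, p0)$p
      exact_p <- stats::binom.test(k, n, p0)$p.value
      if (abs(approx_p - 0.05) > 0.02)   # away from the boundary
        expect_equal(approx_p < 0.05, exact_p < 0.05,
                     info = sprintf("n=%d k=%d p0=%.2f", n, k, p0))
    }
  })
})

test_that("2-digit job-years equal the sum over constituent 6-digit codes", {
  sim <- shared_sim()
  co <- filter_eligible_jobs(sim$cohort)
  m <- merge_coders(sim$candidates_a, sim$candidates_b)
  asg <- build_assignments(co$jobs, m)
  jym <- job_years_matrix(co, asg)
  # independent route: accumulate by 6-digit code, then collapse
  code <- asg$final_code[match(co$jobs$job_id, asg$job_id)]
  by6 <- rowsum(co$jobs$duration,
                paste(co$jobs$participant_id, code, sep = "|"))
  key <- do.call(rbind, strsplit(rownames(by6), "|", fixed = TRUE))
  agg <- rowsum(by6[, 1], paste(key[, 1], soc_major_group(key[, 2])))
  for (i in sample(nrow(agg), 50)) {
    parts <- strsplit(rownames(agg)[i], " ")[[1]]
    expect_equal(jym[parts[1], parts[2]], unname(agg[i, 1]))
  }
})
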