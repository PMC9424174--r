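sf <- function(resp, items = 3, weight = 1) {
  # equal-weight yes/no factor with `items` questions
  list(factor_id = "f", weight = weight,
       items = lapply(seq_len(items), function(i)
         list(question_id = paste0("q", i), map = c(yes = 1, no = 0))))
}

test_that("factor scoring normalizes by the attainable maximum", {
  f <- sf(items = 3)
  expect_equal(score_factor(c(q1 = "no", q2 = "no", q3 = "no"), f), 0)
  expect_equal(score_factor(c(q1 = "yes", q2 = "yes", q3 = "yes"), f), 1)
  # hand sum: one yes of three equal items, one answered no, one missing
  expect_equal(score_factor(c(q1 = "yes", q2 = "no"), f), 1 / 3)
  # all items missing -> missing
  expect_true(is.na(score_factor(c(other = "yes"), f)))
  # ordinal contributions count at their mapped value
  g <- list(factor_id = "g", weight = 1, items = list(
    list(question_id = "q1", map = c(never = 0, sometimes = 0.5, often = 1)),
    list(question_id = "q2", map = c(yes = 1, no = 0))))
  expect_equal(score_factor(c(q1 = "sometimes", q2 = "no"), g), 0.25)
})

test_that("job score is the weighted mean of non-missing factors", {
  ts <- list(type = "x", factors = list(
    list(factor_id = "f1", weight = 2, items = list(
      list(question_id = "q1", map = c(yes = 1, no = 0)),
      list(question_id = "q2", map = c(yes = 1, no = 0)))),
    list(factor_id = "f2", weight = 1, items = list(
      list(question_id = "q3", map = c(yes = 1, no = 0))))))
  # factor scores 0.5 (w=2) and 1.0 (w=1) -> (2*0.5 + 1*1)/3 = 2/3
  expect_equal(score_job(c(q1 = "yes", q2 = "no", q3 = "yes"), ts), 2 / 3)
  # one factor entirely missing -> remaining factor carries the score
  expect_equal(score_job(c(q1 = "yes", q2 = "no"), ts), 0.5)
  expect_equal(score_job(c(q1 = "no", q2 = "no", q3 = "no"), ts), 0)
  expect_true(is.na(score_job(c(zz = "yes"), ts)))
})

test_that("participant aggregation: ever = max, duration-adjusted = weighted mean", {
  expect_equal(participant_ever_score(0.4), 0.4)
  expect_equal(participant_ever_score(c(0.2, 0.7, 0.0)), 0.7)
  expect_true(is.na(participant_ever_score(c(NA, NA))))
  expect_equal(participant_ever_score(c(0.2, 0.6), method = "mean"), 0.4)
  expect_equal(duration_adjusted_score(0.4, 7), 0.4)
  expect_equal(duration_adjusted_score(c(0.8, 0.0), c(10, 30)), 0.2)
  expect_equal(duration_adjusted_score(c(0, 0), c(1, 2)), 0)
  expect_true(is.na(duration_adjusted_score(c(NA, NA), c(1, 2))))
})

test_that("standardization matches the direct formula and rejects constants", {
  x <- c(0, 1, 1, 0, 1)
  z <- standardize_scores(x)
  expect_equal(z, (x - mean(x)) / sd(x))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  # already standardized input passes through unchanged moments
  expect_equal(standardize_scores(z), z)
  expect_error(standardize_scores(rep(0.3, 5)), "distinct")
  # NA propagates but does not poison the moments
  x2 <- c(x, NA)
  expect_equal(standardize_scores(x2)[1:5], z)
  expect_true(is.na(standardize_scores(x2)[6]))
})

test_that("vectorized cohort scoring agrees with per-job scoring", {
  co <- filter_eligible_jobs(toy_mini_cohort())
  sc <- compute_scores(co)
  # independent route: score_job() per job from raw responses
  for (i in seq_len(nrow(sc$job_scores))) {
    row <- sc$job_scores[i, ]
    r <- co$responses[co$responses$job_id == row$job_id, ]
    resp <- setNames(r$response, r$question_id)
    ts <- Filter(function(t) t$type == row$type, unclass(co$schema))[[1]]
    expect_equal(row$score, score_job(resp, ts),
                 info = paste(row$job_id, row$type))
  }
})

test_that("scoring invariants hold over random cohorts", {
  sim <- shared_sim()
  co <- filter_eligible_jobs(sim$cohort)
  sc <- compute_scores(co)
  all_sc <- c(sc$job_scores$score, sc$participant_ever$score,
              sc$participant_duration_adjusted$score)
  expect_true(all(is.na(all_sc) | (all_sc >= 0 & all_sc <= 1)))
  # duration-adjusted lies between the min and max job score
  js <- split(sc$job_scores, paste(sc$job_scores$participant_id,
                                   sc$job_scores$type))
  da <- sc$participant_duration_adjusted
  da_key <- paste(da$participant_id, da$type)
  for (k in sample(names(js), 200)) {
    s <- js[[k]]$score
    if (all(is.na(s))) next
    v <- da$score[match(k, da_key)]
    expect_true(v >= min(s, na.rm = TRUE) - 1e-12 &&
                  v <= max(s, na.rm = TRUE) + 1e-12)
  }
  # monotonicity: flipping one "no" to "yes" never decreases any score
  withr::with_seed(7, {
    for (rep in 1:5) {
      i <- sample(which(co$responses$response == "no"), 1)
      co2 <- co
      co2$responses$response[i] <- "yes"
      sc2 <- compute_scores(co2)
      expect_true(all(sc2$job_scores$score - sc$job_scores$score >= -1e-12,
                      na.rm = TRUE))
      expect_true(all(sc2$participant_duration_adjusted$score -
                        sc$participant_duration_adjusted$score >= -1e-12,
                      na.rm = TRUE))
    }
  })
  # invariance to response row order
  co3 <- co
  perm <- withr::with_seed(8, sample(nrow(co3$responses)))
  co3$responses <- co3$responses[perm, ]
  sc3 <- compute_scores(co3)
  expect_equal(sc3$job_scores[order(sc3$job_scores$job_id,
                                    sc3$job_scores$type), "score"],
               sc$job_scores[order(sc$job_scores$job_id,
                                   sc$job_scores$type), "score"])
})

test_that("equal weights with one item per factor reduce to the yes-fraction", {
  ts <- list(type = "x", factors = lapply(1:4, function(i)
    list(factor_id = paste0("f", i), weight = 1, items = list(
      list(question_id = paste0("q", i), map = c(yes = 1, no = 0))))))
  resp <- c(q1 = "yes", q2 = "no", q3 = "yes", q4 = "yes")
  expect_equal(score_job(resp, ts), 3 / 4)
})

test_that("metal subcomponents tabulate intersections like a brute-force tally", {
  co <- load_cohort(toy_path("participants.csv"), toy_path("jobs.csv"),
                    toy_path("responses.csv"))
  ms <- metal_subcomponents(co)
  ind <- ms$indicators
  # isolated welding: J01 reports welding+iron, J02 other metal only
  expect_true(ind$welding[ind$job_id == "J01"])
  expect_true(ind$iron[ind$job_id == "J01"])
  expect_false(any(ind[ind$job_id == "J03",
                       metal_subcomponent_levels()[1:6]] == TRUE))
  # brute-force subset tally over all jobs
  subs <- setdiff(names(ind), "job_id")
  oracle <- table(apply(ind[subs], 1, function(z)
    if (!any(z)) "(none)" else paste(subs[z], collapse = "+")))
  for (i in seq_len(nrow(ms$intersections)))
    expect_equal(ms$intersections$n_jobs[i],
                 unname(oracle[ms$intersections$pattern[i]]))
  expect_equal(sum(ms$intersections$n_jobs), nrow(co$jobs))
})

test_that("score summaries report moments, quantiles and correlations", {
  sim <- shared_sim()
  co <- filter_eligible_jobs(sim$cohort)
  sc <- compute_scores(co)
  s <- summarize_scores(sc, co)
  expect_setequal(unique(s$group), c("case", "control"))
  expect_true(all(s$n > 0))
  # constant scores give SD 0 and flat quantiles
  sc0 <- sc
  sc0$participant_duration_adjusted$score <- 0.42
  s0 <- summarize_scores(sc0, co)
  expect_true(all(s0$sd == 0) && all(s0$q75 == 0.42) && all(s0$q95 == 0.42))
  # identical score vectors across two types -> Spearman 1
  da <- sc$participant_duration_adjusted
  da$score[da$type == "voc"] <- da$score[da$type == "pm"]
  sc$participant_duration_adjusted <- da
  cm <- score_correlations(sc)
  expect_equal(cm["pm", "voc"], 1)
  # quantiles follow the linear-interpolation convention: order-statistic
  # oracle on a toy 10-value set
  x <- c(0, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 1.0)
  # type-7: h = (n-1)p + 1; q = x[h0] + (h - h0) (x[h0+1] - x[h0])
  h <- (10 - 1) * 0.9 + 1
  oracle <- x[floor(h)] + (h - floor(h)) * (x[floor(h) + 1] - x[floor(h)])
  expect_equal(score_quantile(x, 0.9), oracle)
})
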