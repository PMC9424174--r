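# shared in-code fixtures

toy_path <- function(f) system.file("extdata", "toy", f, package = "occupex")

# minimal two-type schema with unequal factor weights and an ordinal item
toy_schema <- function() {
  as_schema(list(
    list(type = "a", factors = list(
      list(factor_id = "a1", weight = 2, items = list(
        list(question_id = "q1", map = c(yes = 1, no = 0)),
        list(question_id = "q2", map = c(yes = 1, no = 0)))),
      list(factor_id = "a2", weight = 1, items = list(
        list(question_id = "q3",
             map = c(never = 0, sometimes = 0.5, often = 1)))))),
    list(type = "b", factors = list(
      list(factor_id = "b1", weight = 1, items = list(
        list(question_id = "q4", map = c(yes = 1, no = 0)),
        list(question_id = "q5", map = c(yes = 1, no = 0))))))))
}

# tiny in-code cohort against toy_schema(); ages span the quartile grid
toy_mini_cohort <- function(schema = toy_schema()) {
  p <- data.frame(
    participant_id = sprintf("M%02d", 1:8),
    status = rep(c("case", "control"), 4),
    age_at_reference = c(45, 50, 55, 60, 65, 70, 75, 80),
    sex = rep(c("male", "female"), 4),
    military = c("neither", "enlisted", rep("neither", 6)),
    education = "bachelor",
    onset_year = c(2012, NA, 2015, NA, 2010, NA, 2016, NA),
    consent_year = rep(2018, 8), stringsAsFactors = FALSE)
  j <- data.frame(
    job_id = sprintf("MJ%02d", 1:10),
    participant_id = c("M01", "M01", "M02", "M03", "M04", "M05", "M06",
                       "M07", "M08", "M08"),
    slot = "recent", title = "worker", description = "works",
    start_year = c(1990, 2000, 1995, 2000, 1985, 1980, 1999, 2001, 1970,
                   1990),
    end_year = c(2000, 2010, 2015, 2014, 2017, 2009, 2017, 2015, 1990,
                 2017), stringsAsFactors = FALSE)
  r <- data.frame(
    job_id = c("MJ01", "MJ01", "MJ01", "MJ02", "MJ03", "MJ03", "MJ04",
               "MJ05", "MJ06", "MJ07", "MJ08", "MJ09", "MJ10"),
    question_id = c("q1", "q2", "q3", "q1", "q4", "q5", "q1", "q3", "q2",
                    "q4", "q1", "q5", "q2"),
    response = c("yes", "no", "often", "no", "yes", "yes", "yes",
                 "sometimes", "no", "no", "yes", "yes", "no"),
    stringsAsFactors = FALSE)
  load_cohort(p, j, r, schema)
}

# small simulated cohort reused by several tests (generation is the
# expensive step, so share one)
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cohort(sim_config(n_case = 120L, n_control = 90L,
                                           seed = 424242L))
    cache
  }
})
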