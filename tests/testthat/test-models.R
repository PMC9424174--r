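test_that("permutation p-values honour the add-one convention", {
  # identical group distributions: every permutation ties or beats
  v <- c(1, 2, 3, 1, 2, 3)
  g <- rep(c("a", "b"), each = 3)
  expect_equal(permutation_test(v, g, B = 199, seed = 1)$p, 1)
  # fully separated groups: minimal attainable p = 1/(B+1) needs every
  # permutation to fall below the observed difference
  v2 <- c(rnorm(20, 0), rnorm(20, 100))
  g2 <- rep(c("a", "b"), each = 20)
  expect_equal(permutation_test(v2, g2, B = 999, seed = 2)$p, 1 / 1000)
  # invariance to group relabeling and to location shifts
  v3 <- withr::with_seed(3, rnorm(40))
  g3 <- rep(c("x", "y"), 20)
  p1 <- permutation_test(v3, g3, B = 500, seed = 9)$p
  expect_equal(permutation_test(v3 + 17.3, g3, B = 500, seed = 9)$p, p1)
  expect_equal(permutation_test(v3, ifelse(g3 == "x", "y", "x"),
                                B = 500, seed = 9)$p, p1)
  expect_error(permutation_test(v3, rep("x", 40), B = 100, seed = 1),
               "2 groups")
})

test_that("unadjusted logistic OR equals the 2x2 cross-product ratio", {
  withr::with_seed(14, {
    for (i in 1:25) {
      cts <- sample(5:40, 4, replace = TRUE)   # a, b, c, d
      y <- rep(c(1, 1, 0, 0), cts)
      x <- rep(c(1, 0, 1, 0), cts)
      fit <- fit_logistic(y, matrix(x, ncol = 1,
                                    dimnames = list(NULL, "e")))
      expect_equal(fit$or, (cts[1] * cts[4]) / (cts[2] * cts[3]),
                   tolerance = 1e-6)
    }
  })
  expect_error(fit_logistic(rep(1, 20), matrix(rnorm(20), ncol = 1)),
               "constant")
  # perfect separation is refused with the term named
  y <- rep(0:1, each = 20)
  x <- matrix(c(rnorm(20, -5), rnorm(20, 5)), ncol = 1,
              dimnames = list(NULL, "sep_term"))
  expect_error(fit_logistic(y, x), "sep")
})

test_that("OR per k years is an exact reparameterization", {
  withr::with_seed(5, {
    n <- 400
    yrs <- runif(n, 0, 40)
    y <- rbinom(n, 1, plogis(-0.8 + 0.04 * yrs))
    f5 <- or_per_k_years(y, yrs, k = 5)
    f1 <- or_per_k_years(y, yrs, k = 1)
    expect_equal(f5$or, f1$or^5, tolerance = 1e-10)
    expect_equal(f5$p, f1$p, tolerance = 1e-8)
  })
  # per-year log-odds 0.04 -> OR per 5 years = exp(0.2)
  expect_equal(exp(0.04 * 5), 1.2214, tolerance = 1e-4)
  expect_error(or_per_k_years(rbinom(20, 1, 0.5), runif(20), k = 0),
               "positive")
})

test_that("BH adjustment matches a brute-force threshold scan", {
  bh_oracle <- function(p) {
    # adjusted p_i = min over j >= rank(i) of m * p_(j) / j, capped at 1
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    sorted <- p[o]
    for (i in seq_len(m))
      adj[o[i]] <- min(1, min(m * sorted[i:m] / (i:m)))
    adj
  }
  withr::with_seed(21, {
    for (i in 1:50) {
      p <- runif(sample(1:25, 1))^sample(1:3, 1)
      expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
    }
  })
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 7)), rep(0.2, 7))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  # m = 23 family, smallest raw p = 0.001 isolated: adjusted = 23 * 0.001
  p23 <- c(0.001, seq(0.3, 0.96, length.out = 22))
  expect_equal(bh_adjust(p23)[1], 0.023)
  # monotone nondecreasing in the sorted raw p's, bounded by 1
  p <- withr::with_seed(4, runif(15))
  adj <- bh_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_true(all(adj <= 1))
})

test_that("adaptive elastic net recovers the unpenalized fit as lambda -> 0", {
  withr::with_seed(31, {
    n <- 500
    z <- matrix(rnorm(n * 4), n, 4,
                dimnames = list(NULL, paste0("s", 1:4)))
    cv <- matrix(rbinom(n * 2, 1, 0.5), n, 2,
                 dimnames = list(NULL, c("c1", "c2")))
    y <- rbinom(n, 1, plogis(0.4 * z[, 1] - 0.3 * z[, 3] + 0.2 * cv[, 1]))
    aen <- adaptive_elastic_net(y, z, cv, seed = 1, lambda = 1e-7)
    ref <- glm(y ~ ., data = data.frame(y, z, cv),
               family = binomial())
    expect_equal(aen$beta, unname(coef(ref)[colnames(z)]),
                 tolerance = 1e-4)
    # covariates stay in the model regardless of selection
    expect_equal(attr(aen, "covariate_beta"),
                 coef(ref)[colnames(cv)], tolerance = 1e-4)
  })
  expect_error(adaptive_elastic_net(rbinom(30, 1, 0.5),
                                    matrix(1, 30, 3)), "constant")
})

test_that("coefficient paths shrink toward zero as lambda grows", {
  withr::with_seed(33, {
    n <- 300
    z <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("s", 1:5)))
    y <- rbinom(n, 1, plogis(0.6 * z[, 1] + 0.4 * z[, 2]))
    grid <- c(0.2, 0.1, 0.05, 0.02, 0.01, 0.005, 0.001)
    l1 <- vapply(grid, function(l)
      sum(abs(adaptive_elastic_net(y, z, NULL, seed = 1,
                                   lambda = l)$beta)), 0)
    expect_true(all(diff(l1) >= -1e-8))   # grid is decreasing in lambda
  })
})

test_that("adaptive lasso on job-years selects a strong planted group", {
  withr::with_seed(55, {
    n <- 600
    jy <- matrix(rexp(n * 12, rate = 0.2), n, 12,
                 dimnames = list(NULL, sprintf("%02d-0000", 11:22)))
    y <- rbinom(n, 1, plogis(-1 + 0.12 * jy[, 3]))
    sel <- adaptive_lasso_soc(y, jy, NULL, seed = 3)
    expect_true(sel$selected[3])
    expect_true(sel$beta[3] > 0)
  })
})

test_that("linear score-on-job-years models recover slopes and refuse collinearity", {
  withr::with_seed(77, {
    n <- 650
    jy <- rexp(n, 0.1)
    cv <- matrix(rbinom(n * 2, 1, 0.5), n, 2,
                 dimnames = list(NULL, c("male", "enlisted")))
    sc <- 0.15 * jy / 5 + 0.3 * cv[, 1] + rnorm(n)
    est <- replicate(20, {
      sc_i <- 0.15 * jy / 5 + 0.3 * cv[, 1] + rnorm(n)
      linear_score_on_socyears(sc_i, jy, cv)$beta
    })
    expect_equal(mean(est), 0.15, tolerance = 0.05)
    one <- linear_score_on_socyears(sc, jy, cv)
    expect_true(one$ci_low < one$beta && one$beta < one$ci_high)
    dup <- cbind(cv, male2 = cv[, 1])
    expect_error(linear_score_on_socyears(sc, jy, dup), "rank")
  })
})

test_that("model batteries assemble per-term tables with BH families", {
  sim <- shared_sim()
  co <- impute_military(filter_eligible_jobs(sim$cohort))
  sc <- compute_scores(co)
  res <- exposure_model_battery(co, sc, B = 299, seed = 5, nfolds = 5)
  expect_setequal(res$univariate$term, names(exposure_types()))
  expect_true(all(res$univariate$ci_low <= res$univariate$or &
                    res$univariate$or <= res$univariate$ci_high))
  expect_true(all(res$univariate$p > 0 & res$univariate$p <= 1))
  expect_true(all(res$univariate$perm_p >= 1 / 300))
  m <- merge_coders(sim$candidates_a, sim$candidates_b)
  asg <- build_assignments(co$jobs, m)
  jym <- job_years_matrix(co, asg)
  socres <- soc_model_battery(co, jym, seed = 5, nfolds = 5)
  expect_true(all(socres$per_group$p_bh_adj >= socres$per_group$p_adj))
  expect_equal(nrow(socres$lasso), nrow(socres$per_group))
  expect_lte(nrow(socres$per_group), ncol(jym))
})
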