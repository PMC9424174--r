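#' Two-sided permutation test for a difference in group means
#'
#' Statistic is the difference in group means; the permutation p-value uses
#' the add-one convention p = (1 + #\{b : |T_b| >= |T_obs|\}) / (B + 1),
#' with label permutations drawn under the given seed. Missing values are
#' dropped pairwise before permuting.
#'
#' @param values Numeric vector.
#' @param labels Two-level grouping aligned to `values`.
#' @param B Number of permutations (default 10000, minimum 99).
#' @param seed Integer seed.
#' @return List: `p`, `statistic` (observed mean difference), `B`.
#' @export
permutation_test <- function(values, labels, B = 10000L, seed = 1L) {
  stopifnot(B >= 99L)
  keep <- !is.na(values) & !is.na(labels)
  x <- values[keep]
  g <- as.factor(labels[keep])
  if (nlevels(droplevels(g)) != 2L) stop("labels must have exactly 2 groups")
  g <- droplevels(g)
  n1 <- sum(g == levels(g)[1L])
  n2 <- sum(g == levels(g)[2L])
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 observations")
  n <- n1 + n2
  s_tot <- sum(x)
  t_obs <- mean(x[g == levels(g)[1L]]) - mean(x[g == levels(g)[2L]])
  t_perm <- with_local_seed(seed, {
    idx <- replicate(B, sample.int(n, n1))
    s1 <- colSums(matrix(x[idx], nrow = n1))
    s1 / n1 - (s_tot - s1) / n2
  })
  p <- (1 + sum(abs(t_perm) >= abs(t_obs))) / (B + 1)
  list(p = p, statistic = t_obs, B = B)
}

#' Covariate-adjusted logistic regression
#'
#' Maximum-likelihood logistic fit of case status on one or more terms of
#' interest plus the adjustment covariates, reporting odds ratios with Wald
#' 95% intervals and two-sided Wald p-values. Enter exposure scores
#' standardized so the OR is per standard deviation.
#'
#' @param outcome 0/1 (or logical) case indicator.
#' @param terms Named numeric matrix or data.frame of predictors of
#'   interest.
#' @param covariates Optional numeric matrix of adjustment covariates (e.g.
#'   from `covariate_matrix()`); NULL for an unadjusted fit.
#' @return data.frame with one row per term of interest: `term`, `or`
#'   (exp(coefficient)), `ci_low`, `ci_high`, `p`, `beta`, `se`, `n`.
#' @export
fit_logistic <- function(outcome, terms, covariates = NULL) {
  y <- as.integer(outcome)
  if (length(unique(y[!is.na(y)])) < 2L)
    stop("outcome is constant; cannot fit")
  tm <- as.matrix(terms)
  if (is.null(colnames(tm)))
    colnames(tm) <- paste0("term", seq_len(ncol(tm)))
  X <- if (is.null(covariates)) tm else cbind(tm, as.matrix(covariates))
  keep <- stats::complete.cases(X) & !is.na(y)
  Xk <- X[keep, , drop = FALSE]
  if (qr(cbind(1, Xk))$rank < ncol(Xk) + 1L)
    stop("design matrix not full rank")
  labels <- colnames(Xk)
  internal <- paste0("V", seq_len(ncol(Xk)))   # labels may be non-syntactic
  colnames(Xk) <- internal
  dat <- data.frame(.y = y[keep], Xk)
  # tight convergence so small-sample ORs agree with closed forms to ~1e-8
  fit <- stats::glm(.y ~ ., data = dat, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-12,
                                                 maxit = 100L))
  cf <- summary(fit)$coefficients
  rownames(cf)[match(internal, rownames(cf))] <- labels
  bad <- rownames(cf)[abs(cf[, "Estimate"]) > 15 | cf[, "Std. Error"] > 100]
  bad <- setdiff(bad, "(Intercept)")
  if (!fit$converged || length(bad))
    stop("separation detected for term(s): ",
         paste(if (length(bad)) bad else colnames(tm), collapse = ", "))
  zq <- stats::qnorm(0.975)
  rows <- lapply(colnames(tm), function(nm) {
    b <- cf[nm, "Estimate"]; se <- cf[nm, "Std. Error"]
    data.frame(term = nm, or = exp(b), ci_low = exp(b - zq * se),
               ci_high = exp(b + zq * se),
               p = 2 * stats::pnorm(-abs(b / se)),
               beta = b, se = se, n = sum(keep), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Odds ratio per k additional years
#'
#' Divides a years-scale predictor by k before the logistic fit so that
#' exp(coefficient) reads as the OR per k additional years (k = 5 by
#' default, the reporting convention for job-years models).
#'
#' @param outcome 0/1 case indicator.
#' @param years Numeric predictor in years.
#' @param covariates Optional adjustment covariate matrix.
#' @param k Year increment (> 0).
#' @param term Label for the output row.
#' @return One-row data.frame as in [fit_logistic()].
#' @export
or_per_k_years <- function(outcome, years, covariates = NULL, k = 5,
                           term = "years") {
  if (k <= 0) stop("k must be positive")
  tm <- matrix(years / k, ncol = 1, dimnames = list(NULL, term))
  fit_logistic(outcome, tm, covariates)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity,
#' capped at 1.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  stats::p.adjust(p, method = "BH")
}

# shared two-stage machinery for the adaptive penalized fits: stage 1 ridge
# for stable initial coefficients under correlation, stage 2 elastic net
# with penalty factors |beta_ridge|^-gamma on penalized terms and 0 on
# covariates; lambda by seeded K-fold CV minimizing binomial deviance
adaptive_penalized <- function(y, penalized, covariates, alpha, gamma,
                               nfolds, seed, lambda = NULL) {
  pen <- as.matrix(penalized)
  if (all(apply(pen, 2, stats::sd, na.rm = TRUE) == 0))
    stop("all penalized predictors are constant")
  cov <- if (is.null(covariates)) NULL else as.matrix(covariates)
  X <- if (is.null(cov)) pen else cbind(pen, cov)
  keep <- stats::complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]
  yk <- as.integer(y)[keep]
  npen <- ncol(pen)

  ridge <- with_local_seed(seed, glmnet::cv.glmnet(
    X, yk, family = "binomial", alpha = 0, nfolds = nfolds,
    penalty.factor = c(rep(1, npen), rep(0, ncol(X) - npen)),
    standardize = FALSE))
  b1 <- as.numeric(stats::coef(ridge, s = "lambda.min"))[-1L][seq_len(npen)]
  w <- pmin(abs(b1)^(-gamma), 1e6)   # cap so a zero ridge coef stays finite

  pf <- c(w, rep(0, ncol(X) - npen))
  if (is.null(lambda)) {
    fit <- with_local_seed(seed + 1L, glmnet::cv.glmnet(
      X, yk, family = "binomial", alpha = alpha, nfolds = nfolds,
      penalty.factor = pf, standardize = FALSE))
    beta <- as.numeric(stats::coef(fit, s = "lambda.min"))[-1L]
  } else {
    fit <- glmnet::glmnet(X, yk, family = "binomial", alpha = alpha,
                          penalty.factor = pf, standardize = FALSE,
                          lambda = lambda)
    beta <- as.numeric(stats::coef(fit, s = lambda))[-1L]
  }
  names(beta) <- colnames(X)
  sel <- beta[seq_len(npen)]
  out <- data.frame(term = colnames(pen), beta = unname(sel),
                    or = exp(unname(sel)), selected = sel != 0,
                    stringsAsFactors = FALSE)
  attr(out, "covariate_beta") <- beta[-seq_len(npen)]
  out
}

#' Adaptive elastic net over the exposure scores
#'
#' Two-stage penalized multivariable logistic regression for selecting
#' among correlated exposures: a ridge logistic fit supplies adaptive
#' weights |beta|^-gamma, then an elastic net (mixing alpha) with those
#' weights as per-exposure penalty factors; adjustment covariates are never
#' penalized. Lambda is chosen by seeded K-fold cross-validated deviance.
#' Scores should enter standardized so penalization is comparable across
#' exposures and ORs are per SD.
#'
#' @param outcome 0/1 case indicator.
#' @param scores Matrix of standardized exposure scores (columns = types).
#' @param covariates Adjustment covariate matrix (unpenalized), or NULL.
#' @param alpha Elastic-net mixing in \[0, 1\] (default 0.5).
#' @param gamma Adaptive-weight exponent (default 1).
#' @param nfolds CV folds (default 10).
#' @param seed Integer seed for fold assignment.
#' @param lambda Optional fixed penalty; NULL (default) selects lambda by
#'   cross-validation. A value near 0 recovers the unpenalized
#'   multivariable fit.
#' @return data.frame per exposure: `term`, `beta`, `or` (penalized),
#'   `selected`; attribute `"covariate_beta"` holds the (unpenalized)
#'   covariate coefficients, which stay in the model regardless of
#'   selection.
#' @export
adaptive_elastic_net <- function(outcome, scores, covariates = NULL,
                                 alpha = 0.5, gamma = 1, nfolds = 10L,
                                 seed = 1L, lambda = NULL) {
  adaptive_penalized(outcome, scores, covariates, alpha, gamma, nfolds,
                     seed, lambda)
}

#' Adaptive lasso over SOC job-years
#'
#' Same two-stage scheme as [adaptive_elastic_net()] with alpha = 1,
#' applied to the per-5-year job-years of all major groups simultaneously;
#' covariates stay unpenalized.
#'
#' @param outcome 0/1 case indicator.
#' @param jobyears Matrix participants x major groups, in years.
#' @param covariates Adjustment covariate matrix, or NULL.
#' @param gamma,nfolds,seed,lambda As in [adaptive_elastic_net()].
#' @param k Year increment the coefficients refer to (default 5).
#' @return data.frame per group: `term`, `beta`, `or` (per k years),
#'   `selected`; covariate coefficients in attribute `"covariate_beta"`.
#' @export
adaptive_lasso_soc <- function(outcome, jobyears, covariates = NULL,
                               gamma = 1, nfolds = 10L, seed = 1L, k = 5,
                               lambda = NULL) {
  adaptive_penalized(outcome, as.matrix(jobyears) / k, covariates,
                     alpha = 1, gamma, nfolds, seed, lambda)
}

#' Linear model of an exposure score on SOC job-years
#'
#' Ordinary least squares of a standardized exposure score on job-years in
#' one major group (per 5-year units) plus the adjustment covariates, so
#' the slope reads as SD change in score per 5 additional years worked.
#'
#' @param score_z Standardized exposure score vector.
#' @param jobyears Years worked in the group (same length).
#' @param covariates Adjustment covariate matrix, or NULL.
#' @param k Year increment (default 5).
#' @param term Label for the output row.
#' @return One-row data.frame: `term`, `beta` (slope), `ci_low`, `ci_high`
#'   (Wald 95%), `p`, `n`.
#' @export
linear_score_on_socyears <- function(score_z, jobyears, covariates = NULL,
                                     k = 5, term = "jobyears") {
  tm <- matrix(jobyears / k, ncol = 1, dimnames = list(NULL, term))
  X <- if (is.null(covariates)) tm else cbind(tm, as.matrix(covariates))
  keep <- stats::complete.cases(X) & !is.na(score_z)
  Xk <- X[keep, , drop = FALSE]
  if (qr(cbind(1, Xk))$rank < ncol(Xk) + 1L)
    stop("design matrix not full rank")
  colnames(Xk) <- paste0("V", seq_len(ncol(Xk)))
  dat <- data.frame(.y = score_z[keep], Xk)
  fit <- stats::lm(.y ~ ., data = dat)
  cf <- summary(fit)$coefficients
  b <- cf["V1", "Estimate"]; se <- cf["V1", "Std. Error"]
  zq <- stats::qnorm(0.975)
  data.frame(term = term, beta = b, ci_low = b - zq * se,
             ci_high = b + zq * se,
             p = 2 * stats::pnorm(-abs(b / se)), n = sum(keep),
             stringsAsFactors = FALSE)
}

#' Per-exposure association battery
#'
#' Convenience wrapper running, for each exposure type: the permutation
#' test of the case/control mean difference, the covariate-adjusted
#' univariate logistic model on the standardized score, then one joint
#' multivariable logistic model and one adaptive elastic net over all
#' types together. Participants missing a score are dropped from the
#' models of that score, never imputed.
#'
#' @param cohort An `occx_cohort` (filtered, military imputed).
#' @param scores An `occx_scores` object.
#' @param which `"duration_adjusted"` (default) or `"ever"`.
#' @param B Permutation count.
#' @param seed Integer seed.
#' @param alpha,gamma,nfolds Passed to [adaptive_elastic_net()].
#' @return List: `univariate` (per-type rows with permutation p),
#'   `multivariable` (per-type rows from the joint fit), `aen` (adaptive
#'   elastic net selection).
#' @export
exposure_model_battery <- function(cohort, scores,
                                   which = c("duration_adjusted", "ever"),
                                   B = 10000L, seed = 1L, alpha = 0.5,
                                   gamma = 1, nfolds = 10L) {
  which <- match.arg(which)
  m <- score_matrix(scores, which)
  p <- cohort$participants
  ord <- match(rownames(m), p$participant_id)
  y <- as.integer(p$status[ord] == "case")
  cov <- covariate_matrix(make_covariates(cohort), rownames(m))
  z <- apply(m, 2, function(x)
    if (length(unique(x[!is.na(x)])) > 1L) standardize_scores(x)
    else rep(NA_real_, length(x)))

  uni <- list()
  for (i in seq_len(ncol(z))) {
    ty <- colnames(z)[i]
    perm <- permutation_test(m[, i], y, B = B, seed = seed + i)
    row <- fit_logistic(y, matrix(z[, i], ncol = 1,
                                  dimnames = list(NULL, ty)), cov)
    row$perm_p <- perm$p
    uni[[ty]] <- row
  }
  uni <- do.call(rbind, uni)

  keep_joint <- stats::complete.cases(z)
  multi <- fit_logistic(y[keep_joint], z[keep_joint, , drop = FALSE],
                        cov[keep_joint, , drop = FALSE])
  aen <- adaptive_elastic_net(y[keep_joint], z[keep_joint, , drop = FALSE],
                              cov[keep_joint, , drop = FALSE],
                              alpha = alpha, gamma = gamma,
                              nfolds = nfolds, seed = seed)
  list(univariate = uni, multivariable = multi, aen = aen)
}

#' Per-SOC job-years association battery
#'
#' For each major group: unadjusted and covariate-adjusted logistic models
#' of case status on job-years (OR per 5 years) with BH correction across
#' the family of groups, plus the adaptive lasso over all groups jointly.
#'
#' @param cohort An `occx_cohort`.
#' @param jym Unwindowed job-years matrix.
#' @param seed,gamma,nfolds Passed to [adaptive_lasso_soc()].
#' @param k Year increment (default 5).
#' @param min_n Minimum participants with any years in a group for its
#'   single-group models (and membership in the BH family and lasso);
#'   groups below it are too sparse for a stable logistic fit.
#' @return List: `per_group` (rows with unadjusted and adjusted OR, raw and
#'   BH p), `lasso` (adaptive lasso selection).
#' @export
soc_model_battery <- function(cohort, jym, seed = 1L, gamma = 1,
                              nfolds = 10L, k = 5, min_n = 5L) {
  p <- cohort$participants
  jym <- jym[, colSums(jym > 0) >= min_n, drop = FALSE]
  ord <- match(rownames(jym), p$participant_id)
  y <- as.integer(p$status[ord] == "case")
  cov <- covariate_matrix(make_covariates(cohort), rownames(jym))
  rows <- list()
  for (g in colnames(jym)) {
    un <- or_per_k_years(y, jym[, g], NULL, k = k, term = g)
    ad <- or_per_k_years(y, jym[, g], cov, k = k, term = g)
    rows[[g]] <- data.frame(
      major_group = g, or_unadj = un$or, ci_low_unadj = un$ci_low,
      ci_high_unadj = un$ci_high, p_unadj = un$p,
      or_adj = ad$or, ci_low_adj = ad$ci_low, ci_high_adj = ad$ci_high,
      p_adj = ad$p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_bh_unadj <- bh_adjust(out$p_unadj)
  out$p_bh_adj <- bh_adjust(out$p_adj)
  lasso <- adaptive_lasso_soc(y, jym, cov, gamma = gamma, nfolds = nfolds,
                              seed = seed, k = k)
  list(per_group = out, lasso = lasso)
}
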