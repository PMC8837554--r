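#' Prior for the four-model subtype comparison
#'
#' The classifier compares four hypotheses about a variant's effects
#' `(b_MO, b_MA)` in the two subtypes: `NULL` (both zero), `MO` / `MA` (a
#' nonzero effect in one subtype only) and `BOTH` (nonzero in both). Nonzero
#' effects have a Gaussian prior with standard deviation `tau` on the
#' log-odds scale, and `BOTH` is an equal-weight mixture of a fixed-effect
#' component (identical effect in both subtypes) and an independent-effects
#' component (two uncorrelated nonzero effects). `corr` is the correlation of
#' the two effect estimators, induced by control overlap between the subtype
#' analyses.
#'
#' @param tau Prior standard deviation of a nonzero effect (log-odds),
#'   default 0.2.
#' @param model_prior Prior probabilities over `NULL, MO, MA, BOTH`
#'   (sum to 1).
#' @param both_mixture Weights of the fixed / independent components of
#'   `BOTH`.
#' @param corr Estimator correlation `c` in `(-1, 1)`, default 0.148.
#' @return A `subtype_prior` list.
#' @export
subtype_prior <- function(tau = 0.2, model_prior = rep(0.25, 4),
                          both_mixture = c(0.5, 0.5), corr = 0.148) {
  if (tau <= 0) abort("tau must be positive", class = "migwas_domain_error")
  if (length(model_prior) != 4 || abs(sum(model_prior) - 1) > 1e-8 ||
      any(model_prior < 0)) {
    abort("model_prior must be 4 non-negative values summing to 1",
          class = "migwas_domain_error")
  }
  if (length(both_mixture) != 2 || abs(sum(both_mixture) - 1) > 1e-8 ||
      any(both_mixture < 0)) {
    abort("both_mixture must be 2 non-negative weights summing to 1",
          class = "migwas_domain_error")
  }
  if (abs(corr) >= 1) {
    abort("corr must lie in (-1, 1)", class = "migwas_domain_error")
  }
  structure(list(tau = tau,
                 model_prior = setNames(model_prior,
                                        c("NULL", "MO", "MA", "BOTH")),
                 both_mixture = setNames(both_mixture,
                                         c("fixed", "independent")),
                 corr = corr),
            class = "subtype_prior")
}

# log density of (x1, x2) under a centered bivariate normal with the given
# covariance entries; vectorized over observations
log_dbvn <- function(x1, x2, v1, v12, v2) {
  det <- v1 * v2 - v12^2
  if (any(det <= 0) || any(v1 <= 0) || any(v2 <= 0)) {
    abort("covariance is not positive definite", class = "migwas_domain_error")
  }
  q <- (v2 * x1^2 - 2 * v12 * x1 * x2 + v1 * x2^2) / det
  -log(2 * pi) - 0.5 * log(det) - 0.5 * q
}

log_sum_exp <- function(m) {
  # rowwise log-sum-exp of a matrix
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Log marginal likelihoods of the four subtype models
#'
#' The sampling model is a bivariate Gaussian approximation to the
#' likelihood: `(bhat_MO, bhat_MA) ~ N((b_MO, b_MA), Sigma)` with
#' `Sigma = [[se_MO^2, c se_MO se_MA], [c se_MO se_MA, se_MA^2]]`.
#' Integrating the Gaussian effect priors analytically, the marginal
#' likelihood of each model is a centered bivariate normal density of the
#' observed estimates with covariance `Sigma + P_m`, where `P_NULL = 0`,
#' `P_MO = diag(tau^2, 0)`, `P_MA = diag(0, tau^2)`, and `BOTH` is the
#' mixture of `P = tau^2 [[1,1],[1,1]]` (fixed effect) and `P = tau^2 I`
#' (independent effects). All work is done in log space.
#'
#' @param b_mo,se_mo,b_ma,se_ma Estimates and standard errors (vectorized).
#' @param prior A [subtype_prior()].
#' @param corr Estimator correlation; defaults to `prior$corr`.
#' @return A numeric matrix with columns `NULL, MO, MA, BOTH` of log marginal
#'   likelihoods.
#' @export
subtype_log_marginals <- function(b_mo, se_mo, b_ma, se_ma,
                                  prior = subtype_prior(), corr = prior$corr) {
  if (any(se_mo <= 0) || any(se_ma <= 0)) {
    abort("standard errors must be positive", class = "migwas_domain_error")
  }
  if (abs(corr) >= 1) {
    abort("corr must lie in (-1, 1)", class = "migwas_domain_error")
  }
  t2 <- prior$tau^2
  v12 <- corr * se_mo * se_ma
  ml_null <- log_dbvn(b_mo, b_ma, se_mo^2, v12, se_ma^2)
  ml_mo <- log_dbvn(b_mo, b_ma, se_mo^2 + t2, v12, se_ma^2)
  ml_ma <- log_dbvn(b_mo, b_ma, se_mo^2, v12, se_ma^2 + t2)
  ml_fix <- log_dbvn(b_mo, b_ma, se_mo^2 + t2, v12 + t2, se_ma^2 + t2)
  ml_ind <- log_dbvn(b_mo, b_ma, se_mo^2 + t2, v12, se_ma^2 + t2)
  w <- log(prior$both_mixture)
  ml_both <- log_sum_exp(cbind(w[1] + ml_fix, w[2] + ml_ind))
  cbind("NULL" = ml_null, MO = ml_mo, MA = ml_ma, BOTH = ml_both)
}

#' Classify variants as subtype-specific, shared or null
#'
#' Joins the two subtype summary-statistic tables by variant id, computes the
#' four log marginal likelihoods ([subtype_log_marginals()]), converts them to
#' posterior model probabilities under `prior$model_prior` via Bayes'
#' formula (log-sum-exp normalized), assigns the label whose posterior
#' exceeds `threshold` (otherwise `"unresolved"`), and tests effect-size
#' equality between the subtypes with [difference_test()] at the
#' Bonferroni-corrected level `0.05 / n_tests`.
#'
#' @param mo,ma Summary-statistic tibbles (shared dialect) for the two
#'   subtypes, expressed on the same effect alleles.
#' @param prior A [subtype_prior()].
#' @param corr Estimator correlation; `"auto"` estimates it with
#'   [estimate_subtype_correlation()], a number overrides, default
#'   `prior$corr`.
#' @param threshold Posterior probability needed to assign a label.
#' @param n_tests Number of tests for the Bonferroni correction of the
#'   difference test; defaults to the number of variants classified.
#' @return A `subtype_classification` tibble: `SNP, B_MO, SE_MO, B_MA, SE_MA,
#'   LOG_ML_NULL/MO/MA/BOTH, PP_NULL/MO/MA/BOTH, LABEL, DIFF_Z, DIFF_P,
#'   DIFF_FLAG`, with the run settings in attribute `"settings"`.
#' @examples
#' pairs <- simulate_subtype_pairs(sim_config(n_variants = 200, n_blocks = 20,
#'                                            subtype_se = 0.02, seed = 3))
#' cls <- classify_subtypes(pairs$mo, pairs$ma)
#' table(cls$LABEL)
#' @export
classify_subtypes <- function(mo, ma, prior = subtype_prior(), corr = NULL,
                              threshold = 0.95, n_tests = NULL) {
  assert_cols(mo, c("SNP", "BETA", "SE"), "MO table")
  assert_cols(ma, c("SNP", "BETA", "SE"), "MA table")
  j <- dplyr::inner_join(select(as_tibble(mo), "SNP", B_MO = "BETA",
                                SE_MO = "SE"),
                         select(as_tibble(ma), "SNP", B_MA = "BETA",
                                SE_MA = "SE"),
                         by = "SNP")
  if (is.null(corr)) corr <- prior$corr
  if (identical(corr, "auto")) corr <- estimate_subtype_correlation(mo, ma)
  if (is.null(n_tests)) n_tests <- nrow(j)
  alpha <- 0.05 / n_tests

  lm_mat <- subtype_log_marginals(j$B_MO, j$SE_MO, j$B_MA, j$SE_MA,
                                  prior, corr)
  lpost <- sweep(lm_mat, 2, log(prior$model_prior), "+")
  lpost <- lpost - log_sum_exp(lpost)
  pp <- exp(lpost)

  best <- max.col(pp, ties.method = "first")
  label <- if_else(pp[cbind(seq_len(nrow(pp)), best)] > threshold,
                   colnames(pp)[best], "unresolved")

  dt <- difference_test(j$B_MO, j$SE_MO, j$B_MA, j$SE_MA, corr = corr,
                        alpha = alpha)
  out <- mutate(j,
                LOG_ML_NULL = lm_mat[, "NULL"], LOG_ML_MO = lm_mat[, "MO"],
                LOG_ML_MA = lm_mat[, "MA"], LOG_ML_BOTH = lm_mat[, "BOTH"],
                PP_NULL = pp[, "NULL"], PP_MO = pp[, "MO"],
                PP_MA = pp[, "MA"], PP_BOTH = pp[, "BOTH"],
                LABEL = label,
                DIFF_Z = dt$z, DIFF_P = dt$p, DIFF_FLAG = dt$flag)
  attr(out, "settings") <- list(tau = prior$tau, corr = corr,
                                model_prior = prior$model_prior,
                                both_mixture = prior$both_mixture,
                                threshold = threshold, n_tests = n_tests,
                                alpha = alpha)
  class(out) <- c("subtype_classification", class(out))
  out
}

#' @export
tidy.subtype_classification <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @export
glance.subtype_classification <- function(x, ...) {
  s <- attr(x, "settings")
  tibble(n_variants = nrow(x),
         n_null = sum(x$LABEL == "NULL"), n_mo = sum(x$LABEL == "MO"),
         n_ma = sum(x$LABEL == "MA"), n_both = sum(x$LABEL == "BOTH"),
         n_unresolved = sum(x$LABEL == "unresolved"),
         n_diff_flagged = sum(x$DIFF_FLAG),
         corr = s$corr, tau = s$tau, threshold = s$threshold)
}

#' Estimate the correlation of subtype effect estimators
#'
#' Empirical Pearson correlation of the paired effect estimates over common
#' variants (`MAF > maf_min` in both tables) without a strong association to
#' either subtype (`P > p_floor` in both). Over such variants the true
#' effects contribute (nearly) nothing, so the correlation of the estimates
#' estimates the correlation of their errors — the quantity the bivariate
#' likelihood approximation needs.
#'
#' @param mo,ma Subtype summary-statistic tibbles (shared dialect).
#' @param maf_min MAF threshold, default 0.05.
#' @param p_floor Association floor, default 1e-4.
#' @param min_variants Minimum number of qualifying variants, default 100.
#' @return The scalar correlation estimate.
#' @export
estimate_subtype_correlation <- function(mo, ma, maf_min = 0.05,
                                         p_floor = 1e-4, min_variants = 100) {
  assert_cols(mo, c("SNP", "EAF", "BETA", "P"), "MO table")
  assert_cols(ma, c("SNP", "EAF", "BETA", "P"), "MA table")
  j <- dplyr::inner_join(as_tibble(mo), as_tibble(ma), by = "SNP",
                         suffix = c("_mo", "_ma"))
  maf_mo <- pmin(j$EAF_mo, 1 - j$EAF_mo)
  maf_ma <- pmin(j$EAF_ma, 1 - j$EAF_ma)
  q <- maf_mo > maf_min & maf_ma > maf_min & j$P_mo > p_floor & j$P_ma > p_floor
  if (sum(q) < min_variants) {
    abort(sprintf("only %d qualifying variants (need >= %d)",
                  sum(q), min_variants),
          class = "migwas_data_error")
  }
  cor(j$BETA_mo[q], j$BETA_ma[q])
}

#' Test equality of subtype effect sizes
#'
#' Normal-approximation test of `b_MO = b_MA` accounting for the correlation
#' of the estimators:
#' `z = (b_MO - b_MA) / sqrt(se_MO^2 + se_MA^2 - 2 c se_MO se_MA)`, with a
#' two-sided p-value and a flag at the Bonferroni-corrected level `alpha`.
#'
#' @param b_mo,se_mo,b_ma,se_ma Estimates and standard errors (vectorized).
#' @param corr Estimator correlation `c`.
#' @param alpha Per-test significance level, default `0.05 / 123`.
#' @return Tibble with `z`, `p`, `flag`.
#' @export
difference_test <- function(b_mo, se_mo, b_ma, se_ma, corr = 0.148,
                            alpha = 0.05 / 123) {
  if (any(se_mo <= 0) || any(se_ma <= 0)) {
    abort("standard errors must be positive", class = "migwas_domain_error")
  }
  v <- se_mo^2 + se_ma^2 - 2 * corr * se_mo * se_ma
  if (any(v <= 0)) {
    abort("difference variance is non-positive (|corr| too close to 1)",
          class = "migwas_domain_error")
  }
  z <- (b_mo - b_ma) / sqrt(v)
  p <- pmin(2 * pnorm(-abs(z)), 1)
  tibble(z = z, p = p, flag = p < alpha)
}

#' Exact binomial test of effect-direction concordance
#'
#' Counts pairs whose effects share a sign and tests the agreement proportion
#' against 0.5 with an exact two-sided binomial test,
#' `p = min(1, 2 * min(P(X <= k), P(X >= k)))`. Pairs with a zero effect are
#' dropped.
#'
#' @param beta_a,beta_b Paired effect estimates.
#' @return Tibble with `n_pairs`, `n_agree`, `proportion`, `p`.
#' @examples
#' direction_concordance(c(1, 1, -1, 1), c(2, 3, -4, -1))
#' @export
direction_concordance <- function(beta_a, beta_b) {
  stopifnot(length(beta_a) == length(beta_b))
  ok <- beta_a != 0 & beta_b != 0 & !is.na(beta_a) & !is.na(beta_b)
  if (any(!ok)) {
    inform(sprintf("direction_concordance: dropped %d pair(s) with zero or missing effects",
                   sum(!ok)))
  }
  k <- sum(sign(beta_a[ok]) == sign(beta_b[ok]))
  n <- sum(ok)
  p <- if (n == 0) NA_real_ else
    min(1, 2 * min(pbinom(k, n, 0.5), pbinom(k - 1, n, 0.5, lower.tail = FALSE)))
  tibble(n_pairs = n, n_agree = k,
         proportion = if (n == 0) NA_real_ else k / n, p = p)
}
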