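#' Leave-one-out prediction-interval test for tissue eQTL enrichment
#'
#' For each tissue, regresses the observed count of lead variants that are
#' significant cis-eQTLs on the tissue's overall count of eQTL genes using
#' every *other* tissue, predicts the held-out tissue's count with a
#' `level` prediction interval (ordinary least squares, t-based interval with
#' `n - 2` residual degrees of freedom, as `stats::predict.lm` computes it),
#' and flags the tissue `"enriched"` when the observed count exceeds the
#' upper bound or `"depleted"` when it falls below the lower bound.
#'
#' @param counts Tibble with columns `TISSUE`, `OBSERVED` (lead variants that
#'   are significant cis-eQTLs in the tissue) and `PREDICTOR` (genes with at
#'   least one significant cis-eQTL in the tissue). At least 3 tissues.
#' @param level Prediction-interval coverage, default 0.95.
#' @return `counts` with `FIT`, `PI_LOW`, `PI_HIGH` and `FLAG`
#'   (`"enriched"`, `"depleted"` or `NA`) added; row order preserved.
#' @examples
#' counts <- tibble::tibble(TISSUE = letters[1:6],
#'                          PREDICTOR = c(10, 20, 30, 40, 50, 60),
#'                          OBSERVED = c(2, 4, 6, 8, 10, 30))
#' eqtl_enrichment_loo(counts)
#' @export
eqtl_enrichment_loo <- function(counts, level = 0.95) {
  assert_cols(counts, c("TISSUE", "OBSERVED", "PREDICTOR"), "tissue counts")
  counts <- as_tibble(counts)
  n <- nrow(counts)
  if (n < 3) {
    abort("need at least 3 tissues for a leave-one-out fit",
          class = "migwas_domain_error")
  }
  if (any(counts$OBSERVED < 0) || any(counts$PREDICTOR < 0)) {
    abort("counts must be non-negative", class = "migwas_domain_error")
  }
  fit_one <- function(i) {
    train <- counts[-i, ]
    if (length(unique(train$PREDICTOR)) < 2) {
      abort(sprintf("predictor is constant when leaving out tissue '%s'",
                    counts$TISSUE[i]),
            class = "migwas_domain_error")
    }
    fit <- lm(OBSERVED ~ PREDICTOR, data = train)
    pr <- predict(fit, newdata = counts[i, ], interval = "prediction",
                  level = level)
    tibble(FIT = pr[1, "fit"], PI_LOW = pr[1, "lwr"], PI_HIGH = pr[1, "upr"])
  }
  pi <- list_rbind(map(seq_len(n), fit_one))
  mutate(bind_cols(counts, pi),
         FLAG = case_when(.data$OBSERVED > .data$PI_HIGH ~ "enriched",
                          .data$OBSERVED < .data$PI_LOW ~ "depleted",
                          TRUE ~ NA_character_))
}

#' Observed-scale heritability to the liability scale
#'
#' Converts an observed-scale SNP-heritability estimate from a case/control
#' analysis to the liability scale:
#' `h2_l = h2_o * K^2 (1 - K)^2 / (P (1 - P) z^2)` with population prevalence
#' `K`, sample case proportion `P` and `z` the standard normal density at the
#' liability threshold `qnorm(1 - K)`.
#'
#' @param h2_obs Observed-scale heritability (non-negative).
#' @param prevalence Population prevalence `K` in `(0, 1)`.
#' @param case_prop Sample case proportion `P` in `(0, 1)`.
#' @return Tibble with `h2_obs`, `factor` (the conversion factor) and
#'   `h2_liability`.
#' @examples
#' liability_h2(0.05, prevalence = 0.16, case_prop = 0.117)
#' @export
liability_h2 <- function(h2_obs, prevalence = 0.16, case_prop = 0.117) {
  if (any(h2_obs < 0)) {
    abort("h2_obs must be non-negative", class = "migwas_domain_error")
  }
  if (prevalence <= 0 || prevalence >= 1 || case_prop <= 0 || case_prop >= 1) {
    abort("prevalence and case_prop must lie strictly in (0, 1)",
          class = "migwas_domain_error")
  }
  K <- prevalence; P <- case_prop
  z <- dnorm(qnorm(1 - K))
  factor <- K^2 * (1 - K)^2 / (P * (1 - P) * z^2)
  tibble(h2_obs = h2_obs, factor = factor, h2_liability = h2_obs * factor)
}

#' Case proportion from case/control counts
#'
#' @param n_cases,n_controls Counts.
#' @param percent Return a percentage (default) or a proportion.
#' @return Scalar case proportion.
#' @examples
#' case_proportion(102084, 771257)  # 11.69 %
#' @export
case_proportion <- function(n_cases, n_controls, percent = TRUE) {
  stopifnot(n_cases > 0, n_controls > 0)
  p <- n_cases / (n_cases + n_controls)
  if (percent) 100 * p else p
}

#' Bonferroni per-test significance level
#'
#' @param n_tests Number of tests (e.g. lead variants).
#' @param fwer Family-wise error rate, default 0.05.
#' @return Scalar per-test level `fwer / n_tests`.
#' @examples
#' bonferroni_alpha(123)
#' @export
bonferroni_alpha <- function(n_tests, fwer = 0.05) {
  stopifnot(n_tests >= 1)
  fwer / n_tests
}
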