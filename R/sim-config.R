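#' Simulation settings for the synthetic GWAS generator
#'
#' Bundles every tunable of the synthetic multi-cohort generator into one
#' validated object. Defaults emulate a five-collection meta-analysis of a
#' common binary trait (case/control counts of the five collections of a
#' large multi-cohort disease meta-analysis) and a pair of subtype analyses whose effect
#' estimators are correlated through shared controls.
#'
#' @param n_variants Number of variants on the panel.
#' @param n_blocks Number of LD blocks; blocks partition the variants into
#'   near-equal contiguous runs and are mutually independent.
#' @param block_decay AR(1) decay `rho` in `[0, 1)`: adjacent variants within a
#'   block have signed correlation `rho`, variants `k` apart `rho^k`.
#' @param n_cases,n_controls Integer vectors of per-cohort case and control
#'   counts (same length, all positive).
#' @param causal_fraction Probability that a variant carries a nonzero
#'   ("spike") effect.
#' @param effect_sd Standard deviation of true causal effects, log-odds units.
#' @param maf_range Range the minor-allele frequency is drawn from, in
#'   `(0, 0.5]`.
#' @param info_range Range of per-variant, per-cohort imputation info,
#'   in `(0, 1]`.
#' @param missing_rate Per-cohort probability that a variant was not measured
#'   in that cohort (drives the spread of per-variant effective sample sizes).
#' @param indel_fraction Fraction of variants emitted as indels.
#' @param flip_rate Fraction of strand-ambiguous (A/T, G/C) SNPs whose allele
#'   labels are swapped in a non-reference cohort, exercising the
#'   strand-ambiguity audit.
#' @param subtype_model_probs Probabilities of the four generating models
#'   `NULL`, `MO`, `MA`, `BOTH` for subtype pairs; must sum to 1.
#' @param subtype_corr Correlation `c` of the two subtype effect estimators
#'   (induced by shared controls); default 0.148.
#' @param tau Prior standard deviation of nonzero subtype effects on the
#'   log-odds scale; default 0.2.
#' @param subtype_effect_size Optional fixed magnitude for nonzero subtype
#'   effects (sign random). When `NULL`, effects are drawn from `N(0, tau^2)`.
#' @param subtype_n Named list with `mo_cases`, `mo_controls`, `ma_cases`,
#'   `ma_controls`; defaults are the totals of the subtype meta-analyses.
#' @param subtype_se Optional fixed standard error(s) for the subtype
#'   estimates (length 1 or 2, order MO then MA); when `NULL`, standard errors
#'   follow the effective-sample-size relation from `subtype_n` and the MAF.
#' @param seed Integer seed; fully determines all generator output.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_variants = 100, n_blocks = 10, seed = 1)
#' cfg$block_decay
#' @export
sim_config <- function(n_variants = 10000,
                       n_blocks = 500,
                       block_decay = 0.8,
                       n_cases = c(29209, 53109, 10881, 1084, 7801),
                       n_controls = c(172931, 230876, 330170, 4857, 32423),
                       causal_fraction = 0.01,
                       effect_sd = 0.05,
                       maf_range = c(0.01, 0.5),
                       info_range = c(0.7, 1),
                       missing_rate = 0.05,
                       indel_fraction = 0.01,
                       flip_rate = 0.01,
                       subtype_model_probs = c(0.25, 0.25, 0.25, 0.25),
                       subtype_corr = 0.148,
                       tau = 0.2,
                       subtype_effect_size = NULL,
                       subtype_n = list(mo_cases = 15055, mo_controls = 682301,
                                        ma_cases = 14624, ma_controls = 703852),
                       subtype_se = NULL,
                       seed = 1L) {
  if (n_variants < 1) abort("n_variants must be >= 1", class = "migwas_config_error")
  if (n_blocks < 1 || n_blocks > n_variants) {
    abort("n_blocks must be in [1, n_variants]", class = "migwas_config_error")
  }
  if (block_decay < 0 || block_decay >= 1) {
    abort("block_decay must be in [0, 1)", class = "migwas_config_error")
  }
  if (length(n_cases) != length(n_controls)) {
    abort("n_cases and n_controls must have the same length",
          class = "migwas_config_error")
  }
  if (any(n_cases <= 0) || any(n_controls <= 0)) {
    abort("every cohort needs positive case and control counts",
          class = "migwas_config_error")
  }
  if (causal_fraction < 0 || causal_fraction > 1) {
    abort("causal_fraction must be a probability", class = "migwas_config_error")
  }
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    abort("maf_range must lie within (0, 0.5]", class = "migwas_config_error")
  }
  if (length(info_range) != 2 || info_range[1] <= 0 || info_range[2] > 1 ||
      info_range[1] > info_range[2]) {
    abort("info_range must lie within (0, 1]", class = "migwas_config_error")
  }
  if (length(subtype_model_probs) != 4 ||
      abs(sum(subtype_model_probs) - 1) > 1e-8 || any(subtype_model_probs < 0)) {
    abort("subtype_model_probs must be 4 non-negative values summing to 1",
          class = "migwas_config_error")
  }
  if (abs(subtype_corr) >= 1) {
    abort("subtype_corr must lie in (-1, 1)", class = "migwas_config_error")
  }
  if (tau <= 0) abort("tau must be positive", class = "migwas_config_error")
  for (fld in c("mo_cases", "mo_controls", "ma_cases", "ma_controls")) {
    if (is.null(subtype_n[[fld]]) || subtype_n[[fld]] <= 0) {
      abort(sprintf("subtype_n$%s must be positive", fld),
            class = "migwas_config_error")
    }
  }
  if (!is.null(subtype_se) && (any(subtype_se <= 0) ||
                               !length(subtype_se) %in% 1:2)) {
    abort("subtype_se must be 1 or 2 positive values",
          class = "migwas_config_error")
  }
  structure(
    list(n_variants = as.integer(n_variants),
         n_blocks = as.integer(n_blocks),
         block_decay = block_decay,
         n_cases = as.integer(n_cases),
         n_controls = as.integer(n_controls),
         causal_fraction = causal_fraction,
         effect_sd = effect_sd,
         maf_range = maf_range,
         info_range = info_range,
         missing_rate = missing_rate,
         indel_fraction = indel_fraction,
         flip_rate = flip_rate,
         subtype_model_probs = setNames(subtype_model_probs,
                                        c("NULL", "MO", "MA", "BOTH")),
         subtype_corr = subtype_corr,
         tau = tau,
         subtype_effect_size = subtype_effect_size,
         subtype_n = subtype_n,
         subtype_se = subtype_se,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d variants in %d AR(1) blocks (rho = %.2f)\n",
              x$n_variants, x$n_blocks, x$block_decay))
  cat(sprintf("  %d cohorts, %s cases / %s controls total\n",
              length(x$n_cases), format(sum(x$n_cases), big.mark = ","),
              format(sum(x$n_controls), big.mark = ",")))
  cat(sprintf("  causal fraction %.3g, effect sd %.3g; subtype corr %.3f, tau %.2f; seed %d\n",
              x$causal_fraction, x$effect_sd, x$subtype_corr, x$tau, x$seed))
  invisible(x)
}
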