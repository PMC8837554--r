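#' Inverse-variance weighted fixed-effect meta-analysis
#'
#' Pools per-cohort log-odds estimates with weights `w_i = 1/se_i^2`:
#' pooled effect `sum(w b) / sum(w)`, pooled standard error
#' `1 / sqrt(sum(w))`, `z = beta/se` and a two-sided normal p-value. The
#' pooled effect-allele frequency is the weight-averaged `EAF`, and the
#' per-variant effective sample size is `1 / (f (1 - f) se^2)` evaluated at
#' the pooled frequency and standard error. Variants present in a single
#' cohort are kept (precision control is the effective-sample-size filter,
#' [filter_by_neff()]). The direction string has one `+`/`-` per cohort in
#' input order, with `?` where the variant is absent and `0` for an exactly
#' zero estimate. Two-sided p-values are computed in log space, so
#' `MLOG10P` stays informative where `P` underflows to 0 (|z| above ~38).
#'
#' @param cohorts Named list of harmonized summary-statistics tibbles
#'   (columns `SNP, CHR, BP, EA, OA, EAF, BETA, SE`), all expressed on the
#'   same reference alleles (see [harmonize_to_reference()]).
#' @return A tibble with one row per variant: `SNP, CHR, BP, EA, OA, EAF,
#'   BETA_META, SE_META, Z, P, MLOG10P, N_EFF, DIRECTION, N_COHORTS`.
#' @examples
#' c1 <- tibble::tibble(SNP = "rs1", CHR = 1, BP = 1, EA = "A", OA = "G",
#'                      EAF = 0.3, BETA = 0.1, SE = 0.1)
#' c2 <- dplyr::mutate(c1, BETA = 0.3)
#' ivw_meta(list(a = c1, b = c2))[, c("BETA_META", "SE_META")]
#' @export
ivw_meta <- function(cohorts) {
  if (is.data.frame(cohorts)) cohorts <- list(cohort_01 = cohorts)
  if (is.null(names(cohorts)) || any(names(cohorts) == "")) {
    names(cohorts) <- sprintf("cohort_%02d", seq_along(cohorts))
  }
  need <- c("SNP", "CHR", "BP", "EA", "OA", "EAF", "BETA", "SE")
  for (nm in names(cohorts)) {
    assert_cols(cohorts[[nm]], need, sprintf("cohort '%s'", nm))
    bad <- which(!(cohorts[[nm]]$SE > 0))
    if (length(bad) > 0) {
      abort(sprintf("non-positive SE in cohort '%s' at variant %s",
                    nm, cohorts[[nm]]$SNP[bad[1]]),
            class = "migwas_data_error")
    }
    if (anyDuplicated(cohorts[[nm]]$SNP) > 0) {
      abort(sprintf("duplicate SNP id in cohort '%s'", nm),
            class = "migwas_data_error")
    }
  }

  long <- bind_rows(lapply(cohorts, function(x) select(x, all_of(need))),
                    .id = "COHORT")
  long$COHORT <- factor(long$COHORT, levels = names(cohorts))
  long$W <- 1 / long$SE^2

  pooled <- long %>%
    group_by(.data$SNP) %>%
    summarise(CHR = first(.data$CHR), BP = first(.data$BP),
              EA = first(.data$EA), OA = first(.data$OA),
              EAF = sum(.data$W * .data$EAF) / sum(.data$W),
              BETA_META = sum(.data$W * .data$BETA) / sum(.data$W),
              SE_META = 1 / sqrt(sum(.data$W)),
              N_COHORTS = dplyr::n(),
              .groups = "drop")

  dir_tab <- long %>%
    mutate(SIGN = case_when(.data$BETA > 0 ~ "+", .data$BETA < 0 ~ "-",
                            TRUE ~ "0")) %>%
    select("SNP", "COHORT", "SIGN") %>%
    tidyr::pivot_wider(names_from = "COHORT", values_from = "SIGN",
                       values_fill = "?", names_expand = TRUE)
  direction <- apply(as.matrix(dir_tab[, -1, drop = FALSE]), 1, paste,
                     collapse = "")

  pooled %>%
    left_join(tibble(SNP = dir_tab$SNP, DIRECTION = direction), by = "SNP") %>%
    mutate(Z = .data$BETA_META / .data$SE_META,
           logp = pnorm(-abs(.data$Z), log.p = TRUE) + log(2),
           P = pmin(exp(.data$logp), 1),
           MLOG10P = -.data$logp / log(10),
           N_EFF = effective_sample_size(.data$EAF, .data$SE_META)) %>%
    select("SNP", "CHR", "BP", "EA", "OA", "EAF", "BETA_META", "SE_META",
           "Z", "P", "MLOG10P", "N_EFF", "DIRECTION", "N_COHORTS") %>%
    arrange(.data$CHR, .data$BP)
}

#' Effective sample size from frequency and standard error
#'
#' `N_eff = 1 / (f (1 - f) se^2)`, which for a log-odds estimate from a study
#' of `N` samples with case proportion `t` and imputation info `I`
#' approximates `2 N t (1 - t) I`. Symmetric in `f` and `1 - f`.
#'
#' @param eaf Effect-allele frequency in `(0, 1)` (vectorized).
#' @param se Standard error of the log-odds estimate, positive (vectorized).
#' @return Numeric vector of effective sample sizes.
#' @examples
#' effective_sample_size(0.5, 0.02)  # 10000
#' @export
effective_sample_size <- function(eaf, se) {
  if (any(eaf <= 0 | eaf >= 1, na.rm = TRUE)) {
    abort("eaf must lie strictly in (0, 1)", class = "migwas_domain_error")
  }
  if (any(se <= 0, na.rm = TRUE)) {
    abort("se must be positive", class = "migwas_domain_error")
  }
  1 / (eaf * (1 - eaf) * se^2)
}

#' Drop variants with low effective sample size
#'
#' Retains variants with `N_EFF >= min_neff` (default 5,000), removing
#' estimates whose precision is far below the rest of the meta-analysis.
#'
#' @param meta Tibble with an `N_EFF` column (e.g. from [ivw_meta()]).
#' @param min_neff Minimum effective sample size.
#' @return The filtered tibble; the number excluded is reported via a message
#'   and stored in attribute `"n_excluded_neff"`.
#' @export
filter_by_neff <- function(meta, min_neff = 5000) {
  assert_cols(meta, "N_EFF", "meta table")
  keep <- meta$N_EFF >= min_neff
  out <- meta[keep, ]
  attr(out, "n_excluded_neff") <- sum(!keep)
  if (any(!keep)) {
    inform(sprintf("filter_by_neff: excluded %d variant(s) with N_eff < %g",
                   sum(!keep), min_neff))
  }
  out
}

#' Genomic inflation factor
#'
#' `lambda_GC = median(chi^2) / qchisq(0.5, df = 1)`, with the association
#' chi-squares taken from z-statistics (`z^2`) or from two-sided p-values
#' (`qchisq(p, 1, lower.tail = FALSE)`).
#'
#' @param p Two-sided p-values, or `NULL` if `z` is given.
#' @param z z-statistics, or `NULL` if `p` is given.
#' @return The scalar inflation factor.
#' @examples
#' genomic_inflation(z = rnorm(1e4))
#' @export
genomic_inflation <- function(p = NULL, z = NULL) {
  if (is.null(p) == is.null(z)) {
    abort("supply exactly one of p or z", class = "migwas_domain_error")
  }
  chisq <- if (!is.null(z)) z^2 else qchisq(p, df = 1, lower.tail = FALSE)
  chisq <- chisq[is.finite(chisq)]
  if (length(chisq) == 0) {
    abort("no finite statistics supplied", class = "migwas_domain_error")
  }
  median(chisq) / qchisq(0.5, df = 1)
}
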