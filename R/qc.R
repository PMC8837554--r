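#' Variant-level quality-control thresholds
#'
#' Defaults follow standard meta-analysis practice for imputed case/control
#' GWAS: minor-allele frequency above 0.01, imputation info above 0.6,
#' Hardy-Weinberg equilibrium p above 1e-6 and missingness below 0.05 (the
#' latter two applied only when the corresponding columns are present), and
#' exclusion of variants whose effect-allele frequency disagrees with the
#' reference by more than 0.30 (SNPs) or 0.20 (indels).
#'
#' @param maf_min Minimum minor-allele frequency (exclusive bound).
#' @param info_min Minimum imputation info (exclusive bound).
#' @param hwe_p_min Minimum HWE p-value (exclusive bound).
#' @param missingness_max Maximum missingness (exclusive bound).
#' @param eaf_discrepancy_snp,eaf_discrepancy_indel Maximum allowed absolute
#'   difference between cohort and reference effect-allele frequency.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(maf_min = 0.01, info_min = 0.6, hwe_p_min = 1e-6,
                          missingness_max = 0.05, eaf_discrepancy_snp = 0.30,
                          eaf_discrepancy_indel = 0.20) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, info_min >= 0, info_min <= 1,
            hwe_p_min >= 0, hwe_p_min <= 1,
            missingness_max >= 0, missingness_max <= 1,
            eaf_discrepancy_snp >= 0, eaf_discrepancy_snp <= 1,
            eaf_discrepancy_indel >= 0, eaf_discrepancy_indel <= 1)
  structure(list(maf_min = maf_min, info_min = info_min,
                 hwe_p_min = hwe_p_min, missingness_max = missingness_max,
                 eaf_discrepancy_snp = eaf_discrepancy_snp,
                 eaf_discrepancy_indel = eaf_discrepancy_indel),
            class = "qc_thresholds")
}

recode_indels <- function(tab) {
  ea <- toupper(tab$EA); oa <- toupper(tab$OA)
  len_ea <- nchar(ea); len_oa <- nchar(oa)
  indel <- (len_ea > 1 | len_oa > 1) & len_ea != len_oa
  bad <- len_ea > 1 & len_oa > 1 & len_ea == len_oa  # unorientable MNVs
  ea[indel] <- if_else(len_ea[indel] > len_oa[indel], "I", "D")
  oa[indel] <- if_else(ea[indel] == "I", "D", "I")
  tab$EA <- ea; tab$OA <- oa
  tab$.unorientable <- bad
  tab
}

#' Harmonize a cohort table to a reference panel
#'
#' Matches variants to the reference by chromosome, position and alleles.
#' Alleles are uppercased, indels are recoded as insertion (`I`) / deletion
#' (`D`) before matching, multiallelic positions (a position carrying more
#' than one allele pair on either side) are dropped, and where a variant's
#' effect/other alleles are swapped relative to the reference its effect is
#' negated and its frequency replaced by `1 - EAF` so that every retained row
#' is expressed on the reference's effect allele. A `REF_EAF` column with the
#' reference frequency is appended (used downstream by the EAF-discrepancy
#' filter). Harmonizing an already-harmonized table is a no-op.
#'
#' @param cohort Summary-statistics tibble with at least
#'   `SNP, CHR, BP, EA, OA, EAF, BETA`.
#' @param reference Reference tibble with `CHR, BP, EA, OA, EAF`.
#' @return The harmonized tibble (reference allele orientation, plus
#'   `REF_EAF`), with a `harmonization` attribute counting drops by reason
#'   (`multiallelic`, `unmatched`, `retained`).
#' @examples
#' ref <- tibble::tibble(SNP = "rs1", CHR = 1, BP = 100,
#'                       EA = "G", OA = "A", EAF = 0.7)
#' coh <- tibble::tibble(SNP = "rs1", CHR = 1, BP = 100, EA = "A", OA = "G",
#'                       EAF = 0.3, BETA = 0.1, SE = 0.02)
#' harmonize_to_reference(coh, ref)$BETA  # -0.1
#' @export
harmonize_to_reference <- function(cohort, reference) {
  assert_cols(cohort, c("SNP", "CHR", "BP", "EA", "OA", "EAF", "BETA"),
              "cohort table")
  assert_cols(reference, c("CHR", "BP", "EA", "OA", "EAF"), "reference table")

  cohort <- recode_indels(as_tibble(cohort))
  reference <- recode_indels(as_tibble(reference))
  n_input <- nrow(cohort)

  key <- paste(cohort$CHR, cohort$BP, cohort$EA, cohort$OA, sep = ":")
  if (anyDuplicated(key) > 0) {
    abort(sprintf("duplicate variant key within cohort: %s",
                  key[duplicated(key)][1]),
          class = "migwas_data_error")
  }

  pos_c <- paste(cohort$CHR, cohort$BP, sep = ":")
  pos_r <- paste(reference$CHR, reference$BP, sep = ":")
  multi_c <- pos_c %in% pos_c[duplicated(pos_c)]
  multi_r_pos <- unique(pos_r[duplicated(pos_r)])
  multi <- multi_c | pos_c %in% multi_r_pos | cohort$.unorientable
  n_multi <- sum(multi)
  cohort <- cohort[!multi, ]
  pos_c <- pos_c[!multi]
  reference <- reference[!(pos_r %in% multi_r_pos), ]
  pos_r <- paste(reference$CHR, reference$BP, sep = ":")

  ridx <- match(pos_c, pos_r)
  r_ea <- reference$EA[ridx]; r_oa <- reference$OA[ridx]
  same <- !is.na(ridx) & cohort$EA == r_ea & cohort$OA == r_oa
  swap <- !is.na(ridx) & cohort$EA == r_oa & cohort$OA == r_ea
  n_unmatched <- sum(!(same | swap))

  out <- cohort[same | swap, ]
  sw <- swap[same | swap]
  out$BETA[sw] <- -out$BETA[sw]
  out$EAF[sw] <- 1 - out$EAF[sw]
  tmp <- out$EA[sw]; out$EA[sw] <- out$OA[sw]; out$OA[sw] <- tmp
  out$REF_EAF <- reference$EAF[ridx[same | swap]]
  out$.unorientable <- NULL
  attr(out, "harmonization") <- c(multiallelic = n_multi,
                                  unmatched = n_unmatched,
                                  retained = nrow(out))
  stopifnot(n_multi + n_unmatched + nrow(out) == n_input)
  out
}

#' Apply variant-level QC filters
#'
#' Filters a harmonized table by minor-allele frequency, imputation info,
#' Hardy-Weinberg p (column `HWE_P`, when present), missingness (column
#' `MISSINGNESS`, when present) and effect-allele-frequency discrepancy
#' against the reference (column `REF_EAF`, when present; indels recognized by
#' `I`/`D` alleles use the looser indel bound). Each excluded variant is
#' attributed to the first rule it fails, in the order MAF, info, HWE,
#' missingness, EAF discrepancy, so that exclusion counts plus the retained
#' count always add up to the input count.
#'
#' @param tab Harmonized summary-statistics tibble.
#' @param thresholds A [qc_thresholds()].
#' @return The filtered tibble; the per-rule exclusion report is attached as
#'   attribute `"qc_report"` and retrievable with [qc_report()].
#' @export
apply_qc_filters <- function(tab, thresholds = qc_thresholds()) {
  assert_cols(tab, c("SNP", "EAF", "BETA"), "harmonized table")
  th <- thresholds
  if (any(tab$EAF < 0 | tab$EAF > 1, na.rm = TRUE)) {
    abort("EAF outside [0, 1]", class = "migwas_data_error")
  }
  n <- nrow(tab)
  fail <- rep(NA_character_, n)
  maf <- pmin(tab$EAF, 1 - tab$EAF)
  mark <- function(fail, cond, rule) if_else(is.na(fail) & cond, rule, fail)

  fail <- mark(fail, !(maf > th$maf_min), "maf")
  if ("INFO" %in% names(tab)) {
    fail <- mark(fail, !(tab$INFO > th$info_min), "info")
  }
  if ("HWE_P" %in% names(tab)) {
    fail <- mark(fail, !is.na(tab$HWE_P) & !(tab$HWE_P > th$hwe_p_min), "hwe")
  }
  if ("MISSINGNESS" %in% names(tab)) {
    fail <- mark(fail, !is.na(tab$MISSINGNESS) &
                   !(tab$MISSINGNESS < th$missingness_max), "missingness")
  }
  if ("REF_EAF" %in% names(tab)) {
    is_indel <- tab$EA %in% c("I", "D")
    lim <- if_else(is_indel, th$eaf_discrepancy_indel, th$eaf_discrepancy_snp)
    fail <- mark(fail, abs(tab$EAF - tab$REF_EAF) > lim, "eaf_discrepancy")
  }

  rules <- c("maf", "info", "hwe", "missingness", "eaf_discrepancy")
  report <- tibble(rule = rules,
                   n_excluded = unname(vapply(rules, function(r)
                     sum(fail == r, na.rm = TRUE), integer(1))))
  out <- tab[is.na(fail), ]
  attr(out, "qc_report") <- list(exclusions = report,
                                 n_input = n, n_retained = nrow(out))
  out
}

#' Retrieve the QC report attached by [apply_qc_filters()]
#' @param tab A table returned by [apply_qc_filters()].
#' @return A list with the per-rule exclusion tibble and the input/retained
#'   counts.
#' @export
qc_report <- function(tab) attr(tab, "qc_report")

#' Minor-allele concordance audit for strand-ambiguous SNPs
#'
#' For A/T and G/C SNPs shared by two harmonized tables, counts how often the
#' same allele is the minor allele in both, overall and stratified by MAF
#' (taken from the first table) around each supplied threshold. Consistently
#' high concordance at low MAF indicates that ambiguous SNPs are labeled on
#' the same strand across studies; this is a diagnostic report, not a filter.
#'
#' @param a,b Harmonized summary-statistics tibbles sharing `SNP` ids.
#' @param maf_thresholds Numeric thresholds in `(0, 0.5)`.
#' @return A tibble with `stratum`, `n` (ambiguous SNPs in the stratum) and
#'   `concordance` (proportion agreeing; `NA` when the stratum is empty).
#' @export
audit_strand_ambiguous <- function(a, b, maf_thresholds = c(0.25, 0.4)) {
  assert_cols(a, c("SNP", "EA", "OA", "EAF"), "table a")
  assert_cols(b, c("SNP", "EA", "OA", "EAF"), "table b")
  if (any(maf_thresholds <= 0 | maf_thresholds >= 0.5)) {
    abort("maf_thresholds must lie in (0, 0.5)", class = "migwas_config_error")
  }
  j <- dplyr::inner_join(
    select(as_tibble(a), "SNP", "EA", "OA", "EAF"),
    select(as_tibble(b), "SNP", "EA", "OA", "EAF"),
    by = "SNP", suffix = c("_a", "_b"))
  amb <- function(ea, oa) (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
  j <- filter(j, amb(toupper(.data$EA_a), toupper(.data$OA_a)))
  minor <- function(ea, oa, eaf) if_else(eaf <= 0.5, ea, oa)
  agree <- minor(j$EA_a, j$OA_a, j$EAF_a) == minor(j$EA_b, j$OA_b, j$EAF_b)
  maf <- pmin(j$EAF_a, 1 - j$EAF_a)

  strata <- list(all = rep(TRUE, nrow(j)))
  for (t in maf_thresholds) {
    strata[[sprintf("MAF<%g", t)]] <- maf < t
    strata[[sprintf("MAF>%g", t)]] <- maf > t
  }
  tibble(
    stratum = names(strata),
    n = unname(vapply(strata, sum, integer(1))),
    concordance = unname(vapply(strata, function(s)
      if (sum(s) == 0) NA_real_ else mean(agree[s]), numeric(1)))
  )
}
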