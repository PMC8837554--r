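#' Simulate multi-cohort GWAS summary statistics
#'
#' Draws a truth table (true effect-allele frequencies and log-odds effects,
#' with a `causal_fraction` spike of `N(0, effect_sd^2)` effects) and then, for
#' each cohort, per-variant association estimates consistent with the standard
#' summary-statistic model: the standard error of a log-odds estimate at a
#' variant with effect-allele frequency `f` in a cohort of `N` samples with
#' case proportion `t` and imputation info `I` satisfies
#' `1 / (f (1 - f) se^2) = 2 N t (1 - t) I`, and the vector of z-statistics in
#' an LD block is Gaussian with mean `R b / se` and covariance `R`, where `R`
#' is the block's signed LD. Per-cohort variant missingness and info draws
#' make effective sample sizes vary across variants, and a small fraction of
#' strand-ambiguous (A/T, G/C) SNPs is emitted with swapped allele labels in
#' non-reference cohorts to exercise the quality-control audit.
#'
#' @param config A [sim_config()]; `config$seed` fully determines the output.
#' @param panel An `ld_panel` from [simulate_ld_panel()] built from the same
#'   config.
#' @return A list with
#'   * `truth`: tibble `SNP, CHR, BP, EA, OA, EAF, BETA_TRUE, CAUSAL, IS_INDEL`;
#'   * `reference`: a reference table (`SNP, CHR, BP, EA, OA, EAF`) playing the
#'     role of the harmonization panel;
#'   * `cohorts`: named list of per-cohort summary-statistic tibbles in the
#'     shared dialect (`SNP ... N_CASES, N_CONTROLS`).
#' @examples
#' cfg <- sim_config(n_variants = 50, n_blocks = 5, seed = 7)
#' sim <- simulate_cohorts(cfg, simulate_ld_panel(cfg))
#' names(sim$cohorts)
#' @export
simulate_cohorts <- function(config, panel) {
  stopifnot(inherits(config, "sim_config"))
  panel <- as_ld_panel(panel)
  if (nrow(panel$variants) != config$n_variants) {
    abort("panel and config disagree on the number of variants",
          class = "migwas_config_error")
  }
  withr::with_seed(config$seed, simulate_cohorts_impl(config, panel))
}

simulate_cohorts_impl <- function(config, panel) {
  v <- panel$variants
  n <- nrow(v)

  # truth: alleles, frequencies, effects
  is_indel <- runif(n) < config$indel_fraction
  ea <- character(n); oa <- character(n)
  pairs <- t(vapply(seq_len(n), function(i) sample(c("A", "C", "G", "T"), 2),
                    character(2)))
  ea <- pairs[, 1]; oa <- pairs[, 2]
  ins <- vapply(seq_len(n), function(i)
    paste0(pairs[i, 1], paste(sample(c("A", "C", "G", "T"),
                                     sample(1:3, 1), replace = TRUE),
                              collapse = "")), character(1))
  ea[is_indel] <- ins[is_indel]   # indel: long vs single-base allele
  maf <- runif(n, config$maf_range[1], config$maf_range[2])
  f <- if_else(runif(n) < 0.5, maf, 1 - maf)
  causal <- runif(n) < config$causal_fraction
  beta <- if_else(causal, rnorm(n, 0, config$effect_sd), 0)

  truth <- tibble(SNP = v$SNP, CHR = v$CHR, BP = v$BP, EA = ea, OA = oa,
                  EAF = f, BETA_TRUE = beta, CAUSAL = causal,
                  IS_INDEL = is_indel)
  reference <- truth[, c("SNP", "CHR", "BP", "EA", "OA", "EAF")]

  ambiguous <- (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")

  # per-block Cholesky factors, shared across cohorts
  chols <- lapply(panel$blocks, chol)
  block_idx <- split(seq_len(n), v$BLOCK)

  cohorts <- vector("list", length(config$n_cases))
  for (k in seq_along(config$n_cases)) {
    nca <- config$n_cases[k]; nco <- config$n_controls[k]
    N <- nca + nco; t_k <- nca / N
    info <- runif(n, config$info_range[1], config$info_range[2])
    se <- 1 / sqrt(2 * N * t_k * (1 - t_k) * info * f * (1 - f))

    z <- numeric(n)
    for (b in seq_along(block_idx)) {
      idx <- block_idx[[b]]
      R <- panel$blocks[[b]]
      mu <- drop(R %*% (beta[idx] / se[idx]))
      z[idx] <- mu + drop(crossprod(chols[[b]], rnorm(length(idx))))
    }
    bhat <- z * se
    eaf_hat <- pmin(pmax(f + rnorm(n, 0, sqrt(f * (1 - f) / (2 * N))),
                         1e-4), 1 - 1e-4)
    p <- 2 * pnorm(-abs(z))

    tab <- tibble(SNP = v$SNP, CHR = v$CHR, BP = v$BP, EA = ea, OA = oa,
                  EAF = eaf_hat, BETA = bhat, SE = se, P = p, INFO = info,
                  N_CASES = nca, N_CONTROLS = nco)

    # mislabel strand-ambiguous SNPs in non-reference cohorts: the physical
    # allele is read off the other strand, so the EA/OA labels swap while the
    # reported frequency and effect stay attached to the mislabeled allele
    if (k > 1 && config$flip_rate > 0) {
      flip <- ambiguous & runif(n) < config$flip_rate
      tmp <- tab$EA[flip]; tab$EA[flip] <- tab$OA[flip]; tab$OA[flip] <- tmp
    }

    present <- runif(n) >= config$missing_rate
    cohorts[[k]] <- tab[present, ]
  }
  names(cohorts) <- sprintf("cohort_%02d", seq_along(cohorts))
  list(truth = truth, reference = reference, cohorts = cohorts)
}

#' Write cohort tables, truth and reference to a directory
#'
#' Tab-delimited files in the shared dialect (`cohort_01.tsv`, ...,
#' `truth.tsv`, `reference.tsv`), plus the LD panel when given.
#'
#' @param sim Output of [simulate_cohorts()].
#' @param dir Output directory (created if absent).
#' @param panel Optional `ld_panel` to write alongside.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, panel = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  readr::write_tsv(sim$reference, file.path(dir, "reference.tsv"))
  for (nm in names(sim$cohorts)) {
    readr::write_tsv(sim$cohorts[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }
  if (!is.null(panel)) {
    write_ld_panel(panel, file.path(dir, "ld_matrix.txt"),
                   file.path(dir, "ld_variants.tsv"))
  }
  invisible(dir)
}
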