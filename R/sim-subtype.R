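#' Simulate paired subtype summary statistics
#'
#' Generates, per variant, a latent model label drawn from
#' `subtype_model_probs` over `NULL` / `MO` / `MA` / `BOTH`, true subtype
#' effects under that label, and a pair of estimates whose errors are
#' bivariate Gaussian with correlation `subtype_corr` (the correlation induced
#' by shared controls between the two subtype analyses). Under `NULL` both
#' effects are 0; under `MO` (`MA`) only the first (second) is nonzero; under
#' `BOTH` the variant is, with equal probability, fixed-effect (identical
#' effect in both subtypes) or independent-effects (two independent nonzero
#' effects). Nonzero effects are drawn from `N(0, tau^2)` on the log-odds
#' scale, or have fixed magnitude `subtype_effect_size` with random sign when
#' that option is set.
#'
#' @param config A [sim_config()]; uses the `subtype_*`, `tau`, `maf_range`
#'   and `n_variants` fields. Randomness is seeded from `config$seed`
#'   (offset from the cohort generator so the two studies are decoupled).
#' @return A list with
#'   * `truth`: tibble `SNP, MODEL, BOTH_KIND, BETA_MO_TRUE, BETA_MA_TRUE, EAF`;
#'   * `mo`, `ma`: summary-statistic tibbles in the shared dialect.
#' @examples
#' pairs <- simulate_subtype_pairs(sim_config(n_variants = 20, n_blocks = 2))
#' table(pairs$truth$MODEL)
#' @export
simulate_subtype_pairs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + 1L, simulate_subtype_pairs_impl(config))
}

simulate_subtype_pairs_impl <- function(config) {
  n <- config$n_variants
  tau <- config$tau
  cc <- config$subtype_corr

  model <- sample(names(config$subtype_model_probs), n, replace = TRUE,
                  prob = config$subtype_model_probs)
  both_kind <- if_else(model == "BOTH",
                       sample(c("fixed", "independent"), n, replace = TRUE),
                       NA_character_)

  draw_effect <- function(m) {
    if (is.null(config$subtype_effect_size)) rnorm(m, 0, tau)
    else config$subtype_effect_size * sample(c(-1, 1), m, replace = TRUE)
  }
  b_mo <- numeric(n); b_ma <- numeric(n)
  i <- model == "MO"; b_mo[i] <- draw_effect(sum(i))
  i <- model == "MA"; b_ma[i] <- draw_effect(sum(i))
  i <- model == "BOTH" & both_kind == "fixed"
  shared <- draw_effect(sum(i)); b_mo[i] <- shared; b_ma[i] <- shared
  i <- model == "BOTH" & both_kind == "independent"
  b_mo[i] <- draw_effect(sum(i)); b_ma[i] <- draw_effect(sum(i))

  maf <- runif(n, config$maf_range[1], config$maf_range[2])
  f <- if_else(runif(n) < 0.5, maf, 1 - maf)

  if (!is.null(config$subtype_se)) {
    se_mo <- rep_len(config$subtype_se[1], n)
    se_ma <- rep_len(config$subtype_se[length(config$subtype_se)], n)
    n_mo <- c(NA_integer_, NA_integer_); n_ma <- n_mo
  } else {
    sn <- config$subtype_n
    n_mo <- c(sn$mo_cases, sn$mo_controls)
    n_ma <- c(sn$ma_cases, sn$ma_controls)
    t_mo <- n_mo[1] / sum(n_mo); t_ma <- n_ma[1] / sum(n_ma)
    se_mo <- 1 / sqrt(2 * sum(n_mo) * t_mo * (1 - t_mo) * f * (1 - f))
    se_ma <- 1 / sqrt(2 * sum(n_ma) * t_ma * (1 - t_ma) * f * (1 - f))
  }

  e1 <- rnorm(n)
  e2 <- cc * e1 + sqrt(1 - cc^2) * rnorm(n)
  bhat_mo <- b_mo + se_mo * e1
  bhat_ma <- b_ma + se_ma * e2

  snp <- sprintf("rs%06d", seq_len(n))
  base <- tibble(SNP = snp, CHR = 1L, BP = 10000L * seq_len(n),
                 EA = "A", OA = "G", EAF = f)
  mk <- function(bhat, se, counts) {
    mutate(base, BETA = bhat, SE = se, P = 2 * pnorm(-abs(bhat / se)),
           INFO = 1, N_CASES = counts[1], N_CONTROLS = counts[2])
  }
  list(
    truth = tibble(SNP = snp, MODEL = model, BOTH_KIND = both_kind,
                   BETA_MO_TRUE = b_mo, BETA_MA_TRUE = b_ma, EAF = f),
    mo = mk(bhat_mo, se_mo, n_mo),
    ma = mk(bhat_ma, se_ma, n_ma)
  )
}
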