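#' Restrict locus members to the lead variant's effective-sample-size window
#'
#' Conditional analysis from meta-analysis summary statistics is only stable
#' across variants with comparable precision, so candidates are restricted to
#' SNPs (no indels) whose effective sample size lies within `tolerance` of the
#' lead variant's: `N_EFF` in `[1 - tolerance, 1 + tolerance] * N_EFF(lead)`.
#'
#' @param members Tibble of locus member variants with `SNP, EA, OA, N_EFF`.
#' @param lead_snp Lead variant id (must be a row of `members`).
#' @param tolerance Relative window half-width, default 0.10.
#' @return The candidate rows of `members`. The lead itself is excluded when
#'   it is an indel (an attribute `"lead_excluded"` records this).
#' @export
neff_window <- function(members, lead_snp, tolerance = 0.10) {
  assert_cols(members, c("SNP", "EA", "OA", "N_EFF"), "locus members")
  if (!lead_snp %in% members$SNP) {
    abort("lead variant is not among the locus members",
          class = "migwas_data_error")
  }
  lead_neff <- members$N_EFF[members$SNP == lead_snp][1]
  is_snp <- members$EA %in% c("A", "C", "G", "T") &
    members$OA %in% c("A", "C", "G", "T")
  keep <- is_snp & members$N_EFF >= (1 - tolerance) * lead_neff &
    members$N_EFF <= (1 + tolerance) * lead_neff
  out <- members[keep, ]
  attr(out, "lead_excluded") <- !(lead_snp %in% out$SNP)
  out
}

#' Stepwise conditional analysis from summary statistics
#'
#' Starts from the lead variant and, at each step, computes every remaining
#' candidate's z-statistic conditional on the selected set `S` using the
#' reference LD matrix `R`:
#' `z_c|S = (z_c - R_cS R_SS^{-1} z_S) / sqrt(1 - R_cS R_SS^{-1} R_Sc)`.
#' The candidate with the smallest conditional p is added while that p stays
#' below `p_stop`; otherwise the procedure stops. Candidates nearly collinear
#' with the selected set (`r^2 > r2_guard` to any selected variant) are
#' skipped, and candidates without LD information are dropped up front. When
#' the lead variant itself was excluded from the candidates (e.g. an indel),
#' the minimum-p candidate in LD with it (`r^2 > lead_r2`) seeds the
#' procedure instead.
#'
#' @param candidates Candidate tibble with `SNP` and either `BETA_META` /
#'   `SE_META` or `BETA` / `SE` columns.
#' @param panel LD panel covering the candidates.
#' @param p_stop Conditional significance threshold, default 5e-8.
#' @param lead Lead/seed variant id; defaults to the minimum-p candidate.
#' @param orig_lead Original lead id when it is absent from `candidates`
#'   (enables the seeding-by-LD rule).
#' @param lead_r2 Minimum `r^2` between a replacement seed and `orig_lead`.
#' @param max_steps Safety bound on selected variants.
#' @param r2_guard Collinearity guard threshold.
#' @return A `conditional_result`: list with `selected` (tibble of chosen
#'   variants with per-step conditional statistics), `trace` (per-step
#'   conditional statistics of all candidates), `stopping_reason` and
#'   `dropped` (candidates without LD information).
#' @export
stepwise_conditional <- function(candidates, panel, p_stop = GWS_P,
                                 lead = NULL, orig_lead = NULL,
                                 lead_r2 = 0.3, max_steps = 10,
                                 r2_guard = 0.95) {
  candidates <- as_tibble(candidates)
  if (!"BETA_META" %in% names(candidates) && "BETA" %in% names(candidates)) {
    candidates <- rename(candidates, BETA_META = "BETA", SE_META = "SE")
  }
  assert_cols(candidates, c("SNP", "BETA_META", "SE_META"), "candidates")
  panel <- as_ld_panel(panel)

  result <- function(selected, trace, reason, dropped) {
    structure(list(selected = selected, trace = trace,
                   stopping_reason = reason, dropped = dropped),
              class = "conditional_result")
  }
  empty_sel <- tibble(SNP = character(0), STEP = integer(0),
                      Z_COND = numeric(0), P_COND = numeric(0),
                      BETA_COND = numeric(0), SE_COND = numeric(0))

  known <- ld_known(panel, candidates$SNP)
  dropped <- candidates$SNP[!known]
  if (length(dropped) > 0) {
    inform(sprintf("stepwise_conditional: dropped %d candidate(s) without LD",
                   length(dropped)))
  }
  cand <- candidates[known, ]
  if (nrow(cand) == 0) {
    return(result(empty_sel, list(), "no candidates", dropped))
  }

  z <- setNames(cand$BETA_META / cand$SE_META, cand$SNP)
  se <- setNames(cand$SE_META, cand$SNP)
  p_marg <- 2 * pnorm(-abs(z))

  # seed
  if (is.null(lead) || !(lead %in% cand$SNP)) {
    if (!is.null(orig_lead) && ld_known(panel, orig_lead)) {
      r2o <- ld_matrix(panel, c(orig_lead, cand$SNP))[1, -1]^2
      ok <- !is.na(r2o) & r2o > lead_r2
      if (!any(ok)) {
        return(result(empty_sel, list(),
                      "no candidates in LD with the lead", dropped))
      }
      lead <- cand$SNP[ok][which.min(p_marg[ok])]
    } else {
      lead <- cand$SNP[which.min(p_marg)]
    }
  }

  R <- ld_matrix(panel, cand$SNP)
  selected <- lead
  sel_stats <- tibble(SNP = lead, STEP = 0L, Z_COND = z[lead],
                      P_COND = unname(p_marg[lead]),
                      BETA_COND = unname(z[lead] * se[lead]),
                      SE_COND = unname(se[lead]))
  trace <- list()
  excluded <- character(0)
  reason <- "no further genome-wide significant conditional signal"

  repeat {
    remaining <- setdiff(cand$SNP, c(selected, excluded))
    if (length(remaining) == 0) { reason <- "candidates exhausted"; break }
    if (length(selected) >= max_steps) { reason <- "max steps reached"; break }

    guard <- vapply(remaining, function(s)
      max(R[s, selected]^2), numeric(1)) > r2_guard
    excluded <- c(excluded, remaining[guard])
    remaining <- remaining[!guard]
    if (length(remaining) == 0) { reason <- "candidates exhausted"; break }

    Rss_inv <- tryCatch(solve(R[selected, selected, drop = FALSE]),
                        error = function(e) NULL)
    if (is.null(Rss_inv)) { reason <- "singular LD among selected"; break }

    Rcs <- R[remaining, selected, drop = FALSE]
    adj <- Rcs %*% Rss_inv
    num <- z[remaining] - drop(adj %*% z[selected])
    denom <- 1 - rowSums(adj * Rcs)
    stopifnot(all(denom > -1e-8))  # PSD panels keep this in [0, 1]
    denom <- pmin(pmax(denom, 0), 1)
    zc <- if_else(denom < 1e-12, 0, num / sqrt(pmax(denom, 1e-12)))
    pc <- 2 * pnorm(-abs(zc))
    sec <- se[remaining] / sqrt(pmax(denom, 1e-12))

    step_tbl <- tibble(SNP = remaining, Z_COND = unname(zc),
                       P_COND = unname(pc),
                       BETA_COND = unname(zc * sec), SE_COND = unname(sec))
    trace[[length(trace) + 1]] <- step_tbl

    best <- which.min(pc)
    if (pc[best] >= p_stop) break
    pick <- remaining[best]
    selected <- c(selected, pick)
    sel_stats <- bind_rows(sel_stats,
                           mutate(step_tbl[best, ],
                                  STEP = length(selected) - 1L))
  }
  result(sel_stats, trace, reason, dropped)
}

#' @export
print.conditional_result <- function(x, ...) {
  cat(sprintf("<conditional_result> %d selected variant(s); stop: %s\n",
              nrow(x$selected), x$stopping_reason))
  print(x$selected)
  invisible(x)
}

#' @export
tidy.conditional_result <- function(x, ...) x$selected

#' @export
glance.conditional_result <- function(x, ...) {
  tibble(n_selected = nrow(x$selected),
         n_secondary = max(0L, nrow(x$selected) - 1L),
         n_dropped_no_ld = length(x$dropped),
         stopping_reason = x$stopping_reason)
}

#' Stepwise conditional analysis over all risk loci
#'
#' For each locus: pulls member statistics from the meta table, restricts to
#' the lead's effective-sample-size window ([neff_window()]), runs
#' [stepwise_conditional()] (seeding by LD with the original lead when that
#' lead fell outside the window), and tabulates the selected variants.
#'
#' @param loci A `migwas_loci` tibble.
#' @param meta Meta-analysis tibble with `SNP, EA, OA, BETA_META, SE_META,
#'   N_EFF`.
#' @param panel LD panel.
#' @param neff_tol Effective-sample-size window half-width.
#' @param p_stop Conditional significance threshold.
#' @param ... Passed to [stepwise_conditional()].
#' @return Tibble with one row per locus: `LOCUS, LEAD_SNP, N_CANDIDATES,
#'   N_SELECTED, N_SECONDARY, SELECTED` (list), `STOP`; per-locus
#'   `conditional_result`s are attached as attribute `"results"`.
#' @export
conditional_analysis <- function(loci, meta, panel, neff_tol = 0.10,
                                 p_stop = GWS_P, ...) {
  assert_cols(meta, c("SNP", "EA", "OA", "BETA_META", "SE_META", "N_EFF"),
              "meta table")
  results <- vector("list", nrow(loci))
  rows <- vector("list", nrow(loci))
  for (i in seq_len(nrow(loci))) {
    mem <- meta[match(loci$MEMBERS[[i]], meta$SNP), ]
    mem <- mem[!is.na(mem$SNP), ]
    cand <- neff_window(mem, loci$LEAD_SNP[i], neff_tol)
    if (nrow(cand) == 0) {
      res <- structure(list(selected = tibble(SNP = character(0)),
                            trace = list(),
                            stopping_reason = "no candidates",
                            dropped = character(0)),
                       class = "conditional_result")
    } else {
      res <- stepwise_conditional(
        cand, panel, p_stop = p_stop,
        lead = if (attr(cand, "lead_excluded")) NULL else loci$LEAD_SNP[i],
        orig_lead = loci$LEAD_SNP[i], ...)
    }
    results[[i]] <- res
    rows[[i]] <- tibble(LOCUS = loci$LOCUS[i], LEAD_SNP = loci$LEAD_SNP[i],
                        N_CANDIDATES = nrow(cand),
                        N_SELECTED = nrow(res$selected),
                        N_SECONDARY = max(0L, nrow(res$selected) - 1L),
                        SELECTED = list(res$selected$SNP),
                        STOP = res$stopping_reason)
  }
  out <- bind_rows(rows)
  attr(out, "results") <- results
  out
}
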