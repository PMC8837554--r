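#' Quantile-quantile plot of association p-values
#'
#' Observed against expected -log10(p) under the uniform null, annotated with
#' the genomic inflation factor.
#'
#' @param p Vector of two-sided p-values.
#' @param max_points Thin to at most this many points (quantile-preserving).
#' @return A ggplot object.
#' @export
plot_qq <- function(p, max_points = 20000) {
  p <- sort(p[is.finite(p) & p > 0 & p <= 1])
  lambda <- genomic_inflation(p = p)
  n <- length(p)
  expected <- (seq_len(n) - 0.5) / n
  if (n > max_points) {
    keep <- unique(c(1:1000, round(seq(1, n, length.out = max_points))))
    p <- p[keep]; expected <- expected[keep]
  }
  df <- tibble(expected = -log10(expected), observed = -log10(p))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p)),
                  subtitle = sprintf("lambda[GC] == %.3f", lambda)) +
    ggplot2::theme_minimal()
}

#' @describeIn classify_subtypes Scatter of subtype log-odds ratios, coloured
#'   by assigned label (unresolved variants in grey), with the diagonal and
#'   coordinate axes for reference.
#' @param object A `subtype_classification`.
#' @param ... Unused.
#' @export
autoplot.subtype_classification <- function(object, ...) {
  df <- mutate(as_tibble(unclass(object)),
               LABEL = factor(.data$LABEL,
                              levels = c("MO", "MA", "BOTH", "NULL",
                                         "unresolved")))
  cols <- c(MO = "#1b9e77", MA = "#7570b3", BOTH = "#d95f02",
            "NULL" = "#000000", unresolved = "grey70")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$B_MO, y = .data$B_MA,
                                   colour = .data$LABEL)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3,
                         colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = cols, drop = FALSE) +
    ggplot2::labs(x = "log(OR), subtype MO", y = "log(OR), subtype MA",
                  colour = "model") +
    ggplot2::theme_minimal()
}

#' Plot leave-one-out eQTL enrichment results
#'
#' Observed counts against the per-tissue predictor with the leave-one-out
#' prediction intervals; flagged tissues are labelled.
#'
#' @param x Output of [eqtl_enrichment_loo()].
#' @return A ggplot object.
#' @export
plot_enrichment <- function(x) {
  assert_cols(x, c("TISSUE", "OBSERVED", "PREDICTOR", "FIT", "PI_LOW",
                   "PI_HIGH", "FLAG"), "enrichment table")
  flagged <- filter(as_tibble(x), !is.na(.data$FLAG))
  ggplot2::ggplot(x, ggplot2::aes(x = .data$PREDICTOR)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$PI_LOW,
                                      ymax = .data$PI_HIGH),
                         fill = "grey85") +
    ggplot2::geom_line(ggplot2::aes(y = .data$FIT), colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(y = .data$OBSERVED,
                                     colour = !is.na(.data$FLAG))) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black",
                                            `TRUE` = "red"), guide = "none") +
    ggplot2::geom_text(data = flagged,
                       ggplot2::aes(y = .data$OBSERVED, label = .data$TISSUE),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(x = "genes with a significant cis-eQTL in tissue",
                  y = "lead variants that are cis-eQTLs") +
    ggplot2::theme_minimal()
}
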