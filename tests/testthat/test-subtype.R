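mk_pair <- function(beta, se = 0.02, snp = sprintf("v%03d", seq_along(beta))) {
  tibble::tibble(SNP = snp, BETA = beta, SE = se)
}

test_that("analytic log marginal likelihoods match the quadrature oracle", {
  grid <- expand.grid(b1 = c(-0.3, -0.05, 0, 0.1, 0.25),
                      b2 = c(-0.2, 0, 0.08, 0.3),
                      se1 = c(0.02, 0.05, 0.1), se2 = c(0.03, 0.08),
                      cc = c(0, 0.148, 0.4), tau = c(0.1, 0.2))
  expect_gte(nrow(grid), 500)
  worst <- 0
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    pr <- subtype_prior(tau = g$tau, corr = g$cc)
    got <- exp(drop(subtype_log_marginals(g$b1, g$se1, g$b2, g$se2, pr)))
    want <- quad_marginals(g$b1, g$se1, g$b2, g$se2, g$cc, g$tau)
    worst <- max(worst, abs(got / want - 1))
  }
  expect_lt(worst, 1e-6)
})

test_that("posteriors normalize, respect symmetry and degenerate limits", {
  withr::with_seed(31, {
    mo <- mk_pair(rnorm(200, 0, 0.1), se = runif(200, 0.01, 0.1))
    ma <- mk_pair(rnorm(200, 0, 0.1), se = runif(200, 0.01, 0.1))
  })
  cls <- classify_subtypes(mo, ma)
  pp <- as.matrix(cls[, c("PP_NULL", "PP_MO", "PP_MA", "PP_BOTH")])
  expect_equal(unname(rowSums(pp)), rep(1, 200), tolerance = 1e-12)

  # swapping the two subtype tables swaps the MO and MA posteriors exactly
  cls_sw <- classify_subtypes(ma, mo)
  expect_equal(cls_sw$PP_MO, cls$PP_MA, tolerance = 1e-12)
  expect_equal(cls_sw$PP_MA, cls$PP_MO, tolerance = 1e-12)
  expect_equal(cls_sw$PP_NULL, cls$PP_NULL, tolerance = 1e-12)
  expect_equal(cls_sw$PP_BOTH, cls$PP_BOTH, tolerance = 1e-12)

  # no information (se >> tau): posteriors return to the model prior
  pr <- subtype_prior(tau = 0.2, model_prior = c(0.4, 0.3, 0.2, 0.1))
  cls_flat <- classify_subtypes(mk_pair(0, se = 50), mk_pair(0, se = 50),
                                prior = pr)
  expect_equal(c(cls_flat$PP_NULL, cls_flat$PP_MO, cls_flat$PP_MA,
                 cls_flat$PP_BOTH),
               c(0.4, 0.3, 0.2, 0.1), tolerance = 1e-3)
  expect_equal(cls_flat$LABEL, "unresolved")

  # near-noiseless data pin the correct label. Even at b = (0, 0) exactly the
  # NULL posterior is capped by the Occam factors of the rival models,
  # 1 / (1 + 2 se sqrt(1-c^2)/tau + 0.5 se sqrt((1+c)/2)/tau + O(se^2/tau^2)),
  # which at se = 1e-4, tau = 0.2, c = 0.148 is 0.99882 -- so test against
  # 0.998, not 1
  cls0 <- classify_subtypes(mk_pair(0, se = 1e-4), mk_pair(0, se = 1e-4))
  expect_equal(cls0$LABEL, "NULL")
  expect_gt(cls0$PP_NULL, 0.998)
  cls_mo <- classify_subtypes(mk_pair(0.15, se = 1e-3),
                              mk_pair(0, se = 1e-3))
  expect_equal(cls_mo$LABEL, "MO")
  cls_b <- classify_subtypes(mk_pair(0.15, se = 1e-3),
                             mk_pair(-0.12, se = 1e-3))
  expect_equal(cls_b$LABEL, "BOTH")

  # shrinking the se never moves a clear signal away from its label
  pps <- vapply(c(0.05, 0.02, 0.01, 0.005), function(s)
    classify_subtypes(mk_pair(0.15, se = s), mk_pair(0.001, se = s))$PP_MO,
    numeric(1))
  expect_true(all(diff(pps) > 0))

  expect_error(subtype_prior(tau = 0), class = "migwas_domain_error")
  expect_error(subtype_prior(corr = 1), class = "migwas_domain_error")
  expect_error(subtype_log_marginals(0, 0, 0, 1), class = "migwas_domain_error")
})

test_that("the difference test matches its hand-computed closed form", {
  # b = (0.10, 0.02), se = (0.02, 0.02), c = 0.148:
  # v = 4e-4 + 4e-4 - 2 * 0.148 * 4e-4 = 6.816e-4, z = 0.08 / sqrt(v)
  dt <- difference_test(0.10, 0.02, 0.02, 0.02)
  expect_equal(dt$z, 0.08 / sqrt(6.816e-4), tolerance = 1e-12)
  expect_equal(dt$p, 2 * pnorm(-0.08 / sqrt(6.816e-4)), tolerance = 1e-12)
  # p(z ~ 3.064) ~ 2.2e-3 exceeds the default alpha of 0.05 / 123 ~ 4.07e-4
  expect_false(dt$flag)
  expect_true(difference_test(0.10, 0.02, 0.02, 0.02, alpha = 0.01)$flag)
  expect_error(difference_test(0, 0.01, 0, 0.01, corr = 1),
               class = "migwas_domain_error")

  # c = 0 reduces to the usual two-sample z; equality gives z = 0, p = 1
  dt0 <- difference_test(0.1, 0.03, 0.1, 0.04, corr = 0)
  expect_equal(dt0$z, 0)
  expect_equal(dt0$p, 1)
  dt1 <- difference_test(0.1, 0.03, 0.0, 0.04, corr = 0)
  expect_equal(dt1$z, 0.1 / 0.05, tolerance = 1e-12)

  # positive correlation sharpens the test (same difference, larger |z|)
  expect_gt(abs(difference_test(0.1, 0.03, 0, 0.04, corr = 0.5)$z),
            abs(dt1$z))
})

test_that("direction concordance uses the exact two-sided binomial", {
  # 100 of 100 agree: p = 2 * 0.5^100
  d <- direction_concordance(rep(1, 100), rep(2, 100))
  expect_equal(d$p, 2 * 0.5^100)
  expect_equal(d$proportion, 1)

  # 50 of 100: p = 1 exactly (min(1, 2 * min(tails)) caps at 1)
  d50 <- direction_concordance(rep(c(1, 1), 50), rep(c(1, -1), 50))
  expect_equal(d50$p, 1)

  # symmetry: k agreements and n - k agreements give the same p
  d30 <- direction_concordance(rep(1, 100), c(rep(1, 30), rep(-1, 70)))
  d70 <- direction_concordance(rep(1, 100), c(rep(1, 70), rep(-1, 30)))
  expect_equal(d30$p, d70$p, tolerance = 1e-12)

  # agrees with binom.test's two-sided p for a symmetric null
  bt <- stats::binom.test(70, 100, 0.5)$p.value
  expect_equal(d70$p, bt, tolerance = 1e-12)

  # zero effects are dropped with a message
  expect_message(dz <- direction_concordance(c(1, 0, -1), c(1, 1, -1)),
                 "dropped 1")
  expect_equal(dz$n_pairs, 2L)
  expect_equal(dz$n_agree, 2L)
})

test_that("the correlation estimator recovers the generating correlation", {
  cfg <- sim_config(n_variants = 50000,
                    subtype_model_probs = c(1, 0, 0, 0), seed = 17)
  pairs <- simulate_subtype_pairs(cfg)
  est <- estimate_subtype_correlation(pairs$mo, pairs$ma)
  mc_se <- (1 - 0.148^2) / sqrt(50000)
  expect_lt(abs(est - 0.148), 4 * mc_se)

  # identical tables: correlation 1 on the qualifying set
  expect_equal(estimate_subtype_correlation(pairs$mo, pairs$mo), 1)

  # too few qualifying variants is an error, not a silent estimate
  expect_error(estimate_subtype_correlation(pairs$mo[1:50, ], pairs$ma[1:50, ]),
               class = "migwas_data_error")

  # classify_subtypes(corr = "auto") uses the estimate
  small <- 1:2000
  cls <- classify_subtypes(pairs$mo[small, ], pairs$ma[small, ], corr = "auto")
  expect_equal(attr(cls, "settings")$corr,
               estimate_subtype_correlation(pairs$mo[small, ],
                                            pairs$ma[small, ]))
})

test_that("confident labels recover the generating model", {
  # |effect| = 2 tau, se = tau / 10. At this precision the Occam factors cap
  # PP_NULL at ~0.81 and (for a subtype-specific variant) PP_MO at ~0.95, so
  # confident labels are only issued for a subset of variants; the claim
  # under test is that every confident label is (almost always) correct and
  # that no null variant ever earns a confident non-null label
  cfg <- sim_config(n_variants = 4000, subtype_se = 0.02,
                    subtype_effect_size = 0.4, seed = 101)
  pairs <- simulate_subtype_pairs(cfg)
  cls <- classify_subtypes(pairs$mo, pairs$ma)
  j <- dplyr::inner_join(tibble::tibble(SNP = cls$SNP, LABEL = cls$LABEL),
                         pairs$truth, by = "SNP")
  for (m in c("MO", "MA", "BOTH")) {
    sub <- j[j$MODEL == m & j$LABEL != "unresolved", ]
    expect_gt(nrow(sub), 100)
    expect_gt(mean(sub$LABEL == m), 0.90)
  }
  expect_true(all(j$LABEL[j$MODEL == "NULL"] %in% c("NULL", "unresolved")))
  # shared signals of this size are essentially always resolved
  expect_gt(mean(j$LABEL[j$MODEL == "BOTH"] == "BOTH"), 0.90)

  g <- glance(cls)
  expect_equal(g$n_variants, 4000L)
  expect_equal(g$n_null + g$n_mo + g$n_ma + g$n_both + g$n_unresolved, 4000L)
})
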