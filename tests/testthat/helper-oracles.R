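# Independent oracles used by the tests. These deliberately avoid the code
# paths they check: quadrature instead of the analytic marginal likelihoods,
# lm() instead of the closed-form IVW pool, individual-level joint regression
# instead of summary-statistic conditioning.

# bivariate normal density at (x1, x2), mean 0, covariance [[v1, v12],[v12, v2]]
dbvn0 <- function(x1, x2, v1, v12, v2) {
  det <- v1 * v2 - v12^2
  exp(-(v2 * x1^2 - 2 * v12 * x1 * x2 + v1 * x2^2) / (2 * det)) /
    (2 * pi * sqrt(det))
}

# marginal likelihoods of the four subtype models by adaptive quadrature over
# the latent effects (1-D for MO/MA/fixed, 2-D for independent effects).
# Integration limits are centered on each integrand's exact posterior mode
# (plain Gaussian algebra, never the package's marginal-likelihood formulas)
# so adaptive quadrature cannot miss narrow peaks, and each 1-D integral is
# split at the mode so the peak sits on a panel boundary.
quad_marginals <- function(b1, se1, b2, se2, cc, tau) {
  v1 <- se1^2; v2 <- se2^2; v12 <- cc * se1 * se2
  int1 <- function(f, m, s) {
    lo <- m - 15 * s; hi <- m + 15 * s
    stats::integrate(f, lo, m, rel.tol = 1e-12, subdivisions = 500L)$value +
      stats::integrate(f, m, hi, rel.tol = 1e-12, subdivisions = 500L)$value
  }

  ml_null <- dbvn0(b1, b2, v1, v12, v2)

  # MO: as a function of theta, the likelihood factor is Gaussian with mean
  # b1 - (v12/v2) b2 and variance v1 (1 - cc^2); combine with the N(0, tau^2)
  # prior for the posterior mode/width
  po <- function(m_lik, s2_lik) {
    prec <- 1 / s2_lik + 1 / tau^2
    list(m = (m_lik / s2_lik) / prec, s = sqrt(1 / prec))
  }
  p_mo <- po(b1 - (v12 / v2) * b2, v1 * (1 - cc^2))
  ml_mo <- int1(function(th)
    dbvn0(b1 - th, b2, v1, v12, v2) * stats::dnorm(th, 0, tau),
    p_mo$m, p_mo$s)
  p_ma <- po(b2 - (v12 / v1) * b1, v2 * (1 - cc^2))
  ml_ma <- int1(function(th)
    dbvn0(b1, b2 - th, v1, v12, v2) * stats::dnorm(th, 0, tau),
    p_ma$m, p_ma$s)

  # fixed effect: x = (b1 - th, b2 - th); the likelihood is Gaussian in th
  # with precision (v1 + v2 - 2 v12) / det and mean the precision-weighted
  # combination below
  det <- v1 * v2 - v12^2
  s2_fix <- det / (v1 + v2 - 2 * v12)
  m_fix <- ((v2 - v12) * b1 + (v1 - v12) * b2) / (v1 + v2 - 2 * v12)
  p_fix <- po(m_fix, s2_fix)
  ml_fix <- int1(function(th)
    dbvn0(b1 - th, b2 - th, v1, v12, v2) * stats::dnorm(th, 0, tau),
    p_fix$m, p_fix$s)

  # independent effects: iterated adaptive 1-D quadrature (pracma::integral2
  # stalls near 4e-4 relative error on this family). For fixed t1 the inner
  # integrand over t2 is a Gaussian likelihood slice (mean
  # b2 - (v12/v1)(b1 - t1), variance v2 (1 - cc^2)) times the prior, so the
  # inner mode/width follow from the same conjugate algebra
  inner <- function(t1) {
    p2 <- po(b2 - (v12 / v1) * (b1 - t1), v2 * (1 - cc^2))
    int1(function(t2)
      dbvn0(b1 - t1, b2 - t2, v1, v12, v2) * stats::dnorm(t2, 0, tau),
      p2$m, p2$s)
  }
  p1 <- po(b1, v1)  # t1-marginal mode/width bracket (exact at cc = 0)
  ml_ind <- int1(function(t1)
    vapply(t1, inner, numeric(1)) * stats::dnorm(t1, 0, tau),
    p1$m, p1$s)
  # the 15-sd limits leave out tail mass of order pnorm(-15) of the
  # posterior, far below the 1e-6 comparison tolerance
  c("NULL" = ml_null, MO = ml_mo, MA = ml_ma,
    BOTH = 0.5 * ml_fix + 0.5 * ml_ind)
}

# intercept-only weighted least squares via lm(): the IVW oracle
wls_pool <- function(beta, se) {
  fit <- stats::lm(beta ~ 1, weights = 1 / se^2)
  sigma <- summary(fit)$sigma
  c(beta = unname(stats::coef(fit)[1]),
    se = unname(sqrt(diag(stats::vcov(fit)))[1] / sigma))
}

# stepwise joint regression on individual-level data: at each step add the
# variant whose coefficient, fit jointly with the already-selected ones, has
# the smallest p-value, while that p stays below p_stop
joint_stepwise <- function(G, y, p_stop = 5e-8, max_steps = 10) {
  m <- ncol(G); n <- nrow(G)
  XtX <- crossprod(G); Xty <- drop(crossprod(G, y)); yty <- sum(y^2)
  joint_p <- function(S) {
    A <- solve(XtX[S, S, drop = FALSE])
    bhat <- drop(A %*% Xty[S])
    rss <- yty - sum(bhat * Xty[S])
    sigma2 <- rss / (n - length(S))
    t <- bhat / sqrt(diag(A) * sigma2)
    2 * stats::pt(-abs(t), df = n - length(S))
  }
  marg_p <- vapply(seq_len(m), function(j) joint_p(j)[1], numeric(1))
  selected <- which.min(marg_p)
  repeat {
    remaining <- setdiff(seq_len(m), selected)
    if (length(remaining) == 0 || length(selected) >= max_steps) break
    pc <- vapply(remaining, function(j) {
      ps <- joint_p(c(selected, j)); ps[length(ps)]
    }, numeric(1))
    if (min(pc) >= p_stop) break
    selected <- c(selected, remaining[which.min(pc)])
  }
  sort(selected)
}

# marginal summary statistics from individual-level data
marginal_stats <- function(G, y) {
  n <- nrow(G)
  gtg <- colSums(G^2)
  beta <- drop(crossprod(G, y)) / gtg
  rss <- sum(y^2) - beta^2 * gtg   # per-variant simple-regression residual SS
  se <- sqrt(pmax(rss, 0) / ((n - 2) * gtg))
  tibble::tibble(SNP = colnames(G), BETA = beta, SE = se,
                 P = 2 * stats::pt(-abs(beta / se), df = n - 2))
}

# correlated standardized genotypes with correlation matrix R
sim_genotypes <- function(n, R) {
  L <- chol(R)
  G <- matrix(stats::rnorm(n * ncol(R)), n) %*% L
  colnames(G) <- paste0("v", seq_len(ncol(R)))
  G
}

# small GWS table + matching single-block LD matrix for locus tests
mk_gws <- function(bp, p, chr = 1L, snp = sprintf("s%02d", seq_along(bp))) {
  tibble::tibble(SNP = snp, CHR = chr, BP = as.integer(bp),
                 EA = "A", OA = "G", P = p)
}

mk_ld <- function(snps, pairs = list(), diag_only = FALSE) {
  k <- length(snps)
  m <- diag(k); dimnames(m) <- list(snps, snps)
  for (pr in pairs) {  # pr = c(i, j, r)
    m[pr[1], pr[2]] <- pr[3]; m[pr[2], pr[1]] <- pr[3]
  }
  m
}
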