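---
title: "Methods: models, defaults and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, defaults and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migwas)
```

`migwas` implements the downstream stages of a multi-cohort case/control GWAS
meta-analysis with two clinical subtypes: harmonization and QC of per-cohort
summary statistics, inverse-variance-weighted (IVW) meta-analysis, risk-locus
definition from LD, approximate conditional analysis, a four-model Bayesian
subtype classifier, and enrichment/heritability helpers. A block-LD synthetic
generator makes every stage testable without access to individual-level data.
This vignette records the statistical models, the default parameters and why
they were chosen, and the decisions taken where the methods left room for
interpretation.

## The synthetic generator

`simulate_ld_panel()` lays variants out in contiguous blocks. Within a block
of consecutive variants the signed allelic correlation is AR(1),
`r(i, j) = rho^|i - j|` with `rho = block_decay`; across blocks it is exactly
zero. This is a deliberate idealization: real LD decays with distance but is
not Markovian, and block boundaries are soft. The AR(1) form was chosen
because it is positive definite by construction, has a closed-form Cholesky
factor pattern, and scales to `1e5` variants because each block is stored
separately (`ld_matrix()` assembles only the submatrix you request; variants
the panel does not know return `NA` off-diagonal).

`simulate_cohorts()` draws, per cohort, z-scores from the standard
summary-statistic model `z ~ N(R beta / se, R)` per block, where `R` is the
block LD matrix. Standard errors are constructed from the effective-sample-
size identity

```
se = 1 / sqrt(2 N t (1 - t) * info * f (1 - f))
```

with `N = n_cases + n_controls`, case proportion `t`, per-variant imputation
`info ~ U(info_range)` and effect-allele frequency `f`. This makes
`effective_sample_size()` recover `2 N t (1 - t) info` exactly up to the
noise in the estimated frequency, which is itself drawn as
`f + N(0, sqrt(f (1 - f) / 2N))`. Effects are a spike model: a fraction
`causal_fraction = 0.01` of variants receive `N(0, effect_sd^2)` log-odds
effects with `effect_sd = 0.05`; the rest are null. Strand flips are
simulated on ambiguous (A/T, G/C) SNPs by swapping the allele labels in 1% of
rows for every cohort after the first, and 5% of rows are dropped per cohort
to create realistic partial overlap. The default five-cohort case/control
counts total 102,084 cases and 771,257 controls, sized like a large
multi-cohort disease meta-analysis; they are package defaults, not
requirements.

`simulate_subtype_pairs()` draws a generating model per variant from
`subtype_model_probs` (`NULL`, `MO`, `MA`, `BOTH`; `BOTH` half fixed-effect,
half independent-effects), effects from `N(0, tau^2)` or, when
`subtype_effect_size` is set, with fixed magnitude and random sign, and
estimation errors that are bivariate normal with correlation `subtype_corr`
(default 0.148, the scale expected when two subtype analyses share most
controls). All generation is seed-deterministic via `withr::with_seed()`;
the subtype stream uses `seed + 1` so cohort and subtype draws do not alias.

What the generator does **not** model: sample overlap between cohorts,
population stratification, imputation certainty varying with MAF, dominance
or interaction effects, and X-chromosome dosage. Results that depend on those
features cannot be rehearsed with it.

## Harmonization and QC

`harmonize_to_reference()` matches variants to the reference by chromosome,
position and allele pair after uppercasing and recoding indels to `I`/`D`
(the longer allele is the insertion). Equal-length multi-nucleotide pairs are
dropped as unorientable. Multiallelic positions are dropped on both sides
because an allele-pair match is ambiguous there. A swapped pair negates the
effect and reflects the frequency (`EAF -> 1 - EAF`); harmonization is
idempotent. Every input row is accounted for: `multiallelic + unmatched +
retained` equals the input count.

`apply_qc_filters()` excludes on MAF (`> 0.01`), imputation info (`> 0.6`),
optional HWE p (`> 1e-6`) and missingness (`< 0.05`), and frequency
discrepancy against the reference (`<= 0.30` for SNPs, `<= 0.20` for
indels). Each excluded variant is attributed to the *first* rule it fails,
in that order, so the per-rule report sums to the input count. A decision
worth noting: the frequency-discrepancy check runs **after** harmonization,
so a legitimately swapped variant is compared on the correct allele and only
genuine frequency disagreement (e.g. an unfixable strand flip on an
ambiguous SNP, or population mismatch) triggers exclusion.

`audit_strand_ambiguous()` is a diagnostic, not a filter: for A/T and G/C
SNPs it reports how often the same allele is the minor allele in two tables,
overall and stratified by MAF. High concordance at low MAF and ~50% near MAF
0.5 is the expected signature when strands agree, since near 0.5 the minor
allele is decided by noise.

## Meta-analysis

`ivw_meta()` pools per-cohort effects with weights `1/se^2`:
`b = sum(w b_i) / sum(w)`, `se = 1 / sqrt(sum(w))`. P-values are computed in
log space (`pnorm(..., log.p = TRUE)`) so `MLOG10P` stays finite when `P`
underflows (|z| > 37). Direction strings use `+`, `-`, `0` and `?` (variant
absent from a cohort). `effective_sample_size()` implements
`1 / (f (1 - f) se^2)` using the pooled frequency — a pragmatic choice, since
per-cohort frequencies are no longer available after pooling; the synthetic
round-trip shows the approximation error is well under the 10% tolerance the
filter cares about. `filter_by_neff()` drops variants with `N_EFF < 5000`,
where single-cohort results masquerade as meta-analysis results.
`genomic_inflation()` is `median(chi^2) / qchisq(0.5, 1)`.

## Risk loci

`select_index_variants()` performs greedy clumping: visit GWS variants in
increasing p order, keep a variant as an index unless `r^2 > 0.1` with an
already-kept index. Ties are broken deterministically (position, then
alleles), so the result is invariant to input row order. Variants unknown to
the LD panel become their own indices (conservative: no evidence of
redundancy), unless a secondary panel knows them — then they are absorbed
into, or (if lower-p) replace, the index with the largest secondary-panel
`r^2`.

`define_loci()` builds loci in three passes: (1) each index spans the
interval of members with `r^2 > 0.6` (an index with no such partner spans a
single base pair), and intervals on a chromosome closer than 250 kb
(end-to-start) are merged; (2) GWS variants still outside every locus are
assigned to the locus with the nearest boundary, extending it; (3) merging is
repeated, since extension can close a previously open gap. The lead variant
is the minimum-p member. Nearest-locus assignment by boundary distance (not
midpoint) is a documented choice: it matches the intuition that a variant
just outside a wide locus belongs to it. `name_loci()` names a locus by the
nearest protein-coding gene within 250 kb of the lead (falling back to the
nearest gene of any type, then to `chr:pos`), prefixed with `"Near "` when
the lead is outside the gene body.

## Conditional analysis

`stepwise_conditional()` is the standard summary-statistic approximation to
joint regression. With selected set `S` and reference LD `R`,

```
z_c|S = (z_c - R_cS R_SS^-1 z_S) / sqrt(1 - R_cS R_SS^-1 R_Sc)
```

The candidate with the smallest conditional p joins `S` while that p is below
`5e-8`, up to 10 steps; candidates with `r^2 > 0.95` to any selected variant
are skipped (near-collinearity makes the adjustment numerically meaningless).
Conditional effects are reported as `se_cond = se / sqrt(denominator)` and
`beta_cond = z_cond * se_cond`, i.e. on the scale of the marginal standard
error inflated by the usual variance-inflation factor. Under the generator's
own model (`z ~ N(R beta/se, R)`) this procedure is exact, which is what the
individual-level joint-regression oracle in the test suite verifies.

`neff_window()` restricts candidates to SNPs whose `N_EFF` is within ±10% of
the lead's, because conditioning mixes statistics across variants and is only
trustworthy when their precisions are comparable; indels are excluded
outright since their reference LD is least reliable. When this excludes the
lead itself, the minimum-p candidate with `r^2 > 0.3` to the original lead
seeds the procedure instead — conditioning a locus on a variant unrelated to
its lead signal would answer the wrong question.

## Subtype classification

For each variant with paired subtype estimates `(b_mo, b_ma)`, the sampling
model is bivariate normal with covariance
`Sigma = [[se_mo^2, c se_mo se_ma], [c se_mo se_ma, se_ma^2]]`, where
`c = 0.148` reflects shared controls. Four hypotheses are compared through
their marginal likelihoods, each a centered bivariate normal density with
covariance `Sigma + P_m`:

* `NULL`: `P = 0`
* `MO`: `P = diag(tau^2, 0)`
* `MA`: `P = diag(0, tau^2)`
* `BOTH`: equal-weight mixture of `P = tau^2 [[1,1],[1,1]]` (identical
  effect) and `P = tau^2 I` (independent effects)

with `tau = 0.2` on the log-odds scale and equal model priors. All
computation is in log space with log-sum-exp for the mixture, because the
standard errors span orders of magnitude. Posteriors are normalized by Bayes'
formula; a variant is labeled with a model only when its posterior exceeds
0.95, otherwise `"unresolved"`.

Two consequences of this model are worth understanding before reading
results. First, the rival models carry Occam factors of order `se/tau`, so at
`b = (0, 0)` the NULL posterior is *capped* at roughly
`1 / (1 + 2.5 se/tau)`: with `se = tau/10` no null variant can ever reach the
0.95 threshold, and "unresolved" is the expected — and correct — output for
nulls at realistic precision. The classifier's reliability claim is therefore
conditional: labels it does issue at 95% are almost always right, which is
exactly what the label-recovery tests assert. Second, `NULL` is a label in
its own right here (it can be issued when `se` is a few hundredths of `tau`
or smaller), a divergence from conventions that only ever color the three
non-null models.

`estimate_subtype_correlation()` estimates `c` as the Pearson correlation of
effect estimates over common variants (MAF > 0.05 in both tables) with no
strong association in either (`P > 1e-4`), requiring at least 100 qualifying
variants: over such variants the true effects are negligible, so the
correlation of the estimates is the correlation of their errors.
`difference_test()` tests `b_mo = b_ma` with
`z = (b_mo - b_ma) / sqrt(se_mo^2 + se_ma^2 - 2 c se_mo se_ma)` at a
Bonferroni-corrected level (default `0.05/123`). `direction_concordance()`
uses the exact two-sided binomial test,
`p = min(1, 2 min(P(X <= k), P(X >= k)))`, rather than a normal
approximation.

## Enrichment and heritability helpers

`eqtl_enrichment_loo()` implements a leave-one-out prediction-interval test:
for each tissue, regress the observed count of eQTL lead variants on the
tissue's overall eQTL gene count using the other tissues (OLS via `lm()`),
predict the held-out tissue with a 95% t-based prediction interval
(`predict.lm(..., interval = "prediction")`), and flag observations outside
it. `liability_h2()` converts observed-scale heritability to the liability
scale, `h2_l = h2_o K^2 (1-K)^2 / (P (1-P) phi(Phi^-1(1-K))^2)`, with
defaults `K = 0.16` (population prevalence) and `P = 0.117` (sample case
proportion).

## Numerical choices, in one place

* Log-space probabilities everywhere a p-value or density can underflow;
  `MLOG10P` carries significance beyond `P = 5e-324`.
* Block-diagonal LD storage; dense matrices are only formed for requested
  subsets, so 100,000-variant simulations run in seconds.
* Seeds fully determine all generator output; independent streams are
  derived by fixed offsets from the configured seed.
* Deterministic tie-breaking (p, then position, then alleles) makes clumping
  and locus definition order-invariant.
* Collinearity guard `r^2 > 0.95` and an explicit singularity stop protect
  the conditional solver instead of silently regularizing.
```{r session}
sessionInfo()
```
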