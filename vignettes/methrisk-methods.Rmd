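---
title: "Methods: prospective EWAS, methylation risk scores and epigenetic mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prospective EWAS, methylation risk scores and epigenetic mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methrisk)
```

## The scientific problem

Whether DNA methylation (DNAm) differences precede substance use — rather
than merely follow it — can only be addressed prospectively: methylation
measured at birth, long before any exposure to tobacco, cannabis or
alcohol, related to substance-use outcomes reported in adolescence. The
analysis chain this package implements mirrors that design:

1. a **latent substance-use liability** extracted by confirmatory factor
   analysis (CFA) from eight self-report indicators (tobacco and cannabis
   frequency at ages 14/16/18, alcohol-use screening scores at 16/18),
   with three first-order substance factors and a single second-order
   liability factor;
2. a **probe-wise epigenome-wide association study (EWAS)** of
   Illumina-450k-style beta values at birth against that liability score,
   adjusting for sex and five reference-estimated blood cell proportions,
   with Benjamini–Hochberg false-discovery control at q < 0.05;
3. a **spatially-correlated region caller** on the EWAS p-value track
   (autocorrelation-adjusted Stouffer–Liptak smoothing, seed threshold
   1e−4, 500 bp windows, Šidák correction);
4. a **follow-forward** re-test of the discovery probes at a second
   timepoint (mid-childhood), with per-probe cross-time autocorrelation
   and a comparison of within-time co-methylation networks;
5. a **cumulative weighted DNAm risk score** (raw beta values weighted by
   the discovery standardized coefficients and summed — the polygenic-score
   recipe), a genetically de-confounded variant excluding mQTL-associated
   probes, a prenatal-exposure screen, and age-of-onset correlations;
6. a **path-analytic mediation model** (prenatal exposures → DNAm risk
   score → liability) with case-resampling bootstrap percentile intervals
   for the indirect effects.

Because the motivating cohort data are access-controlled, the package
ships a seeded synthetic cohort generator with planted ground truth. The
generator is first-class, tested code: every downstream stage is validated
by recovering what was planted.

## The synthetic cohort generator

On the logit(beta) scale the birth methylome is

$$\mathrm{logit}(\beta_{ij}) = \mu_j + \lambda_j L_i + \sum_e \gamma_{ej} E_{ie}
  + \delta_j G_{ij} + \sum_k c_{kj} \pi_{ik} + \varepsilon_{ij},$$

with \(L_i\) the latent liability, \(E\) standardized prenatal exposures,
\(G \in \{0,1,2\}\) Hardy–Weinberg mQTL genotypes, \(\pi\) Dirichlet
cell-type proportions pushed through the reference signatures, and
Gaussian residuals. Working on the logit scale keeps betas strictly inside
(0,1) after the inverse transform; the price is that planted effect sizes
are nuisance parameters, deliberately *not* identified with published
standardized coefficients — they are calibrated so that the induced
standardized probe-level effects land near 0.3, the magnitude of the
published discovery loci.

Key default choices (all in `sim_config()`):

* **500 samples × 20,000 probes** — desk scale. Full 413,510-probe runs are
  configuration, not code.
* **65 planted DMPs**, signs alternating (the published set split 33
  hypomethylated / 32 hypermethylated), **5 under mQTL control** (4 cis,
  1 trans) with 0.8 logit-units per allele at MAF 0.30.
* `dmp_effect_sd = 0.12` with `noise_sd = 0.35` — together these give
  probe-level standardized effects ≈ 0.3 (verified by the Monte-Carlo
  recovery tests).
* **Liability–exposure path only through maternal smoking** (standardized
  path 0.3, prevalence 0.18 following the published yes/no split), so
  mediation holds by construction and the exposure screen has a single
  true positive. Smoking additionally shifts 20 dedicated probes (an
  AHRR-like prenatal-smoking signature) that are disjoint from the
  liability DMPs.
* **Factor loadings** standardized, first-order 0.65–0.90 and second-order
  0.75–0.85, inside the published 0.58–0.96 range. Ordinal frequency items
  are simulated and modelled as continuous — the published estimator
  treated them with normal-theory ML, and we mirror that; it is a known
  limitation for genuinely categorical data.
* **Cross-time autocorrelation 0.07** (the published mean |r| across
  discovery probes). The age-7 matrix keeps each probe's baseline and
  genotype terms, carries *no* liability or exposure effects (effects are
  birth-specific, as observed), and mixes fresh residuals so non-mQTL
  probes attain the target correlation while mQTL probes stay stable
  through their shared genetic term. Residuals over the DMP set share an
  exchangeable correlation block (default 0.3), regenerated at each
  timepoint, reproducing the observation that the co-methylation network
  is preserved even though individual probes are not temporally stable.
* **Sex ratio 0.51 female** — the source abstract and methods disagree
  (51% vs 54%); the ratio is a config knob and the abstract value is the
  default.

What the generator does *not* emulate: raw array intensities,
normalization artefacts, batch structure, probe-specific measurement
error heteroscedasticity, or genomic clustering of the planted DMPs
(they are placed uniformly at random). Passing tests therefore certify
the statistical machinery, not robustness to array-level technical noise.

## The liability CFA

Estimation minimizes the normal-theory ML discrepancy
\(F_{ML} = \log|\Sigma(\theta)| + \mathrm{tr}(S\Sigma^{-1}(\theta)) -
\log|S| - p\) by quasi-Newton (BFGS, relative tolerance 1e−12, two-stage
restart, max 5,000 iterations), with the first loading of each factor
fixed to 1 for identification and variances optimized on the log scale —
so fitted solutions are admissible by construction and a residual variance
collapsing toward zero surfaces as a boundary (Heywood) flag rather than a
negative estimate. \(\chi^2 = (N-1)F_{ML}\); CFI and TLI use the
independence baseline \(\chi^2_0 = -(N-1)\log|R|\); RMSEA uses
\(\sqrt{\max(\chi^2-df,0)/(df\,(N-1))}\). We use \(N-1\) throughout; at
N = 244 the printed RMSEA (0.08) is reproduced identically under either
convention (0.0849 vs 0.0847). The RMSEA 90% interval inverts the
noncentral chi-square CDF at probabilities 0.95/0.05.

Factor scores are regression scores,
\(\hat\eta = \mathrm{Cov}(\eta, y)\,\Sigma^{-1}(y-\bar y)\), with the
second-order score standardized. Under the default loadings the
population correlation between the regression score and the true
liability has the closed form \(\sqrt{\psi'\Sigma^{-1}\psi}\) ≈ 0.89 —
scores are good but not perfect proxies, and the recovery tests assert
agreement with this ceiling rather than an arbitrary round number.

No SEM library is available at runtime; the CFA code is validated against
closed-form population cases (fitting the exact implied covariance must
give \(F_{ML} \approx 0\), CFI = 1, RMSEA = 0), the printed-statistic
worked example, and generator ground truth.

## Cell-composition estimation

Per sample we minimize \(\|\beta_{panel} - R\pi\|^2\) subject to
\(\pi \ge 0\) and, by default, \(\sum_k \pi_k \le 1\) (the cited
reference-based approach projects onto the non-negative orthant without
forcing the simplex; `constraint = "sum_eq_1"` is available). With K
reference cell types the quadratic program is solved *exactly* by
enumerating all 2^K active sets — each a small equality-constrained
least-squares solve — and keeping the feasible candidate with the smallest
objective. For blood-panel K = 5 this costs 64 tiny solves per sample and
removes any iterative-solver tolerance question; tests verify dominance
over a step-0.001 simplex grid search. Proportions are used as covariates
as estimated (not re-normalized). When estimates sit exactly on the
simplex boundary for every sample the EWAS design would alias the
intercept; the regression engine then drops the redundant proportion
column with a warning, which leaves the adjustment unchanged.

## The EWAS engine

Methylation is the regression **response** and the phenotype the
predictor (the convention of the cited probe-wise analysis tooling), with
`std_beta = b · SD(x)/SD(y)` so that \(|std\_beta|\) is a
correlation-scale quantity comparable to published standardized
coefficients. All probes share one design matrix, so coefficients for the
full matrix come from a single QR decomposition; two-sided t tests use
n − k degrees of freedom; complete cases only; probes with zero variance
are emitted flagged with missing p and q. FDR control is
Benjamini–Hochberg (the published rank-1 q-value of 0.005 at
m = 413,510 corroborates BH as the unnamed "FDR correction"), supporting
adjustment of a sub-vector against a larger family total. The
follow-forward stage reruns the identical model on the discovery probes at
the later timepoint with BH over that restricted set only.

Co-methylation structure is summarized by the pairwise Pearson matrix
with BH-adjusted pair q-values; two timepoints are compared by the
correlation of vectorized lower triangles (no canonical metric exists in
the source; this choice is transparent), with a seeded 999-permutation
Mantel p-value as a secondary output.

## Region calling on spatially-correlated p-values

The distance-binned autocorrelation of probit-transformed p-values
(left-open right-closed 50 bp bins to 500 bp) feeds the
Stouffer–Liptak–Kechris combination
\(z_{comb} = \sum_j z_j / \sqrt{k + 2\sum_{j<l}\rho(d_{jl})}\). Identities
the tests pin down: an isolated probe keeps its raw p; k identical
p-values under perfect correlation return the raw p (denominator k);
independence reduces to the classical Stouffer combination. Candidate
regions are maximal runs of smoothed p < 1e−4 merged across gaps ≤ 500 bp,
never across chromosomes; coordinates are half-open with single-probe
regions spanning [pos, pos+1). The region p-value re-combines the *raw*
p-values inside the region and is Šidák-corrected with exponent
total-covered-bp / region-bp, where the covered footprint is the
probe-covered window span per chromosome (the upstream convention is
ambiguous; ours is documented and configurable). p-values are clipped to
[1e−300, 1−1e−16]; upper-tail quantiles and `expm1`/`log1p` arithmetic
keep genome-scale exponents from underflowing.

## Risk score, screen, and mediation

The risk score is the exact weighted sum of **raw** beta values with the
discovery standardized coefficients as weights ("methylation values" in
the source; raw betas are the literal reading and the default). The score
object freezes its weights and provenance. The mQTL-excluded variant
removes table-listed probes (the cis/trans split is reported); the screen
computes Pearson correlations of score and outcome against six prenatal
exposures with BH over each row's six-test family; onset correlations are
computed within endorsement subgroups only.

The mediation model is recursive and therefore ML-equivalent to two OLS
fits: mediator on exposures (a-paths) and outcome on mediator plus
exposures (b, c′). Indirect effects are \(a_k b\); the exact decomposition
`total = c′ + a·b` is asserted to 1e−8. Inference uses case-resampling
percentile bootstrap intervals (the flavour is unstated in the source;
percentile is the default, with Wald p-values reported alongside to match
the joint reporting style); the mediator and outcome enter z-scored in the
pipeline so path coefficients are comparable across runs, with
unstandardized estimates also reported. Degenerate resamples are redrawn
and counted; a fixed seed reproduces intervals bit-identically. Covariates
are excluded from the path model by default (the published model contains
exposures, score and outcome only). Winsorization at mean ± 3 SD (moments
from the unmodified data) supports the outlier sensitivity rerun.

## Statistical character of the stochastic checks

Several advertised properties are themselves statistical events, and the
test suite budgets for their sampling error rather than treating point
rates as certainties: the per-cohort KS uniformity check rejects ~1% of
truly-null cohorts by construction, so 100-cohort runs allow up to 4
failures (binomial 99.7% bound); the "smoking and nothing else" screen
event has population rate ≈ 0.90 because a null exposure passes a q<0.05
screen at its type-I rate, so the 50-replicate count is tested net of
binomial noise; the family-wise BH discovery rate has population value
0.05 and is asserted ≤ 0.06 as specified. Problem sizes (100 null cohorts
of 300 × 5,000; recovery at n = 2,000–5,000; coverage over 200 replicates
with B = 500; the planted chain at 2,000 × 10,000) were chosen once to
make these rates estimable at useful precision.

## Known limitations

* Continuous-ML treatment of ordinal frequency items (no WLSMV).
* No X-chromosome-specific handling beyond the sex covariate.
* The region caller's `max_gap`/window semantics mirror the two published
  numbers; the upstream tool's exact internal defaults are not public in
  the source text.
* The generator's age-7 matrix redraws cell proportions from the same
  Dirichlet as at birth; real cord-to-whole-blood tissue change shifts the
  composition distribution itself, which is not modelled.
* Bootstrap intervals are percentile; bias-corrected variants are not
  implemented.
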