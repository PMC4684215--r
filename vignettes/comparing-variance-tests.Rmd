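---
title: "Comparing tests for homogeneity of variances in methylation data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing tests for homogeneity of variances in methylation data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varhom)
```

## The problem

Most differential-methylation analyses ask whether the *mean* methylation
level of a CpG site differs between diseased and non-diseased subjects.
A complementary question is whether the *variance* differs: differentially
variable sites have been linked to cancer and other complex diseases, where
epigenetic dysregulation manifests as heterogeneous, stochastic changes in
a subset of cases rather than a uniform mean shift.

Formally, for each site we test H0: &sigma;&sup2;_d = &sigma;&sup2;_n
against a two-sided alternative, where the subscripts denote the diseased
and non-diseased populations, from m_d and m_n samples per group. The
catch is that the textbook tests for this hypothesis (the variance-ratio F
test and Bartlett's test) are exquisitely sensitive to non-normality and to
outliers — both endemic in methylation data — so the choice of test
materially changes which sites are called differentially variable.

`varhom` implements seven candidate tests behind one dispatch point,
`run_test()`, plus the simulation and evaluation machinery needed to
compare them.

## The seven tests

* **F** — ratio of the two unbiased sample variances (diseased group in
  the numerator; the two-sided p-value doubles the smaller tail, so the
  orientation is immaterial). Exact under normality, fragile otherwise.
* **Bartlett** — the classical k-group chi-squared generalisation of F.
  For two groups its p-values are rank-identical to F's.
* **Levene / L.trim / BF** — one-way ANOVA F statistics computed not on
  the raw values x_ik but on transformed values z_ik = |x_ik − c|, where c
  is the within-group mean (Levene), 10%-per-tail trimmed mean (L.trim),
  or median (BF, the Brown-Forsythe test). A group difference in mean
  absolute deviation is evidence of a variance difference; robust centers
  buy robustness to heavy tails and outliers.
* **PO.AD / PO.SQ** — empirical-Bayes moderated t statistics on the
  absolute (AD) or squared (SQ) deviations from the within-group mean.
  Per-site residual variances of the deviations are shrunk toward a prior
  variance s0&sup2; with prior degrees of freedom d0, both estimated
  across all sites, and the t reference distribution gains d0 degrees of
  freedom. These are the two tests proposed specifically for methylation
  arrays, where the number of sites is large and per-site sample sizes
  small.

The moderated-t machinery is implemented in the package
(`fit_fdist()`, `squeeze_var()`, `moderated_t_table()`): hyperparameters
come from closed-form moment matching on the log variances, with the
trigamma inversion done by Newton iteration (tolerance 1e-8, at most 100
iterations); a non-positive dispersion estimate clamps d0 to infinity, in
which case the reference law is normal. The test suite cross-checks every
statistic against independent references (`stats::var.test`,
`stats::bartlett.test`, `car::leveneTest`, `limma::eBayes`) — those
packages are oracles, not the implementation, because the vectorised
implementation is what makes grid-scale simulation affordable.

## What the generators emulate

### Fixed-distribution scenarios (`simulate_study1`)

Each site x subject value is drawn i.i.d. from a per-group distribution
chosen from three families — normal, t, chi-squared — crossed with four
regimes (equal/different means x equal/different variances). The
non-normal families use non-central t and chi-squared members so that a
mean shift can be imposed with or without a variance shift; for example
the "different mean, equal variance" chi-squared pair is &chi;&sup2;_2
(mean 2, var 4) versus non-central &chi;&sup2;(df 1, ncp 0.5) (mean 1.5,
var 4). `scenario_distributions()` returns the full grid and `dist_moments()` its
closed-form moments; the tests verify each printed (mean, variance)
annotation both analytically and by 10^6-draw Monte Carlo.

### Hierarchical variance model (`simulate_study2`)

On the M-value scale (M = log2(&beta;/(1−&beta;)), `beta_to_m()`), each
site's group variance is latent: &sigma;&sup2; ~ scale-inv-&chi;&sup2;(d0,
s0&sup2;), i.e. d0·s0&sup2;/&chi;&sup2;_{d0}. Given the variance, subject
values are normal with group means +2 (cases) and −2 (controls). Defaults
are d0 = 20 and s0&sup2; = 0.64 for both groups (the null); the
alternative raises the case-group scale to 1.5. A non-normal variant emits
conditionally chi-squared values whose real-valued degrees of freedom are
the latent draw (realised through the gamma(shape = v/2, scale = 2)
representation). The chi-squared emission is generated literally — its
group means are whatever the latent degrees of freedom imply — because the
±2 means are defined for the normal emission; a `recenter` flag is
available but off by default. Under the null the per-group sample
variances satisfy s&sup2;/s0&sup2; ~ F(d_g, d0) marginally, which the test
suite asserts by a Kolmogorov–Smirnov comparison at 10,000 sites.

### Outliers

`inject_outlier()` reproduces the contamination protocol of the study:
the global maximum of the pre-injection matrix is computed once, and at
every site the value of one diseased subject is replaced by that maximum.
The replaced subject is the first diseased column by default — a fixed
choice made for reproducibility, since the protocol does not name one —
with a per-site uniform choice available. Injection happens after the full
matrix is generated, so the maximum is the clean-data maximum.

### Seeding

Every generator takes an explicit integer seed and consumes the R stream
in a fixed site-major order (case block first). This makes datasets
byte-reproducible under a fixed seed and, for the fixed-distribution
generator, lets `n_sites` grow without perturbing earlier sites. We did
not adopt counter-based per-site streams: base R's generator has no cheap
splitting, and the ordered-stream design achieves the reproducibility
that matters here. Replicate datasets inside `run_comparison()` use
consecutive seeds from a root seed, and all tests are run on the same
simulated matrices so that per-dataset rates are paired across tests.

### What the generators do not emulate

Sites are independent (fixed-distribution scenarios) or marginally
correlated only through the shared variance prior (hierarchical model);
real arrays have spatially and biologically correlated probes, batch
structure, and beta-value boundary effects that none of this captures.
Passing the simulation-based tests therefore says the tests behave as
expected under these stylised conditions, not that any of them is
uniformly best on real data.

## Evaluating the tests

For a scenario, `run_comparison()` estimates per-dataset rejection
proportions at &alpha; = 0.05 (type I error on null datasets, power on
alternative ones; a site counts as significant when p < 0.05, strictly).
`test_type1_bound()` then tests H0: type I error &le; 0.05 with a
one-sided one-sample t test across the per-dataset rates — the procedure
only says "based on the 100 simulated data sets", and the t test is the
natural choice at that replication; an exact binomial test on the pooled
rejection count is available as an option. Tests whose bound is rejected
at 0.05 are excluded from the power ranking (`rank_powers()`, missing
rank); the rest are ranked ascending in power with average ranks for ties,
so a *higher* median rank reads as *more powerful* — the rank direction is
our choice, made so the summary plot reads naturally. `summarize_ranks()`
condenses a scenario grid into the per-test pair (m, n_reject): the median
rank over ranked scenarios and the number of scenarios with an inflated
type I error. `plot_rank_summary()` draws the classic scatter: good tests
sit low and right.

The full grid (`study_scenarios()`) has 48 scenarios: 3 families x 2
mean-regimes x 2 outlier settings x 3 sample sizes (20, 50, 200 per
group), plus 2 emissions x 2 outlier settings x 3 sizes for the
hierarchical model. Each pairs a null spec with an alternative spec. The
study conditions are 100 datasets of 1000 sites per spec; the packaged
acceptance test runs the grid at 20 datasets per spec, which keeps the
whole suite to minutes while leaving the qualitative ordering — F,
Bartlett, Levene and PO.AD reject the type-I bound in many more scenarios
than L.trim, BF and PO.SQ — far from its decision boundary.

## Discovery and validation across cohorts

`discovery_report()` reproduces the two-cohort design used for real data:
run a test over the discovery cohort, call sites with
Benjamini–Hochberg-adjusted p < 0.05 significant, then re-run the test on
the independent validation cohort and count discovered sites with
unadjusted p < 0.05 as validated. The validation run always covers the
full matrix (the moderated-t tests borrow strength across all sites, so
restricting to the discovered subset would change them). The report also
counts, per test, how many significant sites contain outliers by the IQR
fence rule — any subject more than 1.5 IQR outside its own group's
quartiles, strict inequalities — and how many of those recur as
outlier-bearing in the validation cohort. Quartiles use linear
interpolation (R's default type 7), exposed as a parameter since the rule
is convention-sensitive only for values essentially on the fence.
Applying the workflow to real cohorts (e.g. public GEO methylation
series) requires the user's own downloaded, QC-ed matrices via
`read_methyl_matrix()`; the packaged checks validate the workflow on
synthetic cohort pairs (`make_discovery_validation_pair()`) with known
truth instead.

## Numerical and design choices

* Degenerate sites (no within-group spread of the working values in
  either group, means equal) report statistic 0, p = 1 and a flag: no
  evidence against equal variances, and no NaNs reaching rate estimates.
  A zero-variance group *with* separated means is the opposite limit and
  reports p = 0. Degenerate p-values of 1 count as non-significant.
* Medians are midpoint medians for even n; the L.trim trim fraction
  defaults to 0.10 per tail and is exposed.
* The PO deviations are centered on the within-group mean, as in Phipson
  and Oshlack's DiffVar construction (the overall mean is the other
  commonly seen choice and can be obtained through `center_deviations()`
  directly). DiffVar's optional leave-one-out small-sample adjustment of
  the deviations is not applied; the moderated t acts on the plain
  group-centered deviations.
* `fit_fdist()` clamps d0 to infinity when the log-variance dispersion is
  at or below its sampling floor; exactly constant variances return the
  common value as s0&sup2;. d0 is never truncated or rounded otherwise.
* BH adjustment delegates to `stats::p.adjust(method = "BH")`; the test
  suite holds it against a brute-force double-loop implementation of the
  step-up definition.

## Problem sizes used by the packaged checks

Closed-form moment checks are exact; Monte-Carlo corroborations use 10^6
draws. The hierarchical-mean check uses one dataset of 1000 sites x 200
subjects per group. Type-I and power checks in the test suite use 20-30
datasets of 1000 sites; the acceptance script (`scripts/acceptance.R`)
uses the full 100 datasets per scenario. The grid-wide ordering check runs
all 48 scenarios at 20 datasets per spec. These sizes are the package's
trade-off between replication and turnaround; every threshold they assert
is met with a wide margin at these sizes.

## Known limitations

* Two groups only for the deviation-based tests (Bartlett accepts k > 2
  as its classical definition requires); no covariates, pairing, or
  sandwich variants.
* The simulators do not produce correlated neighbouring sites or
  beta-scale data; power estimates for chi-squared-family data are low
  across all seven tests, and transformation of such data is advisable
  rather than reliance on any of them.
* p-values of the moderated tests assume the deviations are approximately
  independent and normal within a site, which group-centered deviations
  violate mildly (they are correlated by construction); this is the known
  caveat behind the PO.AD inflation visible in the evaluation.
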