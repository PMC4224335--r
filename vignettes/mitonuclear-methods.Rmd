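---
title: "Mitonuclear stratum association analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mitonuclear stratum association analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitonuclear)
```

## The scientific question

Most oxidative-phosphorylation complexes are chimeras of mitochondrially
encoded and nuclear-encoded subunits, so the two genomes must coevolve: a
variant in a nuclear subunit may be neutral on one mtDNA background and
deleterious on another. `mitonuclear` implements the statistical machinery
for testing that idea in a case-control cohort. Each subject carries a
*mitonuclear genotype*: the combination of their mtDNA haplogroup cluster
(here the four common European clusters HV = H+V, UK = U+K, JT = J+T,
IW = I+W+X+N1) and their diploid genotype at a biallelic nuclear variant
(here the NDUFC2 L46V coding SNP rs8875, alleles C and G). Four clusters
crossed with three genotypes give twelve strata; the question is whether
disease risk (type 2 diabetes in the motivating cohort of 1,118 Ashkenazi
Jewish patients and 359 controls) differs across the joint strata even when
neither margin shows an effect on its own.

The package ships the published summary tables of that cohort as plain-text
fixtures (`load_fixture()`), a deterministic expander that turns any stratum
count table back into an individual-level cohort (`expand_counts()`), and a
simulator (`simulate_cohort()`) whose defaults are those study conditions,
so the whole pipeline is exercisable and testable without any data access.

## Stage 1: marginal independence tests

`g_test()` implements the likelihood-ratio test of independence for an
R x C contingency table,

$$G = 2 \sum_{ij:\,O_{ij}>0} O_{ij}\,\ln\frac{O_{ij}}{E_{ij}},\qquad
E_{ij} = \frac{O_{i\cdot}\,O_{\cdot j}}{O_{\cdot\cdot}},$$

referred to $\chi^2_{(r-1)(c-1)}$. Zero observed cells contribute zero (the
$x\ln x \to 0$ limit); an all-zero row or column is an error since the
degrees of freedom collapse. No correction is applied by default: the
uncorrected statistic reproduces the published cluster-margin value
(G = 3.933, df = 3) and genotype-margin value (G = 4.868, df = 2) to within
0.1%, which is also why we conclude the original analysis used the plain
statistic. The Williams small-sample correction is available behind
`williams = TRUE` for users who want it; it only shrinks G and is never
applied silently.

## Stage 2: the permutation enrichment test

The interesting signal is not in either margin but in single strata, so the
second stage asks, stratum by stratum, whether its case proportion is
extreme. With overall case proportion $\bar p$ and stratum case proportion
$p_g$, the statistic is the absolute deviation $d_g = |p_g - \bar p|$
(two-tailed by construction). The null is generated by shuffling the
disease labels over all samples: each replicate permutes the fixed multiset
of 0/1 statuses, which preserves every stratum size and the overall case
count, recomputes all the $d_g$ from the same shuffle, and the p-value of
stratum $g$ is the fraction of replicates whose deviation is *equal to or
greater than* the observed one. Ties count as exceedances, so the smallest
attainable p-value is positive in expectation and the test is valid despite
its discreteness. The default 10,000 replicates put the Monte-Carlo
standard error at $\sqrt{p(1-p)/10^4}$, i.e. about 0.0008 at p = 0.006.

Implementation notes, all visible in `permutation_test()`:

* One shared shuffle stream scores all strata per replicate (the natural
  reading of "shuffle, then recompute every stratum"); an
  independent-stream mode exists for users who want per-stratum streams,
  but it costs k times the work for no inferential gain.
* The raw estimator $b/B$ is the default, matching the published
  description; `estimator = "add-one"` gives $(b+1)/(B+1)$, which can never
  be exactly zero, for users feeding the p-values into downstream
  log-transforms.
* A shuffle of exchangeable labels depends only on the stratum sizes, so
  the engine draws the K case positions directly (`sample.int(N, K)`) and
  tabulates them per stratum; this is exactly equivalent to permuting the
  label vector and makes results invariant to the input record order.
* `seed` is a required argument and is echoed in the result object.

Because the shuffled case count of one stratum is hypergeometric, the test
has a closed-form limit: `exact_stratum_p()` sums the hypergeometric mass
over all outcomes at least as deviant as observed. It is the package's
independent oracle — every Monte-Carlo p-value is checked against it in the
test suite — and it brackets the published headline values (HV_CC:
exact 0.0058 vs printed 0.006; UK_CG: exact 0.0388 vs printed 0.036, the
latter evidently carrying the original run's own Monte-Carlo noise).

## Stage 3: logistic odds ratios against the reference stratum

The stratum flagged by stage 2 (HV_CC, depleted of cases) becomes the
reference level of a logistic regression. The twelve-level stratum factor
enters as eleven indicator variables ("dummy coding", `encode_design()`),
so each coefficient is the log odds ratio of its stratum against HV_CC and
one fit yields all eleven contrasts. `fit_logistic()` is a standard
maximum-likelihood IRLS solver: deviance-change tolerance 1e-10, at most
100 iterations, standard errors from the inverse Fisher information at the
MLE, Wald z tests, and 95% intervals $e^{\hat\beta \pm 1.959964\,SE}$
reported lower-upper. Rank-deficient designs are an error naming the
collinear columns; a coefficient walking past |15| while the deviance still
falls triggers a quasi-separation warning and a non-convergence flag — no
penalisation is applied, matching ordinary GLM behaviour. The test suite
cross-checks the solver against `stats::glm.fit` and against the 2x2
closed forms ($\hat\beta = \ln(ad/bc)$, $SE = \sqrt{1/a+1/b+1/c+1/d}$).

Sex (one indicator) and age (years, uncentred) are supported covariates
with listwise deletion of incomplete rows. The shipped fixtures are counts
only — the original cohort's individual ages and sexes are not published —
so the reproducible surface is the counts-only model. For the HV_CG
contrast the adjustment was negligible and the counts-only odds ratio
(1.586) matches the published adjusted 1.58; for other terms (e.g. UK_CG,
counts-only 1.95 vs adjusted 2.01) the gap is real and documented rather
than imitated. The simulator generates covariates precisely so that this
adjusted-vs-unadjusted gap can be studied on synthetic data.

## Multiple testing: Storey q-values

Twelve (or, with the logistic table, eleven) p-values need an FDR scale.
`qvalues()` computes the monotone Storey q-values
$q_{(i)} = \min_{j \ge i}\; \hat\pi_0\, p_{(j)}\, m / j$, with tied
p-values sharing the q of their largest rank; at $\hat\pi_0 = 1$ this is
exactly Benjamini-Hochberg (asserted against `p.adjust` in the tests).
Two estimators of $\pi_0$, the proportion of true nulls, are provided over
the default tuning grid $\lambda = 0.00, 0.05, \dots, 0.90$:

* `pi0_smoother()` fits a 3-df cubic smoothing spline to
  $\hat\pi_0(\lambda) = \#\{p > \lambda\} / (m(1-\lambda))$ and reads it
  off at the largest $\lambda$;
* `pi0_bootstrap()` picks the $\lambda$ minimising the bootstrap-estimated
  MSE around the minimum raw estimate (default 100 resamples).

Both clamp into (0, 1]. Neither is reliable at m = 12 — the raw estimates
at large $\lambda$ then rest on one or two order statistics — so the
package warns below m = 100 and the reproduction path treats the published
$\pi_0$ values (0.227 smoother / 0.208 bootstrap for the permutation
table) as fixed inputs, under which the published q-values (0.016 for
HV_CC, 0.049 for UK_CG, and 0.015 at the bootstrap $\pi_0$) are recovered
to 3 decimals. Recovering the published $\pi_0$ point estimates themselves
is *not* asserted anywhere: at m = 12 they are not robust to unstated
settings of the original computation.

## PCR-RFLP genotyping

The nuclear genotypes come from a restriction assay: a 326-bp amplicon
around the variant is digested with HpyCH4IV (recognition ACGT, cut after
the first base), which cuts only the rare-allele sequence, yielding
215 + 111 bp; the common allele stays intact. `rflp_digest()` performs the
in-silico digestion (non-overlapping left-to-right scan via
`Biostrings::matchPattern`; fragment lengths always sum to the input
length, and for palindromic motifs such as ACGT the fragment multiset is
strand-symmetric). `genotype_from_bands()` maps an observed band multiset
to a diploid call — {326} homozygous uncut, {215, 111} homozygous cut,
{326, 215, 111} heterozygous — matching each band within a 5-bp default
tolerance, a typical agarose sizing resolution; the published protocol
gives exact sizes only, so the tolerance is a package choice and is fully
overrideable. Any unexpected pattern is a missing call (`NA`), never an
error. One nomenclature wart is preserved deliberately: the source
material labels C the common variant in the assay description but
elsewhere pairs the ~0.74 frequency with the other letter; the package
treats allele letters as opaque labels and reports the major-allele
frequency (0.74 in controls) without attaching an amino acid to it.
`cluster_haplogroup()` resolves fine haplogroup labels (H1a, U5b, ...) to
the four clusters by longest-prefix matching on
{H, V, U, K, J, T, I, W, X, N1}; anything else (L3, M, ...) is a missing
cluster with a warning, because the cluster system is European-specific.

## Growth kinetics for the interaction readout

The quantitative yeast two-hybrid readout converts protein-protein
interaction strength into growth rate in selective medium. Under
exponential growth $OD_t = OD_0 \cdot 2^{t/T}$, so `generation_time()`
fits log2(OD) against time by least squares and returns $T = 1/\text{slope}$,
erroring on non-positive slopes. The default fitting window keeps points
with OD between 1.5x the first reading and 0.5x the final reading — a lag
and plateau trim — and falls back to all points when fewer than two
qualify, which is what short clean curves produce; an explicit window
always wins. `affinity_fold_change()` then compares *growth rates* (1/T,
the quantity that actually changes with interaction strength) between
mutant and wild-type replicate sets: the ratio of means is the fold
change, and a pooled two-sample Student's t-test gives the p-value. The
original raw OD data are unpublished, so the ~40% affinity drop of the
phenylalanine mutant is mirrored as a simulation property (rate ratio 0.6,
four replicates, 5% noise — detected at p < 0.05 in over 80% of runs) and
a null simulation bounds the type-I error, rather than asserting any
numeric reproduction.

## The synthetic cohort generator

`simulate_cohort()` draws from the logistic model the analysis assumes:
stratum $s$ has population frequency $f_s$ and disease odds
$\text{odds}_0 \cdot OR_s$, i.e.
$\text{logit}\,P(\text{case}) = \log \text{odds}_0 + \log OR_s
(+ \beta_{sex} + \beta_{age}\,\text{age})$. Two sampling designs:

* **population**: N subjects, stratum from $f$, status Bernoulli from the
  logit — the design under which prevalence means something;
* **case-control** (default, because the motivating study is one): the
  case and control counts are fixed and each subject's stratum is drawn
  from the status-conditional distribution given by Bayes' rule,
  $P(s\,|\,\text{case}) \propto f_s p_s$ and
  $P(s\,|\,\text{control}) \propto f_s (1-p_s)$.

Defaults are the study conditions: the twelve strata at their observed
total frequencies, 1,118 cases and 359 controls (the sample case
proportion 0.757 is a design artefact, not a prevalence), ages
N(65.8, 8) for cases and N(69.7, 8) for controls, sex a fair coin, and a
baseline odds of 3 reflecting the case-heavy design. In population mode a
single N(69.7, 8) age distribution (the control/background values) is used
since status-conditional ages are not defined before status is drawn.
Covariates are generated but ignored by the counts-only analyses, which is
exactly what makes the adjusted-vs-unadjusted comparison testable. The
generator does **not** emulate linkage disequilibrium, haplotype phase,
population substructure, genotyping error, or age-dependent ascertainment —
so a passing test suite certifies the statistical machinery under the
stated model, not robustness of the scientific conclusion to those
real-data complications.

`expand_counts()` is the deterministic sibling: it reproduces a count
table exactly as individuals (ordered by stratum, cases first, no
covariates), and `stratify(expand_counts(T)) == T` is a tested identity.

## Numerical and design choices

* **Tie handling** is explicit everywhere ties matter: permutation
  exceedances include equality; tied p-values share the largest-rank q.
* **Degenerate inputs**: single-stratum cohorts give deviation 0 and p = 1
  (every shuffle ties) and the pipeline skips the then-undefined
  independence tests, q-values and contrasts with a warning; empty count
  tables, zero margins, impossible hypergeometric counts and non-binary
  statuses are errors naming the offending input.
* **Seeds** are required arguments wherever randomness enters
  (`permutation_test()`, `simulate_cohort()`, `pi0_bootstrap()`), and all
  randomness in `run_pipeline()` flows from its single `seed`, so a rerun
  with the same configuration byte-reproduces every output file.
* **Reporting convention**: confidence intervals are stored lower-upper.
  The shipped logistic reference table originally prints them in the
  opposite order; the fixture normalises them.

## Problem sizes in the test suite

The suite checks the statistical properties at sizes chosen to keep the
whole run around two minutes while leaving the Monte-Carlo error well
inside each asserted band: the reproduction checks run the full published
design (1,477 records, 10,000 shuffles); CI coverage of a known odds ratio
uses 200 simulated cohorts of n = 5,000; null calibration of the
permutation p-value uses 500 cohorts of n = 600 at 2,000 shuffles (decile
frequency SE ≈ 0.013 against a ±0.03 band); the mixture check of the
bootstrap $\pi_0$ uses m = 2,000 over 20 seeds. Larger sizes sharpen
nothing these bands could detect.

## Limitations

The package reproduces and generalises a specific analysis design; it is
not a general epistasis scanner. The permutation test shuffles labels
unconditionally, so it does not adjust for covariates; conditional
(stratified) permutation is out of scope. The logistic stage assumes the
strata are fixed, observed categories — no uncertainty from haplogroup
calling or RFLP scoring propagates into the intervals. And at twelve
tests, $\pi_0$ estimation is intrinsically unstable; q-values computed
with an estimated $\pi_0$ at that scale should be read as descriptive.
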