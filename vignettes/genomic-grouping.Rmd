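---
title: "Genomic grouping of myeloid neoplasms: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic grouping of myeloid neoplasms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mngroups` implements a genomics-first analysis of myeloid neoplasms (MN):
patients are clustered from binary mutation/cytogenetic profiles with a
Dirichlet-process (DP) mixture, the resulting genomic groups are
characterised, mutation acquisition order is inferred from variant allele
fractions, and survival risk is stratified. This vignette is the package's
account of the underlying science: the models, their assumptions, the
tunable parameters, and the choices made where the design was genuinely
open.

## 1. From cohort tables to a feature matrix

The unit of analysis is a cohort of patients, each with pathogenic variant
calls (gene, VAF, somatic/germline) and coded cytogenetic events. The binary
feature matrix has one column per gene with at least one pathogenic variant
in the cohort and one per observed cytogenetic event; a cell is 1 if the
patient carries the lesion. Three conventions matter:

* **Pathogenic-only.** Variants of uncertain significance never enter the
  matrix; the pathogenicity flag is consumed, not computed.
* **Germline variants are kept** as features (a germline DDX41 lesion is
  group-defining) but excluded from clonal ordering, where a VAF near 0.5
  says nothing about acquisition time.
* **Prevalence filter.** Features are retained only if *strictly more than*
  a fraction `threshold` (default 1%) of patients carry them. Strictness
  matters at the boundary: with 1585 patients, 16 carriers (1.0095%) is
  retained, 15 (0.946%) is not.

Patients whose filtered row is all zero carry no analysable lesion; they are
set aside as the `DP0` ("no abnormality") group and re-attached after
clustering. In real MN cohorts this pool is dominated by aplastic anemia and
hypoplastic MDS.

Karyotypes are accepted either as pre-coded event tokens or as ISCN-like
strings parsed by a deliberately small tokenizer (`parse_karyotype()`). The
17-event vocabulary pools whole-arm losses with their partial deletions
(`-7/7q-`), but keeps two clinically distinct splits: der(1;7) — which
produces 1q gain and 7q loss yet behaves better than -7/7q- — is its own
code, and del(5q) is split into isolated versus non-isolated forms.
"Complex" is defined as three or more distinct clonal abnormalities, the
standard cytogenetics convention; unrecognised tokens are logged, ignored as
features, but still counted toward complexity.

## 2. The Dirichlet-process mixture

Within a group, features are modelled as independent Bernoulli draws:

$$ x_{ij} \mid z_i = k \sim \text{Bernoulli}(\theta_{kj}), \qquad
   \theta_{kj} \sim \text{Beta}(1, 1), $$

with a DP prior over the partition $z$ (concentration $\alpha$). The flat
(non-hierarchical) DP mixture is the minimal model consistent with the
analysis goal; a hierarchy over disease strata would presume the clinical
labels the method is trying to transcend.

**Inference** is collapsed Gibbs sampling: $\theta$ is integrated out, so a
patient joins an existing cluster with weight $n_k L_k(x)$ — where
$L_k$ uses the Beta posterior means $(c_{kj}+1)/(n_k+2)$ — or opens a new
cluster with weight $\alpha (1/2)^d$. The concentration is resampled each
sweep by the Beta auxiliary-variable Gamma-mixture update under a
Gamma(1, 1) prior (a fixed-$\alpha$ mode exists, and a prior-only mode used
to verify the sampler against the Chinese-restaurant-process closed form
$E[K] = \sum_{i=1}^n \alpha/(\alpha + i - 1)$).

**Initialisation is a first-class choice.** With $d \approx 53$ features,
the new-cluster weight contains $(1/2)^{53} \approx 10^{-16}$: single-site
updates essentially never open a new cluster, so a chain started from one
big cluster cannot split it, no matter how long it runs. Merging, by
contrast, mixes well. The default therefore starts *over-split*: a
deterministic Ward agglomeration on binary distance cut at
$\min(n, 30)$ clusters, which the sampler then purifies and merges.
Split-merge moves were deliberately not added; they would improve mixing
further but cost the simplicity and seedability of the single-site sampler.

**Summarisation.** Retained post-burn-in, thinned partition samples give the
posterior similarity matrix (PSM) $\text{psm}_{ij}$ = co-clustering
frequency; the reported partition is the sampled one minimising the summed
squared deviation from the PSM (Dahl's least-squares criterion, ties to the
earliest sample). This avoids ad-hoc relabelling and is invariant to
within-sample label permutations.

**Group naming.** Recovered clusters are labelled `DP1..DPk` by decreasing
size — numbers carry no meaning. Each cluster is then matched to a
*canonical identity* via its enrichment-ranked features (JAK2 group, CALR
group, TP53/complex group, NPM1 group, SETBP1 group, TET2/SRSF2 group,
U2AF1/+8/RUNX1 group, CBL/ETV6/KMT2D group, SF3B1/DDX41 group, 1q+/der(1;7)
group). Several clusters may share an identity; a cluster matching no
signature gets `NA` and is excluded from risk-category analyses.

**New-patient assignment** (`predict`) is posterior-predictive: each fitted
group scores the new feature row with size-weighted products of its
per-feature posterior means, against a new-cluster alternative weighted by
the posterior mean $\alpha$. The patient is assigned when the best group's
share of (best + new-cluster) mass reaches `confidence` (default 0.9),
otherwise `"unassigned"`; all-zero rows are `DP0`. The confidence rule is
artifact-defined — the underlying study reports an assignment *rate* but not
its rule — and 0.9 was chosen so that clearly profiled patients assign while
genuinely novel profiles abstain.

Defaults: `iterations = 2000`, `burn_in = 1000`, `thin = 10` (200 retained
samples). On the default synthetic cohort (1359 eligible × 53) a fit takes
a few seconds (compiled sampler); the defaults leave a comfortable margin of
effective samples for the PSM while keeping desk-scale runtime.

## 3. Association testing

All unordered feature pairs are tested with the two-sided Fisher exact test
under the minimum-likelihood convention (the sum of hypergeometric
probabilities no larger than the observed table's). FDR is controlled by
Benjamini–Hochberg across *all* tested pairs as one family — the most
conservative reading when the family definition is unstated. Pairs with
$q < \alpha$ (default 0.05, configurable) are labelled by the direction of
the odds ratio; the Haldane–Anscombe +0.5 correction is applied only when a
cell is zero, keeping typical tables unbiased while bounding the estimate.

## 4. Network structure

The dependency structure among lesions is learned by hill climbing over
DAGs with the decomposable BIC score (Bernoulli likelihood per parent
configuration, penalty $2^{|\text{parents}|}/2 \cdot \log n$), max
in-degree 3, add/delete/reverse moves, and 10 randomised restarts — the
conventional defaults of score-based discrete structure learning. Edge
*directions* from observational binary data are generally not identifiable;
only the skeleton should be interpreted, and the package exposes
`dag_skeleton()` for exactly that reason.

## 5. Clonal ordering

Within a patient, a mutation present in more cells was, under a simple
accumulation model, acquired earlier. VAF converts to clonal fraction as
$cf = \min(1, 2 \cdot \text{VAF})$ — exact for heterozygous autosomal
variants, biased for CNV-affected or X-linked loci (copy-number-aware
correction is out of scope). For every unordered pair of somatic pathogenic
mutations in a patient, a win is recorded for the larger clonal fraction
unless the gap is `tie_margin` (default 0.05) or less; near-ties are
order-uninformative noise and are dropped.

The resulting comparisons feed a Bradley–Terry model,
$P(a \text{ beats } b) = e^{s_a}/(e^{s_a}+e^{s_b})$, fitted by the classical
MM iteration to relative tolerance $10^{-8}$ with abilities mean-centred
(the likelihood is shift-invariant). For every observed pair, `ridge = 0.5`
pseudo-wins are added in both directions: with small per-group cohorts,
perfect separation (a gene that never loses) is common and would push the
MLE to infinity. Fits are produced per genomic group and pooled; groups with
fewer than `min_comparisons` usable records are skipped rather than
over-interpreted.

## 6. Survival and risk stratification

Overall survival runs from diagnosis to death or last follow-up; patients
undergoing stem-cell transplantation (HSCT) are censored at transplant in
the primary analysis (`censor_at_hsct = TRUE`), since post-transplant
survival reflects a different process. Kaplan–Meier curves carry Greenwood
standard errors; the five-year rate is the step-function value at $t = 5$;
the median is the first time $S(t) \le 0.5$ (the standard convention). For
groups whose curve never reaches 0.5, the restricted-mean survival time
(area under the curve to a configurable horizon) is the "estimated survival"
summary. Cox models use Efron tie handling. The multivariate model follows a
univariate screen: covariates with univariate $p < 0.05$ enter alongside the
risk categories.

The six-tier risk mapping is fixed by group identity: DP1, DP5 → very
favorable; DP8, DP10 → favorable; DP3, DP6 → intermediate; DP4 → adverse;
DP2, DP7, DP9 → very adverse; DP0 → no-abnormality reference. It is applied
to the *canonical* identities, never to the size-ranked cluster numbers.

## 7. The synthetic cohort generator

Patient-level data for this kind of MN cohort are not publicly available,
so the package ships a generator that emulates the cohort's published
structure and serves as the test bed:

* 1585 patients in 11 groups with the published sizes (456, 148, 118, 21,
  40, 93, 177, 35, 224, 47, 226);
* per-group feature probabilities: dominant drivers at 0.6–0.95,
  secondaries lower (e.g. der(1;7) at its published 33% within the 1q
  group), all other features at a background 0.02; DP0 carries nothing;
* DDX41 carriers in the SF3B1/DDX41 group flagged germline with
  probability 0.461, calibrating the cohort-wide germline-DDX41 rate to the
  published 3.9%;
* survival exponential per group with rate $-\log(s_5)/5$, so the true
  five-year survivor function equals the published per-group rate; an
  independent exponential censoring time matched to `censor_rate` (0.25)
  and transplant times drawn uniformly before end of follow-up at the
  published per-group transplant rates;
* VAFs encode a planted acquisition order: the $i$-th driver (1-based) gets
  $cf = 0.9 - 0.15(i-1) + N(0, 0.05)$ clipped to (0.02, 1), $\text{VAF} =
  cf/2$; non-driver mutations are subclonal, $cf \sim U(0.1, 0.5)$;
* group sizes are allocated exactly (not multinomially) so structural
  checks are deterministic, and the planted truth (group, order) is emitted
  as a sidecar never read by analysis stages.

Exact driver probabilities are the package's own reconstruction — the
published record anchors sizes, driver identities, survival and transplant
rates, but not per-group probability profiles. Two idealisation are
acknowledged: features are independent *within* groups, which matches the
mixture likelihood and is therefore favourable to the clusterer (a pairwise
feature-correlation switch exists for robustness experiments), and
exponential survival has unrealistically long tails for near-1 five-year
rates even though the five-year window — the quantity all calibrations use —
is exact. Passing recovery tests on this generator shows the estimators
work under the stated conditions; it cannot show robustness to the
correlated, copy-number-distorted features of real cohorts.

A companion validation configuration (150 patients: 143 in the published
validation-cohort proportions plus 7 deliberately atypical mixed profiles)
exercises the new-patient assignment workflow end to end.

## 8. Numerical choices and degenerate inputs

* Fisher p-values are clamped to $[0,1]$ (the underlying implementation can
  overshoot by floating-point error); the empty table tests as $p = 1$.
* Bradley–Terry MM stops at relative ability change $< 10^{-8}$ or 10 000
  iterations, whichever first; convergence is reported, not assumed.
* Cox fits cap Newton iterations at 100 and warn on suspected
  non-convergence or monotone likelihood rather than failing.
* Dahl ties break to the earliest sample; ranking ties in acquisition order
  break alphabetically — both for reproducibility.
* Sub-seeds for pipeline stages are derived from the master seed and the
  stage name, so adding a stage never silently shifts another stage's
  stream.
* Empty clusters are removed eagerly in the sampler; identical patients
  collapse to one cluster; a feature matrix with zero features is rejected.

## 9. Test problem sizes

The shipped tests run the full default cohort (1585 × 53) once for the
recovery suite, exhaustively enumerate all 46 376 two-by-two tables with
$n \le 30$ against an independent Fisher oracle, use 50 000-patient
simulations for Kaplan–Meier recovery, 5 000 per arm for Cox recovery, and
20 replicate cohorts of 150 for acquisition-order recovery — sizes chosen so
the whole suite completes in a couple of minutes on one core while keeping
Monte-Carlo error well inside the asserted tolerances.

## 10. Known limitations

* Feature independence within components; no modelling of lesion
  co-occurrence beyond what the partition induces.
* No split-merge or tempered moves: very flat clusters (many weak lesions)
  can merge irrecoverably; the over-split initialisation mitigates but does
  not eliminate this.
* Clonal fractions ignore copy number, purity and X-linkage; cytogenetic
  lesions (no VAF) cannot enter the ordering.
* Edge orientations in the learned network are not causally interpretable.
* The risk mapping is fixed; it applies to cohorts whose groups genuinely
  correspond to the canonical identities, and `NA`-identity clusters are
  deliberately left unstratified.
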