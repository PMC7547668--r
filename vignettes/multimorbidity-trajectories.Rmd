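---
title: "Modelling five-year multimorbidity trajectories with an absorbing-state hidden Markov model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling five-year multimorbidity trajectories with an absorbing-state hidden Markov model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmtraj)
```

## The problem

Elderly primary-care populations are dominated by multimorbidity — the
coexistence of two or more chronic diseases. Cross-sectional cluster
analyses describe which diseases co-occur, but not how people move between
morbidity profiles as they age, drop out of the health system, or die.
`mmtraj` implements a longitudinal pipeline for closed annual cohorts
(everyone enrolled at baseline, no new entries): each person contributes up
to T = 5 yearly feature vectors (chronic-disease indicators, age, visit and
drug counts), and the population is modelled as a hidden Markov process
whose hidden states are multimorbidity patterns, extended with two
*absorbing* states for dropout and death.

The pipeline has six stages, each exposed as ordinary functions and
orchestrated by `run_pipeline()`:

1. **Synthetic cohort generation** (`generate_cohort()`) with known ground
   truth, so every later stage can be validated without access to any
   clinical registry.
2. **Feature reduction** (`filter_rare_diseases()`, `assemble_features()`):
   diseases under 2% baseline prevalence are removed; continuous features
   go through PCA, categorical features (disease flags, sex) through MCA.
3. **Fuzzy C-means** (`fcm_fit()`) on baseline rows, providing initial
   cluster memberships.
4. **HMM fitting** (`init_hmm_from_fcm()`, `baum_welch()`,
   `fit_with_restarts()`): Baum-Welch over many short independent
   sequences, absorbing rows frozen, best of several restarts kept.
5. **Decoding and validation** (`viterbi_decode()`, `transition_summary()`,
   `validate_bw_vs_decoded()`).
6. **Pattern characterization and mortality**
   (`compute_profile()`, `describe_clusters()`,
   `build_survival_records()`, `hazard_table()`).

## The generative model behind the synthetic cohort

`cohort_config()` describes a cohort of `n_persons` with `C` latent disease
clusters and two absorbing states (dropout = state C+1, death = C+2):

* The baseline cluster is drawn from `init_probs`; each subsequent year the
  state moves by the row-stochastic `annual_transition` matrix, whose last
  two rows are exact one-hot self-loops. A per-cluster mortality offset
  multiplies the death-transition probability before the draw (the row is
  renormalized), so the generator carries known ground-truth hazards for
  the survival stage.
* Chronic-disease flags are **monotone**: the year-0 cross-section is
  Bernoulli with the cluster's prevalence profile, and a disease, once
  diagnosed, never resolves. Incidence in later years is
  `annual_incidence_factor` times the current cluster's prevalence
  (default 0.1/year; 0 freezes the baseline flags). This mirrors chronic
  diagnoses, which accumulate rather than remit, and it has a structural
  consequence for identifiability discussed under *Limitations*.
* Visit and drug counts are Poisson with cluster-specific rates. The
  defaults span per-cluster means of roughly 6–18 visits and 3–8 drugs —
  the range of per-pattern medians reported for elderly primary-care
  cohorts — so that sicker clusters are also heavier users of care.
* Ages advance deterministically by one year; sex is Bernoulli;
  socio-economic quintiles are uniform with 7% missingness by default
  (MCAR; an MAR mode ties missingness to the baseline cluster for
  imputation stress-tests).
* Persons absorbed in year t contribute a terminal observation at year t
  (status `dropped`/`dead`) and nothing afterwards.

Because diseases are conditionally independent given the cluster, the
generator reproduces the *first-order* structure a pattern analysis assumes
(block-structured prevalence, diagonal-dominant dynamics, absorbing
events) but not within-pattern disease correlation beyond cluster
membership, coding artefacts, or care-seeking feedback. Passing tests on
these panels therefore validate the estimation machinery, not any clinical
claim about real cohorts.

## Feature reduction

Continuous features (age, visits, drugs) are centred, scaled to unit
variance and projected by PCA. Categorical features are expanded into a
complete indicator matrix and decomposed by correspondence analysis (MCA);
row principal coordinates are the scores. Both maps are fitted on the
pooled active person-years of all waves by default, so every year lives in
a single space — the HMM needs a common emission space — with a `year0`
option for fitting on baseline only. Component counts default to 2 + 2 in
the bundled configurations; fractional arguments request the smallest
number of components reaching a variance (PCA) or above-average-axis
inertia (MCA) target instead.

Three numerical conventions matter:

* **Sign convention.** Each component is flipped so its largest-magnitude
  loading is positive, making scores bit-stable across runs.
* **Score standardization** (`scale_scores = TRUE`). MCA principal
  coordinates have variances equal to their (small) inertias, an order of
  magnitude below standardized PCA scores; without rescaling, Euclidean
  clustering effectively ignores the disease dimensions. Every retained
  score is therefore standardized to unit variance over the fitting rows.
  The diagonal-Gaussian HMM is invariant to this per-dimension scaling;
  fuzzy C-means and k-means are not, which is the point.
* **Standardizing continuous features before PCA** is a choice, not a
  necessity; it is the default because visit counts would otherwise
  dominate age on raw scale.

## Fuzzy C-means initialization

`fcm_fit()` minimizes the fuzzified within-cluster sum of squares with the
canonical fuzzifier m = 2, k-means++-style seeding and five seeded starts
(single random starts were observed to split large clusters). The
memberships of the baseline rows initialize the HMM: initial probabilities
are membership column means, emission moments are membership-weighted, and
the transition matrix starts diagonal-dominant (self-transition 0.8, 0.02
to each absorbing state, remainder spread uniformly) — fitting re-estimates
all of it, so the initial transition values only need to be in the right
regime. How fuzzy memberships should shape the initial emission
distributions is not canonical; weighted first and second moments are used
here and documented as such.

## The absorbing-state HMM

The state space has K = C + 2 states. Disease clusters emit
diagonal-covariance Gaussians on the reduced feature space — the
FCM-on-PCA/MCA pipeline implies a continuous emission space, and diagonal
Gaussians keep the M-step closed-form. Dropout and death are *observed*
events, not latent ones: their emission is an indicator on the recorded
status, their transition rows are frozen at exact one-hot self-loops, and
their initial mass is structurally zero (cohort entry required surviving to
the index date). Mass *into* the absorbing states from living clusters is
re-estimated; a switch to freeze it is deliberately not offered because the
recorded events are informative about exactly those rates.

`baum_welch()` runs EM over all person-sequences at once (scaled
forward-backward, vectorized across persons), treating sequences as
independent. The total log-likelihood is checked to be non-decreasing at
every iteration (tolerance 1e-8); fitting stops at a relative improvement
below `tol` (1e-6) or `max_iter` (500). `fit_with_restarts()` runs the
FCM-derived initialization verbatim plus seeded jitters of it and keeps
the highest final log-likelihood, mirroring multi-restart practice for
short panel sequences; restart counts of 5–10 are used at desk scale.

**The variance floor is a model choice, not a numerical afterthought.**
MCA scores of binary profiles are quasi-discrete: thousands of persons
share identical indicator patterns and hence identical scores. An
unconstrained Gaussian mixture gains unbounded likelihood by collapsing a
component onto such an atom (observed in development: variances of ~7e-4
and a log-likelihood some 15,000 nats above any clinically meaningful
solution, with cluster recovery destroyed). Emission variances are
therefore floored at 5% of a dimension's overall variance, which removes
the degenerate maxima while leaving genuine clusters (within-cluster
variances of 10–100%) untouched.

`viterbi_decode()` returns each person's most probable state path; ties
break toward the lowest state index. Decoded absorbing states coincide
with observed events by construction. `transition_summary()` tabulates
either annual transitions or each person's baseline-versus-final state;
absorbed persons persist in their absorbing state through the horizon, so
absorbing rows are one-hot in both modes. `validate_bw_vs_decoded()`
contrasts the fitted transition matrix with decoded annual proportions —
on data simulated from the fitted model the maximum absolute difference is
a few thousandths, the model-validation analogue of comparing theoretical
and observed transition values.

## Pattern profiles

For the persons active (not absorbed) in a year, `compute_profile()`
reports per cluster and disease the within-cluster prevalence O, the
overall prevalence, their ratio (O/E), and exclusivity — the share of all
patients with the disease who sit in the cluster. A disease belongs to a
pattern when O/E ≥ 2 (the conventional over-representation cut-off).
Absorbed persons are excluded from denominators because they no longer
contribute observations; a `baseline` denominator mode keeps the year-0
cohort classified by baseline cluster instead. O/E for a disease with zero
overall prevalence in a year is reported as `NA`, never infinity. Two
identities are enforced by tests: exclusivity sums to 100% over clusters
for every disease-year, and the cluster-size-weighted mean of O equals the
overall prevalence, so the weighted mean O/E is 1. Cluster naming is left
to the user; `top_diseases()` emits the highest-O/E diseases per cluster
as naming evidence.

## Mortality by baseline pattern

`build_survival_records()` turns the decoded panel into one record per
person: death in year t maps to continuous time t − 0.5 (mid-year
convention, switchable to year-end), dropout censors at the dropout year,
survivors at the horizon. `fit_cox()` fits the Cox proportional-hazards
model with cluster 1 as reference — unadjusted, or adjusted for baseline
age, sex and SES quintile — using Breslow tie handling by default (the
panel's annual grid makes ties pervasive; Breslow is closed-form and
oracle-checkable, Efron is available). Covariates aliased in a given
dataset (a decoded clustering can coincide with sex on small panels) are
dropped with a warning rather than failing the pipeline.

Missing SES is handled by chained-equation multiple imputation
(`impute_chained()`, m = 7 by default): each imputation refits a
proportional-odds model for SES on age, sex, baseline cluster, the event
indicator and a Nelson-Aalen cumulative-hazard proxy on a bootstrap
resample of the complete rows — the bootstrap approximating a posterior
parameter draw — and draws the missing quintiles from the fitted
conditional distribution. With one incomplete variable the chained cycle
reduces to this single conditional model. `pool_rubin()` combines the
per-imputation log-hazard estimates: total variance =
within + (1 + 1/m)·between, confidence intervals from a t reference with
the classical degrees of freedom. `hazard_table()` emits the unadjusted,
complete-case-adjusted and MI-adjusted columns side by side.

## Problem sizes and reproducibility

The bundled demonstration configuration uses N = 2000 persons, C = 3
clusters, D = 20 diseases and T = 5 waves with 5 restarts — sizes at which
the whole pipeline (simulation through pooled hazards) runs in well under
a minute on a single CPU while leaving every estimate stable to the third
digit. Parameter-recovery checks use panels simulated from known HMM
parameters (N = 2000) and recover transition entries within 0.05 and
initial probabilities within 0.03 after label alignment. A single global
seed derives all stage seeds; `run_pipeline()` writes a manifest with
parameter hashes and per-file MD5 sums, and reruns are bit-identical.

## Limitations

* **Cumulative flags cap dynamic identifiability.** Chronic diagnoses
  never resolve, so a person's disease profile encodes their *history* of
  clusters, not their current one; consecutive-year emissions are
  correlated beyond the hidden state. On generator panels whose only
  state signal is the disease profile, fitted self-transition
  probabilities are biased upward by roughly +0.08 and exact transition
  recovery is unattainable *by design of the data*, not by a defect of the
  fitter — recovery to within 0.05 holds when emissions follow the model
  (per-year utilization signals, or data simulated from known
  parameters). Real EHR panels share this property; decoded transition
  tables should be read as descriptions of the decoded paths, which is
  how they are reported.
* The generator assumes conditional independence of diseases given the
  cluster; real patterns carry residual correlation.
* Only SES is imputed; the imputation model assumes missingness at random
  given the included predictors.
* Time-homogeneous transitions over five waves; no covariate-dependent
  dynamics, competing-risks structure, or semi-Markov dwell times.
* Model selection across the number of clusters C is exposed (fit at
  several C and compare likelihoods/BIC externally) but deliberately not
  automated.
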