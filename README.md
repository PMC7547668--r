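# mmtraj

Longitudinal multimorbidity-trajectory analysis for closed elderly cohorts
observed as annual electronic-health-record panels. `mmtraj` is aimed at
epidemiologists and biostatisticians who want to move beyond
cross-sectional disease clustering: it models each person's sequence of
yearly observations (chronic-disease indicators, age, primary-care visits,
drug counts) with a hidden Markov model whose hidden states are
multimorbidity patterns, extended with absorbing states for dropout and
death, and follows through to pattern characterization and
pattern-specific mortality.

## The model

For person *i* with observation vectors *x*<sub>*i*0</sub>, …,
*x*<sub>*i,T−1*</sub> (reduced to a common feature space by PCA on
continuous features and MCA on categorical ones), the hidden state
*z*<sub>*it*</sub> ∈ {1, …, C, dropout, death} evolves as a Markov chain:

- initial law **π** over the C disease clusters (absorbing states carry no
  initial mass — cohort entry requires surviving to the index date);
- row-stochastic transition matrix **A** of size (C+2)×(C+2), whose dropout
  and death rows are frozen one-hot self-loops;
- emissions: diagonal-covariance Gaussians *N*(**μ**<sub>c</sub>,
  diag(**σ**²<sub>c</sub>)) for disease clusters; dropout and death are
  *observed* terminal events entering the likelihood as indicator
  emissions.

Fitting is Baum-Welch over all person-sequences (treated as independent
short sequences), initialized from a fuzzy C-means segmentation of the
baseline rows and repeated from seeded restarts, keeping the
highest-likelihood fit. Individual trajectories are decoded with the
Viterbi algorithm. Patterns are characterized by the observed/expected
prevalence ratio (disease prevalence in the cluster over prevalence in the
active population; O/E ≥ 2 marks membership in the pattern) and
exclusivity (share of all patients with the disease who sit in the
cluster). Mortality by baseline pattern is estimated with Cox
proportional-hazards regression (Breslow ties), with missing
socio-economic quintiles handled by chained-equation multiple imputation
(m = 7) and Rubin's rules.

A synthetic-cohort generator with known ground truth (latent cluster
paths, transition matrix, mortality offsets) is a first-class module, so
the whole pipeline is testable end to end without access to any clinical
registry.

## Worked example

```r
library(mmtraj)

cfg   <- cohort_config(n_persons = 2000, n_clusters = 3, n_diseases = 20,
                       n_years = 5, seed = 42)
panel <- generate_cohort(cfg)
flt   <- filter_rare_diseases(panel)            # < 2% baseline prevalence
X     <- assemble_features(flt$panel, 2, 2)     # 2 PCA + 2 MCA components
x0    <- X[X$year == 0, ]; class(x0) <- class(X)
fcm   <- fcm_fit(x0, C = 3, seed = 42)
init  <- init_hmm_from_fcm(fcm, x0)
fit   <- fit_with_restarts(flt$panel, X, init, n_restarts = 5, seed = 42)
traj  <- viterbi_decode(fit, flt$panel, X)
transition_summary(traj, "start_to_end")
```

```
<transition_summary> mode: start_to_end
          C1   C2   C3 Dropout Death
C1      81.0  0.0  0.3     7.2  11.6
C2       0.2 80.2  0.0     8.7  11.0
C3       0.5  0.2 81.4     7.3  10.7
Dropout  0.0  0.0  0.0   100.0   0.0
Death    0.0  0.0  0.0     0.0 100.0
```

Rows are baseline decoded clusters; columns the state at end of follow-up.
Most people stay in their baseline pattern over the five waves; the
absorbing rows are one-hot by construction. Agreement between the fitted
transition matrix and the decoded annual proportions
(`validate_bw_vs_decoded(fit, traj)`) is 2e-4 here — the model's internal
validation.

Pattern evidence and mortality:

```r
prof <- compute_profile(flt$panel, traj, year = 0)   # O, O/E, exclusivity
head(prof[prof$in_pattern, ], 4)
#>    cluster disease        O overall_prevalence oe_ratio exclusivity
#> 13       1  d_0013 57.24744              22.35 2.561407    87.47204
#> 14       1  d_0014 61.63982              25.00 2.465593    84.20000
#> 15       1  d_0015 56.07613              23.00 2.438093    83.26087
#> 16       1  d_0016 55.78331              21.75 2.564750    87.58621

rec <- build_survival_records(flt$panel, traj)
hz  <- hazard_table(rec, m = 7, seed = 42)           # MI-adjusted Cox
hz$adjusted_mi[grep("cluster", hz$adjusted_mi$term), c("term", "hr",
                                                       "ci_lower",
                                                       "ci_upper")]
#>       term        hr  ci_lower ci_upper
#> 1 cluster2 0.9456300 0.6867949 1.302013
#> 2 cluster3 0.9121288 0.6615011 1.257714
```

Each decoded cluster over-represents its own block of diseases (O/E ≈ 2.5,
exclusivity ≈ 85%), and — since this configuration assigns no mortality
offsets — the pooled hazard ratios sit near 1 with confidence intervals
covering it.

The entire analysis can also be run from one configuration with
`run_pipeline(pipeline_config(...))`, which writes every intermediate
artifact plus a manifest of seeds, parameter hashes, and per-file MD5
checksums; reruns with the same seed are bit-identical.

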