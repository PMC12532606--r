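---
title: "Modelling multiple sclerosis disease evolution with a factor-analytic hidden Markov model"
author: "msevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling MS disease evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msevo)
```

## The model

`msevo` treats multiple sclerosis (MS) as a latent-state process observed
through eight routine clinical and radiological measurements: the EDSS
disability score, the timed 25-foot walk (T25FWT), the 9-hole peg test
(9HPT), the PASAT cognition test, T2 lesion volume, normalized brain volume
(NBV), the count of Gd-enhancing T1 lesions, and a relapse flag. Two layers
are fitted in sequence.

**Measurement layer (sparse probabilistic factor analysis).** On the
modelling scale (log seconds and log millilitres for the skewed
time/volume measures, log1p for lesion counts, identity otherwise), a
visit's standardized feature vector is modelled as

$$x = \Lambda \eta + \varepsilon, \qquad \eta \sim N(0, I_K), \quad
\varepsilon \sim N(0, \mathrm{diag}(\psi)),$$

with a spike-and-slab prior on each loading: a mixture of two
zero-centred Laplace densities, a narrow *spike* (scale 0.01) that
represents exclusion and a wide *slab* (scale 1.0) that represents
inclusion, with a finite-truncation Indian-buffet-process prior
(`Beta(alpha / k_max, 1)`, `alpha = 1`, `k_max = 10`) on the per-column
inclusion weights. Estimation is MAP by EM: the E-step integrates the
factor scores (Gaussian) and the spike/slab responsibilities exactly; the
M-step is a responsibility-weighted L1 problem per loading row, solved
exactly by coordinate descent, with closed-form updates for uniquenesses
and inclusion weights. The penalized objective is monotone across
iterations and checked to `1e-8` relative tolerance in the tests. A feature
belongs to a dimension when its posterior slab probability exceeds 0.5;
columns with no such entry are pruned, and the surviving count is the
estimated number of composite MS dimensions. The loading matrix is
estimated on each patient's first fully observed (baseline) visit and held
fixed across time; per-visit composite scores are the Gaussian posterior
means given that loading matrix.

**Sequence layer (hidden Markov model).** The per-visit composite scores
of each patient form an independent chain sharing one parameter set: an
initial distribution, an unconstrained row-stochastic monthly transition
matrix, and full-covariance multivariate normal emissions per state.
Estimation is multi-sequence Baum-Welch in the log domain (relative
tolerance `1e-6`, at most 500 iterations, eigenvalue floor `1e-6` on the
emission covariances), initialized by seeded k-means on the pooled scores
with a 0.9-diagonal transition matrix; the best of several restarts is
kept. The number of states is chosen by BIC with the number of visits as
the sample size (a patient-based BIC is reported alongside). Paths are
decoded with the Viterbi algorithm (ties toward the lowest state index)
and forward-backward posteriors accompany each visit.

**Clinical reading of the states.** States are labelled from their score
signatures: the state with the highest relapse-dimension emission *and* a
majority of relapse-flagged visits is the relapse state; the highest
activity-dimension emission (without relapse majority) marks the
asymptomatic radiological activity state; the remaining states are ordered
by disability + brain-damage emission — the disease severity gradient.
The advanced block is then derived from the transition structure alone: the
largest upper segment of the severity ordering that (i) is not left towards
milder severity states (entries at most `epsilon = 0.005`), (ii) is not
entered directly from milder severity states, and (iii) receives inflow
from the activity states. Everything milder is "EME"
(early/mild/evolving). The aggregated meta-state matrix uses
Viterbi-occupancy weights within groups and stays exactly row-stochastic.

**Downstream analyses.** Time to the first 3-month-confirmed progression
independent of relapse activity (PIRA) is analysed with Kaplan-Meier
curves stratified by the baseline meta-state (log-log 95% bands). PIRA
uses the standard EDSS worsening thresholds over baseline (+1.5 from 0,
+1.0 from 0.5-5.0, +0.5 from 5.5 up), 3-month confirmation, a 30-day
pre-onset relapse exclusion window, and irreversibility within follow-up;
all windows are arguments. Treatment effects are estimated with a
continuous-time Markov model on the panel-observed meta-state paths:
maximum likelihood through the matrix exponential of the intensity matrix
over each observation gap, with treatment acting proportionally on the
intensities of transitions into the activity states; `exp(beta)` is the
hazard ratio and `1 - HR` the percentage risk reduction. Prognostication
of the transition to advanced MS uses a discrete-time logistic hazard over
person-months (natural-spline baseline), evaluated on held-out patients by
Harrell's concordance and an IPCW Brier score at a 24-month horizon (the
integrated version is reported alongside).

## The synthetic cohort generator

Access to the large MS trial databases this kind of analysis runs on is
restricted, so the package ships a generator that emulates their
statistical structure and makes every stage testable end to end. Its
default configuration *is* the reference experimental condition used
throughout the tests:

* eight hidden states grouped 3+1+1+3 into EME, asymptomatic activity,
  relapse and advanced; severity states have deliberately non-collinear
  disability/brain-damage profiles (one lesion-heavy and one
  disability-heavy state on each pole) so that the two severity dimensions
  remain separable in baseline covariance;
* a monthly transition matrix whose meta-state aggregates equal the
  published reference values — relapse persistence 37% (equivalently a
  geometric episode of mean 1.59 months ≈ the reported 47-day average
  relapse), relapse to advanced 18%, asymptomatic activity to advanced
  11%, asymptomatic activity to relapse 6%, EME persistence 94.5%, no
  direct EME-to-advanced transitions, advanced self-persistence 99%.
  Every row within a meta-group shares the same aggregate profile, so the
  aggregates are invariant to occupancy weighting; the within-group split
  is severity-adjacent and lives in the configuration object, not in code;
* a sparse 8-by-4 loading matrix: EDSS/T25FWT/9HPT on disability;
  PASAT/T2/NBV on brain damage; the relapse flag (with small EDSS and
  T25FWT cross-loadings — relapses transiently worsen disability) on the
  relapse dimension; the Gd count (with a T2 cross-loading — active
  lesions add to lesion burden) on asymptomatic activity. The
  cross-loadings matter: a factor loading a single feature is not
  identifiable against its uniqueness;
* observation links matching each feature's support: log-normal times and
  volumes, EDSS rounded to its half-point grid on [0, 10], PASAT rounded
  and clamped to [0, 60], Poisson lesion counts with a log-linear rate,
  and a Bernoulli-probit relapse flag. Location/scale calibration follows
  the published per-state summary tables (e.g. advanced-state mean EDSS
  ≈ 5.2) and keeps floor/ceiling point masses rare;
* per-feature missingness at the published rates (T25FWT 32.3%, 9HPT
  43.6%, PASAT 53.9%, T2 volume 72.5%, NBV 69.9%, Gd 73.1%); EDSS and
  relapse are always complete, and the baseline visit is fully observed,
  as trial protocols require;
* a trial-entry state distribution that over-weights recent inflammatory
  activity (12% asymptomatic activity, 10% relapse at entry), reflecting
  eligibility criteria; this is also what makes the activity and relapse
  factors identifiable from baseline covariance;
* an optional treatment arm: a multiplier on all off-diagonal transition
  probabilities into the activity/relapse states, renormalized through the
  diagonal.

**What the generator does not emulate.** Within-state emissions are
independent across months, so real within-patient autocorrelation of MRI
trajectories is absent; Gd counts in non-active states are rarer than the
published advanced-state mean (0.24) — the contrast is sharpened so that
single incidental lesions do not masquerade as activity episodes; visit
schedules are dense monthly grids rather than mixed quarterly/annual
protocols; and demographics (age, sex, MS subtype) are not generated.
Passing tests therefore demonstrate that the estimation chain recovers the
generating structure under these idealized conditions, not that it would
behave identically on trial data.

## Numerical and design choices

* **PFA initialization.** EM with bistable spike/slab weights is
  basin-sensitive, and all-zero columns are fixed points, so the
  initialization's effective rank upper-bounds the recovered dimension
  count. The fit starts at varimax-rotated principal-component loadings,
  keeping components with correlation-matrix eigenvalue above 0.7
  (Jolliffe's relaxed Kaiser criterion); jittered restarts can revive
  pruned columns. The first restart is unjittered, making single-restart
  fits deterministic.
* **Label contention.** Each dimension is labelled by the priority cascade
  relapse → activity → disability → brain damage over its included
  features. When two columns include the same signature feature (a dense
  severity column may weakly include the relapse flag), the column loading
  it most strongly claims the canonical label and the other falls through
  to its next signature.
* **Sign conventions.** Labelled columns are oriented along their clinical
  marker (EDSS up = more disability, T2 up = more damage, Gd up = more
  activity, relapse up = relapse); unlabelled columns orient their
  largest-magnitude loading positive. Orientation by magnitude alone is
  unstable when T2 (+) and NBV (−) load near-equally, and a flipped
  brain-damage axis corrupts the severity ordering downstream.
* **BIC behaviour.** On the generator's composite-score sequences the BIC
  curve bottoms cleanly at the generating eight states. Through the full
  observation layer it keeps decreasing past eight: zero-inflated lesion
  counts place a discrete "exactly one lesion" side-lobe several standard
  deviations off each state's activity score, and an additional state
  capturing that lobe always gains more likelihood than BIC's penalty —
  the same qualitative behaviour reported for real trial data, where
  more-state models kept similarly low BIC and the eight-state model was
  presented for interpretability. State-count recovery is therefore
  assessed on score sequences, where the Gaussian emission assumption
  holds.
* **Transition-structure recovery.** The recovery experiments (2,000
  patients × 24 months; the package's reference problem size) run the
  chain simulate → baseline factor fit → scoring → eight-state HMM →
  decoding → meta-grouping → aggregation on fully observed features. Under
  the default missingness the smooth-trajectory imputation spreads
  transient Gd elevations over months, which inflates the persistence of
  the decoded activity state (observed ≈ 0.8 against a generating 0.40)
  — an imputation artifact, informative in its own right, that would
  otherwise be confounded with estimation error of the transition
  probabilities being measured.
* **Imputation.** Per patient and feature, a penalized-spline GAM over
  month (six or more observed points), else a linear fit (two or more),
  else carry of a single value; imputation only at visits where something
  else was observed; observed cells are never altered; imputed cells are
  flagged. Times/volumes/counts are imputed on their link scale and
  back-transformed to their support.
* **Meta-grouping fallback.** If no upper segment of the severity ordering
  satisfies the entry/exit conditions, the segment minimizing the total
  violating mass is returned with a warning flag rather than failing — the
  partition is then reported as approximate.
* **CTMC.** Intensities for transition types never observed in the panel
  are fixed at zero and flagged. Standard errors come from the numerically
  differentiated observed information; with very sparse transition counts
  the Wald intervals can be wide.
* **Discrete-time prognostication.** The hazard learner is a logistic
  regression over person-month records with a natural-spline baseline —
  deliberately simple and deterministic; the evaluation metrics
  (concordance, Brier) are learner-agnostic, so a richer learner can be
  swapped in behind `fit_prognosis()` without touching the evaluation.

## Worked example

```{r example, eval = FALSE}
cfg <- default_config(n_patients = 500, n_months = 24)
cohort <- generate_cohort(cfg, seed = 1)
fit <- fahmm(cohort, n_states = 8, config = cfg, seed = 1)
fit                      # dimensions, meta-states, aggregated transitions
summary(fit)
report <- run_pipeline(cfg, seed = 1, outdir = "msevo-report")
```

## Known limitations

The PFA is a point-estimate (MAP) treatment of the spike-and-slab/IBP
model; posterior inclusion probabilities are EM responsibilities, not MCMC
posteriors, and are typically more extreme. The HMM assumes conditional
independence of scores given states, which real longitudinal MRI data
violate. PIRA derivation assumes the monthly grid; confirmation windows
shorter than the grid step are not representable. The prognostication
module models baseline features only — no time-varying covariates — and
the CTMC treats treatment as a fixed patient-level indicator.
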