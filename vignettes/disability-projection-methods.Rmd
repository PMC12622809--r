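---
title: "Methods: disability-state scoring, matrix annualization, and cohort projection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disability-state scoring, matrix annualization, and cohort projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LTCproj)
```

This vignette is the package's account of its own methods: the models it
implements, the assumptions they rest on, the parameters that matter, the
numerical choices made where the design was genuinely open, and what the
synthetic-data tests do and do not establish about real survey data.

## 1. The four-state disability scale and its scoring

Elderly disability is represented as an ordinal four-state variable —
healthy (1), mild (2), moderate (3), severe (4) — obtained from a weighted
multidimensional score. Item responses (self-rated health, disease burden,
physical and social activity participation, activities of daily living, a
short mental-state examination, self-rated memory) are scored per item
(`scoreItem()`, `defaultScoreTable()`), summed into four dimension totals
(physical function S, health/disease J, activity participation C, cognition
R), and combined as

$$\mathrm{total} = w_S S + w_J J + w_C C + w_R R,$$

with default weights $w = (0.2513, 0.3201, 0.1968, 0.2318)$, summing to 1
exactly. The total is banded at 5-point intervals: severe $\le 20$,
moderate $(20, 25]$, mild $(25, 30]$, healthy $> 30$.

**The score scale.** Raw dimension maxima under the default item set are
S = 11, J = 5, C = 14, R = 10 points. A weighted sum of raw totals can
therefore never exceed about 9.4 points, which would leave the 20/25/30
band edges unreachable. The package's default therefore rescales each
dimension total to percent of its maximum attainable score (0–100) before
weighting, which puts the weighted total on a 0–100 scale on which the band
edges are meaningful. Raw-total scoring remains available
(`totalScore(..., dimensionMax = NULL)`) for score tables whose native range
spans the bands. Weights and band edges are plain arguments, so the scale
can be recalibrated without touching code.

**Tie and edge handling.** Band edges are treated as closed on the right of
the lower band: a total of exactly 20 is severe, 25 moderate, 30 mild;
fractional totals in (20, 21) are moderate. This makes classification a
deterministic, monotone step function — property-tested over a dense grid.

**Missing and vague data.** Options recorded as "Not evaluated" or
"Unclear" score `NA` and raise a `removableRecord` condition. The default
policy is complete-case removal of the affected subject; per-item modal
imputation is available as `impute = TRUE`. Multiple imputation is out of
scope. The disease item contributes deductions (1 point minus one per
disease category); dimension totals are floored at 0 so deductions can
never produce a negative dimension score.

## 2. Transition estimation and annualization

State changes between panel waves are modelled as a time-homogeneous
discrete-time Markov chain. The multi-year matrix $P_h$ is the
row-proportion estimate from observed origin/destination pairs
(`estimateTransitionMatrix()`), optionally per group (age band DL/HL, sex
ME/FE, residence TN/RL). An origin state with no observations has an
undefined row; this errors unless a fallback `priorRows` matrix is given —
an explicit decision, never a silent uniform fill.

The package ships the pooled 3-year matrix from a 2017–2020 Chinese elderly
panel as `threeYearDisabilityMatrix()`. As printed, its first two rows sum
to 1.0036; a transition matrix must be row-stochastic, so rows are
renormalized on load with a warning (the bit-exact printed values are
available via `renormalize = FALSE`, returned as a plain matrix because the
`TransitionMatrix` class enforces stochasticity). The published annual
matrix is shipped as `annualDisabilityMatrix()` for reference and as a
synthetic-truth default.

**Why not a matrix root.** An annual matrix $P_1$ with $P_1^h = P_h$ need
not exist within the set of stochastic matrices, and eigendecomposition
roots can produce negative entries (the embedding problem). The package
instead uses a step-size transform: off-diagonal entries divided by $h$,
diagonals reset to $1 -$ (row's off-diagonal sum). For a stochastic input
this is always a valid stochastic matrix. It is, however, only a first-order
approximation — on the shipped 3-year matrix its 3-year count projection is
off by up to ~32% — so it is followed by calibration.

**Calibration.** `calibrateAnnualMatrix()` searches row-stochastic matrices
for one whose $h$-fold application to an initial count vector $n$ matches
$n P_h$, judged by the per-state relative error
$e = |a_{\mathrm{act}} - a_{\mathrm{est}}| / a_{\mathrm{act}}$, with
tolerance 0.05 by default. The published procedure behind this correction
step is not fully specified, so the optimizer here is the package's own
design:

* free entries of each row pass through a softmax, so every candidate is
  exactly row-stochastic and entries stay in (0, 1) without clipping;
* off-diagonal entries that are exactly 0 in $P_h$ (structural
  impossibilities such as severe→healthy recovery) are held at 0;
* the smooth objective (sum of squared per-state relative errors) is
  minimized by BFGS from the step-transform starting point, a deterministic
  procedure; the reported criterion is the maximum per-state error, the
  strictest reading of a per-state error requirement;
* if optimization fails to improve on the step transform, the step
  transform is returned, so calibration can never worsen the objective.

On the shipped 3-year matrix with 1,000 persons per state this reaches a
maximum error of order $10^{-6}$%, far inside the 5% criterion. The
calibrated matrix is *not* asserted to equal the published annual matrix
entry-for-entry: that matrix's cube diverges substantially from the 3-year
matrix (maximum per-state count error ≈ 41% on the same fixture), so
entry-level agreement is not an attainable or meaningful target; count-level
agreement is.

Note that calibration matches *count projections* for a given initial
vector, an underdetermined problem (4 constraints, 15 free parameters); the
result is a count-consistent annualization, not a unique matrix root.

## 3. Queue-element cohort projection

`projectCohort()` advances a baseline `PopulationFrame` (groups × states)
one year at a time. For the elderly only death needs to be considered, so
the demographic bookkeeping is: scenario-adjust the matrix, apply survival,
apply the Markov transition, add new entrants at age 60. Counts are
real-valued (fractional persons); integer sampling belongs to the
microsimulation.

**Stage conventions.** The textbook 1,000-person example folds death into
the transition row (90% stay healthy, 9% become mildly disabled, 1% die),
then adds 50 entrants: 1000 × 90% + 50 = 950 healthy, 90 newly mild. The
package supports this *composite* convention (sub-stochastic rows, the row
deficit being death) and the *decomposed* convention (explicit survival at
the group mortality rate, then a stochastic transition among survivors).
The two agree exactly on the example — 0.99 × (0.90/0.99) = 0.90 — and the
decomposed form is the default because it lets mortality vary by group
while one annual matrix drives the health dynamics.

**Entrants** default to 100% healthy ("joining the health queue"),
overridable by a distribution over states. **Scenario drift** rescales the
worsening (above-diagonal) transition probabilities by $(1 \mp 0.02)^t$,
compounding annually, with the displaced mass absorbed on the diagonal;
recovery transitions are untouched, and a drift that would force a negative
diagonal raises a scenario-infeasible error rather than renormalizing
silently. **Ageing across the 80-year boundary** (DL→HL) is supported as an
optional per-year fractional flow (`aging = list(map, fraction)`); it is off
by default because the underlying study does not document such a flow, and
leaving it off keeps the deterministic engine the exact expectation of the
agent model. When enabled, a uniform-age assumption suggests a fraction of
about 1/20 per year for a 60–79 band.

**The microsimulation oracle.** `microsimOracle()` simulates each person
individually (survival draw, transition draw, entrant arrivals) under the
same inputs. Agents are independent, so the deterministic engine is the
exact expectation of the microsimulation, and each state-year count is a
sum of independent Bernoulli indicators with variance at most its
expectation. Tests therefore use $3\sqrt{\text{deterministic count}}$ as a
conservative 3-standard-error agreement band at $10^5$ agents.

## 4. Cost accounting

Per-capita monthly cost is $C = d \times T \times \zeta \times \psi$:
nursing days per month (0, 31], daily nursing hours (0, 24], a unitless
severity cost coefficient, and the nursing staff's hourly time value (USD).
The shipped parameters (`defaultCostParams()`, 2020 survey values, USD)
give 518.95 / 629.47 / 1389.39 USD per month for institutional care of
mild/moderate/severe disability and 397.71 for home care. $\zeta$ and
$\psi$ are treated as given constants. Home care has one parameter row
applied to every level unless overridden; community care is supported
structurally but ships without defaults. Annual totals are headcount × mode
share × $C$ × 12, additive over disjoint population partitions; the default
mode-share table assigns each level fully to home care (the dominant mode
in the study population) and should be overridden where institutional
shares are known. Yuan-denominated national totals are not reproduced: the
conversion rate and national headcounts they require are not available.
Service demand uses fixed need proportions (e.g. 13.2% needing daily care)
applied to the projected population, assuming the proportions stay constant
over the horizon.

## 5. The synthetic-data module

Because the underlying survey microdata cannot be redistributed, every
input is generated:

* `generatePanel()` draws a two-wave panel (default 3,000 subjects,
  emulating a ~3,000-questionnaire cohort) with per-subject multinomial
  follow-up draws from a known truth matrix, group labels at roughly the
  cohort proportions (90% under 80; 48.3% male; even urban/rural), and a
  baseline state mix with a healthy minority (15/45/28/12%), consistent
  with a largely-disabled elderly panel.
* `generateItemResponses()` inverts the default scoring: it draws a target
  total inside each subject's band, realizes integer dimension scores
  (nudging the finest-grained dimension, C at ~1.4 points per item on the
  0–100 scale, until the classification matches), and emits item options
  reproducing those scores. `noise` pushes the configured fraction of
  subjects into an adjacent band, so downstream misclassification occurs at
  that rate in expectation.
* `generateDemography()` builds eight groups (age × sex × residence) with
  mortality higher over 80 (8% vs 2% base, modified by sex and residence)
  and age-60 entrants at 3% of each under-80 group per year — a slowly
  growing elderly population, deaths ≈ 2.6% of the total against entrants
  ≈ 2.7%.

What passing these tests shows: the estimator, calibrator, projector and
cost accountant are internally consistent, recover known truths at
realistic sample sizes, and agree with an independent agent-level model.
What they do not show: robustness to panel attrition, sampling weights,
informative missingness, age-dependent transition heterogeneity within
bands, or measurement drift between waves — features of real survey data
the generator deliberately does not emulate.

## 6. Problem sizes and determinism

The test suite runs at desk scale by design: panels of 300–10,000 subjects,
parameter-recovery at n = 5,000, microsimulation at $10^5$ agents over 5
years, 100-matrix property sweeps, and a bundled pipeline demo with 800
subjects and a 5-year projection — about ten seconds end to end. All
generators are seed-reproducible bit-exactly; the pipeline writes identical
artifacts for identical configuration and seed. These sizes were chosen as
comfortable for interactive use while keeping Monte-Carlo bounds tight
enough to be meaningful.

## 7. Known limitations

* Time-homogeneity: one transition matrix per group for the whole horizon
  (scenario drift is the only dynamics).
* Calibration is count-consistent, not a unique annualization; different
  initial vectors can prefer different annual matrices.
* The published calibrated matrix is not reproduced entry-for-entry (see
  §2); the package reports its own calibrated matrix alongside it.
* Costs are nominal USD with no inflation or price dynamics, and national
  absolute projections are out of scope because their census inputs are
  not available.
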