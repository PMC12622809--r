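# LTCproj

Projection of the disabled-elderly population and its long-term care costs.

Population ageing raises a planning question that single-wave surveys cannot
answer: how many elderly people will be living with each level of disability
in ten years, and what will their care cost? `LTCproj` implements a complete
analysis chain for that question, aimed at health-services researchers and
demographers working with two-wave panel data on elderly disability (such as
the CHARLS panel for China) plus routine demographic inputs (mortality rates
and counts of people turning 60).

## The model

**Disability scoring.** Questionnaire items are scored and aggregated into
four dimensions — physical function (S), health and disease (J), activity
participation (C), cognition (R) — and combined as a weighted total

    total = w_S·S + w_J·J + w_C·C + w_R·R,   w = (0.2513, 0.3201, 0.1968, 0.2318)

with each dimension first rescaled to percent of its maximum attainable
score. Totals are banded at 5-point intervals into four ordinal states:
severe (≤ 20), moderate (20, 25], mild (25, 30], healthy (> 30).

**Transition modelling.** State changes follow a discrete-time Markov chain.
The multi-year transition matrix `P_h` (h = 3 years for a 2017→2020 panel)
is estimated by row proportions from the panel. Because a stochastic h-th
root of `P_h` need not exist (the embedding problem), the annual matrix is
obtained by a step-size transform — off-diagonal entries divided by h,
diagonals reset to preserve row sums — followed by calibration: the free
entries of `P_1` are adjusted (row-softmax parameterization, quasi-Newton
descent) until the counts `n·P_1^h` match `n·P_h` with maximum per-state
relative error `e = |a_act − a_est| / a_act` below 5%. Structural zeros
(e.g. no severe→healthy recovery) are preserved.

**Queue-element projection.** Counts advance one year at a time: survival
against group-specific mortality (for the elderly only death matters — no
fertility, no migration), a Markov transition, then new entrants at age 60
joining the health queue. Optimistic/pessimistic scenarios rescale the
worsening transition probabilities by (1 ∓ 0.02)^t, compounding annually.
An agent-based microsimulation of the identical process is included as an
independent cross-check of the deterministic engine.

**Cost accounting.** Per-capita monthly long-term care cost is
`C = d × T × ζ × ψ` (nursing days/month × hours/day × severity coefficient ×
hourly time value of nursing staff), aggregated over the trajectory as
headcount × mode share × C × 12 per year, level and care mode.

## Worked example

```r
library(LTCproj)

## pooled 3-year matrix (rows renormalized on load, with a warning)
P3 <- threeYearDisabilityMatrix()
cal <- calibrateAnnualMatrix(P3, rep(1000, 4))
cal
#> CalibrationResult: converged (max error 6.664e-06%, tolerance 5%, 53 evaluations)
#> calibrated annual matrix:
#>           to
#> from       healthy   mild moderate severe
#>   healthy   0.7031 0.2655   0.0301 0.0014
#>   mild      0.0180 0.8995   0.0748 0.0077
#>   moderate  0.0066 0.1383   0.8201 0.0349
#>   severe    0.0000 0.0403   0.0885 0.8712

## ten-year projection on a synthetic demographic frame (10,000 persons,
## eight age × sex × residence groups, entrants exceeding deaths)
demo <- generateDemography(baseTotal = 10000)
pr <- projectCohort(demo$frame, annualMatrix(cal),
                    lifeTable = demo$lifeTable, entrants = demo$entrants,
                    years = 10)
growthRate(pr, 2025, 2035)                      # total persons: +2.80 %
growthRate(pr, 2025, 2035, states = "severe")   # severe state: -33.35 %

costs <- aggregateCosts(pr)                     # default: 100% home care
sum(costs$annual_total[costs$year == 2035])     # 43,274,670 USD in 2035
```

The calibrated matrix shows the expected annual stability (diagonals
0.70–0.90) and reproduces the 3-year state counts essentially exactly,
against the 5% criterion. In this synthetic frame the severe count falls
over the decade because the calibrated dynamics let moderate cases
redistribute while mortality removes the heavily-weighted older groups;
with the pessimistic scenario (`drift = -0.02`) the 2035 disabled total
rises by about 1.9% relative to baseline, and falls by about 2.0% under
the optimistic scenario (`drift = 0.02`).

The whole chain — synthetic panel → item responses → scoring → estimation →
calibration → projection → costs — runs from one configuration via
`runPipeline()` (or `runDemo()` for a bundled desk-scale run), writing every
intermediate artifact as CSV plus a JSON report.

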