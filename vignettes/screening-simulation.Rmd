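---
title: "Comparing time-dependent risk-based screening strategies by simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing time-dependent risk-based screening strategies by simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskscreen)
```

## The question

Risk-prediction tools increasingly return not just a cumulative long-term
risk but a sequence of conditional annual risks — *when* a patient is likely
to experience an event, not only *whether*. If screening or follow-up
examinations can only be offered at a few fixed time points, how much
screening effort can be saved by targeting those examinations at high-risk
patients *and* high-risk years, while still detecting a fixed fraction of
events at a curable stage?

`riskscreen` answers this with a patient-level simulation. Populations of
patients carry five annual conditional risks of a hypothetical disease;
examinations can happen at the end of each of the five years; the chance
that a detected occurrence is still curable decays exponentially with the
detection delay. Allocation strategies are calibrated to a common target
detection rate and compared by the number of examinations they need.

## Model

### Occurrence bookkeeping

The annual conditional risk $p_{k,i}$ of patient $k$ in year $i$ is treated
as *expected occurrence mass*: a risk of 1% in year one equals 0.01
theoretical occurrences in that interval. Because the prediction algorithm
is assumed perfectly calibrated, nothing is gained by sampling binary
events in simulation mode — all detection quantities are exact
expectations, which removes one layer of Monte-Carlo noise. An occurrence
in year $i$ is placed at the interval midpoint $t_{occ} = i - 0.5$;
examinations happen at integer times $t_i = i$, so the shortest possible
detection delay is half a year.

### Curability and detection

An occurrence detected with delay $d$ is still fully curable with
probability $dp^{\,d}$, where the progression base $dp \in (0, 1]$
characterizes the disease: 0.6 slow, 0.3 intermediate, 0.1 fast. An
examination detects every occurrence since the previous examination (or
since the start of the programme). With an imperfect per-exam sensitivity
$s$, the cascade over a patient's successive exams at times
$t_j \ge i$ (rank $q = 0, 1, \dots$ among exams at or after the
occurrence interval) contributes

$$\sum_q s\,(1 - s)^q\, dp^{\,t_j - t_{occ}}$$

expected curable detections per unit of occurrence mass. The same cascade
is applied to the full (all-years) schedule, defining $n_{max}$, so the
achieved target detection rate $tdr = n_{actual} / n_{max}$ equals 1 for
full screening at any sensitivity; with $s = 1$ the cascade collapses to
"the first subsequent exam detects". We chose the cascade over a flat
multiplier because it keeps $n_{max}$ interpretable as "best achievable
with this examination" and makes $tdr$ a ratio of like quantities; the
flat-multiplier reading is recoverable by noting that it cancels from the
$tdr$ ratio entirely.

### The population generator

Populations are controlled by three parameters:

* **cvmr** — coefficient of variation of the five population mean annual
  risks. A trajectory of five means is drawn by standardizing five normal
  deviates to *exactly* the target mean (2% per year; 10% over five years)
  and standard deviation `sdmr = cvmr * 0.02` (so cvmr 0.5 ↔ sdmr 1%).
  Exact-moment standardization makes every trajectory satisfy the stated
  moments identically regardless of seed; draws with any mean below
  `1e-4` are rejected and redrawn (at most 100 times) to keep all means
  positive. By default a fresh trajectory is drawn per repetition — the
  scenario pins the *moments*, not one arbitrary shape — with a flag to fix
  one trajectory per scenario instead.
* **r** — equicorrelation between an individual's five annual risks,
  implemented as a shared standard-normal factor plus independent noise
  (exact for any $r \in [0,1)$, trivially positive definite).
* **individual spread** — each year's individual risks are normal around
  that year's mean $m_i$ with standard deviation
  $\sigma_i = \texttt{sigma\_scale} / |\log_{10} m_i|$, i.e. spread grows
  sub-linearly with the mean risk. The inverse-log form pins down only the
  *shape* of the mean–spread relation; its scale is a genuinely free
  parameter of the model and defaults to `sigma_scale = 0.01` (per-year
  CV ≈ 0.3 at the 2% mean). Negative draws are truncated at zero and each
  column is rescaled multiplicatively back to its target mean, so the
  population occurrence total — the denominator of every detection rate —
  is conserved exactly. Because several headline quantities (especially
  the savings of the cumulative approach, which lives entirely off
  between-patient heterogeneity) are sensitive to this scale,
  `sigma_sensitivity()` re-runs a scenario set across `sigma_scale`
  values; the reported grid results should always be read together with
  the `sigma_scale` recorded in the manifest.

### Strategies and calibration

`schedule_ca()`, `schedule_cair()` and `schedule_isa()` implement the
three threshold rules (cumulative all-or-nothing; cumulative with reset
after each triggered exam; interval-specific). All threshold comparisons
are inclusive (`>=`), which gives clean limits: threshold 0 is full
screening for every rule. CAIR does not schedule a terminal exam when the
running sum ends below the threshold at year five — the accumulated risk
simply remains unscreened, as in the rule's definition.

A discrete schedule cannot hit a target detection rate exactly, so
`calibrate_threshold()` brackets the target by bisection (tolerance
`1e-8` risk units on the threshold; the search interval is
[0, max cumulative risk] for CA/CAIR and [0, max annual risk] for ISA) and
reports the linearly interpolated examination count at exactly the target
rate, together with both brackets. Interpolation is what makes the
comparison against the near-continuous random reference fair; the
detection rate is exactly monotone in the threshold for CA and ISA
(schedules are nested), and empirically monotone for CAIR on simulated
populations — if a bisection bracket is ever inconsistent the function
falls back to a monotone envelope over a 512-point threshold grid.
Degenerate brackets (both ends at the same rate) resolve to the
fewer-exams side.

### The random reference

The reference strategy draws patient-year slots uniformly at random, one
at a time, recomputing the achieved detection rate incrementally, and
stops as soon as the target is reached. Two counting conventions are
implemented: in the default `with_replacement` mode a repeated slot
consumes a draw without adding an examination, so the *draw* total counts
the waste inherent in uninformed allocation and can exceed the number of
slots (at the standard scenario size it lands in the low-40,000s for slow
progression); `without_replacement` draws over remaining slots only. The
distinct examination count at stopping has the same distribution either
way — duplicates add nothing — and it is that distinct count that enters
`saving_percentage()`: savings compare examinations actually performed,
never wasted draws. No interpolation is applied to the reference; its
overshoot is at most one examination.

## The scenario grid

`run_grid()` crosses $dp \in \{0.6, 0.3, 0.1\}$,
$cvmr \in \{0.5, 0.25, 0.05\}$ and $r \in \{0.2, 0.5, 0.8\}$ (27
scenarios, numbered with $dp$ slowest-varying, then $r$, then $cvmr$; the
numbering is written into every manifest) at one or more target detection
rates, with 100 repetitions per scenario by default and five
random-allocation runs averaged per repetition. Each repetition calibrates
all three strategies on the same freshly drawn population, so strategies
are always compared like-for-like; per-scenario means carry Monte-Carlo
standard errors (`sd / sqrt(reps)`). All randomness is derived from a
single root seed through named substreams (scenario cell, repetition,
component), making any slice of the grid bit-reproducible in isolation.

Default problem sizes (5000 patients, 100 repetitions, full grid) complete
in a few minutes on a single core; the acceptance script trades the grid
down to 30 repetitions — its Monte-Carlo standard errors on the savings
are then around 0.3–1 percentage point — while keeping 100 repetitions for
individually reported scenarios.

Qualitatively, the grid reproduces the expected mechanics: the
time-dependent strategies (CAIR, ISA) save examinations relative to random
allocation in every scenario and always beat the time-independent
cumulative rule; accumulation (CAIR) wins for slowly progressing disease,
where late detection of an earlier occurrence retains value; the
interval-specific rule wins for fast progression, where only the newest
risk matters; risk variation over time (cvmr) mainly boosts the
time-dependent strategies, while between-year correlation (r) mainly helps
the cumulative rule.

## Cohort mode

`evaluate_cohort()` applies the same machinery to a table of per-patient
annual risk predictions with optionally observed events (the dialect is a
plain CSV, `patient_id, risk_y1..risk_y5, event_year`). Thresholds are
calibrated on the *predicted* risks — mirroring how a planner would deploy
the tool prospectively, before events are known — and the resulting
schedules are then scored on the observed events through the sensitivity
cascade (defaults: dp 0.3, target rate 90%, sensitivity 80%,
without-replacement random reference). A flag allows calibrating on the
observed events instead. Results are additionally stratified by 5-year
cumulative-risk quintile (near-equal fifths, ties broken by patient
order).

`synth_influence_cohort()` generates synthetic cohorts that emulate the
published *moment structure* of a real nomogram cohort: annual mean risks
(0.35%, 0.68%, 0.475%, 0.44%, 0.405%) with the year-1 minimum and year-2
maximum, a five-year total of 2.35%, and a coefficient of variation of the
five means of 0.24 — computed with the population-SD (denominator $n$)
form, since the five yearly means are a complete set rather than a sample
(the printed extremes are arithmetically incompatible with the sample-SD
form). Marginals are lognormal (log-SD 1.2, a heavy right skew typical of
nomogram outputs) coupled through a Gaussian copula whose Spearman
correlations decay linearly with lag (0.77, 0.61, 0.45, 0.29 at lags 1–4;
mean 0.61 over the ten pairs), converted to latent Pearson correlations by
$\rho_P = 2\sin(\pi\rho_S/6)$. Columns are rescaled multiplicatively to
the exact target means. At most one event is sampled per patient,
sequentially, with the conditional annual risk as the per-interval event
probability given no earlier event.

What the generator does *not* emulate: covariate structure (age, tumour
characteristics), any association between risk level and examination
sensitivity, prediction error, competing mortality, or the exact joint
distribution of the real registry cohort. Consequently, cohort-mode tests
establish that the strategies behave sensibly on realistically skewed,
realistically correlated predictions — positive savings for all three
strategies, follow-ups concentrated in the top risk quintile — but
numbers tied to the real registry (absolute follow-up counts, per-quintile
detection counts) are not reproducible from synthetic data and are not
claimed.

## Numerical choices and degenerate inputs

* Exact column recentring guarantees `sum(risks) = N * 0.10` to machine
  precision, so detection-rate denominators are identical across
  strategies within a repetition.
* The bisection tolerance (`1e-8` risk units) is far below any annual
  risk of interest; calibration is idempotent to `1e-9` exam units.
* The random-allocation stopping comparison subtracts `1e-9` from the
  target mass to keep floating-point equality from costing one extra draw.
* `cvmr = 0` with `sigma_scale = 0` collapses the population to identical
  patients: all strategies then degenerate to all-or-nothing plateaus and
  the interpolated exam count is the exact plateau mixture.
* Constant-risk cohorts have undefined rank correlations; summaries flag
  them rather than returning spurious values.
* Extreme `cvmr` that cannot yield positive means rejects with an
  `invalid-parameter` error rather than silently truncating the
  trajectory.

## Known limitations

Progression is homogeneous — one `dp` for everyone, with no
inter-individual variation; there are no false positives, no dropout, no
competing risks, and prediction accuracy is taken as perfect in simulation
mode. The individual-spread scale is under-determined by the model's
qualitative description; all grid-level savings should be interpreted
relative to the recorded `sigma_scale`. The random reference's draw total
(as opposed to its examination count) is convention-dependent and is
reported only as a descriptive statistic.
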