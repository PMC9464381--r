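# riskscreen

Patient-level simulation of **time-dependent, risk-based screening
strategies**, for biostatisticians and health-services researchers who
want to quantify how much screening or follow-up effort can be saved by
exploiting *annual* risk predictions — who to screen and **when** — while
still detecting a fixed fraction of disease occurrences at a curable
stage.

## The model in brief

A population of $N$ patients carries five conditional annual risks
$p_{k,i}(D)$ of a disease $D$; examinations are possible at year-ends
$t_i = i \in \{1..5\}$. Risks are treated as expected occurrence mass
(perfect calibration), with occurrences placed at interval midpoints
$t_{occ} = i - 0.5$. An occurrence detected with delay $d$ is still
curable with probability $dp^{\,d}$ (progression base $dp$: 0.6 slow, 0.3
intermediate, 0.1 fast). Schedules are scored by the achieved **target
detection rate**

$$tdr = \frac{n_{actual}(D_{curable})}{n_{max}(D_{curable})},$$

the curable detections of the schedule relative to full screening (with
imperfect per-exam sensitivity $s$, successive exams form an
independent-miss cascade $s(1-s)^q dp^{\,t_j - t_{occ}}$ applied to both
numerator and denominator).

Four allocation strategies are calibrated to the same target rate and
compared by examinations needed:

* **CA** — cumulative approach: screen every year iff the 5-year risk sum
  exceeds a threshold;
* **CAIR** — cumulative approach with interval-wise reevaluation:
  accumulate annual risks, examine when the running sum reaches the
  threshold, then reset;
* **ISA** — interval-specific approach: examine after each year whose own
  annual risk exceeds the threshold;
* **RA** — random allocation of examination slots until the target rate
  is reached (the efficiency reference).

Populations are generated from three scenario parameters: `cvmr`
(variation of the five population mean annual risks over time, with the
5-year mean fixed at 10%), `r` (equicorrelation of an individual's annual
risks) and `dp`. The headline quantity is each strategy's **saving**,
$100 \cdot (e_{RA} - e_S)/e_{RA}$, the percentage of examinations avoided
relative to random allocation at equal detection rate.

A cohort module applies the same machinery to tables of real or synthetic
per-patient predictions with observed events, including a synthetic
generator that emulates the published moment structure of a breast-cancer
recurrence nomogram cohort (skewed lognormal annual risks, lag-decaying
rank correlation, ~2% five-year risk).

## Worked example

```r
library(riskscreen)

p <- scenario_params(n_patients = 5000, dp = 0.6, cvmr = 0.5, r = 0.2,
                     tdr_target = 0.9, reps = 10, seed = 42)
run_scenario(p)
#> Scenario: dp = 0.60, cvmr = 0.50, r = 0.20, tdr = 0.90 (N = 5000, 10 reps)
#> Random reference: 20690 exams (44041 draws incl. repeats)
#>              exams  saving(%)       SE
#>   CA       21564.8       -4.3     0.59
#>   CAIR     15634.1       24.4     1.85
#>   ISA      15666.5       24.2     1.86
```

Read: to detect 90% of the curable occurrences of a slowly progressing
disease ($dp = 0.6$) in this heterogeneous population, uninformed random
allocation needs ≈ 20,700 examinations (having burned ≈ 44,000 random
draws, duplicates included); the time-dependent strategies CAIR and ISA
need only ≈ 15,600 — about **24% of examinations avoided** — while the
time-independent cumulative rule is here slightly *worse* than random
allocation (−4.3%). `run_grid()` crosses all 27 standard scenarios and
`summary()`/`marginal_savings()` give the per-parameter averages;
`write_grid_results()` emits CSVs plus a JSON manifest with the seed,
conventions and scenario numbering.

Cohort mode, on a synthetic nomogram-like cohort:

```r
co <- synth_influence_cohort(6520, seed = 42)
summarize_cohort(co)
#> Cohort of 6520 patients, 142 observed events
#> Annual mean risks (%): 0.350 0.680 0.475 0.440 0.405
#> Mean annual 0.470%, 5-year 2.35%, cvmr of means 0.240
#> Mean Spearman correlation 0.613 (lags 1-4: 0.77 0.62 0.46 0.29)

evaluate_cohort(co, dp = 0.3, tdr_target = 0.9, sensitivity = 0.8, seed = 42)
#> Cohort evaluation: dp = 0.30, tdr target = 0.90, sensitivity = 0.80
#> 142 observed events; 65.5 expected curable detections under full screening
#>          followups   avoided(%)   detections
#>   RA         28540         ref.         60.0
#>   CA         19390         32.1         59.0
#>   CAIR       17221         39.7         60.0
#>   ISA        16565         42.0         59.9
```

Here thresholds are calibrated on the predicted risks (with an 80%
examination-sensitivity cascade) and the schedules are then scored on the
observed events; all three risk-based strategies detect essentially the
same number of curable recurrences as random allocation while performing
9,000–12,000 fewer follow-ups. `summary()` adds the per-risk-quintile
breakdown of follow-ups and detections.

The methods vignette (`vignettes/screening-simulation.Rmd`) documents the
model assumptions, the generator's free parameters and the numerical
choices in detail.

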