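# cyclekin

Cell-cycle kinetics and neurogenic exit of cycling progenitor populations.

`cyclekin` implements the three quantitative readouts used to ask whether a
signaling perturbation shifts neural progenitors between proliferation and
neurogenic differentiation — developed around human MGE-like (NKX2.1+)
interneuron progenitors derived from pluripotent stem cells, but applicable
to any asynchronously cycling population:

1. **Cumulative S-phase labeling.** Cells are exposed to EdU for increasing
   durations (e.g. 2, 4, 8, 16, 24 h) and the labeled fraction is fitted to
   the linear growth-fraction model

   GF(t) = (GF/t<sub>c</sub>)·t + GF·(t<sub>s</sub>/t<sub>c</sub>),

   whose slope *m* and intercept *b* invert to the cell-cycle length
   t<sub>c</sub> = GF/m and S-phase length t<sub>s</sub> = b·t<sub>c</sub>/GF
   (`fit_labeling_curve()`, `estimate_cycle_params()`), with per-replicate
   SEMs and a plateau-exclusion policy for exposure times past saturation at
   t = t<sub>c</sub> − t<sub>s</sub>.
2. **Pulse-chase cell-cycle-exit index.** The fraction of pulse-labeled
   marker-positive cells that lost Ki67 by the chase endpoint,
   #(marker⁺ EdU⁺ Ki67⁻) / #(EdU⁺), with per-field quartiles
   (`compute_exit_index()`), and its exact generative expectation
   (`expected_exit_index()`).
3. **Gated flow-cytometry timecourses.** Viability exclusion, a positivity
   threshold set on a matched negative-control line (99.9th percentile by
   default), and per-day mean ± SEM timecourses with percent-reduction and
   fold-change summaries (`gate_viable()`, `gate_positive()`,
   `build_timecourse()`).

A seeded simulator of cycling, differentiating populations
(`simulate_cumulative_labeling()`, `simulate_pulse_chase()`,
`simulate_flow_sample()`) generates every input format from ground-truth
parameters, so each estimator is validated by parameter recovery against
closed-form oracles. Group comparisons go through the conventional
Shapiro–Wilk/Levene gatekeeping with parametric tests and rank-based
fallbacks (`compare_groups()`), and `run_pipeline()` drives all stages from
one YAML configuration (`inst/extdata/demo_config.yaml` is a complete
example; `inst/cli/cyclekin.R` wraps the same functions for shell use).

## Worked example

```r
library(cyclekin)

## cumulative-EdU experiment at the published control NKX2.1+ kinetics
pop   <- cycle_population_params(tc = 39.98, ts = 16.51, gf = 0.90)
curve <- simulate_cumulative_labeling(mixture_spec(pop, seed = 42))
fit   <- fit_labeling_curve(curve, policy = "plateau_exclude", gf = 0.90)
estimate_cycle_params(fit, gf = 0.90)
#> Cell-cycle estimate (GF = 0.90):
#>   tc = 40.16 +/- 1.93 h (SEM, 2 replicates)
#>   ts = 16.42 +/- 0.84 h (SEM, 2 replicates)
```

The simulated experiment (six fields, two replicates, ~200 cells/field)
recovers the generating t<sub>c</sub> = 39.98 h and t<sub>s</sub> = 16.51 h
to within well under one replicate-level SEM; the 24-h point was dropped by
the plateau policy because saturation begins at
t<sub>c</sub> − t<sub>s</sub> ≈ 23.5 h.

```r
## pulse-chase exit index with a 30% per-mitosis exit probability
pq  <- cycle_population_params(39.98, 16.51, gf = 0.90, quit_prob = 0.3)
tab <- simulate_pulse_chase(mixture_spec(pq, seed = 42), pulse = 2, chase = 48)
compute_exit_index(tab)
#> Cell-cycle-exit index: 0.4183 (397 / 949 EdU+ cells)
#>   per-field median [q1, q3]: 0.4321 [0.3895, 0.4578] over 12 fields

## gated flow sample at day 45 of differentiation
ev <- gate_viable(simulate_flow_sample(trajectory_params(), day = 45,
                                       n_events = 20000, seed = 42))
gate_positive(ev[ev$role == "reporter", ], ev[ev$role == "negative_control", ])
#> Gate (day 45, control, rep 1): 44.56% positive of 17932 viable events (threshold 474.0)

percent_reduction(44.72, 24.62)
#> [1] 44.94633
```

The exit index reads ~0.42: only labeled cells that pass a mitosis during
the 48-h chase can exit, and each passage exits with probability 0.3. The
exact expectation, `expected_exit_index(pq, 2, 48)` ≈ 0.391, agrees with
the observed 397/949 within Monte-Carlo error (binomial SE ≈ 0.016). The
day-45 gate recovers the trajectory model's 44.8% prevalence, and the
percent reduction of the two day-45 percentages rounds to the familiar
45%.

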