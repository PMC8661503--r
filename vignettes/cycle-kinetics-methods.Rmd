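---
title: "Cell-cycle kinetics, exit indices and gated timecourses: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-cycle kinetics, exit indices and gated timecourses: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclekin)
```

This vignette explains the models behind `cyclekin`, the assumptions they
make, and the design decisions taken where the underlying experimental
conventions leave room. It states no empirical result that the package's
test suite does not itself compute.

## The cumulative-labeling model

Cumulative S-phase labeling exposes an asynchronously cycling population to
a thymidine analogue (EdU) continuously for increasing durations. Any cell
that traverses S-phase during the exposure window becomes permanently
labeled. For a population in which a fraction $GF$ (the *growth fraction*)
cycles with cell-cycle length $t_c$ and S-phase length $t_s$, and in which
cycle positions are uniformly distributed, the expected labeled fraction
after exposure $t$ is linear until it saturates:

$$GF(t) = \frac{GF}{t_c}\,t + GF\,\frac{t_s}{t_c}, \qquad t \le t_c - t_s,$$

with plateau $GF$ for $t \ge t_c - t_s$. Fitting a line to the observed
fractions gives slope $m$ and intercept $b$, which invert to

$$t_c = \frac{GF}{m}, \qquad t_s = \frac{b\,t_c}{GF}.$$

`fit_labeling_curve()` performs the ordinary least-squares fit (fields are
pooled within each biological replicate, weighting fractions by field
totals) and `estimate_cycle_params()` applies the inversion, propagating
per-replicate sub-fits into an SEM for $t_c$ and $t_s$.

### Assumptions

* **Steady-state asynchrony.** Cycle positions are uniform on $[0, t_c)$.
  The simulator realizes this exactly with a non-expanding renewal scheme:
  each mitosis replaces the mother by a single tracked daughter, under
  which the uniform distribution is stationary and the linear law is exact.
  This is what makes estimator correctness testable against a closed form.
  An exponentially expanding population has a mild excess of young cells;
  `mixture_spec(..., age_distribution = "exp_growth")` provides that age
  structure as a robustness option (the linear law then holds only
  approximately), but it is off by default and not used in the validation
  studies.
* **Binary, permanent label.** No dilution across divisions and daughters
  inherit the label — appropriate for click-detected EdU over exposures of
  a day or less.
* **Phase layout.** G1, then S of length $t_s$, then a combined G2/M of
  length `tg2m` (default 2 h, shrunk when $t_c - t_s < 2$ h) ending in
  mitosis. The inversion uses only $t_c$ and $t_s$; `tg2m` matters only for
  pulse-chase mitosis timing.

### The plateau-exclusion policy

The linear law breaks at $t \ge t_c - t_s$. For kinetics in the range seen
in human MGE-like progenitors ($t_c \approx 39$–46 h, $t_s \approx
16$–22 h), the plateau begins between roughly 22 and 24 h, so a 24-h
exposure point sits at or past it. Including such a point on a noise-free
curve biases the slope downward — by about 2% of $t_c$ for
$t_c - t_s \approx 23.5$ h and about 7% when the plateau starts near 22 h —
which is why the package provides `policy = "plateau_exclude"`: the pooled
curve is fitted with all times, and the largest time is dropped
(iteratively, refitting each round) while its fitted prediction reaches
$(1 - 0.01) \cdot GF$. The exclusion set is decided once, on the pooled
curve, and applied identically to every replicate sub-fit so that replicate
dispersion reflects sampling noise, not policy divergence. The recovery
studies in the test suite use this policy; `policy = "all"` remains the
default for data whose exposure schedule is known to stop short of the
plateau, and the bias-removal property is asserted on noise-free curves in
the tests.

### The growth fraction

$GF$ must come from outside the fit. Three routes are supported: a supplied
value, an external Ki67-positive fraction, and a plateau estimate (mean
pooled fraction over times whose fraction is within 2% of the curve
maximum; at least two saturated times are required, otherwise the function
refuses and points to the alternatives — with $t_c - t_s$ near 24 h, a
24-h schedule barely reaches saturation, so plateau estimation from such a
design is fragile by construction). The simulator defaults use $GF = 0.90$
for the NKX2.1+ progenitor population and $GF = 0.75$ for the NKX2.1−
population: day-22 MGE-like cultures are overwhelmingly proliferative, and
the marker-negative compartment mixes cycling non-MGE progenitors with
early postmitotic cells, hence the lower value. These are modeling choices
— published growth fractions for these populations are not available — but
the inversion is algebraically exact for *any* supplied $GF$ (the simulated
curve scales by $GF$ and the inversion divides it out again), so recovery
of $t_c$ and $t_s$ does not depend on them; they only set the
signal-to-noise of the simulated counts.

## The pulse-chase exit model

A 2-h pulse marks cells in S-phase; after a chase, the *cell-cycle-exit
index* is the fraction of marker-positive, labeled cells that have lost
Ki67 among all labeled cells:

$$\mathrm{exit\ index} = \frac{\#(\mathrm{marker^+\,EdU^+\,Ki67^-})}{\#(\mathrm{EdU^+})}.$$

Generatively, each daughter exits the cycle at mitosis with probability
$q$ (`quit_prob`), loses Ki67 immediately upon exit (a detection-lag
parameter exists, default 0), and stops dividing. Cells labeled in S that
do not reach a mitosis within the chase cannot exit — inherent to a
per-mitosis exit model and worth remembering when choosing chase lengths.
`expected_exit_index()` computes the exact expectation
$E[1-(1-q)^{N(a)} \mid \mathrm{labeled}(a)]$ by midpoint quadrature over
the initial position $a$ (20,001 nodes by default; the integrand is
piecewise constant in $a$, so this resolves the expectation to well below
Monte-Carlo noise), giving a second, independent route against which the
simulator is cross-validated on a grid of exit probabilities and chase
lengths.

## Flow-cytometry gating and timecourses

Event tables carry one row per event with reporter and viability-dye
intensities. Two gates are applied in order:

1. **Viability.** Events above `4 x median(viability_intensity)` of their
   own sample are discarded. The multiplier is configurable; the rule is a
   conventional automated stand-in for a manual DAPI gate, not a
   reconstruction of any instrument-specific gate.
2. **Positivity.** The threshold is the 99.9th percentile of the matched
   negative-control sample's reporter channel (parental line at the same
   day). The percentile is configurable; 99.9 is standard practice for a
   knock-in reporter with a parental control and implies a ~0.1%
   false-positive tail by construction, which the tests verify. A missing
   or day-mismatched control is an error — never a silent fallback.

Simulated intensities are log-normal (background around 100 a.u.,
positives around 3,000 a.u., dead cells at 5,000 a.u. on the viability
channel, 10% dead by default) — deliberately simple, single-reporter, with
no compensation or spillover; the gating logic, not the optics, is what
these synthetic samples exercise. Conclusions about real instruments'
spectral behaviour are out of reach of these tests.

The reporter-positive prevalence over differentiation follows a saturating
conversion model
$p(d) = A\,(1 - e^{-H(d)})$, with cumulative hazard $H$ accrued at rate
`hazard x condition_scale` per day after `onset_day`. The defaults
(`asymptote` $A = 0.5$, `hazard` $= 0.094$/day, `onset_day` $= 21$) were
calibrated once against the published anchors of this differentiation
system — roughly 15% reporter-positive at day 25, ~40% at day 40, 44.7% at
day 45 in control cultures, and 24.6% at day 45 under TGF-beta-receptor
inhibition (`condition_scale = 0.3`) — and are not revisited. A forced
cell-cycle-exit mode (`forced_exit_day`) replaces the hazard by
`forced_exit_hazard` (0.3/day) from that day on, reproducing the
qualitative signature of cell-cycle-inhibitor treatment: conditions with
different baseline hazards converge toward the common asymptote at late
days.

## Statistical gatekeeping

`compare_groups()` reproduces the conventional decision tree: Shapiro–Wilk
per group and Levene's test (mean-centered, as in SPSS) across groups at
$\alpha = 0.05$ (configurable); both passing routes to an unpaired
two-tailed t-test with equal variances (two groups) or one-way ANOVA with
Tukey's HSD (more); either failing routes to Mann–Whitney or
Kruskal–Wallis with Dunn's post-hoc, Holm-adjusted (the Dunn step is
implemented in the package, with tie correction). Two edge rules matter at
replicate-level sample sizes:

* Shapiro–Wilk needs $n \ge 3$ non-constant observations, and Levene's
  statistic is degenerate below 3 per group (the two absolute deviations
  in a 2-observation group are identical). Untestable gates are recorded
  in the decision trail and treated as passed — for variance, this is the
  "equal variances assumed" convention that small replicate-level
  comparisons in this field follow.
* Identical data across groups short-circuit to statistic 0, $p = 1$.

Every result carries the full decision trail, raw and adjusted p-values,
so the branch taken is recorded rather than guessed. Under a null
simulation the gatekept procedure holds its nominal 5% type-I error, which
the test suite checks over 1,000 simulated three-group datasets.

## Validation study sizes and numerical choices

The packaged recovery studies simulate the bench design: exposure times
2, 4, 8, 16, 24 h; six fields from two biological replicates; ~200 cells
per field (Poisson field totals, binomial labeled counts); 100 independent
repetitions per condition. At this scale the estimator's mean $t_c$ and
$t_s$ sit within a few tenths of an hour of the generating values for all
four condition-by-population parameter sets. Interval-coverage checks use
six replicate-level fits (two experiments of three technical replicates),
matching how dispersion is conventionally reported for this assay; with
only two replicate fits a $\pm 2\cdot$SEM interval is known to undercover.

Other numerical conventions: every stochastic operation takes an explicit
integer seed and restores the RNG state afterwards (no global state);
sub-seeds for multi-stage runs are drawn once up front from the master
seed, so adding a stage never reshuffles earlier stages' draws;
`run_pipeline()` reports contain no timestamps, making reruns of the same
configuration byte-identical; quantile thresholds use R's default type-7
definition; noise-free exactness tests assert to $10^{-9}$ relative, OLS
against a normal-equations oracle to $10^{-10}$.

## Known limitations

* The exit model ties Ki67 loss to mitosis; quiescence entered without a
  terminal mitosis, or slow Ki67 decay, would need the lag parameter and a
  different generative story.
* The conversion trajectory is a single-compartment hazard model; it
  reproduces prevalence curves, not lineage structure, and its defaults
  are calibrated to one differentiation system.
* Synthetic flow samples do not emulate spectral overlap, autofluorescence
  drift, or acquisition-order effects, so passing gating tests says
  nothing about compensation pipelines.
* The simulator tracks one daughter per mitosis (non-expanding renewal);
  population growth, niche effects and spatial structure are out of scope.
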