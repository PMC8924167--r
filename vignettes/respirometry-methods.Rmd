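---
title: "From oxygen traces to metabolic phenotypes: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From oxygen traces to metabolic phenotypes: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flipscope)
library(dplyr)
```

## The measurement problem

Intermittent-flow respirometry measures an aquatic animal's oxygen uptake by
alternating two chamber states: a sealed *measure* phase, during which the
animal draws the dissolved oxygen concentration down, and a *flush* phase,
during which pumps re-oxygenate the chamber back towards air saturation.
Each measure phase yields one estimate of the mass-specific oxygen uptake
rate,

$$
\dot{M}\mathrm{O}_2
  = \frac{-b \, V_{\mathrm{eff}} - \dot{B}}{m},
$$

where $b$ is the ordinary-least-squares slope of concentration against time
within the sealed phase (mg O~2~ L^-1^ h^-1^), $V_{\mathrm{eff}}$ is the
chamber water volume minus the animal's body volume (L), $\dot{B}$ is the
microbial background respiration rate of the chamber (mg O~2~ h^-1^), and
$m$ is body mass (kg).

When the animal enters the chamber immediately after exhaustive exercise
(e.g. a chase protocol that elicits repeated tail flips in a lobster), the
time course of $\dot{M}\mathrm{O}_2$ over the following one to two days
carries the full aerobic and anaerobic phenotype:

* **MMR** — maximum metabolic rate, the single highest accepted per-cycle
  $\dot{M}\mathrm{O}_2$ of the trial;
* **SMR** — standard metabolic rate, the mean of the lowest 10% of accepted
  values (the quiescent floor);
* **RMR** — routine metabolic rate, the mean from 16 h after exercise to
  trial end, with its standard deviation;
* **aerobic scope** = MMR − SMR and **factorial scope** = MMR / SMR;
* **recovery time** — the time of the third cycle falling below
  RMR + 1 SD;
* **EPOC** — excess post-exercise oxygen consumption, the trapezoidal
  integral of $\dot{M}\mathrm{O}_2$ above a baseline from the first cycle
  to recovery time; and **recovery rate** = EPOC / recovery time.

Escape capacity is measured separately from chase videos: an annotator
clicks the animal's position before and after each tail flip, and speed per
event is the Euclidean pixel displacement divided by the frame gap, scaled
by the frame rate and a pixel-per-centimetre calibration.

## Estimator settings that matter

All settings are arguments with defaults, and every derived table echoes
them as columns.

| Setting | Default | Units | Why |
|---|---|---|---|
| SMR quantile | 0.1 | — | lowest-decile mean; `ceiling(0.1 n)` values, requires ≥ 10 accepted cycles |
| RMR window start | 16 | h | the longest observed recovery time in the design this emulates |
| recovery threshold | RMR + 1 SD | — | SD is that of the RMR window, the only SD defined in context |
| recovery counting | cumulative | — | third sub-threshold cycle counted from trial start; a consecutive-run rule is provided as an alternative |
| EPOC baseline | RMR | — | see below; SMR and no-baseline modes available |
| r² threshold | 0.9 | — | cycles with poorer linear fits are flagged and excluded everywhere |
| saturation floor | 77 | % | cycles whose minimum saturation falls below it are flagged |

**Why EPOC defaults to an RMR baseline.** A literal "area under the curve"
with no baseline grows linearly with recovery time and for a ~1 kg animal
at routine rates near 30–50 mg O~2~ h^-1^ kg^-1^ would exceed reported
EPOC magnitudes (a few hundred mg O~2~ kg^-1^ over ~7–12 h) several-fold.
Magnitudes of that order are only consistent with integrating the *excess*
above a routine baseline, so `baseline_mode = "rmr"` is the default; the
literal mode (`"none"`) and an SMR baseline remain available and the mode
used is recorded in the output. Negative excursions below the baseline
contribute zero area rather than negative area, keeping EPOC monotone
non-decreasing in recovery time.

**Cumulative versus consecutive counting.** "Falls three times below the
threshold" can be read either way; on a monotonically declining trace the
two agree, and both are implemented (`recovery_rule`). Cumulative counting
is the default because it is the weaker reading and never later than the
consecutive rule.

**QC is flag-based.** Short cycles (< 3 samples), poor fits, saturation
floor breaches and negative corrected rates are flagged, never silently
repaired, dropped or clipped; `accepted` collects the flags and the trait
estimators use accepted cycles only. An SMR ≤ RMR ≤ MMR ordering violation
is reported (`qc_ordering_ok`), not reordered.

## What the synthetic generator emulates

`simulation_truth()`, `chamber_spec()` and `cohort_design()` parameterise a
forward model of the whole experiment, so that every estimator can be
tested by parameter recovery against known truth.

The true uptake trajectory is

$$
\dot{M}\mathrm{O}_2(t) = b(t) + (\mathrm{MMR} - \mathrm{RMR})
  \, e^{-t/\tau},
$$

capped at MMR (the aerobic ceiling). The baseline $b(t)$ equals RMR,
interrupted by two stochastic components:

* **quiescent episodes** dipping to SMR — a two-state alternating-renewal
  process (exponential episode lengths, mean 0.5 h) whose long-run
  quiescent fraction is a parameter (default 0.2). Episodes start only
  after `quiescence_onset` (default $4\tau$, by which the recovery excess
  has decayed below 2%): an animal still repaying its oxygen debt does not
  settle into quiescence. This two-state construction makes the
  lowest-decile estimator target SMR without asserting any mechanistic
  model of quiescence;
* **activity bursts** (Poisson rate 0.2 h^-1^, 6 min long, amplitudes
  5–15% of MMR − SMR above baseline) representing spontaneous movement.

The exponential recovery form is a modelling choice made for testability —
it yields the closed-form identity $\mathrm{EPOC} =
(\mathrm{MMR}-\mathrm{RMR})\,\tau$ against which the pipeline's integral
can be checked — not a claim about lobster physiology.

The chamber forward model draws concentration down at
$(\dot{M}\mathrm{O}_2(t)\, m + \dot{B}) / V_{\mathrm{eff}}$ during measure
phases and relaxes it towards saturation during flushes as a first-order
process with rate constant $5/T_{\mathrm{flush}}$, i.e. > 99% recovery by
the end of each 8-min flush — chosen because the emulated setup reports
high end-of-flush saturations but no flush kinetics. Gaussian sensor noise
(default 0.01 mg L^-1^) is added per 10-s sample and readings are capped at
the saturation concentration, so simulated concentrations always lie in
$(0, c_{\mathrm{sat}}]$. A parameter set that would drive the concentration
to zero mid-cycle is rejected with the offending cycle named.

Default magnitudes describe a ~1 kg spiny lobster measured at the middle
(17.5 °C) temperature of the emulated design: SMR 30, RMR 36, MMR
110 mg O~2~ h^-1^ kg^-1^, $\tau$ = 3 h, background respiration 5% of SMR,
10 L chamber, 1 L body volume (1.12 kg at 1.12 g mL^-1^), 6-min
measure / 8-min flush, 10-s sampling, 48-h trials. `simulate_cohort()`
expands a base truth across a fully factorial species × acclimation ×
acute-temperature grid: SMR scales as $Q_{10}^{(T - T_{\mathrm{ref}})/10}$
(default $Q_{10}$ = 3.3) times a per-step acclimation factor (default 0.81
per step, compounding to a ~34% reduction from cold- to warm-acclimated);
MMR uses its own, flatter $Q_{10}$ (1.4) and no acclimation effect
("plastic floors, concrete ceilings"); the recovery constant shrinks by
0.78 per acclimation step. Individual variation is lognormal
(CV 8%), body masses are drawn near 1.07 kg, and each animal's tail-flip
count is Poisson with mean proportional to its true EPOC, giving a known
positive escape–EPOC coupling. Reproducibility is hierarchical: one master
seed expands into per-animal substreams by a stable string hash of the
animal ID, so partial re-runs reproduce exactly.

**What the generator does not emulate** — and hence what passing recovery
tests do not show about real data: haemolymph chemistry (lactate, arginine
phosphate), moulting, digestion, diurnal rhythms, sensor drift or
autocorrelated noise, chamber mixing artefacts, and any behavioural model
of the chase itself. Recovery tests demonstrate that the estimators invert
this forward model at realistic noise; field data can violate the model in
ways the QC flags are designed to surface rather than absorb.

## Numerical choices and degenerate inputs

* Slopes are exact OLS with an analytic $r^2$; a constant cycle has
  undefined $r^2$ and is flagged rather than given $r^2 = 1$.
* Cycle time is the midpoint of the measure phase; with 6-min cycles the
  extracted series equals the generator's trajectory to within
  discretisation error of order the cycle length (< 2% on noise-free
  traces).
* The lowest-decile count is `ceiling(0.1 n)` with ties broken by cycle
  order — deterministic for any series.
* EPOC uses trapezoidal integration on the irregular cycle-time grid; on
  the analytic exponential trajectory it converges to
  $(\mathrm{MMR}-\mathrm{RMR})\tau$ as the cycle period shrinks (well
  within 5% at a 6-min period).
* Zero-frame-gap click pairs have undefined speed: counted as escapes,
  excluded from speed statistics, reported in `n_flagged_zero_gap`.
* Group confidence intervals use the t distribution on the group SD;
  singleton groups are flagged (`ci_defined = FALSE`), not dropped.
* $Q_{10}$ is computed from the two endpoint means of the experimental
  range (14.0 and 21.5 °C), not from a log-linear fit across all three
  temperatures; exchanging both endpoint (rate, temperature) pairs leaves
  it unchanged, and swapping the rates alone inverts it.
* Trial-level escape speed reports both the mean and the maximum over
  events, since either summary is defensible; downstream analyses state
  which they use.

## A worked run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(seed = 1)
res <- run_pipeline(cfg)
res$metrics %>% select(trial_id, smr, smr_true, mmr, mmr_true, epoc, epoc_true)
make_figures(res)
```

The demonstration configuration (2 species × 2 acclimation groups × 2
animals × 2 experimental temperatures, 30-h trials) runs in a few seconds;
the package's validation uses 50 simulated 48-h trials at the default
settings above, which completes in well under a minute. These problem
sizes were chosen so the full validation suite runs comfortably on a
laptop while leaving the median-error estimates stable across seeds.

## Known limitations

* Saturation concentration is a supplied constant; no solubility model
  from temperature and salinity is included, so traces spanning large
  temperature drifts need externally corrected saturation values.
* Background respiration is interpolated linearly between the pre- and
  post-trial blank rates; real microbial growth may be super-linear late
  in long trials.
* The mixed-model analyses often applied to such trait tables (LME/GLMM
  with repeated measures per animal) are deliberately out of scope; the
  package stops at tidy trait tables, group summaries, contrasts,
  divergences and correlations. Contrasts computed from raw group means
  will not equal published model-adjusted percentages where those came
  from mixed-model estimated marginal means.
* A trial whose MO~2~ never falls three times below RMR + 1 SD is
  reported as "not recovered" with `NA` recovery time and EPOC; it is the
  caller's decision whether to extend the trial or exclude the animal.
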