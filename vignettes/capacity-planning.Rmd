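---
title: "Demand-capacity modelling for remote patient monitoring programs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demand-capacity modelling for remote patient monitoring programs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpmcapacity)
```

## The problem

Algorithm-enabled remote patient monitoring (RPM) programs — for example
continuous-glucose-monitor review in paediatric type 1 diabetes clinics —
generate a steady stream of review work: each period an algorithm flags a
subset of monitored patients, clinicians review the flagged data and contact
the patients who need outreach. Clinics planning such programs need to know
whether their reviewer workforce can keep up with the patient population,
and which staffing or workflow lever to pull when it cannot.

`rpmcapacity` implements a deterministic demand-capacity model of this
workload, a single-axis scenario explorer, a stochastic workload simulator,
and tooling to calibrate and evaluate the model against historical
operational logs.

## The deterministic model

Each **cohort** is a patient sub-population sharing a review cadence:
enrolled count $N$, expected new patients per period $A$, graduation
fraction $g$, review frequency $f$ (reviews per patient per period) and
contact fraction $p$ (fraction of reviewed patients needing outreach).
Expected contact demand per period is

$$D = \sum_i f_i \, p_i \, (N_i + A_i).$$

The **provider pool** delivers capacity

$$K = \frac{60}{t} \times m \times h,$$

with $m$ providers, $h$ hours per provider per period and $t$ average
minutes per review (data check plus any message). The per-provider-hour
review capacity is derived as $60/t$ so that review-time scenarios are
expressible; an explicit `reviews_per_hour` override is accepted for
programs that measure throughput directly.

**Coverage** is capacity as a percent of demand, $100\,K/D$, capped at
100\% and reported to the nearest integer percent (commercial, half-up
rounding; full precision is kept internally and the uncapped ratio is
retained in `raw_coverage`). We deliberately define the ratio as
capacity-over-demand: it is the only direction consistent with the
dashboard behaviour the model reproduces — coverage rises from 73\% to 91\%
when the review time drops from 10 to 8 minutes (the capacity ratio
$10/8 = 1.25$ applied to 73 gives 91.25), and saturates at 100\% once
capacity exceeds demand. Zero demand is defined as fully covered rather
than an error.

Population projection uses the recurrence $N(k+1) = N(k)(1-g) + A$:
graduation applies to the current census before the period's enrolments are
added. The alternative ordering differs only at order $g \times A$ per
period and nothing in the program statistics distinguishes the two; we fix
this one. With $g = 0$ the census grows exactly linearly; with $g > 0$ it
converges to the fixed point $A/g$.

### Units

The review period is the model's single time unit (one week by default,
matching the program the model is calibrated to). A monthly review cadence
within a weekly period is expressed as $f = 0.25$ using the plain
4-weeks-per-month convention; users who prefer the calendar-average
conversion can supply $f = 1/4.345$ directly — the choice is a user input,
not baked in.

### Anchored scenarios

The baseline program the model reproduces published its pool (3 providers
$\times$ 4 h/week at 10 min/review, so $K = 72$ reviews/week) and its
baseline coverage (73\%), but never its contact fraction. The implied
demand, $D = 100 K / 73 \approx 98.6$ contacts/week, is recovered with
`demand_from_coverage()` and carried as a fixed-demand **anchored
scenario**; `scale_coverage()` performs the same inversion in one step. The
built-in `generate_scenario("baseline_study")` preset likewise leaves its
cohort contact fractions `NA`: defaulting them silently would fabricate an
unpublished number, so demand computation refuses placeholders until the
user sets them.

## Scenario exploration

`evaluate_modification()` recomputes coverage with exactly one axis changed
— provider count, hours per period, minutes per review, contact fraction,
review frequency, or total population — and reports the resulting reported
coverage and its delta in percentage points. `sufficiency_table()` inverts
the coverage equations in closed form to find, per axis, the minimal change
that makes capacity meet demand:

* providers: $m^\* = \lceil D\,t/(60 h)\rceil$;
* hours: $h^\* = D\,t/(60 m)$;
* minutes: $t^\* = 60\,m\,h/D$;
* contact fraction / review frequency: the common value across cohorts
  solving $D = K$;
* population: the proportional rescaling of all cohorts solving $D = K$.

Sufficiency is judged on the *raw* (uncapped) ratio, since the capped value
saturates at exactly 100. Reported sufficient values are snapped to slider
resolution — 0.1 for hours and minutes, 0.01 for the two fractions, whole
patients for population — always rounded toward more capacity (or less
demand) so the reported value is itself sufficient. The resolutions differ
because an 0.1 step in a fraction bounded by 1 would be far coarser than an
0.1-hour step; 0.01 keeps fraction sliders percent-granular. An axis whose
snapped value cannot reach full coverage (for instance a required review
time below 0.1 min) is flagged unreachable rather than silently rounded.
The table considers one axis at a time by construction — cross-axis
optimisation, like cost-weighting a hire against longer hours, is a
financial-planning question outside this model's scope.

```{r sufficiency}
pool <- provider_pool(3, 4, 10)
base <- scenario(list(), pool, demand = demand_from_coverage(73, pool))
sufficiency_table(base)
```

## The workload simulator

The deterministic model treats demand as its expectation; real flagged
counts fluctuate. `simulate_workload()` adds that variance. Per period:

1. patients shown for review follow the deterministic trajectory,
   `round(f_i * N_i(k))` summed over cohorts;
2. the flagged count is Binomial(shown, `flag_probability`), drawn per
   cohort;
3. the contacted count is the flagged count times a per-period ratio drawn
   from a Normal(`contact_ratio_mean`, `contact_ratio_sd`) truncated to
   $[0, 1]$, rounded half-up;
4. contacts beyond the period's capacity $K$ join a FIFO backlog served
   ahead of new contacts in later periods.

The contacted-given-flagged mechanism is a *period-level* ratio rather than
per-patient Bernoulli thinning because the program statistics the defaults
are calibrated to (ratio mean 51.8\%, SD 17.1\% across roughly two years of
weekly periods) describe period-level dispersion; per-patient Bernoulli
would understate it badly (a binomial thinning of ~60 flagged patients has
a ratio SD near 6 points, not 17). The truncated-normal draw uses the
inverse-CDF construction, so a fixed seed reproduces runs bit-for-bit;
draws occur in a fixed order (flagged counts, then the ratio, within each
period) from the single seeded generator. At the default calibration the
truncation barely bites — the bounds sit 3.0 and 2.8 standard deviations
from the mean — shifting the realised mean by under 0.1 point and shrinking
the SD by about 2\% relative, which is why the recovered statistics land
near 51.5/16.9 rather than exactly 51.8/17.1.

Expected fractional counts are rounded half-up at the shown and contacted
steps; a Poisson draw for shown counts is a documented alternative we chose
not to default to, since the cohort census is a scheduled quantity, not an
arrival process. `shortfall_summary()` aggregates replicates into shortfall
probabilities, backlog statistics and the per-period coverage distribution.
Conservation — cumulative contacts equal cumulative served plus final
backlog — holds exactly on every replicate, and in the degenerate limit
(ratio SD 0, static population) the pooled simulated coverage converges to
the deterministic value.

## Historical logs, calibration and evaluation

Operational logs are CSV time series with the exact header
`period_start,shown,flagged,contacted`, ISO-8601 dates in strictly
increasing order, and `contacted <= flagged <= shown` in every row;
`load_log()`/`write_log()` validate and round-trip them bit-identically.
Dates are treated as period labels only — no calendar arithmetic is
attempted, so gap weeks are the user's responsibility.

`ratio_statistics()` reports the per-period contacted/flagged ratio mean
and sample SD (the $n-1$ denominator; at a hundred-odd periods the $n$
versus $n-1$ distinction is below the one-decimal reporting precision) as
percentages to one decimal, the precision of the published figures.
Periods with zero flagged patients have an undefined ratio and are excluded
with their count reported — the source statistics do not state a handling,
and exclusion is the only choice that does not invent a value.
`fit_calibration()` turns a log into simulator parameters, adding
`flag_probability` as the mean per-period flagged/shown over periods with
patients shown. `projection_vs_actual()` compares projected contacts (and,
given a flag probability, projected flagged counts) against a log,
reporting per-period errors and MAPE.

## The synthetic generator

No real program logs are publicly deposited, so `generate_log()` produces
synthetic ones with the reported statistical structure: shown counts
growing steadily (linear drift by default — the published description is
qualitative, "steadily increased", and a line is the least-structured
match; a logistic option saturating at a carrying capacity is available
via `growth_model`), binomial flagging, and the period-level truncated-
normal contact ratio at the published default calibration (mean 0.518,
SD 0.171). The flag probability was never published and has no default —
it must be supplied or fitted from a log. Generated logs pass `load_log()`
validation by construction and are byte-identical under a fixed seed.

What synthetic logs do **not** emulate: the flagging algorithm's actual
criteria, patient-level correlation (repeat flags for the same patient),
seasonal structure, or the specific published early-month counts and
ratios — those derive from undeposited raw logs and serve only as
plausibility ranges here. Passing tests therefore demonstrate internal
consistency and calibration recovery, not fidelity to any particular
clinic's data.

## Problem sizes and numerical choices

The test suite verifies the published what-if percentages exactly; solver
correctness against exhaustive grid search on 200 randomized scenarios;
calibration recovery over 20 seeds of 110-period logs (the published
statistics span roughly 110 weekly periods) plus single long runs of
500–10,000 periods; and conservation/monotonicity properties on randomized
runs. These sizes put Monte-Carlo standard errors well inside the asserted
tolerances — e.g. the ratio-mean estimate from 10,000 periods carries a
standard error of about 0.17 points. Where a tolerance is checked on a
single-seed statistic whose standard error is comparable to the tolerance,
the test averages a handful of seeds so the bound sits near three standard
errors. Floating-point ceilings in the closed-form solvers carry a $10^{-9}$
guard so that exact boundary cases (capacity exactly equal to demand) do
not round up spuriously.

## Known limitations

* Providers are interchangeable: no per-provider heterogeneity in speed or
  availability, and no synchronous phone/video time — the model prices one
  averaged review-plus-message duration per contacted patient.
* The review period is a single rigid time unit; no intra-period
  scheduling, and the backlog discipline is plain FIFO.
* Demand linearity assumes the contact fraction does not respond to
  population size or backlog (no triage feedback).
* The published cohort counts are internally inconsistent in the source
  program description (a 277-patient total alongside cohort sizes summing
  to 362); the model takes user-supplied counts and does not adjudicate.
* No financial modelling: the sufficiency table says *what* reaches full
  coverage, not what it costs.
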