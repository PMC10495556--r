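# rpmcapacity

Capacity planning for algorithm-enabled remote patient monitoring (RPM)
programs.

In an RPM program — the motivating case is continuous-glucose-monitor
review in a paediatric type 1 diabetes clinic — an algorithm flags a subset
of monitored patients each period, clinicians review the flagged data, and
some reviewed patients are contacted. Clinic leads need to know whether
their reviewer workforce covers the patient population's demand for review
and outreach, and which single lever (hiring, hours, review speed, cadence,
cohort size) closes a gap. `rpmcapacity` is a library and command-line tool
for exactly that question.

## The model

Demand per review period, summed over patient cohorts with review frequency
*f*, contact fraction *p*, enrolled count *N* and expected new patients *A*:

    D = Σᵢ fᵢ · pᵢ · (Nᵢ + Aᵢ)        expected contacts / period

Capacity of a pool of *m* providers, each available *h* hours per period at
*t* minutes per review:

    K = (60 / t) · m · h              reviews / period

Coverage is capacity as a percent of demand, `100·K/D`, capped at 100% and
reported to the nearest integer percent (the uncapped ratio is kept
alongside). On top of the deterministic model sit:

* a **scenario explorer** — single-axis what-ifs and closed-form inversions
  giving the minimal change per axis that reaches full coverage;
* a **Monte-Carlo workload simulator** — binomial flagging plus a
  period-level truncated-normal contacted-to-flagged ratio (default
  calibration: mean 51.8%, SD 17.1%), with FIFO backlog accounting;
* **historical-log tooling** — validated CSV logs of per-period
  shown/flagged/contacted counts, ratio statistics, projection-vs-actual
  comparison, and calibration fitting;
* a **synthetic log generator**, so everything is testable without any
  non-public operational data.

## Worked example

The published program ran 3 providers at 4 h/week and 10 min/review
(K = 72 reviews/week) at a reported 73% coverage. The baseline contact
fraction was never published, so the demand is back-solved from the
coverage figure and carried as a fixed-demand anchored scenario:

```r
library(rpmcapacity)
pool <- provider_pool(3, 4, 10)
base <- scenario(list(), pool, demand = demand_from_coverage(73, pool))
scenario_coverage(base)
#> <coverage> demand=98.63 capacity=72.00 raw=73.00% reported=73%

evaluate_modification(base, "minutes_per_review", 8)
#>                 axis baseline_value modified_value resulting_coverage delta_coverage
#> 1 minutes_per_review             10              8                 91             18
```

Cutting the review time to 8 minutes lifts coverage from 73% to 91% — an
18-point gain; raising the headcount to 5, or hours to 6, each reach the
100% cap (+27 points). The sufficiency table inverts the equations per
axis:

```r
sufficiency_table(base)
#>                 axis baseline_value sufficient_value resulting_coverage reachable note
#> 1        n_providers              3              5.0                100      TRUE
#> 2   hours_per_period              4              5.5                100      TRUE
#> 3 minutes_per_review             10              7.3                100      TRUE
```

Full coverage needs 5 providers, or 5.5 h/week each, or reviews at 7.3
minutes — each change on its own. The demand-side axes (contact fraction,
review frequency, population) appear too when the scenario is built from
explicit cohorts rather than an anchored demand.

The simulator quantifies what the deterministic model hides — week-to-week
demand swings and the backlog they create:

```r
cfg <- simulation_config(52, cohort("t1d", 270, contact_fraction = 0.37),
                         flag_probability = 0.7, seed = 1, n_replicates = 100)
shortfall_summary(simulate_workload(cfg, pool))$pooled
```

## Command line

The installed script `inst/cli/rpmcap.R` exposes the same operations as
subcommands reading/writing CSV and YAML:

```sh
RPMCAP=$(Rscript -e 'cat(system.file("cli", "rpmcap.R", package = "rpmcapacity"))')
Rscript $RPMCAP generate  --periods 110 --initial-shown 80 --flag-probability 0.4 --seed 7 --out log.csv
Rscript $RPMCAP calibrate --log log.csv --out calibration.yaml
Rscript $RPMCAP generate  --preset baseline_study --out scenario.yaml
Rscript $RPMCAP scenarios --scenario scenario.yaml --out sufficiency.csv
Rscript $RPMCAP simulate  --scenario scenario.yaml --flag-probability 0.4 --seed 7 --out sim.csv
Rscript $RPMCAP evaluate  --log log.csv --scenario scenario.yaml --out comparison.csv
```

(The `baseline_study` preset deliberately leaves contact fractions unset —
the study never published them — so set them in `scenario.yaml` before the
`scenarios`, `simulate` and `evaluate` steps.)

## Scope

The model is deliberately population-level: no per-provider heterogeneity,
no patient-level flag correlation, no intra-period scheduling beyond FIFO
backlog, and no financial modelling of the alternatives it enumerates. See
the methods vignette (`vignettes/capacity-planning.Rmd`) for the full
account of assumptions, calibration and limitations.
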