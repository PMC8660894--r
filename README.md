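# ricebench

Yield-gap and resource-use benchmarking for rice cropping systems.

Rice systems differ so much in climate, water regime and cropping
intensity that raw yields and raw input rates cannot be compared across
them. `ricebench` implements the two normalizations that make a global
comparison meaningful, and everything downstream of them:

* **Yield-gap closure** — actual yield as a percentage of the locally
  attainable yield potential Yp (an input, simulated upstream by crop
  models): `closure = 100 · Ya / Yp`.
* **Yield-scaled resource metrics** — global warming potential
  (GWP100 = CO2 + 25·CH4 + 298·N2O, with Tier-1 style paddy methane and
  a nitrogen-surplus N2O model), fossil energy input and net energy
  yield, water supply (irrigation + in-season precipitation), partial
  nitrogen balance and excess N (the part of the balance above
  75 kg N ha⁻¹), pesticide applications and EIQ field-use rating, and
  labor — each per hectare and per Mg of grain.

On top of the per-crop-cycle accounting it provides area-weighted
aggregation to per-crop and annual system metrics, a six-dimension
overall performance index (lower = better), Pearson correlation
reporting, and a scenario engine that closes yield gaps to the
exploitable ceiling (75% of Yp) in large-gap systems (< 60% closure)
under two nitrogen assumptions: balances capped at 75 kg N ha⁻¹ in
large-balance systems (> 100 kg N ha⁻¹), or unchanged yield-scaled
balances. A seeded generator produces synthetic 32-system cohorts with
the structure of multi-country farm-survey compilations, so the whole
pipeline runs and is tested without any external data.

## Worked example

```r
library(ricebench)

cfg     <- default_config()                     # coefficient tables
systems <- generate_cohort(global_cohort_spec(seed = 1), cfg)
metrics <- system_metrics(systems, cfg)

wide <- metrics_wide(metrics, "per_crop")
global_weighted_mean(wide$yield_potential, wide$annual_area)
#> [1] 9.58344
global_weighted_mean(wide$closure, wide$annual_area)
#> [1] 48.51823

run_scenarios(systems, cfg)$cap_n
#> Scenario 'cap_n'
#>   production: 215.1 -> 325.0 Mt (+109.9 Mt, +51%)
#>   excess N:   0.56 -> 0.00 Mt N (-0.56 Mt, -99%)
#>   targets: 19 large-gap, 8 large-N-balance systems
```

Reading: across this cohort the area-weighted yield potential is
9.6 Mg ha⁻¹ crop⁻¹ and farmers realize 48.5% of it. Raising the 19
large-gap systems to 75% of their potential would add 110 Mt of paddy
(+51%) on unchanged area, and capping the N balance of the 8
inefficient systems at 75 kg N ha⁻¹ would remove essentially all excess
nitrogen. The `fixed_ysnb` scenario shows the cost of closing the same
gaps without efficiency gains: excess N rises by ~150% instead.

Real survey tables are read with `read_systems("file.csv")` (one row
per crop cycle; see `inst/extdata/example_systems.csv` for the schema,
and `inst/extdata/example_mapping.yaml` for mapping foreign column
headers). Coefficients can be replaced wholesale or per table via
`read_config("coefficients.yaml")`.

## Analysis workflow

The `analysis/` scripts run the full study pipeline on the reference
cohort and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # cohort -> results/systems.csv
Rscript analysis/02_assess.R        # per-cycle accounts + system metrics
Rscript analysis/03_performance.R   # scores, overall index, radar data
Rscript analysis/04_scenarios.R     # both counterfactuals
Rscript analysis/05_correlations.R  # correlation panel + summaries
```

`RICEBENCH_SEED` changes the cohort seed (default 1).

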