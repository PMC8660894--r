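---
title: "Benchmarking yield gaps and resource-use efficiency in rice cropping systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking yield gaps and resource-use efficiency in rice cropping systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ricebench)
```

## The problem

Rice feeds roughly half the world, and the question of where agronomic
investment buys the most — more grain, less environmental burden, or both —
hinges on two quantities that must be compared across very different
climates: the **yield gap** (how far farmer yields sit below the locally
attainable ceiling) and **resource-use efficiency** (how much energy,
water, nitrogen, pesticide and labor each tonne of grain costs). A yield of
8 Mg/ha is an excellent result where the simulated potential is 10 Mg/ha
and a mediocre one where it is 14.5; only after normalizing by potential,
and only after scaling resource use by yield, do cropping systems in, say,
semiarid irrigated deltas and rainfed tropical lowlands become comparable.

`ricebench` implements that comparison as a pipeline over a survey-style
table of cropping systems — one record per crop cycle, each system holding
one to three cycles per year — with the yield potential taken as an input
(it is produced upstream by calibrated crop models; this package never
simulates it).

## Data model

A cohort is a single tidy table (class `rb_systems`), one row per crop
cycle, carrying the system descriptors (code, country, climate zone, water
regime, ecosystem, establishment method, mechanization, field size, annual
harvested area) and the cycle record (yields at standard moisture of
140 g H2O/kg grain, harvested area, N/P/K fertilizer, manure, seed,
irrigation and in-season precipitation, labor hours, straw management,
flooded-cultivation days, water-regime and pre-season classes, and three
nested event lists: pesticide applications, field operations, organic
amendments). The canonical interchange is CSV with the event lists encoded
as compact `;`-separated strings; a nested JSON form and a header-mapping
mechanism (for third-party survey exports with different column names) are
also supported. Validation is strict: unknown enum levels, duplicate
(system, cycle) keys, negative rates and out-of-range cultivation periods
are typed errors, while survey noise (actual yield above potential) is
kept but warned about. Unknown factor keys never fall back to a default —
a silent substitution would corrupt the greenhouse-gas account.

All coefficients live in a config object (`default_config()`, or a YAML /
JSON file via `read_config()`), each table carrying a provenance string.

## The accounting, per crop cycle

**Global warming potential.** GWP sums, as CO2-equivalents over a 100-year
horizon (CH4 × 25, N2O × 298):

* embodied emissions of inputs (rate × factor over fertilizer, seed,
  pesticide a.i., manure),
* fuel CO2 of field operations including irrigation pumping,
* methane from the flooded paddy, Tier-1 style: a baseline daily emission
  factor scaled by water regime, pre-season water status, and organic
  amendments via `SFo = (1 + Σ rate·CFOA)^0.59`, times the cultivation
  days; upland rice emits none. The packaged factor table is in the style
  of the IPCC 2019 refinement and is labelled as such in the config
  (`ch4$table_label`) so a study can swap in the 2006 vintage or its own
  measurements without touching code,
* nitrous oxide driven by the cycle's **N surplus** — inputs minus
  aboveground N at maturity — through a configurable response; the default
  is the exponential fit from the N-balance meta-analysis literature,
  `N2O-N = 0.54·exp(0.0063·surplus)` kg/ha, and a piecewise-linear form is
  available. Indirect N2O is a fixed fraction (default 20%) of direct.
  Masses are carried as N2O-N and converted by 44/28 exactly once, at the
  CO2-eq step — the bookkeeping that prevents the classic double-conversion
  bug.

Soil carbon is treated as steady state (no term), which is the standard
assumption for long-flooded lowland rice; no claim is made for the upland
system.

**Energy.** Input energy mirrors the GWP structure (embodied energy of
inputs, fuel energy, plus human labor at 2 MJ/h); output is grain energy
on a dry-matter basis (0.86 × 15.2 MJ/kg by default) and net energy yield
is the difference.

**Nitrogen.** The partial balance is inputs (fertilizer + manure N +
biological fixation: 30 kg N/ha/crop in lowland, 10% of that in upland)
minus removals (grain N, plus straw N when straw is removed or burned;
retained straw removes nothing). Leaching and denitrification are taken to
offset inputs from irrigation water and deposition, so neither appears.
Negative balances (soil N mining) are legitimate outputs. **Excess N** is
the part of the balance above 75 kg N/ha — the level above which reactive
losses rise steeply in cereal systems — accumulated as
excess × area over all cycles, in Mt N/yr. Whether grain N concentration
applies to standard-moisture or dry mass is a config switch
(`n_removal_dry_matter`, default standard moisture, matching how survey
yields are reported).

**Pesticides.** Number of application events (the headline metric — EIQ
values are uncertain enough that the count is the more robust signal),
total active ingredient, and the EIQ field-use rating (Σ EIQ × rate), all
split by class. An a.i. missing from the EIQ table stays in the counts but
is excluded from the rating with a warning. Each product in a tank mix
counts as one event.

## Aggregation and the performance index

Cycle values aggregate per system on two bases: **per-crop**
(harvested-area-weighted mean across cycles) and **annual** (sum — so
triple rice has a higher annual than per-crop potential). Closure on each
basis is the ratio of aggregated actual to aggregated potential yield, and
every resource metric also comes yield-scaled (divided by the basis yield),
so that yield-scaled × yield recovers the area value identically. Cohort
averages are weighted by annual harvested area; correlations, following the
convention of the figures they mirror, are unweighted (one point per
system).

The overall performance index scores each system on six dimensions —
yield gap (100 − closure, clipped at 100 for scoring only), and
yield-scaled GWP, water supply, pesticide applications, labor, plus the
absolute deviation of the yield-scaled N balance from 8 kg N/Mg — each
normalized by the cohort maximum. The N-balance dimension is a deviation
rather than a minimization because both a large surplus (reactive losses)
and a strongly negative balance (soil mining) are bad; 8 kg N/Mg is the
level observed in the best-performing irrigated systems. The index is the
mean of three blocks — yield gap, the average of the four resource scores,
labor — a deliberate weighting so that one pillar with four metrics does
not dominate the two with one each. The block weights are configurable
(`cfg$index_weights`), and the normalization cohort can be the full set or
each climate zone separately.

## Scenario engine

Two counterfactuals, selection strict in both cases:

1. **cap_n** — every system with per-crop closure below 60% of potential
   is raised, cycle by cycle, to 75% of its own cycle's potential (the
   exploitable ceiling); every system with per-crop N balance above
   100 kg N/ha has its balance reduced to 75 kg N/ha, zeroing its excess.
   Balances of systems receiving only the yield intervention stay at
   baseline by default — the survey gives no basis for guessing how their
   management would change — but `cap_gap_systems = TRUE` extends the cap
   to them. A system in both sets receives both interventions.
2. **fixed_ysnb** — the same yield increases, but each raised cycle keeps
   its baseline yield-scaled N balance, so the balance scales up with the
   yield. No cap is applied. Cycles with zero yield (undefined
   yield-scaled balance) are left at baseline with a warning.

Production (Σ yield × area, Mt) is identical under both — they raise the
same yields — so the pair isolates the nitrogen consequence of closing
yield gaps with versus without efficiency gains. The 75%-of-potential rule
is applied per cycle rather than to the system mean because potential is
defined per crop; areas, intensity, and water regimes never change.

## The synthetic cohort generator

Because the package must be testable end-to-end without any external
download, `generate_cohort()` draws seeded cohorts with the statistical
structure the analysis assumes, and `global_cohort_spec()` is the
reference preset used in `analysis/` and the acceptance script: 32
systems, roughly half tropical, three-quarters irrigated, single to triple
rice (triple only tropical, one rainfed upland system), per-crop yield
potential 5.9–14.8 Mg/ha, closure 20–80%, labor 7–900 h/ha by
mechanization level, and up to nine pesticide applications per crop using
fictional active ingredients (so no real toxicity data ships with the
package) covered by a bundled EIQ table.

Structural couplings are chosen to emulate how real cohorts hang
together: rainfed systems sit mostly on the large-gap side; mechanization,
establishment method and field size track closure; fertilizer N is linear
in closure (slope 230 kg N per unit closure, recoverable by regression
from large unforced cohorts); irrigation amount follows the water-regime
class and pumping fuel follows the water lifted; retained straw mass is
the crop's own straw; season length tracks yield potential. Two counts are
forced exactly — 19 systems below 60% closure and 8 above 100 kg N/ha
balance — by drawing closures on the appropriate side of the cutoff with a
0.02 margin and back-computing fertilizer from a target balance with the
same coefficient tables the assessment uses (which is why generation and
assessment should share a config). Within a system, all cycles share one
closure value; that sacrifices seasonal yield-gap variation to make the
forced counts exact by construction.

What the generator does *not* emulate: measurement error and reporting
heterogeneity across countries, within-system management variation,
price/GDP covariates, multi-year weather variability, and any spatial
structure. Tests passing on synthetic cohorts therefore demonstrate the
correctness of the accounting and the scenario arithmetic, not the
empirical magnitudes of real systems; magnitudes (e.g., a global closure
near 50%, cap-scenario excess-N reductions near total) are properties of
the preset's design choices.

## Numerical choices and degenerate inputs

* Tolerances: aggregation identities (yield-scaled × yield, ledger
  additivity, GWP component sums) hold to 1e-9 relative or better and are
  tested against flat brute-force recomputations.
* Zero yield: yield-scaled values become `NA` (never `Inf`); such cycles
  are excluded from the fixed-ysNB adjustment with a warning.
* Degenerate score cohorts (a metric whose cohort maximum is 0) score 0
  with a logged warning; identical systems all score 1.
* Boundary systems (closure exactly 60%, balance exactly 100) are
  excluded from selection — the rules are strict inequalities.
* Closure above 100% (survey noise) is stored unclipped and clipped only
  inside the performance index.
* Random generation uses R's default RNG under a single `set.seed` per
  cohort; identical spec + seed reproduces byte-identical CSVs.

## Problem sizes

The shipped analyses and tests run the 32-system preset (54 crop cycles
at the documented seed), property tests on 1,000 randomly drawn cycle
records, and a 120-system cohort for the generator's parameter-recovery
check — sizes chosen to exercise every code path while keeping the whole
suite comfortably interactive.

## Known limitations

Yield potential is trusted as given; no uncertainty is propagated through
the coefficient tables (a study wanting uncertainty bands should re-run
the pipeline over sampled configs); the N2O default parameterization is a
literature-level fit shipped as config, not a site calibration; CH4
factors are Tier-1 class, not process-based; mixed water regimes within a
system (some cycles rainfed, some irrigated) are rejected as invalid
rather than modelled; and the P/K sides of the nutrient budget are
accounted only as embodied emissions and energy, not as balances.
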