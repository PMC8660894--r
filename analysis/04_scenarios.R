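#!/usr/bin/env Rscript
# Stage 4: yield-gap closure counterfactuals.
#
# Scenario 1 (cap_n): raise every large-gap system (per-crop closure
# < 60%) to 75% of its yield potential and cap the N balance of every
# large-balance system (> 100 kg N/ha) at 75 kg N/ha. Scenario 2
# (fixed_ysnb): same yield increases, but each raised cycle keeps its
# baseline yield-scaled N balance, so its balance grows with the yield.
# Areas and cropping intensity stay fixed in both.

suppressMessages(library(ricebench))

cfg <- default_config()
systems <- read_systems("results/systems.csv")

scen <- run_scenarios(systems, cfg)
write_scenario(scen$cap_n, "results/scenario_cap_n.json")
write_scenario(scen$fixed_ysnb, "results/scenario_fixed_ysnb.json")

print(scen$cap_n)
print(scen$fixed_ysnb)
message("wrote results/scenario_cap_n.json, results/scenario_fixed_ysnb.json")
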