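# Header-mapping example: external survey column names (left) to the
# canonical schema (right). Pass to read_systems(path, mapping = ...).
code: system_code
grain_yield_mg_ha: yield_actual
potential_yield_mg_ha: yield_potential
area_ha: harvested_area
fert_n_kg_ha: n_fertilizer
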