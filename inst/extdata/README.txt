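# A synthetic worked example (not field data): one releve and a species
# affinity table of the shape used for site trophic-level scoring.
# exchange_synthesis_table.csv: published synthesis of zone-aggregated
# groundwater/river exchange fluxes (Qf, bank length, unit flow Qu) for the
# Bregnier-Cordon reach of the upper Rhone; used as reference input for
# aggregation and unit-flow checks. Qu_printed is NA where the printed
# value is not legible in the source table.
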