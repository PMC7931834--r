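# Zambia national viral-load scale-up: base-case model inputs.
# Assay performance and unit-cost tables live in the CSVs next to this file.
assays_csv: assays.csv
unit_costs_csv: unit_costs.csv

# Annual share of ART patients accessing VL testing, by facility class and
# specimen class. Low-volume sites lose plasma samples to cold-chain and
# weekly-transport constraints; dried specimens restore high-volume access.
multipliers:
  high_volume: 0.80
  low_volume_plasma: 0.40
  low_volume_dried: 0.80
  unreachable_dried: 0.80

epi:
  # True prevalence of virological failure (>1000 copies/mL) among tested
  # patients, calibrated from base-case plasma volumes (930,982 tests for
  # 814,066 patients on the plasma assay); see calibrate_failure_prevalence().
  failure_prevalence: 0.14085957500758783
  correctness_model: product

visit_transport:
  visit_cost: 3.65          # USD per facility visit for a VL result
  transport:                # USD/year, by sample-transport network
    plasma_only: 3264509
    partial: 3637168
    full: 2390317

scenarios:
  - name: plasma_only
    specimen_high: plasma
    specimen_low: plasma
    include_unreachable: no
    transport_key: plasma_only
  - name: plasma_dbs
    specimen_high: plasma
    specimen_low: dbs
    include_unreachable: yes
    platform_mix: {capctm: 1.0}
    transport_key: partial
  - name: plasma_psc
    specimen_high: plasma
    specimen_low: psc
    include_unreachable: yes
    platform_mix: {capctm: 0.42, cobas8800: 0.58}
    transport_key: partial
  - name: dbs_only
    specimen_high: dbs
    specimen_low: dbs
    include_unreachable: yes
    platform_mix: {capctm: 1.0}
    transport_key: full
  - name: psc_only
    specimen_high: psc
    specimen_low: psc
    include_unreachable: yes
    platform_mix: {capctm: 0.61, cobas8800: 0.39}
    transport_key: full

seed: 1
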