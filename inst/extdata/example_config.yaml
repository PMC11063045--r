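# Example pipeline configuration: published operating counts of three
# fundus-screening models, evaluated in two settings whose prevalences are
# ILLUSTRATIVE placeholders (urban totals above rural, as community fundus
# screening programmes report), not measured values.
seed: 20260901
input: counts
counts_file: fundus_screening_counts.csv
cohort:
  diseases: [AMD, DR, PM]
  size: 100000
  settings:
    urban: {AMD: 0.026, DR: 0.018, PM: 0.010}
    rural: {AMD: 0.019, DR: 0.013, PM: 0.005}
analysis:
  positive_rule: exact_class
  alpha: 0.05
  k_pairwise: 3
  thresholds: {from: 0.01, to: 0.99, by: 0.01}
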