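# Demo analysis: two lowland forest PFTs (wet-like, dry-like), four virtual
# species each, on a 60 x 60 Central-America-like grid with one
# drying-and-warming scenario. Sizes are demo-scale: replicate and
# background counts are reduced from the full-scale function defaults so
# the whole pipeline runs in minutes on one CPU.
seed: 1
grid:
  n_rows: 60
  n_cols: 60
  lat_min: 4
  lat_max: 24
  lon_min: -100
  lon_max: -80
landscape:
  corr_length: 6
species:
  wet_acq1: {optima: {temperature: 26, precipitation: 2900}, breadths: {temperature: 4, precipitation: 520}, prob_max: 0.9, n_records: 600}
  wet_acq2: {optima: {temperature: 27, precipitation: 2700}, breadths: {temperature: 4, precipitation: 500}, prob_max: 0.9, n_records: 600}
  wet_con1: {optima: {temperature: 25, precipitation: 3100}, breadths: {temperature: 4, precipitation: 550}, prob_max: 0.9, n_records: 600}
  wet_con2: {optima: {temperature: 26, precipitation: 2800}, breadths: {temperature: 5, precipitation: 480}, prob_max: 0.9, n_records: 600}
  dry_acq1: {optima: {temperature: 27, precipitation: 1200}, breadths: {temperature: 4, precipitation: 450}, prob_max: 0.9, n_records: 600}
  dry_acq2: {optima: {temperature: 28, precipitation: 1400}, breadths: {temperature: 4, precipitation: 430}, prob_max: 0.9, n_records: 600}
  dry_con1: {optima: {temperature: 27, precipitation: 1100}, breadths: {temperature: 5, precipitation: 420}, prob_max: 0.9, n_records: 600}
  dry_con2: {optima: {temperature: 26, precipitation: 1300}, breadths: {temperature: 4, precipitation: 460}, prob_max: 0.9, n_records: 600}
pfts:
  wet_forest: [wet_acq1, wet_acq2, wet_con1, wet_con2]
  dry_forest: [dry_acq1, dry_acq2, dry_con1, dry_con2]
learners: [GAM, SPLINE, MAXENT, RF]
scenarios:
  warm_dry:
    rcp: "RCP8.5-like"
    gcm: "GCM-A"
    offset: {temperature: 2.0}
    factor: {precipitation: 0.8}
sdm:
  n_replicates: 12
  k_project: 4
  train_frac: 0.7
  pa_n_background: 1500
thresholds:
  min_records: 100
uncertainty:
  n_cells: 120
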