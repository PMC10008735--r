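# Demo configuration for sncfrag::run_pipeline(): a small end-to-end run on
# fully synthetic data (reference, serum library, case-control cohorts,
# paired blood/marrow cohort).
out_dir: sncfrag_demo_out
seed: 42
reference:
  seed: 1
simulate:
  n_reads: 10000
  discovery: {aml: 12, control: 6}
  validation: {aml: 8, control: 4}
  paired_subjects: 8
annotation:
  max_mismatch: 0
de:
  alpha: 0.05
  lfc_threshold: 1
signature:
  classes: [tsRNA, miRNA]
  n_trees: 300
  min_mean_expression: 10
  logreg_alpha: 0.05
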