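# Demo pipeline configuration: simulate a 10-patient tumor-normal cohort on
# a freshly generated toy exome, refine somatic SNVs, and run the burden,
# selection, signature and enrichment stages.  Paths are relative to this
# file; copy it next to demo_sets.gmt or adjust gmt_path.
out_dir: demo_out
stages: [simulate, filter, annotate, burden, dnds, signatures, enrich]
gmt_path: demo_sets.gmt
universe_path: demo_universe.txt
simulate_params:
  n_patients: 10
  somatic_rate: 900
  germline_rate: 2000
  burden_effects:
    g042: 20
    g057: 15
genome_params:
  n_genes: 100
  mean_cds_length: 900
  seed: 1
n_boot: 200
n_subsamples: 500
size_range: [2, 6]
seed: 42
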