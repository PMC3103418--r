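# Demo pipeline configuration: synthetic study system with planted outliers.
# Run with: geodiffr run --config demo_config.yaml
simulate:
  n_regions: 7
  pops_per_region: 4
  samples_per_pop: 20
  n_snps: 200
  n_neutral_snps: 2036
  n_outlier_snps: 10
  outlier_boost: 4
n_perm: 10000
n_resample: 1000
maf_bin_width: 0.05
delta_f_threshold: 0.3
alpha: 0.05
seed: 1
outdir: geodiffr_demo
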