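# Example pipeline configuration for `Rscript inst/cli/backtraj.R run`
# or backtraj::read_pipeline_config().
simulate:
  n_patients: 635
  seed: 1
window_h: 72
horizon_h: 192
flag_policy: flag_only
min_n: 5
death_in_G: censoring
figures: true
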