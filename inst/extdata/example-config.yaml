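# Example fecgsim pipeline configuration.
# Run with: Rscript inst/exec/fecgsim-pipeline.R example-config.yaml
anatomy:
  seed: 0
  geometry:
    h_fine: 0.25      # cardiac-box edge length, cm
    h_coarse: 0.9     # peripheral torso edge length, cm
parameters:
  H_TR: 0.5
  H_AB: 1.0
  anisotropy_ratio: 2.5
protocol:
  pacing_site: rv_apex
  duration_ms: 200
  dt_pde: 0.1
  dt_ode: 0.02
output:
  dir: fecgsim-run
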