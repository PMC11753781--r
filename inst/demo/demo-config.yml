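# Desk-scale demo study: two groups of phantom animals with a 50% K1
# elevation in the striatum region of group B. Run the stages in order:
#   Rscript inst/cli/fdgmap.R simulate --config demo-config.yml
#   Rscript inst/cli/fdgmap.R fit      --config demo-config.yml
#   Rscript inst/cli/fdgmap.R stats    --config demo-config.yml
seed: 1
out_dir: demo_run
simulate:
  n_per_group: 2
  noise_cv: 0.05
  group_effects:
    striatum: 1.5
fit:
  mask: regions        # fit only voxels inside the named tissue regions
  pin_k4: false
  volume_fraction: 0.6
  lumped_factor: 0.26
stats:
  param: CEoverCP
  alpha: 0.05
  min_cluster: 5
  upsample: false
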