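# Desk-scale example configuration for the full pipeline
# (petcbda all --config example_config.yaml --out outdir)
seed: 4
grid.dims: 16,18,16
cohort.tracer: RCL
wrangle.mask: basal_ganglia
wrangle.threshold: 2.0
wrangle.consistency: 0.8
effects.delta_bpnd: 0.5
effects.noise_sd: 0.2
cbda.m: 6
cbda.fsr: 10
cbda.k: 5
cbda.replications: 2
cbda.top_fraction: 0.5
cbda.library: glm
cbda.v: 5
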