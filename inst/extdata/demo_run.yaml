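# Quarter-scale demonstration run: synthetic cohort, two outcomes,
# short chains, few splits. Completes in minutes on one CPU.
output_dir: cvbf_demo
seed: 1
simulation:
  scale: 0.25
outcomes: [PACC5, TMTB]
priors: [normal_sd_0.5, normal_sd_1]
blocks: [main, interaction]
K: 4
train_fraction: 0.5
apoe_sensitivity: false
mcmc:
  chains: 1
  warmup: 300
  draws: 300
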