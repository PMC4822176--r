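# Ownership questionnaire, control-like profile (high embodiment only for
# the own-feet condition), 22 hypotheses per component.
experiment: questionnaire
seed: 1
design:
  groups: [control]
  conditions: [real, fake, void]
  n_participants_per_group: 18
profile: control
mcmc: {n_chains: 1, burn_in: 500, n_samples: 3000}
pilot: {n_chains: 1, burn_in: 200, n_samples: 800}
out: questionnaire_report.json
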