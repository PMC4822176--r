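# Hand-centred CCT, one group, hands within vs outside the compartments.
experiment: exp2
seed: 1
design:
  groups: [pcl]
  conditions: [within, outside]
  n_participants_per_group: 14
effects:
  pcl:
    cce_contra_ms: 30
    cce_ipsi_extra_ms: {within: 70, outside: 0}
    error_rate: 0.07
mcmc: {n_chains: 3, burn_in: 1000, n_samples: 10000}
pilot: {n_chains: 1, burn_in: 500, n_samples: 2000}
out: exp2_report.json
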