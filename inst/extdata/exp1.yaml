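# Feet-centred CCT, two groups: controls carry a PPS effect only when seeing
# their own feet; the lesion group carries none. 8 hypotheses per group.
experiment: exp1
seed: 1
design:
  groups: [control, pcl]
  conditions: [real, fake, void]
  n_participants_per_group: 18
effects:
  control:
    cce_contra_ms: 30
    cce_ipsi_extra_ms: {real: 70, fake: 0, void: 0}
    error_rate: 0.07
  pcl:
    cce_contra_ms: 30
    cce_ipsi_extra_ms: {real: 0, fake: 0, void: 0}
    error_rate: 0.07
mcmc: {n_chains: 3, burn_in: 1000, n_samples: 10000}
pilot: {n_chains: 1, burn_in: 500, n_samples: 2000}
out: exp1_report.json
summary: exp1_summary.txt
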