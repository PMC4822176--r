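# Passive-motion experiment: PPS restored in the mobilised group only.
# The cell_means variant reproduces the "both cell means zero" absence form.
experiment: exp3
seed: 1
exp3_variant: cell_means
design:
  groups: [motion, no_motion]
  conditions: [real, fake, void]
  n_participants_per_group: 7
effects:
  motion:
    cce_contra_ms: 30
    cce_ipsi_extra_ms: 70
    error_rate: 0.08
  no_motion:
    cce_contra_ms: 0
    cce_ipsi_extra_ms: 0
    error_rate: 0.08
mcmc: {n_chains: 3, burn_in: 1000, n_samples: 10000}
pilot: {n_chains: 1, burn_in: 500, n_samples: 2000}
out: exp3_report.json
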