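# Demo pipeline configuration: three trap stiffnesses, two phosphate levels.
# Durations are kept short so the demo runs in well under a minute;
# increase duration_s for publication-grade event counts.
seed: 1
outdir: runs/demo
stages: [simulate, detect, features, table1, fit_bell]
simulate:
  conditions:
    - {label: pi30_k0.04, k_trap: 0.04, n_heads: 4, k_attach: 1,
       k_adp0: 0, d_adp: 0, pi_mM: 30, k_pi0_per_mM: 0.08333333,
       d_pi: 4.1, duration_s: 60}
    - {label: pi30_k0.06, k_trap: 0.06, n_heads: 4, k_attach: 1,
       k_adp0: 0, d_adp: 0, pi_mM: 30, k_pi0_per_mM: 0.08333333,
       d_pi: 4.1, duration_s: 60}
    - {label: pi30_k0.10, k_trap: 0.10, n_heads: 4, k_attach: 1,
       k_adp0: 0, d_adp: 0, pi_mM: 30, k_pi0_per_mM: 0.08333333,
       d_pi: 4.1, duration_s: 60}
detect: {width: 100, step: 25, min_event_windows: 1,
         cp_method: likelihood, cp_window: 50}
features: {window_ms: 5, step_nm: 7}
table1: {step_nm: 7}
fit_bell: {force: per_head, weighted: true}
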