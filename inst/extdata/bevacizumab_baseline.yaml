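# Baseline chitosan-core / PCL-shell microsphere releasing bevacizumab
# (average fitted transport parameters; dose renormalised to 1.03 mg).
geometry:
  r_core_um: 5.10
  delta_r_um: 1.25
transport:
  d_core_cm2_s: 2.6e-15
  d_shell_cm2_s: 2.6e-12
  kappa: 1
  burst_pct: 10
dose:
  a_load0_ug: 1030
  drug: bevacizumab
grid:
  n_core: 100
solver:
  rel_tol: 1.0e-6
  abs_tol: 1.0e-9
  horizon_days: 180
  dt_days: 1
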