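# Built-in radiobiological parameter sets, one per pathology.
# alpha_beta_gy : LQ alpha/beta ratio (Gy)
# t_half_fast_h : fast sublethal-damage repair half-time (h)
# t_half_slow_h : slow sublethal-damage repair half-time (h)
# x_fast        : fraction of damage assigned to the fast component
avm:
  alpha_beta_gy: 2.47
  t_half_fast_h: 0.19
  t_half_slow_h: 2.16
  x_fast: 0.505050505050505   # 1 / (1 + 0.98)
vs:
  alpha_beta_gy: 3.0
  t_half_fast_h: 1.5
  t_half_slow_h: 12.0
  x_fast: 0.5
bm:
  alpha_beta_gy: 10.0
  t_half_fast_h: 0.25
  t_half_slow_h: 6.0
  x_fast: 0.9
men:
  alpha_beta_gy: 3.5
  t_half_fast_h: 0.5
  t_half_slow_h: 4.0
  x_fast: 0.8
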