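# Example drivedyn configuration: 1:1 bisex release of a late-acting
# killer-rescue system with a 5% fitness cost per construct.
ecology:
  alpha: 0.02
  beta: 1.1
  rho: 1.01
  mu: 0.12
  tau: 18
drive:
  system: KR
  suppression: strong
  lethality: bisex
  timing: late
  eps_A: 0.95
release:
  theta: 1
  sexes: bisex
  genotype: AABB
two_deme:
  psi: 0
solver:
  t_end: 2000
  max_step: 0.05
  save_dt: 0.1
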