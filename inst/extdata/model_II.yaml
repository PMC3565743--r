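variant: II
mutations: []
activity: exact
tau_Lt: 10.0
m_leak: 0.0
receptor:
  membrane:
    'N': 1.0
    alpha: 2.0
    m0: 5.0
    K_A_uM: 3000.0
    K_I_uM: 18.0
  cytoplasmic:
    'N': 1.0
    alpha: 2.0
    m0: 5.0
    K_A_uM: 3000.0
    K_I_uM: 18.0
phospho:
  totals:
    A2: 5.0
    A34: 5.0
    Y3: 3.2
    Y4: 13.2
    Y6: 10.0
    B1: 2.0
    B2: 2.0
  k_auto:
    A2: 10.0
    A34: 10.0
  k_transfer:
    A2:
      Y3: 2.0
      Y4: 2.0
      Y6: 2.0
      B1: 2.0
      B2: 2.0
    A34:
      Y6: 2.0
      B2: 2.0
  k_dephos:
    Y3: 5.0
    Y4: 5.0
    Y6: 5.0
    B1: 2.0
    B2: 2.0
  R2: 1.0
  R3: 1.0
methylation:
  k_R: 0.02
  k_Rt: 0.02
  k_B1: 0.01
  k_B2: 0.01
  k_B2t: 0.02
flagellar:
  f_max: 8.0
  q: 12.0
  hill_n: 4.0
solver:
  rtol: 1.0e-10
  atol: 1.0e-10
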