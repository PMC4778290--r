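# Base-case medium and kinetics parameters (defaults shown explicitly).
medium:
  phi_sin: 0.7854
  K_sin_um2: 1.125
  D_sin_m2s: 4.2e-10
  phi_tis: 0.2382
  K_tis_um2: 7.35e-2
  D_tis_m2s: 4.2e-11
  mu_Pas: 3.5e-3
kinetics:
  vmax_uM_min: 0.06
  Km_uM: 10.0
  mode: michaelis_menten
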