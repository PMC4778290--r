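# Reduced-scale end-to-end run: 32-cell lobule, fixed pressure drop,
# base-rate metabolism, no diffusion. Suitable for a quick demonstration of
# the full pipeline (see run_pipeline()).
seed: 4
morphology:
  dim: 2
  M_dim: 32
  N_par: 148
  N_cen1_par: 19
  N_cen2_par: 12
  N_cor_par: 8
wells:
  delta_p_Pa: 50
kinetics:
  preset: base
time:
  t_end_min: 0.2
transport:
  diffusion: false
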