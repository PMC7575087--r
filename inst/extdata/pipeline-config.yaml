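# Small fully-synthetic end-to-end run: tree/synteny simulation, ohnologue
# calling, all four expression designs, divergence report.
seed: 7
out_dir: "ohnodiverge_run"
simulate:
  n_orthogroups: 30
  p_loss_post_wgd: 0.2
  n_negative_controls: 5
designs: [atlas, circadian, smolt, seawater]
thresholds:
  alpha_rhythm: 0.05
  fdr_de: 0.01
  p_profile: 0.01
  alpha_interaction: 0.05
rhythm:
  n_perm: 1000
rediploid_boundaries: [90, 95]
edi_offset: 0.5
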