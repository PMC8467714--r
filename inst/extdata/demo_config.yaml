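# Demonstration pipeline configuration (see read_run_config()).
# Unlisted fields fall back to default_run_config().
seed: 1
missing_rate: 0.03
crosses:
  AxB:
    strains: [B, A]
    generations:
      F2: 1200
    panel:
      spacing_mb: 20
  FxB:
    strains: [B, F]
    generations:
      F2: 600
      F10: 400
      F14: 400
    panel:
      spacing_mb: 6
scan:
  n_perm: 200
  alphas: [0.05, 0.2]
epistasis:
  n_loci: 2
  exclusion_bp: 80000000
severity:
  ASD: 1
  membranous_VSD: 2
  muscular_VSD: 2
  AVSD: 3
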