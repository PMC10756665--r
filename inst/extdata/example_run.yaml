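# Example ysrna run configuration: default sperm-head simulation with the
# packaged synthetic YRNA stand-in reference and a four-aliquot treatment
# panel.
reference:
  synthetic:
    lengths: [112, 101, 93, 83]
    stem_len: 10
    ids: [hY1, hY3, hY4, hY5]
    seed: 5
simulate:
  preset: sperm_head
  n_reads: 100000
  seed: 1
  treatments: [NONE, OXIDATION_BETA_ELIM, PNK, RPPH]
  p_pnk_5p_dephos: 0.8
quantify:
  min_len: 20
  max_len: 50
infer:
  thresholds:
    protected: 0.5
    gain: 2.0
    loss: 0.5
    floor: 1.0
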