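# Cat-like parallel-coil network vs amphibian-like straight tube.
geometry:
  preset: cat
  seed: 1
breathing:
  total_flow: 2.2e-5
  frequency: 1.0
odorants:
  table: packaged
  use: [2-acetylthiazole, 2-(1-mercaptoethyl)furan]
experiments:
  depletion: true
  sweep: {from: 1.0e-6, to: 1.0, n: 19}
gc:
  calibrations: [cat, rat, human, tube]
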