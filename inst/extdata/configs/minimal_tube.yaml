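# Minimal pipeline: straight tube, one odorant, one plate curve.
geometry:
  preset: tube
  seed: 1
breathing:
  total_flow: 4.4e-6
  frequency: 1.0
odorants:
  table: packaged
  use: [2-(1-mercaptoethyl)furan]
gc:
  calibrations: [tube]
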