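# Human-like olfactory cleft calibration (back-derived).
# A single non-parallel passage: ~1 mm cleft width and ~4.7 cm path with
# the shared k' = 1, Da, Dm, d values gives a peak plate number of 17.
# The operating velocity (0.148 m/s) is far above the ~0.009 m/s optimum
# — the human cleft lacks the parallel-coil slowdown — and yields an
# actual plate number of about 2 (illustrative calibration only).
name: human
Lc: 0.0468
dc: 1.0e-3
d: 3.0e-5
k_prime: 1.0
Da: 6.0e-6
Dm: 1.0e-9
operating_velocity: 0.148
reference: false
notes: >
  Back-derived to the documented peak plate number of 17; the operating
  velocity is an illustrative value chosen so the actual plate number
  is about 2, reflecting a cleft velocity well above optimum.
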