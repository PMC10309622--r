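# Rat-like olfactory column calibration (back-derived).
# Shorter coiled paths and narrower channels than cat; with the shared
# k' = 1, Da, Dm, d values these dimensions give a peak plate number of
# 33.  The operating band brackets the optimum velocity (~0.009 m/s):
# rat olfactory velocities are low enough to reach near-optimal plates.
name: rat
Lc: 0.089
dc: 2.0e-4
d: 3.0e-5
k_prime: 1.0
Da: 6.0e-6
Dm: 1.0e-9
operating_velocity: [0.005, 0.02]
reference: false
notes: >
  Back-derived to the documented peak plate number of 33; operating
  band chosen to straddle the Golay optimum.
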