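# Amphibian-like straight-tube calibration.
# The tube diameter (= dc) follows the DM-inlet-area rule: cross section
# A = Q_dm / u_dm with Q_dm = 4.4e-6 m^3/s (20% of 22 ml/s restful flow)
# and u_dm = 0.3 m/s, giving D = sqrt(4A/pi) = 4.3215e-3 m.  Lc is the
# straight-line olfactory inlet-to-outlet extent fitting the same skull
# space.  The operating velocity is the DM-stream velocity itself: the
# tube is fed directly by the DM stream.
name: tube
Lc: 0.0264
dc: 4.3215e-3
d: 3.0e-5
k_prime: 1.0
Da: 6.0e-6
Dm: 1.0e-9
operating_velocity: 0.3
reference: false
notes: >
  Straight-tube stand-in occupying the cat skull space; diameter from
  the DM inlet area rule, length the olfactory inlet-outlet distance.
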