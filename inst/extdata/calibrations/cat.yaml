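# Cat parallel-coil olfactory column calibration.
# Lc is the 10-path mean olfactory path length of the cat-like network
# (dorsal-medial channel 0.031 m + coil 0.15 m); dc the coil slit width;
# d the 30 um mucus film.  k', Da, Dm are documented reference values
# shared across species (k' = 1 default; Da a typical small-odorant air
# diffusivity; Dm a typical aqueous diffusivity).  The operating velocity
# range is the computed coil velocity band at restful breathing.
name: cat
Lc: 0.181
dc: 5.0e-4
d: 3.0e-5
k_prime: 1.0
Da: 6.0e-6
Dm: 1.0e-9
operating_velocity: [0.01, 0.11]
reference: true
notes: >
  Back-derived calibration: coil width and path length reproduce the
  documented peak plate number of 67 together with the shared k', Da,
  Dm, d values; the operating band 0.01-0.11 m/s is the coil velocity
  range of the cat-like network at 22 ml/s restful breathing.
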