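---
title: "The nose as a coiled parallel gas chromatograph: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The nose as a coiled parallel gas chromatograph: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nasalGC)
```

`nasalGC` is a reduced-order pipeline for asking how nasal architecture —
in particular a high-speed dorsal-medial (DM) stream feeding many
parallel coiled olfactory channels — shapes odorant delivery and
chromatographic separation. This vignette is the package's account of
its models: the assumptions, the parameters that matter, what the
synthetic geometry does and does not emulate, and the numerical and
design choices we made where the design was genuinely open.

## 1. The channel-network abstraction

Real nasal airways are a labyrinth resolved only by micro-CT. We replace
them with a directed graph of laminar channel segments, each with a
length, a cross-section (rectangular slit by default, since turbinate
airways are slit-like; circular for the straight-tube model), an
epithelium class (squamous, respiratory, olfactory), and a mucus film of
thickness $d$ (default 30 µm). The cat-like generator
(`build_parallel_coil_network()`) wires together:

* a short squamous vestibule (the naris),
* a fast, low-surface **anterior DM passage** in parallel with a dense
  **maxillary bank** of thousands of fine respiratory channels,
* a **dorsal-medial olfactory channel** feeding `n_coils` identical
  parallel **olfactory coils**,
* a **posterior respiratory bank** and a nasopharynx segment closing the
  network.

This is the coarsest topology that still contains the mechanism under
study: the olfactory path (vestibule → DM passage → DM channel → coil)
bypasses the absorbing maxillary surfaces, while the posterior
respiratory path does not.

**What the defaults encode.** The default dimensions are a documented
calibration, chosen once to satisfy the operating constraints of the
restful-breathing cat model (22 ml/s, 1 Hz): a DM stream carrying
15–20% of the flow at ~0.3 m/s, coil velocities in the 0.01–0.11 m/s
band, an olfactory epithelium share of ~12% of lateral surface area with
an interior peak of ~50% along the distance profile, and a mean olfactory
path length of 0.181 m. One hundred coils is not an anatomical count; it
is the parallelism needed to slow the DM flow to the coil-velocity band
at the chosen slit width (0.5 mm). Absolute surface areas are *not*
matched — only scale-free shares and fractions are tuned, because a
network of rectangular slits cannot and should not reproduce CT-derived
absolute areas.

**What passing tests do not show.** The generator has perfect mixing at
junctions, direction-symmetric resistances, identical coils and no
secondary flows. Agreement of the mechanism tests (depletion ordering,
interior solubility optimum) therefore demonstrates that the *network
topology plus wall physics* suffice to produce these phenomena — not
that the quantitative absorption percentages of any real species are
reproduced. CFD-derived quantities that depend on 3-D geometry (axial
DM-percentage curves, absorption maps, species absorption curves,
inhale/exhale asymmetry) are explicitly out of scope.

**Distance semantics.** The area profile plots epithelium shares against
*path distance* from the inlet (shortest directed path), the network
analogue of the axial distance-to-nostril coordinate used with imaging
data. The two coincide for a straight tube but differ inside coils; this
is a deliberate semantic substitution.

**Path sampling.** The GC column length is the mean of 10 sampled
olfactory paths (`mean_path_length()`, default `n_paths = 10`). How such
paths "should" be chosen is not well defined in a network; we use a
seeded uniform random walk over outgoing olfactory segments, with
replacement, ties broken by segment id order. In the cat-like default
all paths are identical (0.031 m DM + 0.15 m coil = 0.181 m), so the
estimator is exact there and only matters for irregular networks.

## 2. Airflow

Flow is solved as a linear resistance network: per-segment laminar
resistance $128 \mu L / (\pi d_h^4)$ on the hydraulic diameter
$d_h = 4A/P$, an optional per-segment shape factor (default 1 — the pure
hydraulic-diameter approximation, adequate for a stand-in model), node
pressures from the sparse Laplacian, prescribed total inlet flow. The
solve is exact, so Kirchhoff balance holds to solver precision (tested
at $10^{-12}$ relative) and flows scale exactly linearly in $Q$. The
network is direction-symmetric: exchanging inlet and outlet negates all
flows, which is why inhale/exhale asymmetry cannot be represented and is
not attempted.

Quasi-steadiness and laminarity are assessed with
$W_0 = R\sqrt{2\pi f/\nu}$, $S = 2\pi f L/U$ and $Re = U R / \nu$
(`regime_report()`), with thresholds $W_0 < 4$, $S < 1$, $Re < 2300$.
Two reduced-order substitutions are logged here: $R$ is taken as the
*local segment hydraulic diameter* (with a naris-based global value also
reported, since the conventional reference location is the external
naris), and the Strouhal length $L$ is the local axial position rather
than the total cavity length. In slow lateral channels the local $S$ can
exceed 1 even when the bulk flow is quasi-steady; the per-segment report
makes that visible rather than hiding it in a single global number. The
report also logs each segment's axial Péclet number and warns below
$Pe \le 10$, where the plug-flow transport model (which neglects axial
diffusion) loses validity.

## 3. Odorant uptake

At the air/mucus interface the normalized concentration obeys the Robin
condition $\partial C'/\partial y' + K C' = 0$. The printed form of $K$
is typographically ambiguous; we adopt

$$K = \frac{d_{in}\, D_m}{D_a\, \beta\, d},$$

the unique grouping of the listed symbols that is dimensionless
(`wall_uptake_parameter()` documents the unit cancellation) and
consistent with the dimensional wall flux $j = (D_m/\beta d)\,C_{air}$
used throughout the absorption module. Physically, $D_m/(\beta d)$ is
the conductance of a mucus film acting as a perfect sink — no
saturation, no desorption — matching a steady absorption boundary
condition.

**The closure.** Within a segment we use plug flow with a series
conductance: $k_{wall} = D_m/(\beta d)$, $k_{conv} = \mathrm{Sh}\,D_a /
d_h$ with a constant Sherwood number 3.66, and survival ratio
$\exp(-P k_{tot} L / (uA))$. We chose the constant-wall-concentration
laminar value (3.66) rather than the constant-flux value (4.36) because
soluble odorants put the wall closer to the Dirichlet limit, which is
where uptake actually matters; for weakly soluble odorants the wall
resistance dominates $k_{tot}$ and the choice is immaterial.

**The oracle.** `graetz_reference_solution()` solves the 2-D
axisymmetric problem (parabolic profile, Robin wall, axial diffusion
neglected) by implicit finite-volume marching in the Graetz coordinate
$\zeta = x D_a/(U R^2)$, with the wall flux discretized as the half-cell
diffusive resistance in series with the wall conductance (this makes the
$K\to\infty$ limit exactly the Dirichlet problem). The acceptance suite
checks that the solver recovers the classical fully developed Sherwood
number 3.657 within 1%, that the outlet ratio is grid-converged (≤0.5%
between successive doublings), and that the closure tracks the oracle's
developed-flow survival within 15% across $\hat K \in [0.1, 10]$. The
closure has no entrance-region enhancement — its constant Sherwood
number is the developed-flow value — so its accuracy envelope is stated,
and tested, in the developed regime (survival between $\zeta = 0.25$ and
$0.5$); including the entrance transient the discrepancy grows toward
~20% at high $\hat K$, which is the price of a one-parameter closure.

**Network sweep.** Absorption is propagated in topological order
(descending node pressure — a valid order because potential flow admits
no directed cycles), with perfect flow-weighted mixing at junctions;
3-D secondary flows are not representable in a network model. Mass
balance (inlet flux = outlet flux + absorbed) is tested to $10^{-9}$
relative on randomized networks. Region fractions aggregate
dorsal-medial and coil segments into a single "olfactory" region.

The two headline experiments are `anterior_depletion_experiment()`
(uptake on vs off in the anterior respiratory region) and
`solubility_sweep()` (absorption against $\beta$ over ≥4 decades). On
the cat-like defaults the suite verifies the mechanism qualitatively:
anterior uptake reduces olfactory absorption proportionally less than
posterior-respiratory absorption; the olfactory curve has an interior
maximum at intermediate solubility when anterior uptake is on and is
monotone when it is off; and shortening the anterior region moves the
optimum toward more-soluble odorants.

## 4. Odorant properties

Odorants carry molecular weight, molar volume at boiling, the air/mucus
partition coefficient $\beta$ (small = mucosa-soluble), and
diffusivities $D_a$, $D_m$. The Wilke–Chang correlation
$D = 7.4\times10^{-8} (\varphi M_B)^{1/2} T /(\mu_B V_A^{0.6})$
(cm²/s) is implemented literally as the stated estimation route for the
air-phase diffusivity, even though it is a liquid-phase correlation that
under-predicts gas diffusivities by roughly two orders of magnitude.
Reproducibility wins over physical plausibility here, with two guards:
a $D_a$ supplied directly in an odorant table always takes precedence,
and the packaged fixture table supplies explicit air-typical values
($D_a = 6\times10^{-6}$ m²/s) for all odorants used in transport
experiments. Missing $D_m$ falls back to an explicit, logged default of
$10^{-9}$ m²/s (typical small-molecule aqueous diffusivity); nothing is
guessed silently. The fixture's named odorants (2-acetylthiazole, high
solubility; 2-(1-mercaptoethyl)furan, intermediate) carry *placeholder*
$\beta$ values — the measured values are not printed in any source
available to this package — chosen so the set spans six log-decades.

## 5. Chromatographic efficiency

The olfactory channel system is scored as an open-tubular GC column via
the Golay plate height (see README for the formula) and the plate number
$N = L_c/H$. Two conventions are implemented exactly as documented even
where they are unconventional:

* In $k' = (C_m/C_a)(V_m/V_a)$, $V_m$ is the **stationary** (mucus) and
  $V_a$ the **mobile** (air) volume, with $C_m = C_{in} - C_{out}$ and
  $C_a = C_{out}$ sampled at the column inlet/outlet planes.
* Peak plate numbers are reported rounded to the nearest integer.

$k'$ defaults to 1 as a calibration input, because the concentrations
it derives from in the source analysis are not printed; alternatively
`k_prime_from_absorption()` wires it from the network absorption
solution's DM-inlet and coil-outlet planes. A fully absorbed odorant
makes $C_{out} \to 0$ and $k'$ divergent; `capacity_factor()` refuses
$C_{out} = 0$ outright, and the wiring clamps $C_{out} \ge 10^{-9}
C_{in}$ (documented in both places). With that clamp, every fixture
odorant with $\beta \ge 10^{-4}$ yields a finite $k' \ge 0$.

**Velocity grid.** Plate curves use 2000 log-spaced points over
$[10^{-4}, 1]$ m/s, covering both the cat operating band (0.01–0.11 m/s)
and the tube velocity (~0.3 m/s). The grid peak is cross-checked against
the closed form $u_{opt} = \sqrt{2D_a/(B+C)}$, $H_{min} =
2\sqrt{2D_a(B+C)}$ to 0.1%, and is stable to 0.1% under grid doubling.
Within an operating *range*, the reported "actual" plate number is the
best achievable: $N$ at the in-range velocity closest to $u_{opt}$
(evaluated in closed form, so it can exceed the grid peak by sub-grid
amounts; the grid peak is still what `N_peak` reports).

**Calibrations.** The species calibration files
(`inst/extdata/calibrations/`) are back-derived: the source analysis
does not print $L_c$, $d_c$, $k'$, $D_a$, $D_m$, so the shipped values
are chosen once to satisfy the printed constraints — 30 µm mucus film,
the cat velocity band and path-length rule, the straight-tube
diameter-from-DM-inlet-area rule, and the published peak plate numbers
(67/33/17/7) under shared $k' = 1$, $D_a = 6\times 10^{-6}$ m²/s,
$D_m = 10^{-9}$ m²/s. Each YAML carries a provenance note. The human
operating velocity (0.148 m/s, giving an actual plate number ≈ 2) is an
illustrative back-derivation only. For the straight tube, the published
description of its length is ambiguous ("same length" vs "inlet–outlet
distance"); we follow the methods-level definition — the straight-line
olfactory inlet-to-outlet extent (0.0264 m), a configuration value, not
the coiled path length.

## 6. Numerical choices and degenerate inputs

* Tridiagonal Graetz systems are pre-factored once and re-solved per
  axial step (backward Euler; first-order in $\zeta$, which the
  convergence test bounds).
* Default oracle resolution: 128 radial cells × 400 steps for closure
  comparisons, 256 × 1600 for the Sherwood check — chosen as the
  smallest grids whose refinement changes the outlet ratio by well under
  the tested tolerances.
* The flow Laplacian is assembled sparsely (duplicate parallel edges sum
  their conductances) and solved densely — junction-node counts are
  single digits even when segment counts are in the thousands.
* Zero-flow segments carry no mass and are skipped in the absorption
  sweep; a node fed only by zero-flow segments gets concentration 0.
* `solubility_sweep()` calls a maximum "interior" only if it exceeds
  both curve ends by more than $10^{-9}$ relative, so flat plateaus at
  the soluble end are not misread as peaks.
* Problem sizes throughout the test suite (networks of $10^2$–$10^4$
  segments, 5–6 randomized property cases per invariant, 19–49-point
  solubility grids) were chosen as the smallest sizes that exercise
  every code path with comfortable numerical headroom.

## 7. Known limitations

* A linear resistance network is direction-symmetric: no inhale/exhale
  asymmetry, no unsteady solve ($f$ enters only the regime report), no
  turbulence.
* Perfect junction mixing and identical coils erase cross-channel
  heterogeneity; the ring-detector aspects of the biology are untouched.
* The mucus is a perfect sink: no saturation, desorption, or retronasal
  transport, so retention is purely absorptive.
* The plate-number analysis treats each species as one effective column;
  it inherits whatever error the back-derived calibrations carry, and
  quantitative absorption percentages from CT-based models are not
  reproducible here by construction.
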