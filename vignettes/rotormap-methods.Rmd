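---
title: "Methods: simulating, mapping and ablating rotors in 2D atrial tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating, mapping and ablating rotors in 2D atrial tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`rotormap` simulates electrical wave propagation in a homogeneous, isotropic
2D sheet of human atrial tissue with the monodomain reaction-diffusion
equation

$$\partial V_m/\partial t = D_\mathrm{eff}\,\nabla^2 V_m - (I_\mathrm{ion} + I_s),$$

where $V_m$ is the membrane potential (mV), currents are in pA/pF
(numerically mV/ms), and $D_\mathrm{eff}$ (mm²/ms) lumps tissue conductivity,
surface-to-volume ratio and membrane capacitance into one effective
diffusivity.  $I_\mathrm{ion}$ is the sum of the 12 membrane currents of the
Courtemanche-Ramirez-Nattel (CRN) human atrial action-potential model, with
its 21 state variables (potential, 15 gates, 5 concentrations) integrated at
every node.

Two ionic presets are built in.  *Control* is the unmodified CRN parameter
set (gNa 7.8, gto 0.1652, gCaL 0.1238, gK1 0.09 nS/pF, INaCa(max) 1600
pA/pF, Iup(max) 0.005 mM/ms).  *PeAF* applies persistent-AF remodeling as
multiplicative scalers (INa x0.9, Ito x0.3, ICaL x0.5, IK1 x2, IKur x0.5,
INaCa x1.4, Iup x1.25), which shortens the action potential (single-cell
APD90 drops from roughly 290 ms to 180 ms at 1-Hz pacing in this
implementation) and flattens its dome - the substrate that lets reentry
persist.  The voltage-dependent IKur conductance uses the standard CRN
sigmoid gKur(V) = 0.005 + 0.05/(1 + exp(-(V-15)/13)) nS/pF.

## Numerics

* **Operator splitting.** Gates are advanced with exponential (Rush-Larsen)
  updates, V and concentrations with forward Euler; the default step is
  0.05 ms (0.02 ms reproduces single-cell APD90 to well under 1%).
* **Space.** 5-point finite-difference Laplacian on the regular grid with
  no-flux (mirror) boundaries.  For homogeneous isotropic tissue this
  coincides with a linear finite-element discretization up to
  discretization order.  The explicit diffusion step is guarded by
  dt <= 0.8 dx²/(4 Deff); violating configurations are rejected rather than
  silently integrated.
* **Lookup tables.** All voltage-dependent gate rates and current shape
  factors are pre-tabulated on a 0.02-mV grid per run and linearly
  interpolated, which is what makes second-scale 2D runs tractable on one
  core.
* **Discretization bias.** The sharp sodium upstroke limits the accuracy
  of 2nd-order finite differences: at 250-um spacing the planar CV is
  ~6-8% below its grid-converged value (and ~10-15% at the 500-um desk
  spacing).  This is the usual accuracy class of explicit monodomain
  solvers at these spacings; the diffusivity calibration absorbs the bias,
  and convergence is verified by test (halving dx changes CV by under 8%,
  always speeding it up).
* **Degenerate inputs.** Non-finite fields abort with a time stamp;
  quiescent tissue is verified to be a fixed point of the full PDE step;
  lesion nodes are clamped to the preset's resting potential and keep
  participating in diffusion as resting tissue (the resting-value-clamp
  simplification, chosen deliberately over decoupling).

## Calibration and study conditions

The effective diffusivity is not a printed quantity; it is calibrated so
that the planar conduction velocity at 600-ms line pacing falls in the
physiological atrial range (0.4-0.6 mm/ms).  The package default
`Deff = 0.15` gives CV ~0.46 mm/ms under control kinetics at 500-um spacing
(`calibrate_deff()` reproduces this calibration).  Wavelength is measured on
a long paced strip as the spatial extent of the excited band (V >= -60 mV);
under PeAF remodeling it is ~65-70 mm, so the mother-rotor confinement
circle (diameter = wavelength/2) fits comfortably in a 5-cm sheet.

The reference full-scale configuration is a 600 x 600 grid at 250-um
spacing (15 x 15 cm) observed for 30 s or more.  That configuration is
fully expressible here (`tissue_grid()` defaults), but a single episode
takes hours of CPU.  The package's *desk configuration*, used by the test
suite and the acceptance script, is a 100 x 100 grid at 500-um spacing
(5 x 5 cm) with ~7 s of fibrillation after reentry initiation and 6-s
analysis windows at 1-kHz sampling.  These sizes are the package's own
choice of the smallest domain that still exhibits the core phenomenology: a
sustained, spatiotemporally confined rotor under PeAF remodeling (the
frozen desk conditions - Deff 0.15, cross-field reset at 240 ms - yield a
rotor whose tip stays confined for the whole 6-s analysis window, rotates
at ~8.6 Hz at its core, and self-terminates only after ~11 s), a control
preset that cannot sustain reentry (its wavelength exceeds the sheet), and
the DF/ShEn/CFAE map structure around the core.

Three full-scale features do **not** survive this down-scaling, and desk
results must be read accordingly:

* *Peripheral wavebreak.*  A 5-cm sheet has no periphery distant enough
  from the core for wavefront instability, so the strict mother-rotor
  definition (which requires breakup) labels the desk rotor "stable
  reentry", exactly as it labels the control-condition rotor of a
  full-scale run.
* *Area-overlap orderings.*  The rotor area scales with the wavelength,
  not with the sheet, so at desk scale it covers ~28% of the domain and
  every 2.5% parameter area - DF, ShEn and CFAE alike concentrate at the
  core - is covered almost completely.  The full-scale ordering of
  rotor-coverage percentages across the three maps is a property of
  multi-wavelet fibrillation on a domain of at least two wavelengths
  (roughly 13 cm, a 270 x 270 grid or larger) and cannot be reproduced
  below that size; the package still computes and reports the overlap
  table at any scale.
* *The rotor rate relative to fixed thresholds.*  The desk rotor rotates
  just below the 9-Hz high-DF cutoff, so the threshold mask is empty; the
  percentile form of the high-DF area (upper 2.5%, the same construction
  used for ShEn and CFAE) is computed alongside it.

## Reentry initiation

A planar wave is elicited by line stimulation at the row-1 edge
(600-ms cycle length).  Reentry is started cross-field style: the membrane
potential on the half-sheet of columns > nx/2 is reset to 0 mV across a
boundary perpendicular to the wavefront.  The reset time matters: resetting
while the whole sheet is depolarized does nothing.  The automatic trigger
therefore fires when the paced planar wave is *repolarizing* - the
paced-edge node has activated and then recovered below -60 mV - so the
reset boundary cuts across an excitability gradient and the broken end of
the re-excited region curls into a spiral.  A fixed `reset_time` is also
accepted.

## Phase, PS detection and the mother-rotor classifier

Node phase is the analytic-signal (Hilbert-quadrature) phase of the
de-meaned action potential; nodes with < 5 mV dynamic range over the window
are flagged undefined rather than given a meaningless phase.  Phase
singularities are detected with the topological-charge (Iyer-Gray) rule:
wrapped phase differences summed around every 2 x 2 plaquette; a winding of
+/-2*pi marks a singularity with that chirality.  Tips are linked across
frames by greedy nearest-neighbour matching of same-charge points within a
2-mm-per-frame gate; unmatched points open or close trajectories.

A tracked trajectory qualifies as a **mother rotor** when

1. its tip stays within a circle of diameter half the paced wavelength
   (the smallest enclosing circle of the tip points, computed exactly);
2. it lasts longer than 5 s; and
3. peripheral wave breakup is observed.

Peripheral breakup has no standard quantitative definition; it is operationalized
here as at least one other PS trajectory being born outside the *rotor
area* - the circle centered on the mean tip position with radius the
distance to the farthest tip point - during the rotor's lifetime.  Without
such births a stable stationary reentry deliberately does not count.  The
confinement test applies to the tip trajectory (not the rotor area), which
is the reading consistent with a tip-meander criterion.

## Parameter maps

* **DF**: per-node power spectrum of the de-meaned, Hann-windowed AP over a
  6-s window, zero-padded to 0.05-Hz bins; DF is the argmax-power frequency
  in 0.5-20 Hz.  The 9-Hz "high-DF area" threshold is kept at its reference
  value.
* **ShEn**: bipolar electrograms are synthesized by averaging V over the
  footprints of a 3.5 x 2.0 mm distal and 1.5 x 2.0 mm proximal electrode
  1 mm apart (AP averaging; no extracellular forward model) on a 2-mm tile
  grid; ShEn is the Shannon entropy (bits) of the 50-bin amplitude
  histogram clipped at +/-3 SD.  Bin count and clip are configurable since
  there is no single standard choice of binning for this statistic.
* **CFAE-CL**: mean interval between consecutive local minima of the
  electrogram's time derivative over 6 s, with a depth threshold (20% of
  the window's most negative derivative) and a 30-ms refractory gap; fewer
  than two detections flags the tile undefined rather than zero.
* **Area masks**: threshold rules (DF > 9 Hz) or percentile rules
  (upper/lower 2.5%, 5%, 10%) with deterministic tie-breaking (value, then
  row-major node order).  Overlap between areas is reported as
  100 |A ∩ B| / |A| with a chi-square association test on the 2 x 2 node
  contingency table - the simplest test consistent with reporting
  "p < 0.001" on large masks; it treats nodes as exchangeable units and is
  reported as such.

## Virtual ablation

Four strategies produce 5%-of-domain lesions: highest-DF, highest-ShEn,
lowest-CFAE-CL percentile masks, and PS-guided ablation that walks the PS
point stream in time order adding 1-mm disks (the catheter tip size) until
the budget is met.  Lesions clamp V to rest permanently.  Outcomes are
classified from the post-ablation movie: *AF-terminated* when no node
exceeds -40 mV for 500 ms through the end of the record; *AT-converted*
when activity persists with periodic global activation (cycle-length
coefficient of variation < 5% over 10 beats at sentinel nodes); otherwise
*AF-sustained*.  The -40-mV activity cut and 5% CV threshold are defaults
of this package - there is no standard published value - and are configurable.

One degeneracy matters at desk scale: when the pre-ablation baseline is a
single organized rotor (rather than multi-wavelet AF), its activation is
already periodic, so any post-ablation state in which activity persists is
classified "AT-converted" by the cycle-length criterion - including states
a full-scale observer would call unchanged AF.  The robust desk-scale
contrast between strategies is therefore *terminated versus not
terminated*, and that is what the package's end-to-end checks assert; the
AT/AF label split is only meaningful when the baseline itself is
aperiodic.

## What the fixtures do and do not show

The `spiral_fixture`/`make_egm`/`make_ps_stream` generators produce
analytic spirals (Archimedean phase fields through an AP-like waveform),
deflection trains with prescribed intervals, and PS point streams with
known segmentation.  They carry their own ground truth, so detector tests
compare against construction, never against another detector.  They
emulate only the geometric and spectral structure the detectors consume -
vortex phase topology, periodicity, deflection statistics - not
Courtemanche dynamics, tissue-level conduction, or electrogram physics.
Passing fixture tests therefore validates the *analysis stack*, while the
PDE-level tests (fixed point, diffusion conservation, isotropy, CV
convergence, conduction block) validate the *solver*; neither validates
clinical realism of the ionic remodeling itself.

## Known limitations

* Homogeneous isotropic monolayer only: no fibre orientation, no
  heterogeneity, no 3D anatomy.
* Electrograms are AP averages; real bipolar electrograms include far-field
  and filtering effects that fractionate differently.
* Desk-scale domains shrink absolute map areas and shorten episode
  durations; only full-scale runs are comparable to full-scale numbers.
* The chi-square p-values treat nodes as independent, which overstates
  significance on smooth maps; they are reported for parity with the
  reference workflow, not as calibrated error rates.
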