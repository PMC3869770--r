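---
title: "Modeling kinetic IKur block and rotor dynamics in remodeled atrial tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling kinetic IKur block and rotor dynamics in remodeled atrial tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

Inhibition of the ultra-rapid delayed rectifier potassium current IKur
(Kv1.5) is an attractive antiarrhythmic strategy because the current is
expressed in human atria but virtually absent in the ventricles.  Clinical
and experimental results are nonetheless contradictory, and one candidate
explanation is that IKur inhibitors differ in the *kinetics* of their block:
how fast block develops at depolarized potentials and how fast the channel
recovers at hyperpolarized potentials.  `atriawave` provides a mechanistic
simulator to study this question end to end: a human atrial myocyte model
with chronic-AF (cAF) electrical remodeling, a state-dependent description
of IKur block, a monodomain tissue solver, restitution protocols, and
quantitative analyses of fibrillatory dynamics (refractory area, pseudo-ECG
dominant frequency, spiral-tip tracking).

# The cellular model

The myocyte model is the Courtemanche–Ramirez–Nattel (CRN) human atrial
action potential model, re-implemented from its curated CellML encoding:
21 state variables covering INa, IK1, Ito, IKur, IKr, IKs, ICa,L, the
NaK pump, the Na/Ca exchanger, background and pump Ca currents, and the
SERCA/SR calcium handling with its release, uptake and transfer fluxes.
Chronic-AF electrical remodeling is applied as conductance scalings:
IK1 increased by 110% (factor 2.1), ICa,L and Ito each reduced by 65%
(factor 0.35), plus a 30% reduction of tissue conductivity at the tissue
level.  `apply_remodeling()` guards against double application; with all
factors at 1 the model is bit-identical to baseline.

At 1 Hz steady-state pacing the implementation yields APD90 of about 298 ms
for normal cells and about 128 ms for remodeled cells, with the remodeled AP
profoundly triangulated.  One caveat we document openly: APD30 — the time to
30% repolarization — is structurally fragile in this model family.  The CRN
spike-notch-dome AP places the dome only 2–4 mV below the 30% threshold, so
the APD30 crossing can land either on the phase-1 shoulder (tens of ms) or
after the dome (>100 ms) depending on minute plateau-height differences
between model variants.  Our encoding places the dome just below the
threshold; APD70/APD90 and all APD90-based orderings are insensitive to this
and reproduce published behaviour closely, but absolute APD30 values should
not be compared across CRN variants.  See `pace_cell()`, `ap_metrics()`.

## Steady-state pacing and stimulus conventions

0D pacing uses rectangular 2 ms stimuli at 20 pA/pF (about twice diastolic
threshold); APD is insensitive to the stimulus details above threshold.
Twenty beats suffice for drug-free steady state (APD drift < 0.1 ms/beat);
runs with a compound use 60 beats so that slowly dissociating compounds
(recovery time constants up to 16 s) reach their pharmacological steady
state.  APD fractions use the peak-to-resting amplitude of the same beat,
measured from the maximum-upstroke time, with linear interpolation at the
crossing.

# State-dependent IKur block

Block is modeled as a multiplicative non-blocked fraction `y` on the CRN
IKur conductance.  `y` relaxes exponentially toward a voltage-dependent
steady state — a Boltzmann with half-maximum block at −40 mV, slope 5 mV and
90% maximal block, so channels are free at rest and up to 90% blocked at
depolarized potentials — with a voltage-dependent time constant that equals
`tau_onset` at depolarized and `tau_recovery` at hyperpolarized potentials.
The published description fixes only these two limits; for the transition we
chose a sigmoidal interpolation sharing the midpoint (−40 mV) and slope
(5 mV) of the steady-state curve, exposed in `block_time_constant()` so a
step-switch variant can be substituted and compared.  The five compound
profiles (onset/recovery in ms: 5/1000, 16/238, 100/16000, 200/250, and a
tonic 50% block) ship as a plain-text library (`compound_library()`).

Two deliberate interpretations, both flagged in the documentation: the tonic
compound #5 is a constant 50% non-blocked fraction — the heterozygous
loss-of-function situation — rather than `1 − max_block`; and the 90%
maximal block is assumed to apply uniformly to all dynamic compounds.
Drug application is instantaneous: `y = 1` until the drug-on time.

The voltage-step assay (`voltage_step_assay()`) reproduces the repeated
500 ms clamp step to +30 mV at 1 Hz.  Because all three variables (ua, ui,
y) relax exponentially under constant voltage, the assay is evaluated in
closed form, which doubles as an independent oracle for the compiled
integrator.

# Tissue model and numerics

Propagation uses the isotropic monodomain equation with explicit finite
differences: Rush–Larsen exponential integration for the twelve
voltage-gated variables, forward Euler for Vm, concentrations and the
calcium-release gates (whose time constants far exceed the step), and a
centered 5-point Laplacian with no-flux (mirrored) boundaries.  The
reference discretization is dt = 10 µs, dx = 0.1 mm; strand protocols
default to dt = 20 µs, which changes APD90 by well under 1 ms (a property
the test suite checks).  A guard warns when dt exceeds
`0.9 dx²/(2 D dim)`.

Voltage-dependent coefficients are tabulated on a 0.05 mV grid and linearly
interpolated (the standard lookup-table treatment for this model family);
the calcium-release sigmoids use a shared tabulated logistic at 0.02
argument resolution, and the Na/K Nernst potentials are refreshed lazily on
1 mmol/L drifts (Ca on 2% changes — it enters only the small background Ca
current).  These resolutions were chosen so that halving dt or refining the
tables changes APD90 by far less than the 1 ms temporal-convergence budget.

## Conductivity calibration

The effective conductivity D (mm²/ms) is calibrated by bisection so that a
paced 20 mm strand conducts plane waves at ≈750 mm/s at 1 Hz in the normal
condition (CV grows like sqrt(D), so the bisection is monotone).  Calibrated
values are stored per discretization (0.21875 at dx 0.1 mm up to 0.290625
at the desk-scale dx 0.5 mm); the cAF condition always uses 0.7× the
calibrated normal value, never a re-calibration, mirroring gap-junction
remodeling.  With cellular remodeling plus the conductivity reduction the
remodeled strand conducts at ≈600 mm/s.

# Restitution protocols

Restitution protocol details vary across laboratories and are rarely
reported in full, so the package states its own conventions precisely:

* **APD restitution** (`apd_restitution()`): S1–S2 on a single cell; 10 S1
  beats at 1 Hz (40 with a compound), one S2 at coupling interval
  `APD90(S1) + DI`.  Capture requires a regenerative upstroke
  (max dV/dt ≥ 10 mV/ms after the stimulus).
* **ERP restitution** (`erp_restitution()`): on the 20 mm strand, the S1
  cycle length targets the requested DI; ERP is the shortest S1–S2 interval
  whose S2 propagates to the distal 10% of the strand (binary search, 1 ms
  resolution; the suite checks equivalence with a linear scan).
* **CV restitution** (`cv_restitution()`): S2 wavefront speed between
  probes at 25% and 75% of the strand (activation = −40 mV upward crossing,
  linearly interpolated).
* **Wavelength**: WL(DI) = ERP(DI) × CV(DI).
* **Minimum DI** (`minimum_di()`): a dynamic downward cycle-length sweep on
  the paced strand (coarse 8 ms steps, then 1 ms), carrying state between
  stages; capture demands 1:1 propagation to the distal strand.  The
  reported value is the shortest diastolic interval actually traversed
  under full capture, measured per beat from 90% repolarization to the next
  upstroke.  A space-clamped variant (`medium = "cell"`) shows how much of
  the limit is set by propagation: the lone cell re-excites down to ~10 ms
  DIs, the strand fails near 23 ms.
* **Alternans** (`detect_alternans()`, `alternans_onset()`): even/odd APD
  separation above a 2 ms threshold (small but above protocol jitter) in
  fixed-rate trains.

# Rotor experiments at desk scale

The full-scale rotor experiment — a 100 mm × 100 mm sheet, dt 10 µs,
dx 0.1 mm, 30 s of fibrillation with five coexisting rotors — is
three orders of magnitude beyond an interactive single-CPU budget, so the
package defines a desk-scale tier and reports *orderings and properties*
rather than full-scale absolute counts.  The desk-scale patch is 64 mm ×
64 mm at dx 0.5 mm, dt 25 µs, with conductivity calibrated at that
discretization; runs last a few seconds.  The methods and analysis code are
identical at both scales; only the geometry/discretization config differs.

Rotors are initiated by the cross-field protocol
(`cross_field_induction()`): a plane-wave S1 from the left edge, then a
half-field S2 over the lower half timed into the repolarization tail of the
S1 wave so that the S2 front propagates into recovered tissue but is blocked
where the tail has not yet passed; the broken end curls into a spiral.  The
working timings are frozen per condition in a versioned protocol file
(`inst/extdata/protocols/desk_patch.yaml`).

Domain size matters more than might be expected: immediately after the
break, the free end travels *with* the recovery front at roughly the
conduction velocity, and only anchors into a rotating core once the tissue
behind it becomes re-excitable.  That transient consumes several centimetres
of runway — in scans at 36 mm and 48 mm the tip reached the boundary and
annihilated for every S2 timing tried, while at 64 mm a single stable rotor
forms reliably.  The S2 timing window is narrow (at 64 mm, 170 ms works and
195 ms already fails), which is why the timings are deliberately
configuration, not code.

In the remodeled substrate this yields a sustained rotor; in the
non-remodeled substrate the same protocol fails to sustain reentry because
the wavelength exceeds what the patch can accommodate — reproducing, at
reduced scale, the qualitative full-scale finding.

## What scales and what does not

The desk-scale pharmacology runs reproduce the slowing effect of the
slow-recovery compounds where it is measurable: #3 lowers the dominant
frequency of the pseudo-ECG (8.1 Hz control vs 7.7 Hz), and #1 — the
fast-onset/slow-recovery profile — terminates the rotor outright within
~0.6 s of drug onset, the extinction-by-wavelength-prolongation mechanism
in its strongest form.  Termination, however, leaves #1 without a
meaningful dominant frequency at this scale: the PSD of its brief death
transient peaks well above the rotor frequency (a chirp/breakup artifact
robust to windowing choices), so the #1 frequency comparison — which at
full scale is made on activity that persists for tens of seconds — is
reported but should be read alongside the termination time, not as a rotor
rate.

The *percent refractory area* comparison, by contrast, does not survive the
scale reduction, and we report that openly rather than adjusting windows.
At full scale a single rotor's refractory arm covers ~17% of a 100 mm
patch, leaving a large excitable margin in which wavelength prolongation
visibly increases the refractory fraction.  In a 64 mm patch the same arm
covers ~79% of the domain: the measure sits near its ceiling, where APD and
rotation period prolong roughly proportionally and the fraction barely
moves (control 78.9%, #3 78.6%), while rotor termination under #1 pulls
the post-drug mean *down* (25.9%) because quiescent tissue is fully
excitable.  The refractory-area ordering should therefore be evaluated at
full scale only; the desk tier demonstrates the machinery and the frequency
and termination endpoints.

# Fibrillation analysis

* **Refractory area**: percent of nodes with the INa inactivation gate
  h < 0.5, averaged over an analysis window (the single-rotor pharmacology
  experiments average from 250 ms after drug-on to the end of the run).
* **Pseudo-ECG**: infinite-volume-conductor potential
  `1/(4 pi sigma) * sum Im/r` with the diffusive current `D * lap(Vm)` as the
  distributed source, evaluated at two electrodes over the patch center,
  10 mm apart and 5 mm off-plane (orientation of the pair is a free choice;
  we use a horizontal pair).  The conductivity scale cancels in all
  frequency-domain uses.
* **Dominant frequency**: PSD peak (mean removal, Hann window) above a 1 Hz
  drift floor; traces must be at least 2 s for 0.5 Hz resolution.
* **Phase singularities**: time-delay-embedded phase
  `atan2(Vm(t−tau)−V*, Vm(t)−V*)` with tau ≈ 4–5 ms and V* = −40 mV
  (streaming-friendly, no Hilbert transform), followed by ±2π winding
  detection on 2×2 plaquettes; sub-grid position is the plaquette center.
* **Tip tracking**: greedy nearest-neighbour linking of same-chirality
  detections within a per-frame displacement radius (default 3 mm at 10 ms
  analysis cadence) with a 5-frame gap tolerance.  Rotor counts are live-
  trajectory counts; a minimum-lifetime filter (100 ms) suppresses
  single-frame flickers.

# What the synthetic fixtures do and do not show

`make_spiral_movie()`, `make_figure_of_eight()` and `make_two_tone_ecg()`
generate analytic inputs with the *structure* the analyses assume — a
rotating phase field with a known core path, a counter-rotating pair with
zero net topological charge, known spectral content, and a synthetic h field
thresholded in antiphase to Vm (smoothed over ~2 mm) with an analytic
refractory expectation.  They validate the analysis stages (core recovery to
sub-grid accuracy, chirality, charge conservation, DF to spectral
resolution) independently of the ionic model.  They do not emulate ionic
dynamics: passing fixture tests demonstrates correctness of the analysis
pipeline, not fidelity of the tissue model, which is tested separately
against its own cellular and conduction benchmarks.

# Numerical choices and degenerate inputs

Singular points of the CRN rate expressions (V = −47.13, −10, 7.9 mV, ...)
use their analytic limits.  Gating updates are exact exponential relaxations,
so gates remain in [0, 1] for any step size.  The solver aborts with a
diagnostic if |Vm| exceeds 200 mV (divergence) and names the offending
variable if a state is non-finite.  Binary searches (ERP, conductivity)
verify that their brackets actually enclose the target and report the
achieved value alongside the result.  All randomness in the package lives in
the fixture noise and flows from a single seed; the physical simulations are
deterministic, and identical configs hash identically in the run manifests.

# Known limitations

* 2D isotropic monodomain only: no 3D atrial geometry, fiber anisotropy, or
  structural heterogeneity; no bidomain effects.
* Single ionic model family (CRN and its cAF variant); no alternative atrial
  models; no Markov-chain channel or binding-site drug models, and no
  concentration–response (IC50) scaling — compounds act through their
  kinetic profiles alone.
* Desk-scale rotor experiments reproduce orderings (refractory-area and
  dominant-frequency shifts under slow-recovery compounds) but not
  full-scale rotor counts; multi-rotor splitting protocols are configuration
  stubs at desk scale.
* APD30-level comparisons across CRN variants are unreliable for the reason
  given above; APD70/APD90 comparisons are robust.
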