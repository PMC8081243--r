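---
title: "Methods: bidomain forward-ECG simulation and parameter sensitivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bidomain forward-ECG simulation and parameter sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`fecgsim` simulates focal ventricular excitation and the resulting
body-surface electrocardiogram on a labeled heart–torso volume conductor,
and quantifies how sensitive the simulated potentials are to seven tissue
and organ parameters.

The electrical source model is the bidomain system with a surrounding
passive bath. On the myocardial domain $\Omega$ with boundary
$\partial\Omega$, embedded in the torso $\Omega_b$ with outer surface
$\partial\Omega_b$:

$$\nabla\!\cdot\!\big(\Sigma_i(\nabla V_m + \nabla\phi_e)\big)
  = \beta\big(C_m \partial_t V_m + I_{ion} + I_{app}\big), \qquad
\nabla\!\cdot\!\big((\Sigma_i+\Sigma_e)\nabla\phi_e\big)
  = -\nabla\!\cdot\!(\Sigma_i \nabla V_m),$$

with $\nabla\!\cdot\!(\Sigma_b\nabla\phi_b)=0$ in the torso,
potential continuity $\phi_e=\phi_b$ and flux matching across
$\partial\Omega$, and zero flux on $\partial\Omega_b$. Both conditions on
$\partial\Omega$ are enforced naturally by assembling the extracellular and
bath operators on one shared nodal field. The additive constant of this
pure-Neumann problem is fixed internally by a zero-mean gauge and, whenever
limb electrodes are defined, re-referenced afterwards so that the Wilson
central terminal (the RA/LA/LL mean) is exactly zero; reported signals are
invariant to the internal gauge.

Transmembrane currents come from the ten Tusscher–Panfilov 2006 human
ventricular myocyte model in its epicardial and endocardial variants,
transcribed from the published formulation (19 state variables; where the
printed equations and the authors' distributed code differ, e.g. in
$\tau_{f2}$, the printed equations are used). Units throughout: cm, ms, mV, mM, mS/cm,
µF/cm²; cellular currents are pA/pF.

## Conductivities and heterogeneity

Myocardial anisotropy uses equal transverse conductivities and a rotation
onto the local fiber: $\Sigma = M\,\mathrm{diag}(\sigma_l, \sigma_t,
\sigma_t)\,M^\top$. The four bidomain conductivities derive from Roth's
one-parameter framework: $\sigma_{li}=\sigma$,
$\sigma_{ti}=\sigma\lambda^{-2}(1+\alpha(1-\epsilon))/(1+\alpha)$,
$\sigma_{le}=\sigma/\alpha$,
$\sigma_{te}=\sigma_{ti}/(\alpha(1-\epsilon))$, so a single anisotropy
ratio $\lambda = \lambda_L/\lambda_T$ controls all four. At the reference
values ($\sigma=3$ mS/cm, $\alpha=1$, $\epsilon=0.75$, $\lambda=2.5$) this
gives (3, 0.3, 3, 1.2) mS/cm.

Two cellular heterogeneity rules are controlled by coefficients in [0, 1]:

* **Transmural** ($H_{TR}$): the wall is split into two discrete layers; a
  node at transmural depth $d$ (0 endo, 1 epi) is epicardial iff
  $d > 1 - H_{TR}$, i.e. the epicardial layer occupies the outer fraction
  $H_{TR}$ of the wall, measured from the epicardium inward so that
  $H_{TR}=1$ gives an all-epi wall exactly.
* **Apicobasal** ($H_{AB}$): the slow-potassium conductance follows
  $g_{Ks}(z) = 0.392 - 0.294\,H_{AB}\,z$ (nS/pF) with $z$ the normalized
  apex-to-base coordinate. The printed linear rule carries no explicit
  spatial argument; we resolve it so the apex keeps the nominal 0.392 and
  the base is maximally reduced, which is the only reading that yields the
  conventional shorter apical action potential. The same scaling applies to
  both cell variants, since the rule is stated independently of the layer
  split.

## Reference parameters and ranges

| parameter | symbol | reference | unit | study range | physiological range |
|---|---|---|---|---|---|
| membrane capacitance | $C_m$ | 1 | µF/cm² | fixed | — |
| surface-to-volume ratio | $\beta$ | 400 | cm⁻¹ | fixed | — |
| basic myocardial conductivity | $\sigma$ | 3.0 | mS/cm | fixed | — |
| Roth ratio | $\alpha$ | 1 | — | fixed | — |
| Roth imbalance | $\epsilon$ | 0.75 | — | fixed | — |
| torso bulk conductivity | $\sigma_b$ | 2.0 | mS/cm | fixed | — |
| transmural heterogeneity | $H_{TR}$ | 0.5 | — | [0, 1] | [0.2, 0.6] |
| apicobasal heterogeneity | $H_{AB}$ | 1 | — | [0, 1] | [0.7, 1.0] |
| anisotropy ratio | $\lambda_L/\lambda_T$ | 2.5 | — | [1.6, 6.0] | [2.0, 3.0] |
| lungs | $\sigma_{lungs}$ | 0.39 | mS/cm | [0.39, 1.34] | same |
| blood | $\sigma_{blood}$ | 7 | mS/cm | [4.35, 10] | same |
| spine | $\sigma_{spine}$ | 0.2 | mS/cm | [0.05, 0.6] | same |
| liver | $\sigma_{liver}$ | 0.28 | mS/cm | [0.28, 2.0] | same |

The apicobasal physiological range is quoted both as [0.7, 1.0] and
[0.75, 1.0] in the source literature; the configuration defaults to the
tabulated [0.7, 1.0] and exposes the narrower variant
(`hab_range_alternative()`).

A note on conduction velocity: with this parameter set the effective
longitudinal monodomain conductivity is
$\sigma_{li}\sigma_{le}/(\sigma_{li}+\sigma_{le}) = 1.5$ mS/cm, i.e. a
diffusivity of $1.5/(\beta C_m) = 3.75\times10^{-3}$ cm²/ms, and the
acceptance bar measures about 1.1 m/s along fibers and 0.40 m/s across on a
near-converged 0.02 cm mesh. The frequently quoted physiological bands of
0.5–0.6 and 0.15–0.25 m/s correspond to a surface-to-volume–capacitance
product around 1400 µF/cm³ rather than the tabulated 400; since planar CV
scales as $(\beta C_m)^{-1/2}$, those bands are reachable here only on
much coarser meshes (numerical CV slowing) or with a larger $\beta C_m$.
We keep the tabulated values and report the measured velocities as they
are.

# Synthetic anatomy

No patient meshes are distributed, so the generator builds an idealized
stand-in that reproduces the topological relations the regional analyses
depend on: two truncated confocal half-ellipsoids (thick LV ~1 cm, thin RV
crescent ~0.5 cm) sharing the septum, truncated at a base plane, with
blood-filled cavities, inside an elliptic-cylinder torso; two lateral lung
ellipsoids with the left lung adjoining the LV epicardium, a liver
ellipsoid under the apex, and a posterior spine cylinder. The frame is
right-handed with $+z$ apex-to-base and $-y$ anterior.

Meshing is a graded rectilinear grid (fine spacing inside a heart bounding
box, geometric coarsening outside, six Kuhn tetrahedra per cell —
conforming across cells), with labels assigned from the implicit geometry
at (jittered) element centroids. The jitter, derived deterministically from
the generation seed, breaks grid symmetry; `(geometry, seed)` determine the
anatomy bit-for-bit. Region surfaces extracted from a rectilinear carving
are watertight but staircase-shaped, and may contain occasional
non-manifold (pinched) edges.

The defaults use 0.2 cm edges in the cardiac box and 0.8 cm in the torso
periphery (~75k nodes, ~410k tets); the RV wall is kept at 0.5 cm so it
spans at least two element layers. These are desk-scale choices: wall
thicknesses and potentials behave physiologically, but the mesh slows the
wavefront numerically (late activation ~200 ms under RV-apex pacing),
which is acceptable for calibration-bound and directional analyses, not
for patient-level timing.

Anatomical coordinates are Laplace–Dirichlet interpolants on the
myocardial sub-mesh: transmural depth $d$ between the endocardium
(myocardium–blood interfaces) and epicardium (myocardium-to-organ/torso
interfaces and exterior walls), and apicobasal $z$ between an apical cap
(all myocardial nodes within 0.45 cm of the lowest point — a point apex
would be a single-node Dirichlet set on a jittered mesh) and the base
plane. Fibers lie tangent to the wall (orthogonal to a smoothed transmural
gradient; one to three passes of volume-weighted nodal averaging recover a
usable gradient on elements whose nodes all touch one Dirichlet surface)
and rotate linearly in $d$ from +60° (endo) to −60° (epi) against the
circumferential direction.

What the generator does **not** emulate: patient-specific shape and
rotation of the heart, atria and great vessels as separate electrical or
geometric entities (their blood pools fold into the blood/torso labels),
epicardial fat, sternum and ribs, pericardium, and anisotropic skeletal
muscle. Passing tests on this anatomy demonstrate correct mechanics of the
pipeline and reproduce direction-level physiology; they do not validate
patient-level ECG morphology.

## Electrodes and pacing

The default vest is a regular 14 × 16 grid over the full torso
circumference (224 unipolar leads), snapped to distinct torso-surface
nodes, plus RA/LA/LL at the shoulders/left lower torso and V1–V6 on the
anterior chest. Pacing sites snap to myocardial nodes: `rv_apex` (lowest RV
node), `lv_lateral_epi` (epicardial $d \ge 0.95$, mid-height, most-lateral),
`rvot` (basal anterior RV). The stimulus is a rectangular current pulse,
default 3 ms over a 0.3 cm radius; the default amplitude of 24 pA/pF is
twice the capture threshold that `capture_threshold()` finds by bisection
on the reference meshes (9.75 pA/pF bar, 11.7 pA/pF anatomy).

# Numerics

* **Space**: P1 tetrahedral finite elements; per-element anisotropic
  stiffness; lumped (diagonal) mass for positivity and speed.
* **Time**: Godunov splitting. Cell ODEs advance with Rush–Larsen
  exponential gate updates and forward Euler elsewhere (default
  `dt_ode` 0.02 ms; single-cell APD90 changes < 1 ms under halving); the
  parabolic step is implicit in $V_m$ with the extracellular field lagged
  (default `dt_pde` 0.1 ms); the elliptic solve closes each step
  (optionally every k-th step via `phi_update_every` at desk scale).
* **Linear algebra**: sparse supernodal Cholesky factorizations computed
  once per run (Matrix/CHOLMOD); the singular pure-Neumann elliptic
  operator is pinned at one node and re-gauged to zero mean afterwards
  (the right-hand side is compatible by construction).
* **Guards**: non-finite states abort with the offending node;
  $|V_m| > 100$ mV outside active stimulation aborts as an instability;
  calcium buffering uses the analytic quadratic update so concentrations
  stay positive.
* **Sampling**: outputs are recorded on an exact 1 kHz grid (t = 0, 1, …
  ms) regardless of internal steps.
* **Initial state**: tissue nodes start from the variant's quiescent
  steady state (3 s settling, cached); no pre-pacing, matching a
  resting-state initialization.

## Signal analysis rules

Detection rules the source description leaves open are fixed as:

* activation = first upward 0 mV crossing, linearly interpolated (a
  max-dV/dt detector would be sharper but is threshold-fragile at 1 kHz);
* repolarization = first downward crossing of
  $V_{rest} + 0.1 (V_{peak}-V_{rest})$ after the peak (APD90 convention);
  nodes that have not repolarized in the simulated window are excluded
  from dispersions with a logged count;
* QRS onset/offset: the RMS of the 12 standard leads crosses 5% of its
  global peak, with above-threshold runs merged when separated by < 10 ms;
  the QRS complex is the merged run containing the peak, QT extends to the
  last crossing. The depolarization/repolarization windows for amplitude
  biomarkers split at the QRS offset;
* late activation time is referenced to stimulus onset (not QRS onset);
  the QRS onset is also reported so the offset between conventions is
  recoverable;
* the torso QRS/T amplitude biomarkers are maxima of the torso-surface
  potential itself (WCT-referenced $\phi_b$ at surface nodes), not of
  bipolar leads, which can move in the opposite direction.

# Sensitivity pipeline

One-at-a-time sweeps vary a single parameter over its study or
physiological range (default 5 evenly spaced points, plus the reference
value), rerun the full forward model, and summarize each signal class
($V_m$ and $\phi_e$ over the myocardial volume and surface, $\phi_b$ over
the torso surface, and the BSM array) by the relative Euclidean distance
(RED) to the cached reference run. The sweep curve is interpolated with a
natural cubic spline (second derivatives zero at the ends); the reported
sensitivity is the maximum RED over tested values, with ties broken toward
the lower parameter value. Scalar biomarkers are summarized as min/max
percentages of the reference. Regional maps evaluate the per-node RED of
the local time trace on the heart surface ($\phi_e$) or torso surface
($\phi_b$, chosen over derived leads since the quantity of interest is the
surface potential), min–max scaled for display; nodes with an identically
zero reference trace are undefined and displayed as missing. Leads or
nodes with undefined metrics (constant traces) are excluded from summaries
with a logged count rather than zero-filled.

# Problem sizes used by the tests

The test and acceptance suites choose sizes that keep the full suite in
tens of minutes on one CPU: a 2.0 × 0.1 × 0.1 cm calibration bar at 0.02 cm
(3.6k nodes; conduction velocity, monodomain-reduction and refinement
checks), the default anatomy (~75k nodes) for the QRS calibration, and a
reduced anatomy (~36k nodes, 0.2 cm cardiac spacing) with `dt_pde` 0.2 ms
and a staggered elliptic update for directional sensitivity checks. The
directional findings asserted there — later activation with higher
anisotropy, larger APD dispersion with stronger apicobasal heterogeneity,
damped torso QRS/T amplitudes with higher lung conductivity, and
liver-conductivity sensitivity concentrated on the liver-facing cardiac
surface — are scale-robust, which is why they are tested at reduced size.

# Known limitations

* The idealized anatomy and coarse desk-scale meshes slow conduction
  numerically; absolute timing biomarkers are mesh-dependent (the
  refinement check quantifies this).
* No His–Purkinje system: only focal stimulation protocols are meaningful.
* The two-layer epi/endo wall has no M-cell option by design.
* The ionic model's repolarization is steeper than human recordings, a
  known property of this formulation.
* Sweeps treat parameters one at a time; no interaction or global
  sensitivity analysis is attempted.
* At coarse mesh spacing a few staircase epicardial nodes adjacent to the
  stimulus produce abortive action potentials, inflating max-minus-min APD
  dispersions; and when late activation overlaps repolarization onset the
  RMS-based QRS delimiter fuses QRS and T, so width biomarkers are only
  meaningful where a quiescent ST segment exists.
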