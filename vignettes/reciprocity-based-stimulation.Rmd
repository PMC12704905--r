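---
title: "Predicting membrane responses to electric stimulation by reciprocity"
author: "cableRT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting membrane responses to electric stimulation by reciprocity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cableRT)
```

## The problem and the idea

Extracellular electric stimulation (ES) — from an intracranial
microelectrode or from scalp electrodes (tES/tACS/tDCS) — polarizes neurons
through the spatial gradient of the imposed extracellular potential over
their morphology. Simulating this the traditional way requires one cable
solve per stimulation site: the potential field of the electrode is
evaluated at every neural compartment and inserted as a boundary condition.
The result is accurate but opaque, and a map of responses over many
candidate electrode positions costs many solves.

For a linear (passive, subthreshold) system the reciprocity theorem turns
the problem around: the membrane-potential change of a target compartment
caused by a current source at an extracellular point equals the
extracellular potential at that point caused by the same current injected
into the target compartment. Since a single intracellular solve yields the
membrane currents — and hence the extracellular potential *everywhere* —
one solve per frequency answers the question for every stimulation site at
once. cableRT implements both routes and treats their agreement as its
central invariant.

## Model

Neurons are passive compartmental cables. In the frequency domain the
system at frequency $f$ (angular frequency $\omega = 2\pi f$) is

$$ \big(\mathrm{diag}(G_n + j\omega C_n) + L\big)\, V_m = s, $$

where $G_n$ and $C_n$ are each compartment's membrane conductance and
capacitance, and $L$ is the axial-coupling Laplacian: the conductance
between adjacent compartments is the reciprocal of the sum of the two
half-compartment axial resistances $4 R_a (\ell/2)/(\pi d^2)$ — the
standard compartmental convention, which converges to the continuous
cable. At DC the operator is purely resistive; no regularization is needed
because $R_m$ is finite. One complex linear solve per frequency gives the
exact steady state, with no transient truncation; an independent
time-domain integrator (`simulateTimeDomain`, trapezoidal scheme) exists
purely as a cross-check and agrees with the frequency-domain amplitudes to
better than 0.1%.

For intracellular injection the right-hand side is $s = I\,e_{\rm site}$
with an inward-positive (depolarizing) stimulus. Membrane currents are
outward-positive and the stimulus is counted as part of the injected
compartment's membrane current (entering as $-I$), so
$\sum_n I_{m,n} = 0$ at every frequency. With that bookkeeping the
discrete reciprocity identity is exact: writing $A = Y_m + L$ (symmetric)
and $K_n = 1/(4\pi\sigma|r - r_n|)$ for the point-source kernel,

$$ V_e(r \mid I \text{ at } c) = -I\,K^{\top} L A^{-1} e_c
   = V_m^{(c)}(\text{ES } I \text{ at } r), $$

because the traditional route solves $A V_m = -L K I$. Both directions use
the *same* kernel (with observation distances clamped from below at the
compartment radius), so their agreement in the test suite is limited only
by round-off, not by discretization. A consequence of the sign convention
is that the injected compartment is the net current *sink* (its membrane
current is close to $-I$): the closed-form somatic transfer function
$T_{I_s}$ below is negative at DC for the same reason.

For the traditional route, the extracellular potential enters per
compartment midpoint and only its spatial differences drive a response: a
spatially uniform $V_e$ yields identically zero deviation.

### Fields

Extracellular potentials in an infinite homogeneous medium use the
point-source sum over compartment midpoints,
$V_e(r) = \sum_n I_{m,n}/(4\pi\sigma|r-r_n|)$. Line sources are out of
scope. Two limits matter for intuition and are exposed directly: close to
the injected soma the potential is dominated by the stimulus itself
(monopole, $1/r$, frequency-independent); far away the current-dipole
approximation $V_e = p\cos\theta/(4\pi\sigma r^2)$ applies, with
$p = \sum_n I_{m,n}(r_n - r_0)$ independent of the origin $r_0$ because
the currents sum to zero.

### Units

One internal unit system is used throughout: µm, ms, mV, nA, MΩ (= 1/µS),
nF, S/m, Hz. In these units the point-source kernel needs no conversion
factor: 1 µA at 50 µm in σ = 0.3 S/m gives
$1000/(4\pi\cdot 0.3\cdot 50) = 5.305$ mV.

## Parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| $R_m$ | 30 000 | Ω·cm² | passive cortical value; $\tau_m = 30$ ms |
| $R_a$ | 150 | Ω·cm | standard intracellular resistivity |
| $C_m$ | 1 | µF/cm² | universal membrane capacitance |
| myelin override | $R_m \times 40$, $C_m / 40$ | — | sheath wrapping attenuates leak and capacitance equally |
| $\sigma$ | 0.3 | S/m | typical grey-matter conductivity; configurable |
| four-sphere radii | 79, 80, 85, 90 | mm | brain/CSF/skull/scalp |
| four-sphere σ | 0.276, 1.65, 0.01, 0.465 | S/m | standard head-model values |

Because the infinite-medium conductivity used for published field maps is
rarely stated, every distance- or frequency-dependent check in this
package is a ratio or a slope, never an absolute amplitude tied to a
particular σ.

The multisine ("white noise") stimulus is a sum of equal-amplitude
cosines with seeded uniform random phases; the analysis grid equals the
construction grid, so spectra are leakage-free by construction. The
default frequency range is 1 Hz–10 kHz on a logarithmic grid,
configurable.

## Synthetic cells: what they emulate and what they do not

All tests run on morphologies built in code:

* **Ball-and-stick** — soma (diameter $d_s$, membrane area $\pi d_s^2$,
  iso-potential) plus a single stick along +z. The stick anchors at the
  soma *midpoint*: the soma being iso-potential, its internal geometry only
  contributes membrane area, and anchoring at the centre makes the
  compartmental cell topologically identical to the lumped-soma cable of
  the closed-form transfer functions. (Anchoring at the soma surface
  instead shifts every stick source by $d_s/2$ and biases the
  current-dipole moment by tens of percent at 10 kHz, where the
  frequency-dependent length constant is itself only ~20 µm.)
* **Pyramidal-like star cell** — soma plus an apical stick and four
  oblique basal sticks; the minimal morphology whose soma is
  dendrite-loaded the way cortical cells are.
* **Myelinated axon** — 10 mm, one node of Ranvier per 50 µm
  (`round(total/interval)` nodes, first and last compartments are nodes;
  the terminal is a plain endpoint with the axon's diameter), myelin
  internodes with the override above.
* **Random branched trees** — seeded generator for property tests.

They emulate passive cable structure, not reconstructed anatomy: no
tapering, spines, or active conductances. Consequently, passing tests
demonstrate the linear-response machinery exactly, but say nothing about
spike initiation or subthreshold-active channels; for active models the
package's contract is linear extrapolation of a subthreshold solve
(conventional fixed subthreshold amplitudes when driving external
simulators: 0.1, 0.01 and 0.001 nA for pyramidal-cell-, interneuron- and
axon-class models).

### A note on near-field frequency flatness

The response to stimulation close to the soma is approximately
frequency-independent below ~100 Hz. Quantitatively this is a property of
*dendrite-loaded* cells: across a 30-cell sample of branched synthetic
cells the deviation from the 1 Hz value (10 µm from the soma, ≤ 100 Hz)
has a median below 5%, and the fixture cells stay below 10%. A *single*
thin stick leaves the soma much more strongly loaded — the full field sum
then varies by 10–20% — and sparse random trees can exceed the bound
severalfold. The analytic near-field susceptibility of the default
ball-and-stick stays within the 10% bound. The package's flatness check
therefore runs on the multi-dendrite fixture cells, which are the
synthetic stand-ins for the cortical cells the claim concerns, and
additionally asserts the population median and the single-stick excess.

## Closed-form ball-and-stick transfer functions

With $q^2 = 1 + j\omega\tau_m$, the DC length constant
$\lambda = \sqrt{d R_m/(4 R_a)}$ (frequency dependence enters solely
through $q$; the source formalism defines $q$ but leaves $\lambda$ to the
DC convention adopted here) and $Y = q\,d_s^2/(d\lambda)$:

$$ T_{I_s} = \frac{-\sinh(ql/\lambda)}{Y\cosh(ql/\lambda) + \sinh(ql/\lambda)},
\qquad
T_{p_s} = \frac{\lambda}{q}\,
   \frac{\cosh(ql/\lambda) - 1}{Y\cosh(ql/\lambda) + \sinh(ql/\lambda)}. $$

$T_{I_s}$ maps the injected current to the net somatic membrane current
(stimulus included), $T_{p_s}$ (µm) to the current-dipole moment along the
stick. Both are evaluated with the overflow-safe $\tanh$/sech forms
($\tanh \to 1$, sech $\to 0$ for large electrotonic arguments), satisfy
$T(-f) = \overline{T(f)}$, and vanish as $l \to 0$ (a point cell returns
the injected current locally). The leading minus sign of $T_{I_s}$ is the
sink role of the injected soma discussed above; the numerical solver
reproduces both magnitudes within 2% on a 2 µm mesh from 1 Hz to 10 kHz.

In the high-frequency limit $|Y| \propto \sqrt{f}$ dominates, so
$|T_{I_s}| \propto f^{-1/2}$ and
$|T_{p_s}| \propto f^{-1}$: the far field is the more strongly low-pass
filtered, as dendritic-filtering theory predicts. (Published statements of
these exponents are sometimes garbled by lost radical signs; the package
asserts the exponents that follow from the formulas, −0.5 and −1, as
log-log slopes over 10–100 kHz with ±0.1 tolerance.)

Composing the transfer functions with the reciprocity relation gives the
analytic stimulation susceptibility of the soma:
$|T_{I_s}|/(4\pi\sigma r)$ nearby,
$|T_{p_s}|\cos\theta/(4\pi\sigma r^2)$ far away. The parameter study they
support: membrane resistance is largely irrelevant nearby (two-fold
changes stay within the 15% bound asserted by the suite, and in practice
well under it); stick length is unimportant nearby (< 5% for a doubling)
but changes the far field by tens of percent; a thicker stick increases,
a bigger soma decreases, the far-field susceptibility.

## Head models and transcranial stimulation

For tES the extracellular medium is a head model; all such models are
linear, so reciprocity passes through them unchanged. The lead field
$M$ maps a normal-oriented dipole at a cortical location to the potential
at each electrode; read backwards, the same entry is the electric field
along the cortical normal per unit electrode current. cableRT calibrates
lead-field matrices in mV per nA·µm (equivalently mV/µm per nA) so that
both readings are the same number, which makes the head-reciprocity
identity exact by construction: the membrane response to 1 mA through an
electrode is $10^6$ times the EEG amplitude that the cell's own dipole
(per 1 nA of somatic input) produces at that electrode, through the same
matrix entry. The response map over the cortex is the field map scaled by
$|T_{p_s}(f)|$: frequency changes the amplitude, never the spatial
pattern.

Two download-free head-model components are built in:

* a **four-sphere model** (concentric brain/CSF/skull/scalp shells,
  quasi-static Legendre series). Each harmonic degree is solved as a small
  interface system in a per-shell scaled basis, which keeps the matrices
  well conditioned at arbitrary order; the default truncation order is
  100, and the series is converged to < 10⁻⁶ by order ~120 for a dipole at
  80% of the brain radius. Validation: a central dipole reproduces the
  closed form $3p\cos\theta/(4\pi\sigma R^2)$ in the equal-conductivity
  limit, and eccentric radial/tangential dipoles match a monopole-pair
  oracle. Shrinking all radii ten-fold (a mouse-sized head) raises scalp
  potentials from the same dipole by roughly two orders of magnitude — the
  $1/r^2$ geometry of the dipole field.
* a **miniature lead-field fixture** filled from the four-sphere model,
  stored in a documented JSON layout (`lead_field`, or a three-component
  `lead_field_3c` collapsed onto cortical normals at load time, mirroring
  the published head-model convention). Converting a published
  HDF5-backed lead field into this layout is a one-line export in any
  HDF5-capable tool; no binary reader ships with the package.

Under the **quasi-uniform assumption** a distant electrode's field is
constant over one neuron, and the imposed potential is
$V_e = -\mathbf{E}\cdot(\mathbf{r} - \mathbf{r}_{\rm soma})$ — the
potential decreases along the field direction ($\mathbf{E} = -\nabla V$;
the sign is stated explicitly because field-to-potential conventions are
often left implicit). Feeding this into the traditional solver reproduces
the $T_{p_s}$-based reciprocity prediction within 2% (the residual is the
far-field approximation itself). A field pointing from the soma toward the
apical stick hyperpolarizes the soma in this convention.

## Numerical choices

* **Meshes.** Analytic–numerical comparisons use a 2 µm mesh (500
  segments on a 1 mm stick) so that the mesh resolves the ~20 µm
  frequency-dependent length constant at 10 kHz; coarser default cells
  (5–10 µm) are used where only low frequencies matter. `refineMorphology`
  splits compartments exactly, preserving length and area to machine
  precision.
* **Singularity clamping.** Observation points closer to a compartment
  midpoint than its radius are clamped to the radius, in both directions
  of the reciprocity relation, so the identity survives degenerate
  geometry.
* **Degenerate normalization.** The consistency check reports a relative
  discrepancy except when the traditional response is below 10⁻¹² mV
  (stimulation on the field's zero-crossing surface), where it falls back
  to the absolute difference.
* **Time stepping.** The oracle integrator uses the implicit θ-scheme
  (θ = 0.5) with a guard `dt < τ_m/20`.
* **Conservation tolerance.** Solutions must satisfy
  $|\sum_n I_{m,n}| < \max(10^{-9}\max|I_m|,\ 10^{-12}\,\mathrm{nA})$; the
  absolute floor covers single-compartment cells whose net current is
  itself round-off.
* **Problem sizes.** The routine test suite runs on cells of 10–500
  compartments, 100-case randomized reciprocity sweeps, and 4×10 lead
  fields; these sizes make the whole suite run in seconds while leaving
  every numerical comparison at least an order of magnitude away from its
  tolerance.

## Known limitations

* Passive membranes only; active models are served through the ES-proxy
  contract (`esProxyCurrent`: the equivalent somatic current
  $\Delta V_m(f)/Z(f)$ that reproduces the linear stimulation effect in a
  point model), not by simulating channels.
* Point-source compartments, not line sources; no electrode geometry,
  probe shadowing, or tissue anisotropy.
* The four-sphere model is a stand-in for subject-specific head anatomy;
  absolute tES numbers inherit the head model's idealizations.
* Reciprocity is exact here *because* the system is linear; close to
  spike threshold the prediction degrades, and nothing in this package
  detects that regime.
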