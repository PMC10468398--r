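---
title: "Methods: droplet ionic power sources and calcium-wave statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: droplet ionic power sources and calcium-wave statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iondrop)
```

This vignette explains the models implemented by `iondrop`, the
assumptions behind them, the parameters that matter and why their
defaults are what they are, and what the synthetic-data generators do and
do not emulate. The device under study is a five-droplet hydrogel chain —
high-salt | cation-selective | low-salt | anion-selective | high-salt —
that converts a stored salt gradient into ionic current once the
insulating lipid bilayers between droplets are ruptured, and that can be
attached to a neural microtissue to modulate its network activity.

## The equivalent-circuit model

A salinity gradient across an ion-selective hydrogel develops an
electromotive force. For a monovalent counter-ion and an ideally
selective membrane, each of the two selective droplets contributes the
Nernst EMF $(RT/F)\ln(c_\mathrm{high}/c_\mathrm{low})$, about 136 mV for
the working 200-fold gradient at 25&nbsp;°C, so the ideal stack develops
about 272 mV. Real units fall short of the ideal stack (co-ion leakage,
junction potentials, electrode non-idealities), which the model absorbs
into a single *apparent permselectivity* $\alpha \in [0,1]$ per membrane.
`calibrate_permselectivity()` fits $\alpha$ to a measured open-circuit
voltage; for the measured 127 mV of the 50-nl unit it gives
$\alpha \approx 0.47$. The divalent working salt is treated with the
monovalent idealization by default (a `valence` argument exposes the
alternative); the transport simulation uses monovalent ions for the same
reason, and no bi-ionic membrane model is attempted because none of its
parameters is observable from the available measurements.

The internal resistance sums $L_i/(\sigma_i A_i)$ over the five droplets.
Conductivities are limiting molar conductivities times concentration;
ion-selective droplets conduct through their polyelectrolyte counter-ions
(fixed-site concentration times the single-ion conductivity). Droplet
contact geometry is not observable: a droplet is modelled as a cylinder of
length one sphere-equivalent diameter whose cross-section is a fraction
(`area_factor`, default 0.7) of the equatorial cross-section, and
`calibrate_area_factor()` rescales that fraction so the computed
resistance matches the measured ~78 kΩ of the 50-nl unit (the calibrated
fraction is about 0.25). Resistance is exactly inversely proportional to
the factor, so the calibration is a single ratio.

Two printed characterizations of the same unit — 127 mV with 78 kΩ, and a
maximum output power of ~75 nW — are mutually inconsistent with the
matched-load identity $P_\mathrm{max} = V_{OC}^2/(4R_\mathrm{int})$,
which gives 51.7 nW. The package computes and asserts only the internally
consistent quantity; both measured values are kept as calibration
targets, not jointly enforced. Similarly, the reported ~1,300 W m⁻³ is
described as an *average* energy density at matching resistance over an
unstated window; the package computes the *peak* power density
$(V_{OC} I_{SC}/4)/(5 V_\mathrm{droplet})$, which reproduces the printed
~100× gain between the 1,000-nl and 1.84-nl units (a ratio of about 107
from the printed voltage/current pairs) without reproducing the absolute
1,300 W m⁻³ figure.

Series/parallel composition is ideal and exactly multiplicative: voltage
scales with units in series, current and released charge with units in
parallel, resistance with their ratio. No inter-unit contact resistance
is modelled.

## The transport simulation

The solver integrates two monovalent species (K⁺, Cl⁻) on a 1-D
finite-volume grid spanning the five compartments, with Scharfetter–
Gummel face fluxes

$$J = \frac{D}{\Delta x}\left[B(\delta)\,c_L - B(-\delta)\,c_R\right],
\qquad \delta = \frac{zF\,\Delta\phi}{RT},\quad B(x)=\frac{x}{e^x-1},$$

which reduce exactly to Fick's law at $\Delta\phi = 0$ and to the
Boltzmann equilibrium ratio at zero flux — the discrete interface
therefore reproduces the closed-form Donnan step
$(RT/F)\,\mathrm{asinh}(X/2c_s)$ to machine precision, which is one of
the test oracles.

**Potential closure.** True electric double layers at these interfaces
are nanometres thick and unresolvable on a grid of hundreds of
micrometres. The default closure is algebraic electroneutrality including
the fixed charge: at every face the potential drop is solved (vectorized
damped Newton on a strictly monotone scalar residual) so that the total
ionic current is spatially uniform and equal to the circuit current. This
keeps $F(c_K - c_{Cl}) + \rho_\mathrm{fix}$ exactly invariant and makes
the conservative explicit update preserve species mass to machine
precision with blocked boundaries. An optional `poisson_scaled` closure
solves the Poisson equation with an artificially enlarged permittivity so
the interface space-charge layers spread over a grid-resolvable Debye
length; it is provided for verifying interface equilibria in open-circuit
settings and is not used for quantitative discharge traces (its
dielectric-relaxation time limit makes long transients expensive).

**Electrodes and modes.** Electrodes are ideal non-polarizable Ag/AgCl:
they exchange Cl⁻ only, carry the full circuit current at the boundary
faces, and contribute $-(RT/F)\ln(c_{Cl,R}/c_{Cl,L})$ to the terminal
voltage. Open circuit solves the face potentials at zero current;
short-circuit, resistive-load and applied-potential modes wrap that solve
in a secant iteration on the circuit current so the terminal condition
($U=0$, $U=IR_\mathrm{ext}$, or $U=V_\mathrm{app}$) holds each step.
Recharging holds the terminal at +200 mV — above the remaining cell EMF —
which reverses the current and moves cations from the low- back to the
high-salt side; the recharge tests assert the flux direction and that
longer recharge recovers monotonically more short-circuit current.

**The fixed-charge parameter.** The published simulation setup assigns
the selective droplets "fixed charges of 1,000 C m⁻³". Read literally
that is $1000/F \approx 10^{-5}$ mol L⁻¹ of charged sites — five orders
of magnitude below even the low-salt concentration — which would make the
membranes non-selective and the stack EMF essentially zero, contradicting
the measured 127 mV. The membrane recipe (20% w/v polystyrene sulfonate,
monomer mass ≈ 206 g mol⁻¹) corresponds to roughly 1,000 *mol* m⁻³ of
fixed sites, so the package reads the printed figure as an
ion-exchange-site concentration: `power_unit()` takes
`fixed_charge_mol_m3` (default 1,000) and converts to C m⁻³ internally,
while the grid and solver work in C m⁻³ throughout and any value can be
supplied. As the fixed-site concentration grows the simulated
open-circuit voltage rises monotonically to the 272-mV Nernst limit
(within 2% by $10^6$ mol m⁻³), another test oracle.

**Initial conditions and reported quantities.** Non-selective
compartments start at their nominal concentrations; selective
compartments start at Donnan equilibrium with the *low*-salt side (the
minimal-invasion convention), so the initial open-circuit voltage is the
full 272-mV Nernst stack which then relaxes within seconds to the
Teorell–Meyer–Sievers value (~216 mV for the default parameters) as the
high-salt interfaces invade. The reproduction targets are defined as: the
open-circuit *plateau* is the mean terminal voltage over 10–60 s of the
transient (fixed before any simulation was run); the short-circuit *peak*
is the maximum current over the first 60 s; the late current is
$I(1800\,\mathrm{s})$. With the defaults the plateau lands within a few
percent of the measured 127 mV.

**Known limitations.** The 1-D reduction stores each droplet's full
physical volume in its cells (so the 100-nmol salt inventory and the
charge budget are exact) while transporting through the calibrated
contact area. With free-solution diffusivities (K⁺ 1.96·10⁻⁹, Cl⁻
2.03·10⁻⁹, Ca²⁺ 0.79·10⁻⁹ m² s⁻¹; hydrogel obstruction off by default,
adjustable through the species diffusivities) the model's co-ion leak
runs the gradient down considerably faster than the real device: the
simulated short-circuit current peaks not at $t=0$ (where it is ~2.8 µA,
close to the measured 2.2 µA peak) but tens of seconds later after the
low-salt droplet has salinated and the dominant resistance collapsed, and
by 30 min the inventory is exhausted so the small residual current is
*reversed*, driven by the Cl⁻ asymmetry the electrodes themselves created
— unlike the measured ~30 nA forward current. These discrepancies are
reported as computed; no parameter was adjusted toward the measured
values beyond the two stated calibrations (127 mV, 78 kΩ).

**Numerics and problem sizes.** Explicit conservative updates under a CFL
bound $\Delta t \le \mathrm{cfl}\cdot V_\mathrm{cell} / \sum_f D A_f
(1+|\delta_f|)/\Delta x_f$ (default cfl 0.4, capped at 0.5 s); the face
Newton solve is warm-started from the previous step and tolerances are
relative ($10^{-10}$ by default). The default grid uses 12 cells per
compartment; tests verify that halving the spatial and temporal
resolution moves the reported plateau and peak by less than 2%, and the
analysis scripts and acceptance runs use the 12-cell default over the
full 0–1,800 s protocol (a run takes on the order of a second).

## Imaging statistics

The relative concentration $C = (\mathrm{Fluo}(t) - F_0)/(F_\mathrm{final}
- F_0)$ is anchored at 0 (baseline) and 1 (extremal frame), with
$F_\mathrm{final}$ the maximum for a fluorogenic indicator (calcium) and
the minimum for a quenching one (chloride); it is invariant to gain and
offset. $F_0$ is the mean of the pre-attachment baseline frames (default
3 for bare traces; the recordings' first frames before the conductive
hydrogel network forms) — the source description names no frame count, so
a short average was chosen over a single frame to damp shot noise, and
the same convention (3-frame averages) defines the displacement window
endpoints.

The centre of fluorescence along a measurement line is the intensity-
weighted mean distance; the relative displacement is its shift between
the pre-attachment baseline and the end of the 90-s observation window,
normalized by line length. The measurement line runs along the tissue's
horizontal diameter with its origin on the boundary facing the incoming
current (current flows left to right), sampled at one-pixel spacing with
bilinear interpolation and a 5-pixel transverse average.

The weighted mean is translation-equivariant and scale-invariant but
*offset-sensitive*: uniform background pulls it toward the line midpoint.
The displacement statistic is therefore computed on raw intensities by
default (matching its definition), while an optional constant background
subtraction (`background = "auto"`, median + 2 MAD of the baseline
frames; the guard band suppresses the spurious uniform weight that
clipped noise would otherwise contribute) is recommended when the
*slope* of the centre — the wave speed — is the quantity of interest.
The wave speed is the least-squares slope of the centre-of-fluorescence
trajectory over the observation window.

Classification into wave-like vs simultaneous activation thresholds
$|$relative displacement$|$; since the original classification was
visual, the default threshold (0.1) is the midpoint between the mean
displacements of synthetic wave-like and synchronous cohorts
(`calibrate_activation_threshold()` recomputes it for any cohort). Group
comparison offers the unpaired one-tailed two-sample t-test
(pooled-variance by default, Welch selectable) — the test used to
annotate the published group figure — and a one-way ANOVA, the test named
in the published methods; both are reported by the cohort analysis script
and the discrepancy between the two descriptions is left as such.

## The synthetic-data generators

`gen_wave_stack()` emulates a maximum-projected confocal time-lapse of a
570-µm neural microtissue at 1.28 s per frame and 2 µm pixels: somata
(default 800) placed uniformly in the disc, each following
double-exponential indicator kinetics (rise 0.5 s, decay 3 s — fast
calcium-dye scales) rendered as Gaussian blobs (σ = 6 µm), over a
constant resting fluorescence (10 intensity units vs a 300-unit soma
peak) with photon-like Gaussian noise (variance proportional to
intensity). The three regimes plant their ground truth in the onset
times: wave-like onsets at distance/speed from the left boundary (default
6 µm s⁻¹, chosen so one wave traverses the tissue within the 90-s
window); synchronous onsets at a common 5-s latency with 1-s jitter
(within the published "15 s" description); suppressed onsets like the
wave but at 0.25× amplitude — the amplitude factor is a free parameter of
the emulation, not an estimate, since no quantitative suppression level
is published. The generator also returns an analytic ground truth
(onset times, planted speed, and the displacement computed from the
continuous generative model along the standard line, without
rasterization or noise), and all randomness is fixed by the seed with the
caller's RNG state preserved.

What the generator does *not* emulate: neuronal biophysics (no membrane
potentials, synapses or receptor kinetics), cell morphology beyond
Gaussian blobs, z-stack optics (stacks are generated post-projection),
photobleaching, motion, or detector artefacts. Passing tests therefore
show that the *statistics* recover planted kinematics and regime
orderings under photon-like noise — not that they are robust to the full
complexity of real recordings (drift, segmentation ambiguity, uneven
staining), which the non-goals exclude.

`gen_discharge_trace()` wraps a simulated discharge in Gaussian
measurement noise per channel (zero noise returns the simulator output
exactly), for testing the trace readers and summary statistics.

## File formats

Stacks are multi-page TIFFs with a JSON sidecar (frame interval, pixel
size, intensity scale, metadata). The available TIFF writer stores 32-bit
unsigned-integer samples in [0, 1], so intensities are scaled by a
recorded power of two; integer camera counts round-trip exactly (the
sidecar flags them), arbitrary values to ~10⁻⁹ relative. Traces are CSV
with unit-bearing headers (`t_s,V_mV,I_uA,Q_mC`) written at full double
precision with locale-independent decimal points; cumulative charge is
the trapezoidal integral of the stored current samples. Run
configurations are YAML or JSON with units embedded in key names
(`volume_nl`, `c_high_M`) to prevent unit mistakes.
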