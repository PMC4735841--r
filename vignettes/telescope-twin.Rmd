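---
title: "A digital twin of a three-layer LaBr3 Compton telescope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A digital twin of a three-layer LaBr3 Compton telescope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

comptwin is a desk-scale digital twin of a three-layer LaBr3 Compton
telescope developed for treatment monitoring in hadron therapy and first
characterized with a 22Na point source. The package simulates the
laboratory measurement end to end — radioactive decay, photon transport
through the three scintillator layers, detector response, the triple
coincidence trigger — and then runs the same analysis chain a real
measurement would: gamma-spectroscopy calibration, three-interaction
Compton-cone building, and list-mode ML-EM image reconstruction. This
vignette documents the physics model, the tunable parameters, the design
choices made where the instrument description leaves the model open, and
the limits of what the twin can and cannot say about the real device.

## The instrument and its coordinate frame

The telescope stacks three LaBr3 crystals read out by SiPM arrays:

| layer | size (mm)        | thickness | energy res. @511 keV | role |
|------:|------------------|-----------|----------------------|------|
| 1     | 27.2 x 26.8      | 5 mm      | 6.4% FWHM            | scatterer |
| 2     | 32 x 36          | 5 mm      | 7.4% FWHM            | scatterer |
| 3     | 32 x 36          | 10 mm     | 7.2% FWHM            | absorber  |

All coordinates are millimetres in a right-handed frame with origin at the
centre of the layer-1 entrance face and +z running from the source towards
layer 3; the 22Na source sits on the axis at z = -35 mm. The 60 and 65 mm
inter-layer distances are interpreted as *gaps between adjacent crystal
faces* (the description does not say; `default_prototype("center")` gives
the centre-to-centre alternative). With face gaps the layer-3 entrance face
is 35 + 5 + 60 + 5 + 65 = 170 mm from the source. The layers are coaxial
and parallel; transverse misalignment is not modelled because none is
reported.

```{r}
library(comptwin)
default_prototype()
```

## Physics kernel

Compton kinematics use a single constant, `electron_rest_kev = 511.0`
(rounded from 510.999 so the annihilation line and the kinematic constant
coincide in worked examples). Scattering angles are sampled from the
Klein-Nishina differential cross-section by rejection with a uniform
envelope (the density is maximal in the forward direction at every energy).

Attenuation in LaBr3 (density 5.08 g/cm^3, Z/A = 162/378.617) is tabulated
at 17 energies from 30 to 2000 keV and interpolated log-log:

* the **Compton** column is the closed-form total Klein-Nishina
  cross-section times the electron density, so free-path sampling and
  angular sampling share one cross-section model exactly;
* the **photoelectric** column is semi-empirical: classic above-K-edge
  lead photoelectric values scaled to La and Br with a Z^4.5 power law and
  the atomic-mass ratio, then mass-weighted. Both K edges (38.9 and
  13.5 keV) lie below the table floor, so the curve is edge-free. Accuracy
  is a few per cent on the Compton part above 200 keV and roughly 10-30%
  on the photoelectric part, which is sub-dominant above 300 keV. The
  resulting mu_total(511 keV) = 0.42 cm^-1 compares to ~0.45-0.47 cm^-1 in
  standard compilations that additionally include Rayleigh scattering.

Rayleigh scattering, pair production, fluorescence escape, Doppler
broadening and electron transport are deliberately not modelled: they are
sub-dominant for the transport of 0.3-1.8 MeV photons through thin LaBr3
layers, with one important caveat for image resolution discussed below.
Photons degraded below 30 keV (the table floor) deposit their remaining
energy locally, which keeps energy conservation exact on every history —
a property the test-suite asserts.

## Detector response model

* **Energy**: Gaussian blur with FWHM(E) = r511 * 511 * sqrt(E/511) keV,
  i.e. relative resolution scaling as 1/sqrt(E) (photostatistics), anchored
  at the measured 511 keV values per layer. The description gives no
  scaling law; this is the standard scintillator assumption.
* **Position**: transverse (x, y) Gaussian blur of 1 mm FWHM, clamped to
  the crystal; the reported depth is always the layer mid-plane, because
  the light-distribution position estimation of the real device is 2D.
  (The spatial-light-model algorithm itself is out of scope and replaced
  by this parametric blur.)
* **Threshold**: 50 keV per layer, applied to the measured (blurred,
  merged) energy, inclusive at the boundary.
* **Trigger**: a greedy non-overlapping 25 ns window; an event is emitted
  when all three layers carry an above-threshold signal in the window.
  Deposits that the detector cannot separate — several interactions of one
  decay in one layer, or window pile-up — are merged with summed energy and
  energy-weighted centroid *before* blur/threshold.

Timing is simplified: every interaction inherits its decay time (transit
times are sub-ns) and detector time jitter is not modelled, since the
prototype's timing characterization is future work. Accidental coincidences
therefore arise exactly from decay-rate pile-up inside the 25 ns window at
the 700 kBq source activity.

## The Monte Carlo source and emission importance sampling

The 22Na model emits, per decay, a back-to-back 511 keV pair with
probability 0.903 (isotropic axis) and one 1275 keV photon (1274.5 rounded)
with probability 0.999, from a 0.25 mm diameter disc. Positron range and
annihilation acollinearity are ignored (sub-resolution at 0.25 mm scale).

A triple coincidence needs a layer-1 deposit, and the angular footprints of
layers 2 and 3 (≤ 14 degrees from the source) are strict subsets of
layer 1's (≤ 29 degrees), so only photons emitted into the 30-degree cone
around the axis can ever touch a crystal. `emit_decays_aimed()` exploits
this twice, exactly and without weights:

1. decays are stratified by which photon falls in the cone — stratum A
   (the 1275 photon, probability 0.999 f with f = (1-cos30)/2 ≈ 0.067) and
   stratum B (one 511 photon, probability 2 * 0.903 f, its 1275 isotropic
   outside the cone); the order-f^2 overlap is assigned to A;
2. any generated photon whose straight-line path misses every crystal is
   dropped at emission (it could never deposit energy).

Decay times are the physical Poisson thinning at the source activity, so
within-stratum accidental rates are preserved, and every efficiency is
book-kept on the 4-pi-equivalent scale. The default pipeline sizes the
strata independently (1.45e9 equivalent decays for the line component with
its annihilation partners, 3.5e8 for the pair component, and a 4.5e8
annihilation-free component for the single-line efficiency) so that the
sum-energy-selected sample exceeds 500 triples, the 511 keV sum photopeak
holds on the order of a hundred events, and the efficiency carries a
few-percent statistical error; the one coincidence class this allocation
cannot form is an accidental between decays of different components.
Fully isotropic emission (`emission = "isotropic"`) remains available and
is used by the test-suite to validate the importance-sampled path.

A consequence of modelling the full cascade is worth flagging: a
substantial minority of triple coincidences are built by *two* photons of
one decay (for example the 1275 photon supplying two layers and a
same-decay annihilation photon the third). These are true coincidences of
the 22Na cascade, they pass the hardware trigger exactly as single-photon
triples do, and some fall inside the 800-1400 keV selection where their
cones carry wrong kinematics. The truth flags (`pileup` for any
multi-photon event, `accidental` for multi-decay events, `ordered` for the
clean single-photon layer-ordered class) make every such population
quantifiable.

## Calibration chain

`histogram_energies()`, `fit_photopeak()` (Gaussian plus constant
background, Levenberg-Marquardt, window of about +/-3 expected sigma),
`build_calibration()` (ordinary least squares keV-vs-ADC line) and
`equalize_channels()` (multiplicative software gains equalizing an 8x8
channel map estimated from >10^4 events) reproduce the characterization
chain. Where the package needs an ADC scale to exercise this chain
end-to-end, a nominal linear 5 keV-per-count scale is synthesized; the
hardware DAC/bias mechanics are out of scope.

Gain variation with temperature is modelled linearly:
gain(T) = 1 - 0.05 (T - 25.5 degC), valid on 10-40 degC. The single
published figure (about 5%/degC) does not distinguish a local slope of an
exponential trend from a global linear fit; linear is assumed and the
validity window documented. `fit_temperature_slope()` normalizes the fitted
slope by the fitted gain at the reference temperature, so model and
estimate are directly comparable.

## Three-interaction energy determination and cones

For a triple with deposits e1, e2 (layers 1, 2) and the geometric
second-scatter angle theta2 measured from the three positions, the photon
energy after the first scatter is

    E1 = e2/2 + sqrt(e2^2/4 + e2 * 511 / (1 - cos theta2))

and the incident energy estimate is E0 = e1 + E1. The third deposit enters
only through the 800-1400 keV sum-energy selection, which makes the
estimator robust to incomplete absorption in layer 3. The cone apex is the
layer-1 interaction, the axis points from the layer-2 towards the layer-1
interaction, and the half-angle follows from the first-scatter Compton
relation. Interaction order is *assumed* to be layer order; the simulator's
truth labels events violating this (about 7% of triples in the default
configuration), so the contamination is quantifiable, but the processor
accepts them as the hardware would. Events that become kinematically
inconsistent after blurring (|cos theta1| > 1, or cos theta2 within 1e-9
of 1) are dropped with reason codes, not clamped.

Per-event angular uncertainties combine, first order and in quadrature:
energy blur on e1 and e2 through the estimator, position blur through
theta2 (transverse sigma from the 1 mm FWHM model; depth sigma
thickness/sqrt(12), since the mid-plane convention carries no depth
information), and the axis direction uncertainty of the two apex-defining
points. Correlations between the terms are neglected. This delta-method
sigma underestimates the non-Gaussian tails of the real error distribution
(see the resolution discussion below).

## List-mode ML-EM

The system model for cone i and voxel j is

    w_ij = exp(-(alpha_j - theta_i)^2 / (2 sigma_i^2)) / d_j^2

with alpha_j the apex angle between axis and voxel centre, d_j the
apex-voxel distance, and sigma_i the per-event sigma floored at 0.01 rad
(`sigma_floor`, preventing degenerate rows). Angular — not Euclidean —
distance to the cone is used, voxel centres are point-sampled, and weights
below 1e-6 of the row maximum are truncated to keep the matrix sparse. The
update is the standard list-mode ML-EM with uniform initialization, a fixed
30 iterations and no stopping rule; sensitivity is uniform by default
(small near-axis field of view; a data-driven column-sum mode is available
for comparison). The list-mode log-likelihood is recorded each iteration
and is non-decreasing, which the test-suite checks numerically. The
acceptance grid is 80 x 80 x 1 voxels of 1 mm at the source plane; full-3D
grids are supported.

## What the twin reproduces, and what it honestly does not

Three findings from running the chain at scale deserve a permanent record.
All three are recomputed by `scripts/acceptance.R` and the test-suite; none
is an input to the model.

**Efficiency and count rate.** The measured triple-coincidence efficiency
of the twin for the 1275 keV line is ~4e-7 per photon emitted into 4 pi and
~9e-6 per photon geometrically incident on layer 1. The prototype's
published efficiency ("about 7e-6") does not state its denominator; only
the per-incident reading is compatible with the twin's interaction chain.
Two independent observations support it: (i) activity times the twin's
per-4-pi efficiency, 7e5 x 4e-7 ≈ 0.3 events/s, reproduces the prototype's
published count rate with no dead-time correction at all, and (ii) the
per-incident value sits within a factor 1.3 of the published efficiency.
`compute_efficiency()` therefore reports the per-incident number as its
headline and the per-emitted, per-decay and sum-windowed variants
alongside.

**The 511 keV sum photopeak.** Single-scatter kinematics forbids an
ordered 1-2-3 triple from a 511 keV photon over a 50 keV threshold:
reaching layer 2 needs a first-scatter angle below ~17 degrees, while a
50 keV deposit needs at least ~27 degrees. The peak nevertheless exists in
the simulation, fed by multi-scatter-in-layer-1 topologies, at a per-decay
rate comparable to the 1275 triple rate. The same kinematic squeeze is a
plausible reason the prototype could not form an image from 511 keV
photopeak data: the surviving events are dominated by multi-interaction
topologies that break the single-scatter cone model.

**Image resolution.** Under the stated parametric response, the selected
triples carry angular residuals of ~0.05 rad (robust scale), and 30 ML-EM
iterations on the 1 mm source-plane grid converge to a point image of
about 1.3 mm FWHM centred on the source — substantially sharper than the
7.8 mm FWHM measured on the prototype. Inflating the cone-width sigma does
not bridge the gap (EM converges past the kernel width). The twin's
conclusion is that the measured resolution is dominated by effects outside
the stated response parameters: Doppler broadening (excluded from scope),
position-estimation artifacts beyond a 1 mm Gaussian, and calibration
systematics. The default cone-width model remains the documented
first-order per-event sigma; no parameter was adjusted towards the
published figure, and the package reports the resolution its model
actually produces.

The 1786 keV sum population, finally, is dominated in the twin by *true
coincidence summing* of the 22Na cascade (full absorption of a 1275 photon
plus a same-decay annihilation photon) rather than by two-decay accidentals
at 700 kBq; both classes are modelled and truth-flagged. For the same
reason the efficiency quantity is computed from the annihilation-free
component: a single-line experiment contains no cascade-summing triples,
and including them would inflate the 1275 efficiency by roughly half.

## Numerical choices and degenerate inputs

* Transport nudges positions by 1e-9 mm across boundaries; histories are
  capped at 10^5 steps (never approached in practice).
* `cos_scatter_angle()` clips to [-1, 1] within 1e-9 and raises a
  kinematic-inconsistency error beyond; bulk paths use `on_invalid = "na"`.
* Photopeak and profile fits are Levenberg-Marquardt with box constraints;
  a window must contain at least five non-empty bins; flat windows either
  error or return an amplitude consistent with zero.
* Coincidence windows are greedy and non-overlapping; clusters of chained
  overlaps (rare at 700 kBq) are subdivided from their first interaction.
* A fitted profile FWHM below one voxel pitch is flagged under-resolved.
* The per-stage seed scheme is a Park-Miller multiplicative step from one
  global seed (`child_seed()`), so stages are independently reproducible;
  all results are deterministic for a fixed seed and streaming block size.

## Problem sizes

The default configuration simulates 1.45e9 equivalent decays for the line
component, 3.5e8 for the pair component and 4.5e8 for the efficiency
component — the scale at which the selected sample exceeds 500 triples,
the sum spectrum's photopeaks are cleanly fittable and the efficiency
carries a few-percent error — which runs in roughly a quarter of an hour
on one core. The
test-suite exercises the same code paths at reduced sizes (10^6-10^8
equivalent decays) chosen so each statistical assertion retains at least
3-sigma headroom.

## Known limitations

* No Doppler broadening, Rayleigh scattering, pair production or electron
  transport; no polarization. The resolution consequences are discussed
  above.
* No DAQ dead time, SiPM saturation or crosstalk; the published events/s
  figure is reproduced only through the efficiency-times-activity identity.
* The depth coordinate is the layer mid-plane by construction.
* The attenuation table is semi-empirical (documented above); a few-percent
  cross-section bias propagates linearly into efficiencies but is well
  inside the factor-2 comparison used for that quantity.
* Cross-component accidentals are not formed when the two emission strata
  are sized independently (the default); use isotropic emission for studies
  of the full accidental budget.
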