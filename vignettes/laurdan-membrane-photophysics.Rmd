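---
title: "Models and methods: Laurdan photophysics and membrane-phase fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: Laurdan photophysics and membrane-phase fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`laurdanscope` computes the observables through which the Laurdan probe
reports the phase of a DPPC bilayer: orientation and depth of the probe,
hydration and solvent relaxation around its head group, structural phase
fingerprints of the membrane, and the fluorescence quantities an
experimentalist measures (spectra, GP, lifetimes, anisotropy). This
vignette is the package's own account of the models behind each stage, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the numerical decisions taken where the design was open.

```{r setup}
library(laurdanscope)
```

## Conventions and containers

All internal lengths are nanometres; areas per lipid are reported in Å²
(the field's unit). The z-axis is the membrane normal. The membrane centre
of a frame is the midpoint between the per-leaflet mean phosphorus z; a
lipid's leaflet must agree with the sign of its phosphorus z relative to
that midplane, and distances use the minimum-image convention in all three
dimensions. Trajectories are tidy tables (box, phosphorus positions, C–H
bond vectors, probe anchors, water O/H positions) bundled in a
`membrane_trajectory`; on disk they are a GRO-style fixed-column dialect
with positions written to 7 decimals so write→read round-trips below
10⁻⁶ nm, orientations serialised as anchor atoms, and a YAML sidecar for
temperature, conformer, frame spacing and excitation time. Emission records
carry wavelength and energy reconciled through E[eV] = 1239.84193/λ[nm].

## Probe geometry

Tilt angles are plain `acos` values in [0°, 180°], deliberately **not**
folded across 90°: for an embedded probe, a dipole at 100° (head tilted
past the membrane plane) is physically different from one at 80°. A folding
switch exists for comparison with symmetric conventions. The angular
distribution is a histogram with 5° bins *centred* on multiples of the bin
width, so canonical angles (0°, 90°) are bin centres; the mode is the
centre of the maximal bin (ties resolve toward the smaller angle) and the
HWHM comes from linear interpolation of bin counts across the half-maximum.
A histogram rather than a kernel fit keeps the "maximum of the
distribution" reading reproducible. Because converged simulations are
expected to show a stable dipole tilt, `angle_distribution()` also reports
the drift of the mode across thirds of the trajectory as a convergence
diagnostic.

The "long molecular axis" is whatever pair of anchor atoms the trajectory
supplies (the generator uses an axis equivalent to the naphthalene long
axis); the choice is a file-format convention, not an algorithmic one.

## Hydration and solvent relaxation

`water_rdf()` bins minimum-image head-to-oxygen distances; g(r) is
normalised by the ideal-gas shell count 4πr²Δr·ρ. The density ρ defaults to
the whole-box mean, which is correct for homogeneous fixtures; for a
bilayer system the solvent-slab density should be passed explicitly.
Coordination numbers N(r) are exact cumulative counts (they match
brute-force pair enumeration in the tests). Shell boundaries default to
0.35/0.5 nm when g(r) minima are not evident.

Hydrogen bonds use the common geometric criterion — donor–acceptor
distance ≤ 0.35 nm and H–donor–acceptor angle ≤ 30°, waters restricted to
0.5 nm around the head — because no tighter definition is forced by the
data being emulated.

The *cumulative solvent orientation* is, per frame,
`s · Σ cos θ` over waters within 1 nm of the head centre of mass, with θ
the angle between v₁ = head→O and v₂ = O→(H₁+H₂)/2. The sign is fixed to
s = −1 so that an oxygen pointing toward the probe contributes negatively:
a verbal description of this statistic admits either sign, but the
equilibrated shell around the enlarged excited-state dipole must come out
negative, and reported magnitudes well beyond 1 also force the *sum* (not
the mean) over waters. Both the sign and the radius are arguments. Window
values average the per-frame statistic over each window (0–1, 3–4, 6–7,
9–10, 12–13, 20–21 ns after excitation by default); whether one averages
or picks single frames is not fixed by the quantity itself, and averaging
is the lower-variance choice. `fit_solvent_relaxation()` fits
C(t) = A·exp(−t/τ) + C∞ by Levenberg–Marquardt over a deterministic ladder
of τ starts; constant series and non-convergence return a flagged row, not
an error.

## Membrane-phase fingerprints

* **APL**: lateral box area × 100 / lipids-per-leaflet, per frame. The
  probe is not counted as a lipid by default (a switch includes it): at 1
  probe per 128 lipids the choice moves the value by under 1%, but it must
  be explicit.
* **S_CD**: `⟨(3cos²θ − 1)/2⟩` over all C–H vectors of a carbon, averaged
  over lipids and frames; −0.5 is a chain perpendicular to the normal, 0
  isotropic. The package consumes explicit C–H vectors; reconstructing
  hydrogens for united-atom models is out of scope.
* **Thickness maps**: per lateral cell, mean upper-leaflet phosphorus z
  minus mean lower-leaflet phosphorus z, on the last frame by default (a
  single representative snapshot is the convention for ripple
  visualisation). Cells empty in either leaflet are nearest-neighbour
  filled under periodic boundaries and flagged. `ripple_metrics()` reports
  the RMS about the mean and the dominant wavelength from the peak of the
  2-D FFT power spectrum (zero mode removed); a flat or fully interpolated
  map is flagged.
* **Phase call**: a transparent rule table on (APL, plateau |S_CD|, ripple
  RMS): APL ≥ 55 Å² with low order → La; APL ≤ 51.5 Å² with high order →
  Lc; otherwise Lb', upgraded to Pb' when the ripple RMS crosses its
  threshold (0.2 nm). The thresholds sit between the APL anchor points of
  the phases (~51 Å² for Lc, ~52 Å² for the gel/ripple phases, 57 Å² for
  La) and are echoed in every call; the label is advisory, mirroring how
  phases are identified by inspection of the same features.

## Photophysics

**Spectra.** Each snapshot emission line is broadened with a Gaussian of
FWHM 15 nm and summed, weighted by oscillator strength (uniform weighting
is a switch, since either convention is defensible for summing snapshot
spectra). 15 nm is chosen so two conformer components ~15 nm apart merge
into a peak-plus-shoulder, which is how the summed spectra present.
Shoulders are detected as secondary local maxima plus local minima of the
smoothed second derivative — the classic signature of a partially merged
component — excluding the minimum belonging to the main peak; ties in peak
height resolve to the shorter wavelength.

**GP.** (I_blue − I_red)/(I_blue + I_red) with band integrals over
configurable windows centred at the experimental 440 and 490 nm channels.

**Radiative lifetimes.** k_r[s⁻¹] = f·ν̃²/1.499 (ν̃ in cm⁻¹), the standard
oscillator-strength/radiative-rate relation. How reference decay-time
histograms are computed from excited-state outputs is generally not
documented; this estimator is this package's documented choice and is
flagged as such in the function help.

**Anisotropy.** r(t) = (2/5)·⟨P₂(μ̂(t₀)·μ̂(t₀+t))⟩ over all time origins
(origin stride configurable), with absorption and emission dipoles
collinear, so r(0) = 0.4 exactly. The plateau is the mean of the final 20%
of lags; a single-exponential-plus-offset least-squares fit supplies a time
constant and is flagged when the decay is unresolvable at the frame
spacing. For restricted rotation the plateau obeys the wobbling-in-cone
closed form r∞/r₀ = [cos θc (1 + cos θc)/2]².

**TCSPC.** `simulate_tcspc_decay()` draws photon arrivals from an
exponential mixture whose per-component probabilities equal the
integrated-intensity fractions, adds Gaussian IRF jitter, and histograms
them. `fit_exponential_decay()` maximises the Poisson likelihood of the
binned counts under a scaled mixture of exponential densities analytically
reconvolved with the Gaussian IRF (stable via the scaled complementary
error function), over deterministic multi-starts; a least-squares mode
exists for parity checks. Poisson MLE is the correct noise model for
photon counting and is what makes fraction uncertainties honest at low
counts. Intensity fractions follow the integrated-intensity convention
f_i = α_iτ_i/Σα_jτ_j and always sum to 100; amplitudes α_i are derived
from the fractions. Uncertainties come from the observed information
matrix via the delta method.

**Two-population anisotropy.** Co-emitting populations mix as
r(t) = Σ w_i(t) r_i(t)/Σ w_i(t) with w_i(t) = (f_i/τ_i)·exp(−t/τ_i). When
a long-lived population holds a high constant anisotropy while a
short-lived one decays, the intensity weights swing back to the slow
population at late times and r(t) rises again — the mechanism behind the
ripple-phase turn-up. Steady-state anisotropy is the intensity-weighted
trapezoidal time average and reproduces the Perrin form
r₀/(1 + τ/θ) in the mono-exponential limit.

## The synthetic-data generator

`generate_trajectory()` builds a system with the statistical structure the
analysis assumes and *known ground truth*, with defaults describing the
reference system: 64 lipids per leaflet, 3314 waters, gel-phase packing at
the 52.3 Å² X-ray value, a 2 nm leaflet half-thickness (4 nm bilayer,
within the 3.0–5.4 nm range the thickness maps span), a 25° dipole cone
with 1 rad²/ns wobbling, a 1.5 ns water relaxation time (the upper end of
reported probe-shell relaxation times), and 380 ± 10 nm emission.
Specifically:

* the lateral box area is *exactly* `n_lipids_per_leaflet × apl_target`
  (lipids on a jittered lattice);
* leaflet phosphorus planes sit at ±(half_thickness + A·sin(2πx/λ)), i.e.
  the ripple modulates the local thickness by 4A peak-to-trough. Under
  periodic boundaries a sinusoid must close on the box, so λ snaps to the
  nearest commensurate value, which is recorded as
  `ripple_wavelength_effective` in the attached ground truth;
* C–H vectors are drawn from a mixture (isotropic with probability
  1 + 2·S_target, exactly perpendicular otherwise) whose expected S_CD
  equals the per-carbon target profile — plateau carbons 2–10 at the
  target, tapering toward the terminal methyl;
* the transition dipole performs tangential-step Brownian motion on the
  sphere (sub-stepped to stay in the diffusion limit) with reflective
  confinement at the cone boundary, whose stationary distribution is
  uniform on the cap — so the anisotropy plateau has a closed form to test
  against, and a 0° cone freezes the dipole (r ≡ 0.4);
* waters fill the solvent slab just past the phosphate planes; after the
  excitation time each water's orientation cosine is drawn with mean
  relaxing as m∞(1 − e^(−Δt/τ)) plus uniform scatter of half-width
  `orientation_noise` (default 0.5, a partially ordered shell — the
  scatter width controls how much data the relaxation fit needs);
* per-component RNG streams (lipids/chains/probe/waters/emission) are
  split from the master seed, so enabling one component never shifts
  another's draws.

What it does **not** emulate: any force field or water–lipid interaction,
chain torsional dynamics (C–H vectors are drawn as orientation
distributions, which is all the downstream statistics consume),
conformer-specific hydration numbers, vibronic structure, or
excited-state electronic response. Passing tests therefore demonstrate
that the *analysis* is correct on data with the assumed statistical
structure — not that real trajectories have that structure.

## Numerical choices and degenerate inputs

* Exponential fits (relaxation, anisotropy) run Levenberg–Marquardt over a
  deterministic ladder of time-constant starts; the Poisson MLE uses BFGS
  from moment-based multi-starts. Non-convergence and degenerate inputs
  (constant series, flat spectra, all-interpolated maps, unresolvable
  decay constants) return flagged results rather than errors; genuine
  contract violations (empty records, non-unit vectors beyond 10⁻³,
  mismatched fractions) raise errors.
* The exp⊗Gaussian reconvolution is evaluated with `erfcx` to avoid
  overflow, switching to the pure exponential tail where erfc saturates.
* Histogram conventions: angle bins centred on multiples of the width;
  TCSPC bins of 0.05 ns; the decay-time histogram widens a zero-width
  range by ±0.5 ns.
* Problem sizes in the test suite are chosen so the whole chain exercises
  at desk scale: order-parameter recovery uses 32 lipids/leaflet × 100
  frames, relaxation recovery 1500 waters × 200 frames at 0.1 ns, dipole
  limits 3×10⁴–5×10⁴ steps (averaged over independent runs for the
  free-diffusion rate), and TCSPC recovery 10⁵–5×10⁵ photons.

## Known limitations

* Phase labels are heuristic; borderline systems near the transition
  temperatures will sit on whichever side of the threshold their features
  fall.
* The RDF normalisation needs a user-supplied density for inhomogeneous
  systems; no automatic slab detection is attempted.
* The radiative-lifetime estimator is one defensible choice among several;
  it should not be read as reproducing any particular published histogram.
* Binary trajectory formats (XTC/TRR/DCD) are not read; the GRO-style
  dialect and TSV tables are the interchange formats.
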