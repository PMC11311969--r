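# laurdanscope

Membrane-phase fingerprints and fluorescence observables for the
solvatochromic probe **Laurdan** embedded in a DPPC lipid bilayer.

Laurdan reports the physical state of a membrane: its emission shifts red as
water penetrates and relaxes around the excited head group, its anisotropy
decay reflects how tightly the surrounding lipid phase confines the rotating
transition dipole, and its fluorescence lifetime differs between the two
carbonyl conformers (Conf-I, carbonyl oxygen toward the naphthalene
beta-position; Conf-II, toward the alpha-position). Across 270–320 K a DPPC
bilayer traverses the liquid-crystal (Lc), gel (Lb'), ripple (Pb') and
liquid-disordered (La) phases, and each phase leaves signatures in all of
these observables. `laurdanscope` implements the full analysis chain that
turns bilayer/probe/water trajectories and per-snapshot emission records
into those observables, plus a synthetic-data generator so the whole
pipeline runs — and is tested against known ground truth — without any
molecular-dynamics or electronic-structure engine.

It is aimed at membrane biophysicists and simulators who want a tested,
scriptable reference implementation of these standard analyses.

## What it computes

* **Probe geometry** — tilt angles of the transition dipole and long
  molecular axis against the membrane normal (`angle_distribution`, with
  mode, HWHM and a mode-drift convergence diagnostic), and depth profiles
  of the head group, carbonyl O and amino N relative to the membrane centre
  (`depth_profile`).
* **Hydration** — water RDF around the head group with exact coordination
  counts (`water_rdf`, `shell_occupancy`), geometric hydrogen-bond counts
  (`count_hbonds`), and the signed *cumulative solvent orientation*
  `s · Σ_waters cos θ` (s = −1; θ between head→O and O→H-midpoint) in time
  windows after excitation, with an exponential relaxation fit
  (`solvent_orientation`, `cumulative_solvent_orientation`,
  `fit_solvent_relaxation`).
* **Membrane phase** — area per lipid in Å²; deuterium order parameters
  `S_CD = ⟨(3 cos²θ − 1)/2⟩` per chain carbon; 2-D thickness maps with
  ripple RMS and dominant wavelength; a rule-based phase call
  (`area_per_lipid`, `deuterium_order_parameters`, `thickness_map`,
  `ripple_metrics`, `classify_phase`).
* **Photophysics** — Gaussian-broadened emission spectra with per-conformer
  components and peak/shoulder detection; generalized polarization
  `GP = (I₄₄₀ − I₄₉₀)/(I₄₄₀ + I₄₉₀)`; radiative lifetimes from
  `k_r = f ν̃²/1.499`; anisotropy decay
  `r(t) = (2/5)⟨P₂(μ̂(0)·μ̂(t))⟩` (r(0) = 0.4) with wobbling-in-cone
  plateaus; TCSPC decay simulation and **Poisson maximum-likelihood
  multi-exponential fitting with Gaussian-IRF reconvolution**, reporting
  integrated-intensity fractions `f_i = α_iτ_i/Σα_jτ_j`; two-population
  anisotropy mixtures (the ripple-phase "turn-up"); steady-state anisotropy
  `∫r I dt / ∫I dt` (Perrin limit).
* **Synthetic data** — `synth_params()` + `generate_trajectory()` /
  `generate_emission_table()` build bilayer + probe + water trajectories
  with exact ground truth (APL, S_CD targets, ripple field, cone-confined
  dipole diffusion, exponentially relaxing water orientation, Gaussian
  emission lines).

All functions are data-frame-first and return tibbles; fitted objects have
`tidy()`/`glance()` methods and result types have `autoplot()` methods.

## Worked example

```r
library(laurdanscope)

params <- synth_params(n_lipids_per_leaflet = 32, n_waters = 800,
                       n_frames = 60, scd_plateau_target = -0.25, seed = 7)
traj <- generate_trajectory(params)

apl <- area_per_lipid(traj)
sn1 <- deuterium_order_parameters(traj, "sn1")
rip <- ripple_metrics(thickness_map(traj, cell_size = 0.4))
classify_phase(attr(apl, "mean_apl"), scd_plateau(sn1), rip$rms)$label
#> [1] "Pbeta"
attr(apl, "mean_apl"); scd_plateau(sn1); round(rip$rms, 3)
#> [1] 52.3
#> [1] 0.2489833
#> [1] 0.215
```

The generator was asked for gel-like packing (52.3 Å², the X-ray reference
value at 298 K) with a visible ripple, and the analysis chain recovers the
area per lipid exactly, the plateau order parameter within sampling error,
and enough thickness modulation to label the frame as the ripple phase.

Fitting a simulated photon-counting decay built from a two-component
lifetime mixture (7.46 ns at 43% + 3.58 ns at 57%, the ripple-phase 440 nm
channel) recovers the generating parameters:

```r
cv <- simulate_tcspc_decay(list(c(7.46, 43), c(3.58, 57)), n_photons = 5e5,
                           irf = list(mean = 1, sigma = 0.25), t_max = 50, seed = 7)
fit_exponential_decay(cv, n_components = 2)
#> <exp_fit> 2-component poisson fit, reduced chi-square 0.989
#>   tau1 = 7.478 +/- 0.080 ns  (43.0 +/- 1.4 %)
#>   tau2 = 3.583 +/- 0.041 ns  (57.0 +/- 1.4 %)
```

Anisotropy from the wobbling dipole pins r(0) at 0.4 and plateaus where the
cone model says it should:

```r
anisotropy_decay(traj, max_lag = 6)
#> <anisotropy_result> r0 = 0.4000, plateau = 0.2963, time constant = n/a ns
```

(the within-cone decay here is faster than the frame spacing, so the fit
flags the time constant rather than inventing one).

A thin command-line wrapper over the same functions lives at
`inst/cli/laurdanscope`:

```sh
Rscript inst/cli/laurdanscope all --seed 1 --out out_dir
```

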