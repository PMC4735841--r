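# comptwin

A digital twin of a three-layer LaBr3 Compton telescope for emission
imaging, of the kind developed for treatment monitoring in hadron therapy.
The package simulates a laboratory 22Na point-source measurement end to
end — decay, Klein-Nishina photon transport through the three scintillator
layers, parametric detector response, triple-coincidence trigger with
accidental and pile-up modelling — and analyses it the way the real
measurement is analysed: gamma-spectroscopy calibration, three-interaction
Compton-cone building, and list-mode ML-EM image reconstruction.

It is aimed at instrument developers and medical-physics students who want
a transparent, fully scriptable model of a three-layer Compton camera to
study design trade-offs (layer spacings, thresholds, resolutions) before
touching hardware or a full Geant4-class simulation.

## The physics in brief

A photon of energy E0 Compton-scatters in layer 1 (deposit e1), scatters
again in layer 2 (deposit e2) and interacts in layer 3. Because the second
scattering angle theta2 is *measured geometrically* from the three
interaction positions, the energy of the photon after the first scatter is
fixed by Compton kinematics,

    E1 = e2/2 + sqrt(e2^2/4 + e2 * m_e c^2 / (1 - cos theta2)),

so the incident energy E0 = e1 + E1 is determined **without full
absorption** — the key advantage of a three-layer telescope for the broad,
MeV-range prompt-gamma spectra of hadron therapy. Each event then defines
a cone of possible incidence directions with apex at the first interaction,
axis along (r1 - r2) and half-angle theta1 with

    cos theta1 = 1 - m_e c^2 (1/(E0 - e1) - 1/E0),

and a list-mode ML-EM iteration,

    lambda_j <- (lambda_j / s_j) * sum_i w_ij / (sum_k w_ik lambda_k),

with Gaussian-in-angle, inverse-square cone weights w_ij, reconstructs the
source intensity on a voxel grid from a few hundred cones.

The default configuration is a real prototype's: three LaBr3 crystals
(27.2 x 26.8 x 5, 32 x 36 x 5, 32 x 36 x 10 mm) with 6.4 / 7.4 / 7.2%
FWHM energy resolution at 511 keV, 1 mm FWHM position resolution, 50 keV
thresholds, source-to-layer distances 35 / 60 / 65 mm, a 25 ns coincidence
window and a 700 kBq 22Na source. See `vignette("telescope-twin")` for the
full model description and the design decisions behind it.

## Worked example

A reduced-statistics run of the whole chain (a few minutes; the default
configuration simulates ~2.5x more decays and takes about a quarter of an
hour):

```r
library(comptwin)

cfg <- default_config()
cfg$simulation$n_decays_equivalent <- 6e8       # 1275 keV line component
cfg$simulation$n_decays_equivalent_pair <- 2e8  # 511 keV pair component
cfg$simulation$n_decays_equivalent_efficiency <- 2e8
cfg$simulation$seed <- 7
res <- run_pipeline(cfg)
#> [comptwin] simulate: line component, 6e+08 equivalent decays
#> [comptwin] simulate: line component, 370 triples
#> [comptwin] simulate: pair component, 2e+08 equivalent decays
#> [comptwin] simulate: pair component, 50 triples
#> [comptwin] simulate: 420 triple coincidences
#> sum-energy cut [800, 1400] keV kept 225 / 420 events
#> [comptwin] process: 225 cones from 225 selected triples
#> [comptwin] simulate: efficiency component, 2e+08 equivalent decays
#> [comptwin] analyze: x-profile FWHM 1.26 mm

res$photopeaks
#> # A tibble: 2 x 6
#>   expected_kev present centroid sigma fwhm_percent n_counts
#>          <dbl> <lgl>      <dbl> <dbl>        <dbl>    <int>
#> 1          511 TRUE        514.  13.0         5.95       95
#> 2         1275 TRUE       1273.  19.7         3.64      115

res$efficiency[, c("n_incident_1275", "n_triples",
                   "efficiency_per_incident_1275",
                   "efficiency_per_emitted_1275")]
#>   n_incident_1275 n_triples efficiency_per_incident_1275
#> 1         8257246        62                 7.508557e-06
#>   efficiency_per_emitted_1275
#> 1                3.103103e-07

res$profile_x
#> <profile_fit> x profile: centroid -0.09 mm, FWHM 1.26 mm

glance(res$image)
#> # A tibble: 1 x 6
#>   iteration_count n_events loglik max_x_mm max_y_mm max_z_mm
#>             <dbl>    <int>  <dbl>    <dbl>    <dbl>    <dbl>
#> 1              30      225 -1168.     -0.5      0.5      -35
```

What the numbers mean:

* the **sum spectrum** of the triple coincidences shows the two 22Na
  photopeaks; their fitted centroids sit at 511 and 1275 keV because the
  three-layer sum recovers the full photon energy for absorbed events;
* the **efficiency** of the triple coincidence for the 1275 keV line is
  ~1e-5 per photon incident on the first layer, equivalently ~4e-7 per
  photon emitted into 4 pi — multiplied by the 700 kBq activity the latter
  reproduces the ~0.3 triples/s such an instrument records;
* the **image** of the point source reconstructs at the source position
  (maximum voxel within half a millimetre of the axis); its profile FWHM
  under this parametric response model is ~1.3 mm — the vignette discusses
  at length why the physical prototype measures a broader 7.8 mm and why
  the twin deliberately does not tune itself to that number.

Plotting is one call per result type: `autoplot(res$spectrum)`,
`autoplot(res$image)`, `autoplot(res$profile_x)`.

A thin command-line driver with `simulate / process / reconstruct /
analyze / calibrate / run / fixture` subcommands is installed at
`inst/scripts/comptwin`.

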