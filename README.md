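# aggrekin

Analysis toolkit for single-aggregate studies of full-length p53
aggregation at physiological (sub-micromolar) concentrations. It is aimed
at researchers running thioflavin-T (ThT) kinetics and diffraction-limited
fluorescence imaging of protein aggregates who need to (i) fit aggregation
kinetics mechanistically, (ii) quantify individual aggregates in images in
a background-robust way, and (iii) score downstream assays: Proteinase-K
(PK) resistance, supported-lipid-bilayer (SLB) disruption, and immunoblot
monomer quantitation.

## The model

At low concentrations the aggregation of wild-type p53 and its
aggregation-prone R248Q mutant is governed by classical nucleation and
growth rather than by formation of aggregation-prone monomer. For the
number concentration of aggregates P(t) and the free precursor
concentration m(t):

    dP/dt = k_n m(t)^nc
    dm/dt = -2 (k_+ m(t) - k_off) P(t)

with elongation rate constant k+, dissociation rate k_off, nucleation rate
constant k_n and nucleation reaction order nc. ThT fluorescence reports
total aggregate mass M(t) = m0 - m(t). Two identifiable parameters govern
unseeded mass curves:

* the combined nucleation-elongation rate `lambda = k_n k_+ m0^nc` (s^-2),
* the solubility `k_off / k_+` (M), the steady-state free monomer level.

`aggrekin` simulates this system in its reduced dimensionless form, fits
`lambda` as the single free parameter with the solubility fixed from
measurement, converts ThT traces to mass trajectories, handles seeded
reactions, and provides the early-time log-log slope (2 for nucleated
growth, 1 for seeded or precursor-limited kinetics) as a model diagnostic.

The imaging side reproduces a single-aggregate detection pipeline: frame
averaging, difference-of-Gaussians bandpass, robust thresholding,
8-connected segmentation with sub-pixel centroids, and per-particle
intensities as summed signal-to-background ratios (SBR = (I - bg)/bg),
which are exactly invariant to illumination and gain rescaling.

Seeded synthetic-data generators (model-based traces, PSF-blurred particle
stacks over modulated backgrounds with shot and read noise, matched
before/after PK pairs, bilayer hole images, blot standards) provide ground
truth for every stage.

## Worked example

```r
library(aggrekin)

wt  <- rate_parameters(lambda = 7e-9, solubility = 7e-7, nc = 2)  # wild type
mut <- rate_parameters(lambda = 2e-8, solubility = 1e-7, nc = 2)  # R248Q

tg <- seq(0, 72 * 3600, length.out = 100)
traj <- simulate_aggregation(wt, initial_state(m0 = 1e-6), tg)
tail(traj$monomer, 1) * 1e9
#> [1] 700

# synthesise a noisy trace, calibrate it to mass, re-fit the rate
g <- gen_tht_trace(wt, initial_state(1e-6), mult_sigma = 0.05, seed = 1)
mass <- tht_to_mass(g$trace, m0 = 1e-6, m_eq = 7e-7)
fit_combined_rate(mass, fixed = list(solubility = 7e-7, m0 = 1e-6))
#> One-parameter nucleation-growth fit
#>   lambda_hat: 7.17e-09 s^-2 (converged: TRUE)
#>   residual norm: 1.3e-07 over 100 points
#>   fixed: solubility = 7e-07 M, nc = 2, m0 = 1e-06 M, P0 = 0
```

The simulated wild-type reaction relaxes to 700 nM free monomer — the
measured wild-type solubility — and the one-parameter fit recovers the
generating combined rate (7e-9 s^-2) to within a few percent under 5%
multiplicative noise, and to better than 1% on noiseless traces.

Image analysis on synthetic ground truth:

```r
sp <- scene_spec(particles = data.frame(row = c(50, 120, 200),
                                        col = c(60, 90, 200),
                                        radius = 3, sbr = 5),
                 shape = c(256L, 256L), frames = 10L, seed = 7)
g <- gen_image_stack(sp)
detect_particles(g$stack)[, c("centroid_row", "centroid_col", "area_um2", "sbr_intensity")]
#>   centroid_row centroid_col area_um2 sbr_intensity
#> 1     50.00605     59.99067 14.20471      162.2929
#> 2    119.95105     90.01579 14.51576      163.0813
#> 3    200.01338    200.01613 14.20471      163.1912
```

All three planted particles are found with centroids within a few
hundredths of a pixel, and summed-SBR intensities close to the rendered
ground truth (~168).

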