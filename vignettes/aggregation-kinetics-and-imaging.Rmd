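---
title: "Methods: nucleation-growth kinetics and single-aggregate image analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nucleation-growth kinetics and single-aggregate image analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggrekin)
```

## The kinetic model and its assumptions

`aggrekin` models aggregation of an aggregation-prone precursor (free
monomer, concentration $m(t)$) into aggregates (number concentration
$P(t)$) by primary nucleation, elongation and dissociation:

$$\frac{dP}{dt} = k_n m^{n_c}, \qquad
  \frac{dm}{dt} = -2\,(k_+ m - k_{off})\,P .$$

The factor 2 reflects growth at both aggregate ends. The model assumes:

* **no secondary processes** — existing aggregates neither catalyse new
  nucleation nor fragment. Consequently $dP/dt$ depends on $m$ only;
  the package tests this structurally (injecting extra aggregate *mass*
  without changing $P$ leaves the number trajectory untouched);
* **aggregation, not conformational conversion, is rate limiting** —
  unseeded mass curves then show upward curvature, with
  $M(t)\propto t^2$ at early times;
* **ThT linearity** — bulk ThT fluorescence is proportional to aggregate
  mass $M(t) = m_0 - m(t)$ across aggregate morphologies. This is an
  assumption of the assay, not something the package can verify.

The monomer equation has the fixed point $m^\ast = k_{off}/k_+$: the
solubility. Any reaction that aggregates at all relaxes to it, which
anchors the calibration of ThT intensity to absolute mass.

### Reduced parameterisation

Only two parameter combinations are identifiable from an unseeded mass
curve: the solubility and the combined nucleation-elongation rate
$\lambda = k_n k_+ m_0^{n_c}$ (units s$^{-2}$, normalised at the initial
monomer). Substituting $Q = k_+ P$ and $x = m/m_0$ gives

$$\frac{dQ}{dt} = \lambda\, x^{n_c}, \qquad
  \frac{dx}{dt} = -2\,(x - s)\,Q, \qquad s = \frac{k_{off}/k_+}{m_0},$$

which `simulate_aggregation()` integrates directly, so no arbitrary
split of $\lambda$ into $k_n$ and $k_+$ is ever needed. An explicit
decomposition may still be attached to `rate_parameters()` and is checked
for consistency. Seeds enter as $Q_0 = k_+ P_0$ (s$^{-1}$); when a seed
mass and a mean seed size are known instead, $Q_0$ can be derived by the
user from that assumption and passed directly.

### Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| `lambda` | s$^{-2}$ | — (fit) | combined nucleation-elongation rate; wild-type-like 7e-9, mutant-like 2e-8 |
| `solubility` | M | — (measured) | steady-state monomer; 7e-7 (wild type), 1e-7 (mutant) |
| `nc` | — | 2 | reaction order of primary nucleation. Not identifiable from a single-concentration curve; 2 is the smallest classical nucleus consistent with the s$^{-2}$ units of $\lambda$ under the $m_0$ normalisation. Exposed everywhere; the terminal-monomer and recovery behaviour is insensitive to `nc` in 1–3 (tested). |
| `rtol`, `atol` | — | 1e-8, 1e-12 | solver tolerances. Integration runs on the dimensionless $x = m/m_0$, so `atol` applies to the monomer *fraction*; this resolves early-time aggregate masses of order $10^{-11}$ M that a molar-scale absolute tolerance would drown, which matters for the early-time slope diagnostic. |
| `lambda_bounds_log10` | — | $[-12, -4]$ | fit search interval; ties broken toward smaller $\lambda$, tolerance 1e-10 on $\log_{10}\lambda$. |
| `plateau_fraction` | — | 0.1 | trailing fraction of a trace averaged as the plateau for ThT calibration. |

### Fitting and calibration

`tht_to_mass()` maps intensity affinely: baseline $\mapsto 0$, plateau
$\mapsto m_0 - m_{eq}$, with the plateau taken as the mean of the final
decile. A trace whose trailing decile still rises by more than 2% of the
total rise per 10% of duration is flagged (`plateau_found = FALSE`) and
the final value is used — calibrating such a trace against an external
solubility measurement is the user's responsibility.

`fit_combined_rate()` minimises the sum of squared residuals between the
simulated and observed mass over $\log_{10}\lambda$ by bounded scalar
optimisation. This is deterministic, derivative-free, and cannot leave
the search box; an all-zero trace returns the lower bound unconverged
rather than an arbitrary interior value.

```{r fit-demo}
tg <- seq(0, 72 * 3600, length.out = 100)
wt <- rate_parameters(lambda = 7e-9, solubility = 7e-7, nc = 2)
traj <- simulate_aggregation(wt, initial_state(m0 = 1e-6), tg)
fit_combined_rate(traj, fixed = list(solubility = 7e-7, m0 = 1e-6))
```

### Model diagnostics

`early_time_exponent()` fits the slope of $\log M$ vs $\log t$ over the
earliest fraction of the half-time. Unseeded nucleated growth gives 2;
strongly seeded growth and precursor-limited first-order conversion
($M = A(1-e^{-kt})$) both give 1. The window defaults to the earliest 2%
of the half-time; for seeded or first-order curves, whose half-times are
much earlier, a window of ~10% with a log-spaced grid is appropriate —
the limit slope is approached from below as the window shrinks.

## Image analysis

The detection pipeline mirrors standard diffraction-limited single-
aggregate processing:

1. **average** all frames of a field of view (noise falls as $1/\sqrt F$);
2. **bandpass** via difference of Gaussians (defaults: pass 1 px, reject
   20 px) plus a final 1 px blur. The operation is linear and removes DC
   exactly; kernels are truncated at $3\sigma$ and renormalised, and are
   capped at the image size so small test images behave identically;
3. **segment** supra-threshold 8-connected components with areas in
   `[min_area_px, max_area_px]` (defaults 4 px to a quarter of the
   image). The default threshold is `median + 3 * mad` of the *filtered*
   image, whose background is centred at zero. Centroids are
   intensity-weighted; border-touching particles are flagged and
   excluded from size statistics because their areas are truncated;
4. **quantify** on the *raw averaged* image: per-particle intensity is
   the sum over its pixels of $(I - bg)/bg$, with $bg$ a large-window
   (default 25 px) median-filtered background. Summed SBR is exactly
   invariant under global rescaling of illumination or gain, which is
   the point of using it.

Detection (step 3) and quantification (step 4) are deliberately separated:
thresholds act on the filtered image, intensities are always ratios of raw
values.

Two numerical caveats are worth knowing. The median background tracks a
smoothly modulated background to ~2% provided the window is small
relative to the modulation period but large relative to particles (the
default 25 px window suits periods of ≥128 px and particles of ≤8 px
radius). And the adaptive `median + 3·mad` threshold rises with scene
occupancy; when comparing particle *sizes across time points* a single
fixed threshold should be used, otherwise later, busier fields are
segmented slightly tighter.

## Assay quantifiers

**Proteinase-K sensitivity.** Matched before/after particles (mutual
nearest centroids within 2 px; unmatched 'before' particles count as
fully digested, $f = 0$, to avoid biasing toward resistance) are classed
by intensity loss $1 - f$: sensitive (> 70% loss), partially sensitive
(30–70%, closed interval at both boundaries), resistant (< 30%);
brightening ($f > 1$) is resistant.

**Bilayer disruption.** Holes are 8-connected components of sub-threshold
pixels (default threshold: half the image median, a robust proxy for the
bilayer mode when holes are sparse; minimum 4 px) with areas in µm² at
87.21 nm pixels. Hole and bilayer pixels partition the image exactly.
Per-condition means are normalised to a reference condition.

**Monomer quantitation.** A least-squares line through band intensity vs
known amounts (≥ 3 standards, positive slope required) is inverted for
unknowns; estimates far outside the calibrated intensity range are
flagged as extrapolated. `percent_reduction(before, after)` is
$100(1 - \text{after}/\text{before})$.

## Synthetic data: what it does and does not emulate

Generators exist so every stage can be scored against ground truth:

* **traces**: simulated mass with per-point multiplicative Gaussian noise
  and an additive floor;
* **image stacks**: particles as uniform disks convolved with an
  isotropic Gaussian PSF ($\sigma$ = 1.5 px, the right order for a
  40×/0.75 NA objective at 322 nm pixels), amplitudes pre-compensated for
  blur so the rendered peak SBR matches specification within 10%; a 2-D
  sinusoidal background (period 128 px, amplitude 10% of offset) to
  exercise the bandpass; Poisson shot noise and 1% Gaussian read noise;
* **time series**: planted counts proportional to the simulated $Q(t)$,
  lognormal sizes with optionally growing median (static for
  wild-type-like, growing for mutant-like samples);
* **PK pairs**: true classes drawn from a mixture, losses drawn uniformly
  *within* each class's loss band so the planted class is recoverable;
* **bilayer images**: bright field with dark disks plus Gaussian noise;
* **blot tables**: linear response with multiplicative noise.

Everything is deterministic given a seed.

What the generators do **not** reproduce: real amorphous and mesh-like
aggregate morphologies (disks only; shapes in real data are irregular),
EMCCD gain statistics, optical aberrations, focal drift, photobleaching,
and spatial correlation of background beyond one sinusoid. Passing the
recovery tests therefore demonstrates the *pipeline logic* — detection,
photometry, matching, classification arithmetic — not performance on real
micrographs, where thresholds must be tuned to the instrument.

## Pipeline orchestration

`validate_config()` accepts YAML/JSON (text, file, or list), rejects
unknown keys and stages, reports all schema violations at once, and fills
defaults. `run_pipeline()` executes enabled stages in dependency order,
derives per-stage seeds from the global seed (seed + stage index), writes
every artifact plus a JSON report (written even on partial failure;
downstream stages of a failure are skipped), and hashes the configuration
(excluding the output directory, so the same analysis in two locations
hashes identically). Reruns with identical config and seed produce
byte-identical artifacts.

## Problem sizes and known limitations

Tests use 100–200-point time grids, 192–512 px synthetic fields with
5–25 particles, 10–50 frames, and 20-seed repetition for stochastic
claims — sizes chosen to exercise every code path at comfortable runtime
on a laptop; all statistical tolerances (e.g. median $\hat\lambda$ error
≤ 10% at 5% noise) were chosen from the study design, not from runtime.

Known limitations:

* `nc` cannot be estimated from a single-concentration curve; it is a
  configuration choice (default 2), and so is any seed-size assumption
  behind $Q_0$;
* the fitter assumes the solubility is measured independently; errors in
  $m_{eq}$ propagate into $\hat\lambda$ through the calibration;
* absolute particle counts from real data depend on unpublished
  instrument-specific thresholds; only relative and ground-truth-recovery
  statements are supported;
* the PK matcher assumes surface-attached, well-separated particles
  (≥ ~4 px apart); dense fields would need a global assignment method.
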