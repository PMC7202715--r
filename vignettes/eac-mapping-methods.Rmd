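---
title: "Methods: effective attenuation coefficient mapping from multi-distance CW-NIRS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: effective attenuation coefficient mapping from multi-distance CW-NIRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement model

In a diffusive medium such as the head, far enough from a source (beyond
~10 mm), continuous-wave near-infrared light decays exponentially with
source-detector distance at a rate given by the effective attenuation
coefficient (EAC),

$$\mu_\mathrm{eff} = \sqrt{3\,\mu_a\,(\mu_a + \mu_s')} \approx
  \sqrt{3\,\mu_a\,\mu_s'} \quad (\mu_a \ll \mu_s'),$$

where $\mu_a$ is the absorption and $\mu_s'$ the reduced scattering
coefficient (both mm$^{-1}$). For a semi-infinite homogeneous medium with
zero boundary conditions the detected intensity is
$I(r) \propto e^{-\mu_\mathrm{eff} r}/r^2$, so $\ln(I\,r^2)$ is linear in
$r$ with slope $-\mu_\mathrm{eff}$.

A continuous-wave instrument does not measure absolute intensity on a common
scale across channels: each channel's level is multiplied by unknown source
power, detector efficiency and fiber-coupling gains. The estimator therefore
works with the signal-to-noise ratio of each channel,
$\mathrm{SNR}^2 = 1/\mathrm{var}(i(t)/\bar i)$, computed on frequencies above
the physiological band (>10 Hz), where the variance is photon shot noise and
hence $\mathrm{SNR}^2 \propto I$. The regression response is
$y = \ln(\mathrm{SNR}^2 r^2)$, fit by ordinary least squares on $r$; the
intercept $k$ absorbs the gains (they are distance-independent), and
$\hat\mu_\mathrm{eff}$ is minus the slope. Fits use only channels at
20-50 mm (inclusive): shorter distances violate the diffusive log-linear
regime, longer ones lose SNR linearity. Per-channel maps repeat the fit over
the channels of the same wavelength whose midpoints lie within a 30 mm
neighborhood radius; global estimates use a radius much larger than the head.
A minimum of 5 channels spanning at least 10 mm guards against degenerate
slopes; per-channel failures are recorded as missing values with a reason,
never raised.

## The synthetic cohort generator

No public data exist for this design, so every analysis runs on a synthetic
cohort whose generator is the estimator's own forward model plus the noise
structure the method assumes. It emulates:

* **Design.** 48 subjects, ages uniform over 18-78 with 8 subjects and
  balanced sex per decade; four montage placements per subject on a
  spherical head (radius 90 mm), optodes quasi-uniform on the superior cap
  (polar angle <= 100 degrees), ~384 channels per wavelength per placement at
  15-80 mm; 690 and 830 nm source fibers co-located in pairs; sampling at
  39.0625 Hz in 30 s blocks.
* **Signal.** Expected counts per channel from the semi-infinite forward
  model, scaled so a gain-1 reference channel at 20 mm receives 1e5 counts
  per sample, multiplied by log-normal per-optode gains (sigma = 0.5, an
  order-of-magnitude coupling spread that deliberately stresses the
  estimator). The reference budget is set so that detected light is not
  extremely low anywhere in the 20-50 mm window -- the stated premise of the
  SNR-intensity proportionality; at much lower budgets the starved long
  channels bias the slope.
* **Noise.** Poisson shot noise per sample; multiplicative physiology below
  10 Hz: a quasi-periodic cardiac wave (subject heart rate, inter-beat
  intervals jittered by the subject's HRV, diastolic trough at each beat
  boundary), a 0.25 Hz respiratory sinusoid and slow drift. No electronic
  noise floor.
* **Latent structure.** Cortical thickness declines linearly with age
  (target r = -0.65); tissue oxygen saturation declines weakly
  (r = -0.313); total hemoglobin is log-normal (70 uM, CV 0.15). Absorption
  follows the hemoglobin extinction model exactly; reduced scattering
  carries an anatomy factor routed through thickness (thinner cortex ->
  thicker clear-CSF layer -> lower scattering -> lower EAC) plus independent
  per-wavelength dispersion. The four loadings are solved analytically from
  the target EAC means/SDs (0.192/0.040 and 0.170/0.036 mm^-1) and the
  inter-wavelength correlation (0.85); infeasible targets raise an error.
  The anatomy factor is 90% thickness (`anatomy_rho = 0.9`): routing the
  whole age->EAC anatomy path through thickness is what makes thickness a
  complete mediator, at the cost of a somewhat stronger thickness-EAC
  correlation than a real cohort shows.
* **Spatial structure.** A fixed cohort-level multiplicative EAC field over
  the scalp, $1 - 0.08\cos\phi + 0.04\cos 2\phi$ in azimuth (occipital high,
  frontal and lateral low), shared by both wavelengths. A pure-azimuth field
  has zero mean at every polar angle, so it is distance-neutral for the
  slope in expectation; the realized montage still gives it a small
  (~ -0.7%) common bias on global fits, which we accept as the price of
  having reliable topographic structure. Covariates (cortical volume, WMSA,
  fitness, heart-rate variability, pulse-relaxation, neuropsychological test
  scores) are generated with age- and thickness-loadings matching the
  cross-sectional correlation structure being emulated.

What the generator does **not** emulate: layered or voxelized head anatomy
(the medium is homogeneous per subject up to the smooth field), photon
transport beyond the diffusion closed form, motion artifacts (the movement
corrector is exercised with injected spikes in tests), instrument drift and
electronic noise, and any real helmet geometry. Passing recovery tests
therefore demonstrate internal consistency of estimator and assumed physics,
not robustness to model mismatch in real heads.

## Preprocessing

The chain is fixed: normalize by the block mean; replace samples whose
robust z (against a running median, MAD scale) exceeds 5; high-pass with a
zero-phase order-4 Butterworth at 10 Hz; then compute SNR. Two numerical
details matter. The series is demeaned before zero-phase filtering: the
filter would suppress the DC anyway, but the edge handling of
forward-backward filtering injects O(mean) transients that otherwise put a
variance floor under every channel. And the robust scale is floored at the
channel's physical shot-noise scale ($1/\sqrt{\bar i}$ on normalized data):
on sparse integer counts the MAD can collapse to zero and ordinary Poisson
fluctuations would be interpolated away, crushing the variance the SNR is
made of.

Heart rate and HRV come from the optical pulse: the normalized series
averaged over acceptable channels, band-passed to 0.5-2.5 Hz, diastolic
troughs detected as local minima with a 0.33 s refractory period and
parabolic sub-sample refinement, after trimming 1.5 s of filter-settling
edges. HR is 60000 / mean inter-beat interval (ms); HRV is the SD of the
intervals.

## Topographic maps

Channel midpoints are projected by the azimuthal-equidistant map about the
vertex ($\rho = \theta/\theta_{max}$, azimuth preserved, $\theta_{max} =
100^\circ$); points beyond the cap clip to the rim with a flag. Values are
interpolated by triangulation-based piecewise-linear interpolation onto a
64x64 disk raster; pixels inside the disk but outside the convex hull are
nearest-neighbor filled and flagged extrapolated. Group statistics are the
per-pixel mean and the SE of the mean as a percentage of it; split-half
reliability draws a random half per (decade, sex) stratum and correlates the
two half-cohort mean maps over jointly valid pixels.

## Oxygenation and wavelength components

The tissue oxygenation index inverts the dual-wavelength EAC pair under a
scattering power law $\mu_s'(\lambda) = \mu_s'(830)\,(\lambda/830)^{-b}$
(defaults $b = 1$, $\mu_s'(830) = 0.72$ mm$^{-1}$, in line with published
in-vivo head values): solve the EAC definition exactly for $\mu_a$ per
wavelength (positive root), unmix into oxy/deoxy-hemoglobin through the
extinction system, and take the oxygenated fraction. Negative concentrations
clamp to zero with a non-physical flag. With the approximate inversion
$\mu_a \approx \mathrm{EAC}^2/(3\mu_s')$ the TOI depends on the EAC pair
only through their ratio; exact and approximate paths differ by under 2% in
the physiological range. The inversion is exact by construction whenever its
scattering assumptions match the generator's, which is what the round-trip
tests exercise; on the cohort the generator's per-subject scattering differs
from the power-law reference, so cohort TOI is an index, not a recovery of
SO2.

The wavelength-space decomposition is an eigendecomposition of the 2x2
covariance (not correlation: same units) of the per-subject (EAC690, EAC830)
pairs. Signs are fixed so the first component has both loadings positive
(the common anatomy axis) and the second has a positive 690 nm loading (the
spectral difference, tracking oxygenation); ties in the eigenvalues would be
broken by wavelength order. Local component maps apply the cohort-level
(global) loadings to each pixel's centered pair -- global loadings keep the
decomposition identifiable across pixels.

## Association battery and mediation

Composite cognitive scores are equal-weight means of per-test z-scores,
oriented so positive is better (timed tests negated). Correlations report
Fisher $z = \mathrm{atanh}(r)$ with standard error $(N-3)^{-1/2}$ and
two-sided p from the t distribution; $|r| = 1$ yields a flagged infinite z.
Partial correlations residualize both variables on the covariate with an
intercept and lose one degree of freedom. Mediation follows the three-step
approach on standardized variables with a 0.05 two-sided threshold at every
step: total effect, then the independent-to-mediator path (either
non-significant makes mediation not assessable), then the joint regression.
"Full" requires the direct effect to lose significance while the mediator
stays significant; "partial" additionally requires attenuation and a
significant Sobel statistic $ab/\sqrt{b^2 SE_a^2 + a^2 SE_b^2}$ (reported
with both normal- and t-referenced p). No multiple-comparison correction is
applied anywhere in the battery, by design.

## Problem sizes and numerical choices

The default conditions used by the tests, the analysis scripts and
`scripts/acceptance.R` are 48 subjects x 4 placements x ~770 channels
(both wavelengths) x 1172 samples (30 s); a full pipeline run takes a few
minutes on one core, and mediation replicate studies use latent subjects
only (no time series). Block length 30 s keeps the variance-estimation
noise of $y$ (~0.04) far below the optode-gain scatter (~0.7), which is
the accuracy-limiting term; with ~600 accepted channels per wavelength the
per-subject global EAC error floor is about 1.5-2% SD, consistent with the
few-percent accuracy the multi-distance method is known for, and implies
occasional single-subject errors slightly above 5% under the deliberately
harsh order-of-magnitude gain spread. Distance windows and bins are closed
on both ends; inside a 10 mm stratified bin the global 10 mm minimum-span
floor is geometrically unreachable, so bin fits require a spread of at
least half the bin width instead. Degenerate inputs error early and explicitly (zero-variance
channels, collinear projections, empty selections); per-channel and
per-stratum fit failures are data, not exceptions.

## Known limitations

* The helmet layout is a jittered spherical-cap lattice, not a
  reconstruction of any real montage; absolute map values are comparable in
  pattern only.
* The spatial field is a smooth two-harmonic azimuthal pattern; real heads
  have focal features (veins, sinuses) the generator does not produce.
* The homogeneous-medium assumption is shared between generator and
  estimator, so recovery accuracy here is an upper bound on real-data
  accuracy.
* Cohort TOI inherits estimation noise from both EAC fits; its correlation
  with the second wavelength component is structural (both are functions of
  the same pair), not evidence about tissue.
* The pulse detector assumes a dominant fundamental in 0.5-2.5 Hz; it is
  not an arrhythmia-grade beat detector.
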