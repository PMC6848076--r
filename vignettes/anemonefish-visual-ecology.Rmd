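---
title: "Modelling reef-fish vision: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling reef-fish vision: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anemovis)
```

anemovis models the visual system of a coral reef fish from first inputs —
spectra, transcript counts, retinal counting-frame data — through to
behavioural quantities: colour discriminability, acuity, and detection
distances. The motivating system is the anemonefish retina: a regular cone
mosaic (one single cone ringed by four double cones), a UV-transmitting
lens, double cones expressing the mid-wavelength RH2B/RH2A opsins matched to
reef spacelight, single cones expressing the UV SWS1 opsin, and a small
temporal retinal region where SWS2B is coexpressed with SWS1. This vignette
records the models, the tunable parameters, and the design choices made
where the method literature leaves them open.

## Spectra and lens transmission

All modelling runs on a common wavelength grid, 300–800 nm at 1 nm
(`spectral_grid()`), which covers the measured range of teleost ocular media
and resolves every lambda-max comparison made downstream. Integrals are
trapezoidal throughout. Spectra are validated on construction: strictly
increasing wavelengths, nonnegative values. Negative measured values are
rejected rather than clipped, so instrument artefacts surface instead of
being silently absorbed.

Lens transmission curves are normalized at 700 nm and summarized by T50, the
wavelength of half-maximal transmittance. The conventional definition says
"by linear regression" without fixing a window; `t50()` fits ordinary least
squares to the contiguous run of points with normalized value in [0.2, 0.8]
around the rising limb and solves the fitted line at 0.5. On synthetic
logistic curves this recovers the construction midpoint within one grid step
for limb slopes of 2 nm and steeper. If the limb is steeper than the grid
(a step), the first point at or above 0.5 is returned. Curves with several
rising crossings use the longest-wavelength one, with a warning. T50 below
400 nm classifies a lens as UV-transmitting.

## Visual pigments

Pigment absorbance uses the vitamin-A1 template of Govardovskii et al.
(2000): the alpha band in log-inverse form plus a Gaussian beta band at
`189 + 0.315 * lambda_max` nm. Constants live in `a1_template_constants()`
so alternates can be configured; A2 chromophores are out of scope. The
template is valid over 330–620 nm. One subtlety: for UV pigments the beta
band sits close under the alpha peak, and the discrete argmax of the
evaluated curve can sit one grid step short of the nominal lambda-max; the
curve is renormalized to peak 1 regardless.

`fit_lambda_max()` fits the template to a peak-normalized measured
absorbance by least squares on a 0.1 nm search lattice, ties broken toward
the shorter wavelength, with a warning when the optimum lands on the search
boundary (usually a sign the window misses the peak). On noiseless
templates the round trip is exact to the lattice; at a noise SD of 0.02 on
the normalized scale, recovery is within ±2 nm in at least 95% of seeded
replicates.

Opsin coexpression within one cone is modelled as a single effective
pigment: a convex mixture of the two peak-normalized absorbances,
renormalized (`mix_coexpressed()`). This matches what microspectrophotometry
reads out from a coexpressing cone — one intermediate lambda-max — rather
than two resolvable pigments. Sequence-based lambda-max estimation
(`estimate_lambda_max_from_sequence()`) adds user-supplied substitution
shifts at tuning sites to a reference lambda-max; shifts are assumed
additive, unmatched variants contribute zero and are reported, and residue
numbering follows the reference sequence (any renumbering against bovine
rhodopsin is the caller's responsibility). Receptor sensitivity is pigment
absorbance times lens transmission, unnormalized — quantum-catch ratios
absorb the scale.

## Quantum catch and the receptor-noise-limited model

A receptor's catch of a reflecting target is the integral of reflectance ×
irradiance × sensitivity; of a directly viewed radiance, radiance ×
sensitivity. Catches are computed in the energy units of the supplied
spectra with no photon conversion: the discrimination model uses only von
Kries-normalized catch ratios, so the convention cancels provided all
spectra share it. This is worth stating prominently because absolute catches
from this package are not comparable across unit conventions.

Discriminability follows the receptor-noise-limited model. Contrasts are
log catch ratios against the background (`delta_f_i = ln(Q_t/Q_b)`), channel
noise derives from relative cone abundances, `omega_i = weber *
sqrt(n_ref/n_i)` with the most abundant channel as reference. The mosaic
fixes the abundances at n_S : n_M : n_L = 1 : 2 : 2 and behavioural work in
other fish puts the Weber fraction at 0.1, so omega = (0.1·√2, 0.1, 0.1).
The trichromatic distance is

$$\Delta S^2 = \frac{\omega_S^2(\Delta f_L-\Delta f_M)^2 +
\omega_M^2(\Delta f_L-\Delta f_S)^2 + \omega_L^2(\Delta f_S-\Delta f_M)^2}
{(\omega_S\omega_M)^2 + (\omega_S\omega_L)^2 + (\omega_M\omega_L)^2}$$

with the standard dichromatic reduction for two channels; tetrachromatic
opponency is out of scope. Luminance contrast uses the summed double-cone
(M + L) catches with the same Weber fraction — luminance noise has not been
measured separately, and the double cones are the standard teleost
achromatic channel. LWS is excluded from the modelled trichromat: its
expression is marginal (~1% of cones), its labelled cells are rare and
unpatterned, and the retina gives no evidence of a functional long-wave
channel.

Two sweeps mirror the study questions. The monochromatic sweep builds one
template pigment per candidate wavelength behind the lens and scores the
luminance JND between two scenarios (a monochromat has no chromatic
channel); the coexpression sweep varies the SWS2B fraction mixed into the
single cones of the trichromat and scores chromatic JND. Both break ties
toward the shortest wavelength / smallest fraction.

## Opsin expression

Expression is summarized as simplex-valued proportions in the partitions the
field reports: rod (RH1) versus cone of total opsin expression; each cone
gene over total cone expression; and the single-cone genes (SWS1, SWS2B) and
double-cone genes (RH2B, RH2A, LWS) normalized separately — a partition
justified by in-situ labelling, which places SWS genes exclusively in single
cones and RH2/LWS in double cones. Input counts are assumed already
length-normalized; `length_normalize()` handles raw counts. The
sex/size regression on these proportions is deliberately not reimplemented —
the tidy proportion table is exactly what an off-the-shelf beta regression
consumes.

## Stereology and topographic maps

Counting-frame data follow the optical-fractionator design for wholemounts:
frames of area *a* at sites tiling the retina on a grid of cell area *A*
(thickness sampling fraction 1). The total estimate is `sum(Q) * A/a`. The
precision measure CE is reported as the relative standard error of the mean
per-site count, `(sd/sqrt(n))/mean`: the published tables cite
Scheaffer-type estimators without printing a formula, and this form has the
required properties (zero for uniform counts, ∝ 1/√n under replication). It
is documented as replaceable rather than claimed as the original
computation.

Topographic maps are Gaussian-kernel smooths computed directly on a raster
clipped to the digitized outline. Each site contributes its estimated
`q_i * A/a` cells as a Gaussian mass of standard deviation sigma,
renormalized by the kernel mass falling inside the outline — without this
edge correction, rim densities are biased low by the mass that leaks
outside the wholemount. The area-weighted mean of the map then matches the
mean site density (within 5% for reasonable sigma), a mass-consistency
property the tests enforce. Sigma defaults to the site spacing √A,
following the convention of adjusting the smoother to the grid; the raster
step defaults to sigma/4. Peak extraction is an argmax with ties broken
toward the mask centroid, then lexicographically. No shrinkage correction
is applied (wholemount protocols are treated as shrinkage-free); maps
rotate rigidly with the coordinate frame, which is millimetres with +x
temporal and +y dorsal, origin at the outline centroid.

Coexpression-region detection smooths the coexpressing and total single-cone
counts with the same kernel and thresholds their ratio. Because numerator
and denominator share edge effects, the ratio field tolerates — and
benefits from — a narrower kernel than density maps: the default bandwidth
is 0.7 of the site spacing, which on simulated discs roughly halves the
spread of the area error relative to a full-spacing kernel without
introducing bias. The threshold default, 0.25, is half the plateau fraction
of the generator's 50% disc: under symmetric smoothing the half-plateau
contour estimates the disc boundary. The largest 4-connected component
above threshold is reported with centroid, area and peak fraction.

The ideal mosaic (`mosaic_lattice()`) places one single cone at each unit
cell centre and double cones at two edge midpoints, periodic boundaries;
every single cone has exactly four double-cone nearest neighbours and the
double:single ratio is exactly 2 at every lattice size.

## Acuity

Spatial resolving power uses the peak-ganglion-cell method: focal length =
2.55 × lens radius (Matthiessen's ratio, configurable), retinal
magnification `f·tan(1°)` mm/deg, linear cell density √D under a
square-lattice assumption (the hexagonal √(2D/√3) is a flag), and SRP =
half the cells per degree. The square-lattice convention is the one under
which the published distance chain is self-consistent. Note that
recomputing SRP from the rounded published inputs (peak 40,400 cells/mm²,
lens 2.5 mm) gives 5.59 cycles/deg where 5.77 was printed from unrounded
inputs — a ~3% gap this package reports honestly rather than chasing.

Detection distance inverts the angular size: `d = size / tan((1/SRP)°)`,
the range at which the target subtends one full resolvable cycle. Reported
distances are floored at the printed precision of each scale (whole metres
for a fish, one decimal for a stripe): with SRPs of 5.77 and 3.63
cycles/deg this reproduces 26 m and 16 m for an 8 cm fish and 1.6 m and
1 m for its 5 mm white stripe.

## Synthetic data: what it emulates, and what it does not

Because the raw measurements behind the study system are not published at
desk scale, every input is emulated by a seeded generator
(`gen_reflectances()`, `gen_lightfield()`, `gen_lens_transmission()`,
`gen_retina_counts()`, `gen_fish_counts()`, `gen_expression_cohort()`,
`gen_msp_spectrum()`). Generators are pure functions of configuration and
seed, and restore the caller's RNG state.

Defaults encode the documented study conditions:

* **Reflectances** are sums of Gaussians/logistics with the reported
  qualitative shapes: white stripe reflecting from below 400 nm with a
  ~520 nm peak; orange body with a small 360–380 nm UV peak and a larger
  long-wave plateau; anemone peaking near 600 nm; zooplankton and the dark
  looming predator as exactly flat 10% reflectors.
* **Light field**: blue-green (≈480 nm) peaked downwelling and horizontal
  irradiance, horizontal radiance a scaled copy — the shape of reef
  spacelight, not a radiative-transfer model.
* **Retina**: a near-circular outline of radius 4 mm; ganglion density =
  10,000 baseline + 15,000 horizontal-streak ridge (width 0.8 mm) + 15,000
  temporal peak at (2.2, 0) mm — peak density ≈ 40,000 cells/mm², total
  ≈ 0.7 M cells, matching the adult scale. Cone surfaces are tied to the
  mosaic (double = 2 × single, total = 3 × single) at a cone:ganglion ratio
  of 2. Site counts are Poisson (the fractionator's idealized sampling
  model) at spacing 0.5 mm with 50 × 50 µm frames.
* **FISH**: all single cones SWS1-positive; SWS2B coexpression on a
  binomial 50% within a temporal disc (centre (2.6, 0) mm, radius 0.8 mm),
  matching the reported 30–70% in-region fractions; RH2A/RH2B pairing at
  99.5% of double cones; LWS sprinkled at 0.5%.
* **Expression**: cone proportions Dirichlet around means (6.8, 0.7, 49.2,
  42.0, 1.3)% for (SWS1, SWS2B, RH2B, RH2A, LWS). A single Dirichlet
  concentration cannot reproduce every reported per-gene SD simultaneously;
  the default (100) brackets them. The rod fraction is Beta(mean 0.503,
  concentration 16), matching its reported 12% SD.

What passing tests on these data do **not** show: real reflectance spectra
have measurement structure (specular artefacts, fluorescence) the Gaussians
lack; real counting data are overdispersed relative to Poisson where cell
classes cluster; FISH maps systematically underestimate density through
processing losses, with no correction factor established; and the real
light field varies with depth, weather and viewing geometry. Conclusions
about the *machinery* — estimator bias, map fidelity, model identities —
transfer; conclusions about the *organism* require the measurements.

## Numerical choices and problem sizes

Fit lattice 0.1 nm; sweep ties toward short wavelengths/small fractions;
map peak ties toward the mask centroid; trapezoidal integration; strict
validation errors over silent repair. The test suite runs the stereology
property checks at 200 replicates of ~200-site retinas, the noisy-fit study
at 100 seeds, and the expression recovery at a 10⁴ cohort — sizes chosen so
the statistical assertions (unbiasedness within 1 SE, 95% coverage, 2 SE
mean recovery) are sharp while the whole suite stays interactive.

## Known limitations

Single-channel luminance and three-channel chromatic models only; no
spatial or temporal vision; no photon-unit conversion; no A2 chromophore;
no phylogenetic inference on opsins; the CE formula is a documented
convention, not a reconstruction of any specific published table; and the
pipeline's figures are deliberately omitted — every artefact is a tidy CSV
or JSON so results are diffable and scriptable.
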