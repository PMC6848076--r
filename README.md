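# anemovis

Visual-ecology modelling for coral reef fish, built around the anemonefish
visual system: from spectra, opsin transcript counts and retinal
counting-frame data to colour discriminability, retinal topography and
behavioural acuity.

## What it models

Reef fish see their world through a chain this package implements end to
end:

* **Ocular media** — lens transmission curves, normalized at 700 nm and
  summarized by T50 (UV-transmitting if T50 < 400 nm).
* **Visual pigments** — A1 template absorbance curves (Govardovskii alpha +
  beta bands) parameterized by lambda-max; lambda-max estimation both by
  template fitting to measured absorbance and by additive amino-acid
  tuning-site shifts; opsin coexpression as a single effective mixed
  pigment.
* **Colour vision** — quantum catches and the receptor-noise-limited (RNL)
  model. For channel contrasts Δf_i = ln(Q_target/Q_background) and noises
  ω_i = ν·√(n_ref/n_i) (abundances n_S:n_M:n_L = 1:2:2, Weber fraction
  ν = 0.1):

  ΔS² = [ω_S²(Δf_L−Δf_M)² + ω_M²(Δf_L−Δf_S)² + ω_L²(Δf_S−Δf_M)²] /
  [(ω_Sω_M)² + (ω_Sω_L)² + (ω_Mω_L)²]

  in just-noticeable differences (JND), plus a double-cone luminance channel
  ΔL = |Δf_lum|/ω. Sweeps explore the optimal monochromatic pigment and the
  effect of SWS2B coexpression in the single cones.
* **Expression** — simplex-valued opsin proportions (rod vs cone; fractions
  of all cones; single- and double-cone genes normalized separately) with
  cohort means ± SD.
* **Topography** — optical-fractionator totals (N = ΣQ·A/a), coefficients
  of error, Gaussian-kernel isodensity maps with outline clipping and edge
  renormalization, peak extraction, cone:ganglion ratio maps, FISH channel
  proportions, coexpression-region detection, and the ideal 2:1 cone
  mosaic.
* **Acuity** — spatial resolving power from peak ganglion-cell density and
  lens size (Matthiessen's ratio 2.55), and detection distances for targets
  of known size.

Every input can be produced by seeded synthetic generators
(`gen_reflectances()`, `gen_lightfield()`, `gen_retina_counts()`,
`gen_fish_counts()`, `gen_expression_cohort()`, `gen_msp_spectrum()`) that
emulate the statistical structure of the measured data, so the whole
pipeline is testable without downloads. See the vignette
(`vignettes/anemonefish-visual-ecology.Rmd`) for the models, parameter
defaults and design decisions.

## Worked example

```r
library(anemovis)
wl   <- spectral_grid()                      # 300-800 nm at 1 nm
lens <- gen_lens_transmission(wl)
t50(lens)
#> T50: 358  UV-transmitting: TRUE

# does SWS2B coexpression in the single cones help tell the orange body
# from the white stripe?
lf   <- gen_lightfield(wl)
refl <- gen_reflectances(wl)
sw <- coexpression_sweep(viewing_scenario(refl$body_orange),
                         viewing_scenario(refl$white_stripe), lf, lens)
#> dS at 0% SWS2B: 1.93 | at 100%: 4.38 | best: 100 %

# stereology and topography of a synthetic adult retina
rc <- gen_retina_counts(seed = 1)
fractionator_total(rc$grid, "ganglion")      #> 694300 cells
scheaffer_ce(rc$grid, "ganglion")            #> 0.033
m <- kernel_map(rc$grid, rc$outline, "ganglion")
m$peak                                       #> x 2.12, y 0 (temporal), 29032 cells/mm^2

# acuity chain from the peak site density and a 2.5 mm lens
peak <- max(rc$grid$sites$ganglion) / rc$grid$frame_area   #> 36800 cells/mm^2
a <- srp(peak, eye_geometry(2.5))            #> 5.34 cycles/deg
detection_distance(0.08, a$srp_cyc_deg)      #> an 8 cm conspecific from 24 m
```

The contrast of the orange body against the white stripe more than doubles
as SWS2B replaces SWS1 in the single cones (1.93 to 4.38 JND) — the shift
toward ~450 nm sensitivity is where these two colours differ most. The
synthetic retina reproduces the adult scale: a horizontal streak with a
temporal peak near 40,000 cells/mm² supporting an acuity of ~5.5 cycles/deg,
enough to resolve a conspecific tens of metres away.

`run_pipeline(out_dir, seed)` chains all stages (spectra, pigments, JND
sweeps, expression, topography, acuity) into tidy CSVs plus a JSON manifest;
reruns with the same seed are bit-identical.

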