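test_that("quantum catch integrates stimulus x sensitivity and is linear", {
  wl <- spectral_grid()
  sens <- flat_spec(1, wl, "sensitivity")
  illum <- flat_spec(1, wl, "irradiance")
  refl <- flat_spec(0.1, wl)
  # rectangle integral over 300-800 nm
  expect_equal(quantum_catch(sens, illum, refl), 0.1 * 500)
  # doubling the illuminant doubles the catch
  illum2 <- flat_spec(2, wl, "irradiance")
  expect_equal(quantum_catch(sens, illum2, refl),
               2 * quantum_catch(sens, illum, refl))
  # a flat-10% target catches exactly 0.1x a perfect reflector under any light
  real <- gen_lightfield(wl)
  s520 <- template_absorbance(520, wl)
  sens520 <- spec(wl, s520$value, "sensitivity")
  expect_equal(quantum_catch(sens520, real$horizontal_irradiance, flat_spec(0.1, wl)),
               0.1 * quantum_catch(sens520, real$horizontal_irradiance,
                                   flat_spec(1, wl)))
  expect_error(quantum_catch(flat_spec(0, wl, "sensitivity"), illum), "zero")
})

test_that("receptor contrasts are log catch ratios with the expected symmetries", {
  expect_equal(receptor_contrasts(c(1, 2, 3), c(1, 2, 3)), c(0, 0, 0))
  expect_equal(receptor_contrasts(c(0.5, 1), c(1, 2)), rep(log(0.5), 2))
  qt <- c(1.3, 0.7, 2.1); qb <- c(0.9, 1.1, 2.0)
  expect_equal(receptor_contrasts(qt, qb), -receptor_contrasts(qb, qt))
  expect_error(receptor_contrasts(c(1, -1), c(1, 1)), "positive")
})

test_that("receptor_set derives channel noise from relative abundances", {
  wl <- spectral_grid()
  sens <- lapply(c(400, 498, 520), function(l) {
    spec(wl, template_absorbance(l, wl)$value, "sensitivity")
  })
  rs <- receptor_set(sens, c(1, 2, 2), weber = 0.1)
  expect_equal(rs$omega, c(0.1 * sqrt(2), 0.1, 0.1))
  expect_error(receptor_set(sens, c(1, 2), 0.1), "match")
  expect_error(receptor_set(c(sens, sens, sens)[1:5], rep(1, 5)), "at most 4")
})

test_that("chromatic JND matches the hand-evaluated trichromat oracle", {
  omega <- c(0.1 * sqrt(2), 0.1, 0.1)
  # independently hand-computed: dS^2 = (0.01*0.01 + 0.01*0.01) / 5e-4 = 0.4
  expect_equal(chromatic_jnd(c(0.1, 0, 0), omega), sqrt(0.4), tolerance = 1e-12)
  # achromatic shifts are exactly zero
  expect_equal(chromatic_jnd(c(0.3, 0.3, 0.3), omega), 0)
  # homogeneity: scaling all omega by c scales dS by 1/c
  expect_equal(chromatic_jnd(c(0.1, 0, 0), 3 * omega),
               chromatic_jnd(c(0.1, 0, 0), omega) / 3)
  expect_error(chromatic_jnd(rep(0.1, 4), rep(0.1, 4)), "2 or 3")
})

test_that("trichromat formula collapses to the dichromat one as a channel drowns in noise", {
  f <- c(0.25, 0.1, -0.05)
  w <- c(1e6, 0.1, 0.12)
  tri <- chromatic_jnd(f, w)
  di <- chromatic_jnd(f[2:3], w[2:3])
  expect_equal(tri, di, tolerance = 1e-6)
})

test_that("luminance JND is the noise-scaled absolute contrast", {
  expect_equal(luminance_jnd(0.1, 0.1), 1.0)
  expect_equal(luminance_jnd(0, 0.1), 0)
  expect_gt(luminance_jnd(0.3, 0.1), luminance_jnd(0.2, 0.1))
  expect_error(luminance_jnd(0.1, 0), "positive")
})

build_trichromat <- function(wl, lens = unit_lens(wl)) {
  sens <- lapply(c(400, 498, 520), function(l) {
    receptor_sensitivity(template_absorbance(l, wl), lens)
  })
  receptor_set(sens, c(1, 2, 2), 0.1)
}

test_that("JNDs vanish for identical stimuli and are von Kries invariant", {
  wl <- spectral_grid()
  lf <- gen_lightfield(wl)
  rs <- build_trichromat(wl)
  refl <- gen_reflectances(wl)
  same <- jnd_pair(rs, lf, viewing_scenario(refl$body_orange),
                   viewing_scenario(refl$body_orange))
  expect_equal(same$dS, 0)
  expect_equal(same$dL, 0)
  # proportional catches (brighter copy of the same reflectance) -> dS = 0
  brighter <- spec(wl, 2 * refl$anemone$value, "reflectance")
  prop <- jnd_pair(rs, lf, viewing_scenario(brighter),
                   viewing_scenario(refl$anemone))
  expect_equal(prop$dS, 0, tolerance = 1e-9)
  expect_gt(prop$dL, 0)
  # global illuminant rescaling cancels in every contrast
  lf2 <- light_field(
    spec(wl, 7 * lf$downwelling$value, "irradiance"),
    spec(wl, 7 * lf$horizontal_irradiance$value, "irradiance"),
    spec(wl, 7 * lf$horizontal_radiance$value, "radiance"))
  a <- jnd_pair(rs, lf, viewing_scenario(refl$body_orange),
                viewing_scenario(refl$white_stripe))
  b <- jnd_pair(rs, lf2, viewing_scenario(refl$body_orange),
                viewing_scenario(refl$white_stripe))
  expect_equal(a$dS, b$dS, tolerance = 1e-9)
  expect_equal(a$dL, b$dL, tolerance = 1e-9)
})

test_that("monochromatic sweep finds the wavelength of maximal target contrast", {
  wl <- spectral_grid()
  lf <- flat_light_field(wl)
  target <- viewing_scenario(spec(wl, 0.1 + 0.4 * exp(-((wl - 450) / 30)^2),
                                  "reflectance"))
  background <- viewing_scenario(flat_spec(0.1, wl))
  sw <- monochromatic_sweep(target, background, lf, unit_lens(wl),
                            lambda = seq(350, 600, by = 1))
  # brute-force fine-sweep oracle around the optimum
  fine <- monochromatic_sweep(target, background, lf, unit_lens(wl),
                              lambda = seq(430, 470, by = 0.25))
  expect_lt(abs(sw$best_lambda - 450), 5)
  expect_lt(abs(sw$best_lambda - fine$best_lambda), 2)
  # identical scenarios give a flat zero curve with a tie warning
  expect_warning(
    flat_sw <- monochromatic_sweep(background, background, lf, unit_lens(wl),
                                   lambda = seq(400, 500, 10)),
    "tie")
  expect_equal(max(flat_sw$curve$jnd), 0)
  # curve invariant to global illuminant rescaling
  lf7 <- light_field(
    spec(wl, 7 * lf$downwelling$value, "irradiance"),
    spec(wl, 7 * lf$horizontal_irradiance$value, "irradiance"),
    spec(wl, 7 * lf$horizontal_radiance$value, "radiance"))
  sw7 <- monochromatic_sweep(target, background, lf7, unit_lens(wl),
                             lambda = seq(430, 470, 10))
  swA <- monochromatic_sweep(target, background, lf, unit_lens(wl),
                             lambda = seq(430, 470, 10))
  expect_equal(sw7$curve$jnd, swA$curve$jnd, tolerance = 1e-9)
  expect_error(monochromatic_sweep(target, background, lf, unit_lens(wl),
                                   lambda = numeric(0)), "empty")
})

test_that("coexpression sweep endpoints equal the pure-pigment trichromats and the curve is smooth", {
  wl <- spectral_grid()
  lf <- gen_lightfield(wl)
  lens <- gen_lens_transmission(wl)
  refl <- gen_reflectances(wl)
  target <- viewing_scenario(refl$body_orange)
  background <- viewing_scenario(refl$white_stripe)
  sw <- coexpression_sweep(target, background, lf, lens)
  # endpoint consistency against independently assembled pure trichromats
  pure <- function(single_lmax) {
    sens <- lapply(c(single_lmax, 498, 520), function(l) {
      receptor_sensitivity(template_absorbance(l, wl), lens)
    })
    rs <- receptor_set(sens, c(1, 2, 2), 0.1)
    jnd_pair(rs, lf, target, background)$dS
  }
  expect_equal(sw$curve$dS[1], pure(370), tolerance = 1e-9)
  expect_equal(sw$curve$dS[nrow(sw$curve)], pure(408), tolerance = 1e-9)
  # continuity: adjacent 1% steps differ by well under 10% of the curve range
  rng <- diff(range(sw$curve$dS))
  expect_lt(max(abs(diff(sw$curve$dS))), 0.1 * rng)
})

test_that("coexpression sweep is flat when the targets differ only at long wavelengths", {
  wl <- spectral_grid()
  lf <- flat_light_field(wl)
  base <- 0.2 + 0 * wl
  bump <- base + 0.3 * exp(-((wl - 650) / 25)^2)  # differs only above ~560 nm
  sw <- coexpression_sweep(viewing_scenario(spec(wl, bump, "reflectance")),
                           viewing_scenario(spec(wl, base, "reflectance")),
                           lf, unit_lens(wl),
                           fractions = seq(0, 1, 0.1))
  # single-cone pigments (370/408) barely see 650 nm: curve flat
  expect_lt(diff(range(sw$curve$dS)), 0.02 * max(sw$curve$dS))
})
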