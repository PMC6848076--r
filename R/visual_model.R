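#' Ambient light field
#'
#' The three light measurements the viewing scenarios draw on: downwelling
#' irradiance (lights targets seen from below, e.g. zooplankton), horizontal
#' irradiance (lights vertically viewed targets: fish flanks, anemone), and
#' horizontal radiance (the background spacelight a target is seen against).
#'
#' @param downwelling,horizontal_irradiance,horizontal_radiance Spectra on a
#'   common grid, strictly positive over 320--700 nm.
#' @return An object of class `"light_field"`.
#' @export
light_field <- function(downwelling, horizontal_irradiance, horizontal_radiance) {
  assert_spec(downwelling); assert_spec(horizontal_irradiance)
  assert_spec(horizontal_radiance)
  assert_same_grid(downwelling, horizontal_irradiance)
  assert_same_grid(downwelling, horizontal_radiance)
  for (s in list(downwelling, horizontal_irradiance, horizontal_radiance)) {
    band <- s$wl >= 320 & s$wl <= 700
    if (any(s$value[band] <= 0)) {
      stop("light field spectra must be strictly positive over 320-700 nm",
           call. = FALSE)
    }
  }
  structure(list(downwelling = downwelling,
                 horizontal_irradiance = horizontal_irradiance,
                 horizontal_radiance = horizontal_radiance),
            class = "light_field")
}

#' Receptor set for the receptor-noise-limited model
#'
#' Orders 1--4 spectral channels and derives each channel's noise from the
#' Weber fraction of the most abundant channel: `omega_i = weber *
#' sqrt(n_ref / n_i)`, where `n_ref` is the largest relative abundance. With
#' the anemonefish mosaic ratio n_S : n_M : n_L = 1 : 2 : 2 and Weber
#' fraction 0.1 this gives omega = (0.1 * sqrt(2), 0.1, 0.1).
#'
#' @param sensitivities Named list of sensitivity spectra, in channel order
#'   (conventionally shortest to longest wavelength).
#' @param abundances Relative cone abundances n_i (> 0), same length.
#' @param weber Weber fraction of the reference (most abundant) channel.
#' @return An object of class `"receptor_set"` with elements `sensitivities`,
#'   `abundances`, `omega`, `weber`.
#' @export
receptor_set <- function(sensitivities, abundances, weber = 0.1) {
  if (!is.list(sensitivities) || !length(sensitivities)) {
    stop("sensitivities must be a non-empty list of spectra", call. = FALSE)
  }
  if (length(sensitivities) > 4) {
    stop("at most 4 receptor channels are supported", call. = FALSE)
  }
  if (length(abundances) != length(sensitivities) || any(abundances <= 0)) {
    stop("abundances must be positive and match the number of channels",
         call. = FALSE)
  }
  if (weber <= 0) stop("weber fraction must be positive", call. = FALSE)
  lapply(sensitivities, assert_spec)
  for (s in sensitivities[-1]) assert_same_grid(sensitivities[[1]], s)
  omega <- weber * sqrt(max(abundances) / abundances)
  structure(list(sensitivities = sensitivities,
                 abundances = abundances,
                 omega = omega, weber = weber),
            class = "receptor_set")
}

#' Quantum catch of a receptor
#'
#' Trapezoidal integral of the receptor sensitivity against the stimulus: for
#' a reflecting target, `integral R(lambda) I(lambda) S(lambda) dlambda`; for
#' a directly viewed radiance, `integral L(lambda) S(lambda) dlambda`.
#' Catches are computed in the energy units of the supplied spectra (no
#' photon conversion); because the discrimination model only uses von
#' Kries-normalized catch ratios, the unit convention cancels provided all
#' spectra share it.
#'
#' @param sensitivity Receptor sensitivity [spec()].
#' @param illuminant Irradiance (if `reflectance` given) or radiance spectrum.
#' @param reflectance Optional target reflectance [spec()]; omit to view the
#'   illuminant/radiance directly.
#' @return Positive scalar catch.
#' @export
quantum_catch <- function(sensitivity, illuminant, reflectance = NULL) {
  assert_spec(sensitivity); assert_spec(illuminant)
  assert_same_grid(sensitivity, illuminant)
  if (all(sensitivity$value == 0)) {
    stop("sensitivity is identically zero", call. = FALSE)
  }
  integrand <- sensitivity$value * illuminant$value
  if (!is.null(reflectance)) {
    assert_spec(reflectance)
    assert_same_grid(sensitivity, reflectance)
    integrand <- integrand * reflectance$value
  }
  pracma::trapz(sensitivity$wl, integrand)
}

#' Per-channel receptor contrasts
#'
#' Log catch ratios `delta_f_i = ln(Q_target,i / Q_background,i)`. Dividing by
#' the background catch is the von Kries step: a common rescaling of the
#' illuminant cancels.
#'
#' @param q_target,q_background Positive catch vectors, equal length.
#' @return Numeric vector of log contrasts.
#' @export
receptor_contrasts <- function(q_target, q_background) {
  if (length(q_target) != length(q_background)) {
    stop("catch vectors differ in length", call. = FALSE)
  }
  if (any(q_target <= 0) || any(q_background <= 0)) {
    stop("catches must be strictly positive", call. = FALSE)
  }
  log(q_target / q_background)
}

#' Chromatic discriminability (receptor-noise-limited model)
#'
#' Distance between two stimuli in units of just-noticeable differences.
#' For a trichromat with channels (S, M, L), contrasts `delta_f` and noises
#' `omega`:
#' \deqn{\Delta S^2 = \frac{\omega_S^2 (\Delta f_L - \Delta f_M)^2 +
#'   \omega_M^2 (\Delta f_L - \Delta f_S)^2 +
#'   \omega_L^2 (\Delta f_S - \Delta f_M)^2}{
#'   (\omega_S \omega_M)^2 + (\omega_S \omega_L)^2 + (\omega_M \omega_L)^2}}
#' For a dichromat, `dS = |df_1 - df_2| / sqrt(omega_1^2 + omega_2^2)`.
#' Purely achromatic shifts (all contrasts equal) give exactly zero.
#'
#' @param delta_f Per-channel log contrasts (length 2 or 3).
#' @param omega Per-channel noise, or a [receptor_set()].
#' @return Nonnegative scalar, JND units.
#' @export
chromatic_jnd <- function(delta_f, omega) {
  if (inherits(omega, "receptor_set")) omega <- omega$omega
  n <- length(delta_f)
  if (length(omega) != n) stop("delta_f and omega differ in length", call. = FALSE)
  if (n == 2) {
    return(abs(delta_f[1] - delta_f[2]) / sqrt(omega[1]^2 + omega[2]^2))
  }
  if (n == 3) {
    f <- delta_f; w <- omega
    num <- w[1]^2 * (f[3] - f[2])^2 + w[2]^2 * (f[3] - f[1])^2 +
      w[3]^2 * (f[1] - f[2])^2
    den <- (w[1] * w[2])^2 + (w[1] * w[3])^2 + (w[2] * w[3])^2
    return(sqrt(num / den))
  }
  stop("chromatic_jnd supports 2 or 3 channels (tetrachromatic opponency out of scope)",
       call. = FALSE)
}

#' Luminance discriminability
#'
#' `dL = |delta_f_lum| / omega_lum`, with `delta_f_lum` the log ratio of the
#' summed double-cone catches of the two stimuli. The Weber fraction is
#' assumed equal for colour and luminance.
#'
#' @param delta_f_lum Scalar log contrast of the luminance channel.
#' @param omega_lum Luminance channel noise (> 0).
#' @return Nonnegative scalar, JND units.
#' @export
luminance_jnd <- function(delta_f_lum, omega_lum = 0.1) {
  if (omega_lum <= 0) stop("omega_lum must be positive", call. = FALSE)
  abs(delta_f_lum) / omega_lum
}

#' Describe a viewing scenario
#'
#' A target is either a reflectance illuminated by one of the light-field
#' roles, or the background spacelight (horizontal radiance) viewed directly.
#'
#' @param reflectance Target reflectance [spec()], or NULL for the spacelight.
#' @param illuminant `"horizontal"` (fish flanks, anemone) or `"downwelling"`
#'   (zooplankton seen from below); ignored when `reflectance` is NULL.
#' @return An object of class `"viewing_scenario"`.
#' @export
viewing_scenario <- function(reflectance = NULL,
                             illuminant = c("horizontal", "downwelling")) {
  illuminant <- match.arg(illuminant)
  if (!is.null(reflectance)) assert_spec(reflectance)
  structure(list(reflectance = reflectance, illuminant = illuminant),
            class = "viewing_scenario")
}

#' Background spacelight scenario
#' @return A [viewing_scenario()] viewing the horizontal radiance directly.
#' @export
spacelight_scenario <- function() viewing_scenario(NULL)

#' Catches of all channels for a scenario
#'
#' @param receptors A [receptor_set()].
#' @param lf A [light_field()].
#' @param scenario A [viewing_scenario()].
#' @return Positive catch vector, one per channel.
#' @export
scenario_catches <- function(receptors, lf, scenario) {
  if (!inherits(scenario, "viewing_scenario")) {
    stop("scenario must be a viewing_scenario()", call. = FALSE)
  }
  vapply(receptors$sensitivities, function(s) {
    if (is.null(scenario$reflectance)) {
      quantum_catch(s, lf$horizontal_radiance)
    } else {
      illum <- if (scenario$illuminant == "downwelling") lf$downwelling
               else lf$horizontal_irradiance
      quantum_catch(s, illum, scenario$reflectance)
    }
  }, numeric(1))
}

#' Chromatic and luminance JNDs between two scenarios
#'
#' Full receptor-noise-limited comparison of a target and a background
#' scenario seen by a receptor set. The luminance channel is the sum of the
#' double-cone (M + L) catches; which channels those are is configurable.
#'
#' @param receptors A [receptor_set()].
#' @param lf A [light_field()].
#' @param target,background [viewing_scenario()] objects.
#' @param luminance_channels Indices of the channels summed into the
#'   luminance signal (default the last two, the double-cone members).
#' @return List with `dS`, `dL`, `delta_f` (per channel) and `delta_f_lum`.
#' @export
jnd_pair <- function(receptors, lf, target, background,
                     luminance_channels = NULL) {
  nchan <- length(receptors$sensitivities)
  if (is.null(luminance_channels)) {
    luminance_channels <- if (nchan >= 2) c(nchan - 1, nchan) else 1L
  }
  qt <- scenario_catches(receptors, lf, target)
  qb <- scenario_catches(receptors, lf, background)
  df <- receptor_contrasts(qt, qb)
  df_lum <- log(sum(qt[luminance_channels]) / sum(qb[luminance_channels]))
  list(dS = chromatic_jnd(df, receptors$omega),
       dL = luminance_jnd(df_lum, receptors$weber),
       delta_f = df, delta_f_lum = df_lum)
}

#' Optimal monochromatic pigment sweep
#'
#' For each candidate lambda-max, builds a single template pigment behind the
#' lens and computes the luminance JND between target and background (a
#' monochromat has no chromatic channel). Returns the full contrast curve and
#' the best wavelength; ties are broken toward the shortest wavelength, and a
#' flat-zero curve is reported with a warning.
#'
#' @param target,background [viewing_scenario()] objects.
#' @param lf A [light_field()].
#' @param lens Lens transmission [spec()] on the light-field grid.
#' @param lambda Candidate lambda-max values (nm).
#' @param weber Weber fraction for the single channel.
#' @return List with `best_lambda` (nm) and `curve` (data frame
#'   `lambda`, `jnd`).
#' @export
monochromatic_sweep <- function(target, background, lf, lens,
                                lambda = seq(350, 600, by = 1), weber = 0.1) {
  if (!length(lambda)) stop("empty lambda range", call. = FALSE)
  jnd <- vapply(lambda, function(l) {
    sens <- receptor_sensitivity(template_absorbance(l, lens$wl), lens)
    rs <- receptor_set(list(mono = sens), 1, weber)
    qt <- scenario_catches(rs, lf, target)
    qb <- scenario_catches(rs, lf, background)
    luminance_jnd(log(qt / qb), weber)
  }, numeric(1))
  if (max(jnd) - min(jnd) < 1e-12 && max(jnd) < 1e-12) {
    warning("contrast curve is identically zero; best wavelength is a tie")
  }
  list(best_lambda = lambda[which.max(jnd)],
       curve = data.frame(lambda = lambda, jnd = jnd))
}

#' SWS2B coexpression sweep for the trichromat
#'
#' Varies the fraction of SWS2B mixed into the SWS1-expressing single cones
#' (0--100%), holding the double-cone channels (RH2B, RH2A) fixed, and
#' computes the chromatic JND between the two scenarios at each fraction.
#' Endpoints equal the pure-SWS1 and pure-SWS2B trichromat values.
#'
#' @param target,background [viewing_scenario()] objects.
#' @param lf A [light_field()].
#' @param lens Lens transmission [spec()].
#' @param sws1,sws2b,m,l Lambda-max (nm) of the single-cone pigments and of
#'   the fixed M (RH2B) and L (RH2A) channels.
#' @param fractions SWS2B fractions in \[0, 1\].
#' @param abundances Relative abundances n_S : n_M : n_L.
#' @param weber Weber fraction of the reference channel.
#' @return List with `best_fraction` (smallest on ties) and `curve`
#'   (data frame `fraction`, `dS`, `dL`).
#' @export
coexpression_sweep <- function(target, background, lf, lens,
                               sws1 = 370, sws2b = 408, m = 498, l = 520,
                               fractions = seq(0, 1, by = 0.01),
                               abundances = c(1, 2, 2), weber = 0.1) {
  if (any(fractions < 0 | fractions > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  wl <- lens$wl
  p1 <- template_absorbance(sws1, wl)
  p2 <- template_absorbance(sws2b, wl)
  sens_m <- receptor_sensitivity(template_absorbance(m, wl), lens)
  sens_l <- receptor_sensitivity(template_absorbance(l, wl), lens)
  res <- vapply(fractions, function(f) {
    sens_s <- receptor_sensitivity(mix_coexpressed(p1, p2, f), lens)
    rs <- receptor_set(list(S = sens_s, M = sens_m, L = sens_l),
                       abundances, weber)
    out <- jnd_pair(rs, lf, target, background)
    c(out$dS, out$dL)
  }, numeric(2))
  curve <- data.frame(fraction = fractions, dS = res[1, ], dL = res[2, ])
  list(best_fraction = fractions[which.max(curve$dS)], curve = curve)
}
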