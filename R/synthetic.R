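#' Seeded synthetic-data generators
#'
#' Every input the analysis pipeline consumes can be generated synthetically
#' with the statistical structure the analyses assume: smooth reflectance and
#' light-field spectra built from sums of Gaussians/logistics matching the
#' qualitative shapes of reef measurements, Poisson counting-frame counts over
#' streak-plus-peak retinal density surfaces, binomially thinned FISH
#' channels with a temporal coexpression disc, Dirichlet opsin-expression
#' cohorts, and noisy pigment absorbance curves. Each generator is a pure
#' function of its arguments (including the seed).
#'
#' @name synthetic_data
#' @keywords internal
NULL

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Synthetic reflectance spectra
#'
#' Deterministic smooth curves emulating the measured shapes: the white
#' stripe reflects from below 400 nm upward with a peak around 520 nm; the
#' orange body shows a small UV peak (360--380 nm) and a larger long-wave
#' plateau (500--700 nm); the host anemone peaks around 600 nm; zooplankton
#' and the dark looming predator are exactly flat 10% reflectors.
#'
#' @param wl Wavelength grid (nm).
#' @return Named list of reflectance spectra: `body_orange`, `white_stripe`,
#'   `anemone`, `zooplankton`, `predator`.
#' @export
gen_reflectances <- function(wl = spectral_grid()) {
  flat10 <- spec(wl, rep(0.1, length(wl)), "reflectance")
  list(
    body_orange = spec(wl,
      0.04 + 0.12 * exp(-((wl - 370) / 18)^2) +
        0.55 / (1 + exp(-(wl - 545) / 22)),
      "reflectance"),
    white_stripe = spec(wl,
      0.35 + 0.40 * exp(-((wl - 520) / 120)^2),
      "reflectance"),
    anemone = spec(wl,
      0.06 + 0.45 * exp(-((wl - 600) / 70)^2) +
        0.05 * exp(-((wl - 360) / 40)^2),
      "reflectance"),
    zooplankton = flat10,
    predator = flat10)
}

#' Synthetic reef light field
#'
#' Blue-green-peaked (about 480 nm) downwelling and horizontal irradiance,
#' positive across the grid, with the horizontal radiance a scaled copy of
#' the horizontal irradiance (spacelight viewed directly is dimmer than the
#' irradiance that lights a target).
#'
#' @param wl Wavelength grid (nm).
#' @param radiance_scale Horizontal radiance as a fraction of horizontal
#'   irradiance.
#' @return A [light_field()].
#' @export
gen_lightfield <- function(wl = spectral_grid(), radiance_scale = 0.05) {
  down <- 1e-3 + exp(-((wl - 480) / 110)^2)
  horiz <- 0.3 * (1e-3 + exp(-((wl - 480) / 90)^2))
  light_field(
    downwelling = spec(wl, down, "irradiance"),
    horizontal_irradiance = spec(wl, horiz, "irradiance"),
    horizontal_radiance = spec(wl, radiance_scale * horiz, "radiance"))
}

#' Synthetic lens transmission curve
#'
#' Logistic transmission rising through its midpoint at `t50_nm`, normalized
#' at 700 nm. The default midpoint mirrors a UV-transmitting adult lens.
#'
#' @param wl Wavelength grid (nm).
#' @param t50_nm Transmission midpoint (nm).
#' @param slope_nm Logistic slope parameter (nm).
#' @return Transmission [spec()], value 1 at 700 nm.
#' @export
gen_lens_transmission <- function(wl = spectral_grid(), t50_nm = 358,
                                  slope_nm = 8) {
  v <- 1 / (1 + exp(-(wl - t50_nm) / slope_nm))
  normalize_at(spec(wl, v, "transmission"), 700)
}

#' Parametric retinal density surface
#'
#' Baseline density plus a Gaussian horizontal streak along the y = 0
#' meridian plus a Gaussian temporal peak: the ganglion-cell topography of a
#' reef fish with a horizontal streak and a temporo-central acute zone
#' (+x = temporal).
#'
#' @param x,y Coordinates (mm).
#' @param baseline Baseline density (cells/mm^2).
#' @param streak_amp,streak_width Streak amplitude (cells/mm^2) and vertical
#'   Gaussian width (mm).
#' @param peak_amp,peak_x,peak_y,peak_width Temporal peak amplitude,
#'   location (mm) and isotropic Gaussian width (mm).
#' @return Density at (x, y), cells/mm^2.
#' @export
density_surface <- function(x, y, baseline = 10000,
                            streak_amp = 15000, streak_width = 0.8,
                            peak_amp = 15000, peak_x = 2.2, peak_y = 0,
                            peak_width = 0.7) {
  baseline + streak_amp * exp(-(y / streak_width)^2) +
    peak_amp * exp(-(((x - peak_x)^2 + (y - peak_y)^2) / peak_width^2))
}

# near-circular outline polygon and a systematic site grid inside it
make_outline <- function(radius = 4, n_vertices = 72) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  retina_outline(radius * cos(th), radius * sin(th))
}

systematic_sites <- function(outline, spacing, offset = c(0, 0)) {
  xs <- seq(min(outline$x) + offset[1], max(outline$x), by = spacing)
  ys <- seq(min(outline$y) + offset[2], max(outline$y), by = spacing)
  pts <- expand.grid(x = xs, y = ys)
  pts[points_in_outline(outline, pts$x, pts$y), , drop = FALSE]
}

#' Synthetic retinal counting-frame data
#'
#' Builds a near-circular retina outline, places a systematic grid of
#' counting sites inside it (random grid offset, as in systematic uniform
#' random sampling), and draws per-site Poisson counts with mean
#' `frame_area * D(x, y)` where `D` is the streak-plus-peak
#' [density_surface()] for ganglion cells. Cone classes honour the mosaic:
#' single cones at `cone_gc_ratio / 3` of the cone surface, doubles twice the
#' singles, total three times; the cone surface is `cone_gc_ratio` times the
#' ganglion surface.
#'
#' @param seed Integer seed.
#' @param classes Subset of `c("ganglion", "single_cone", "double_cone",
#'   "total_cone")`.
#' @param radius Retina radius (mm).
#' @param spacing Site grid spacing (mm); grid cell area A = spacing^2.
#' @param frame_area Counting frame area a (mm^2).
#' @param cone_gc_ratio Total-cone to ganglion-cell density ratio.
#' @param ... Passed to [density_surface()].
#' @return List with `outline` ([retina_outline()]) and `grid`
#'   ([count_grid()]).
#' @export
gen_retina_counts <- function(seed = 1,
                              classes = c("ganglion", "single_cone",
                                          "double_cone", "total_cone"),
                              radius = 4, spacing = 0.5, frame_area = 0.0025,
                              cone_gc_ratio = 2, ...) {
  known <- c("ganglion", "single_cone", "double_cone", "total_cone")
  if (!length(classes) || !all(classes %in% known)) {
    stop("classes must be a subset of: ", paste(known, collapse = ", "),
         call. = FALSE)
  }
  outline <- make_outline(radius)
  with_seed(seed, {
    offset <- stats::runif(2, 0, spacing)
    sites <- systematic_sites(outline, spacing, offset)
    d_gc <- density_surface(sites$x, sites$y, ...)
    surfaces <- list(ganglion = d_gc,
                     single_cone = cone_gc_ratio * d_gc / 3,
                     double_cone = 2 * cone_gc_ratio * d_gc / 3,
                     total_cone = cone_gc_ratio * d_gc)
    for (cl in classes) {
      sites[[cl]] <- stats::rpois(nrow(sites), frame_area * surfaces[[cl]])
    }
    list(outline = outline,
         grid = count_grid(sites, frame_area, spacing^2))
  })
}

#' Synthetic FISH channel counts
#'
#' Single cones all express SWS1; inside a temporal coexpression disc a
#' binomial subset additionally expresses SWS2B; double cones carry the
#' RH2A/RH2B paired arrangement at a high rate; LWS labels a sprinkling of
#' double cones.
#'
#' @param seed Integer seed.
#' @param radius,spacing,frame_area,cone_gc_ratio,... As in
#'   [gen_retina_counts()].
#' @param coexp_centre Disc centre (mm), temporal by default.
#' @param coexp_radius Disc radius (mm).
#' @param coexp_fraction Coexpression probability inside the disc.
#' @param pairing_rate Probability a double cone shows the RH2A/RH2B pairing.
#' @param lws_rate Probability a double cone labels for LWS.
#' @return List with `outline` and `grid` (classes `single_cone`, `sws1`,
#'   `sws2b`, `double_cone`, `rh2_paired`, `lws`).
#' @export
gen_fish_counts <- function(seed = 1, radius = 4, spacing = 0.5,
                            frame_area = 0.0025, cone_gc_ratio = 2,
                            coexp_centre = c(2.6, 0), coexp_radius = 0.8,
                            coexp_fraction = 0.5, pairing_rate = 0.995,
                            lws_rate = 0.005, ...) {
  outline <- make_outline(radius)
  if (sqrt(sum(coexp_centre^2)) + coexp_radius > radius) {
    stop("coexpression disc must lie inside the outline", call. = FALSE)
  }
  with_seed(seed, {
    offset <- stats::runif(2, 0, spacing)
    sites <- systematic_sites(outline, spacing, offset)
    d_gc <- density_surface(sites$x, sites$y, ...)
    singles <- stats::rpois(nrow(sites), frame_area * cone_gc_ratio * d_gc / 3)
    doubles <- stats::rpois(nrow(sites), frame_area * 2 * cone_gc_ratio * d_gc / 3)
    in_disc <- (sites$x - coexp_centre[1])^2 + (sites$y - coexp_centre[2])^2 <=
      coexp_radius^2
    sites$single_cone <- singles
    sites$sws1 <- singles   # every single cone is SWS1-positive
    sites$sws2b <- ifelse(in_disc,
                          stats::rbinom(nrow(sites), singles, coexp_fraction),
                          0L)
    sites$double_cone <- doubles
    sites$rh2_paired <- stats::rbinom(nrow(sites), doubles, pairing_rate)
    sites$lws <- stats::rbinom(nrow(sites), doubles, lws_rate)
    list(outline = outline,
         grid = count_grid(sites, frame_area, spacing^2))
  })
}

#' Default cone opsin expression means
#'
#' Mean cone-opsin proportions (fraction of total cone expression) used by
#' the cohort generator: SWS1 6.8%, SWS2B 0.7%, RH2B 49.2%, RH2A 42.0%,
#' LWS 1.3%.
#'
#' @return Named numeric vector on the simplex.
#' @export
default_cone_means <- function() {
  c(SWS1 = 0.068, SWS2B = 0.007, RH2B = 0.492, RH2A = 0.420, LWS = 0.013)
}

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = alpha), nrow = n, byrow = TRUE)
  x / rowSums(x)
}

#' Synthetic opsin expression cohort
#'
#' Per-individual cone proportions drawn Dirichlet around the configured
#' means; the rod fraction of total expression drawn Beta around its mean.
#' Proportions are converted to pseudo-counts (per-individual library size)
#' and sex/size labels are attached with no expression dependence.
#'
#' A single Dirichlet concentration cannot match every reported per-gene SD
#' simultaneously; the default is a compromise that brackets them.
#'
#' @param n Cohort size.
#' @param seed Integer seed.
#' @param cone_means Mean cone proportions (simplex).
#' @param concentration Dirichlet concentration (sum of alphas).
#' @param rod_mean Mean rod fraction of total expression.
#' @param rod_concentration Beta concentration for the rod fraction.
#' @param library_size Pseudo-count total per individual.
#' @return Data frame with columns individual, sex, size_cm, RH1 and the five
#'   cone genes.
#' @export
gen_expression_cohort <- function(n = 10, seed = 1,
                                  cone_means = default_cone_means(),
                                  concentration = 100,
                                  rod_mean = 0.503, rod_concentration = 16,
                                  library_size = 1e6) {
  if (any(cone_means < 0) || abs(sum(cone_means) - 1) > 1e-8) {
    stop("cone_means must lie on the simplex", call. = FALSE)
  }
  with_seed(seed, {
    props <- rdirichlet(n, concentration * cone_means)
    colnames(props) <- names(cone_means)
    rod <- stats::rbeta(n, rod_mean * rod_concentration,
                        (1 - rod_mean) * rod_concentration)
    counts <- props * (1 - rod) * library_size
    sexes <- sample(c("female", "male", "immature"), n, replace = TRUE,
                    prob = c(0.4, 0.2, 0.4))
    size <- round(stats::runif(n, 3, 9), 1)
    out <- data.frame(individual = sprintf("ind%02d", seq_len(n)),
                      sex = sexes, size_cm = size,
                      RH1 = rod * library_size)
    cbind(out, as.data.frame(counts))
  })
}

#' Synthetic microspectrophotometry absorbance record
#'
#' Template absorbance at the given lambda-max plus i.i.d. Gaussian noise,
#' clipped at zero (absorbance records are nonnegative).
#'
#' @param lambda_max Pigment lambda-max (nm).
#' @param noise_sd Gaussian noise SD on the peak-normalized scale.
#' @param seed Integer seed.
#' @param wl Wavelength grid (nm).
#' @return Absorbance [spec()].
#' @export
gen_msp_spectrum <- function(lambda_max, noise_sd = 0.02, seed = 1,
                             wl = spectral_grid()) {
  base <- template_absorbance(lambda_max, wl)
  with_seed(seed, {
    v <- pmax(0, base$value + stats::rnorm(length(wl), 0, noise_sd))
    spec(wl, v, "absorbance")
  })
}
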