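#' Eye geometry for acuity estimation
#'
#' @param lens_diameter_mm Lens diameter (mm), > 0.
#' @param matthiessen_ratio Focal length per lens radius; the teleost
#'   standard is 2.55.
#' @return An object of class `"eye_geometry"`.
#' @export
eye_geometry <- function(lens_diameter_mm, matthiessen_ratio = 2.55) {
  if (lens_diameter_mm <= 0) stop("lens diameter must be positive", call. = FALSE)
  if (matthiessen_ratio <= 0) stop("Matthiessen's ratio must be positive", call. = FALSE)
  structure(list(lens_diameter_mm = lens_diameter_mm,
                 matthiessen_ratio = matthiessen_ratio),
            class = "eye_geometry")
}

#' Spatial resolving power from peak ganglion-cell density
#'
#' Upper-limit visual acuity in cycles per degree, following the standard
#' peak-density method: focal length `f = matthiessen_ratio * lens_radius`;
#' retinal magnification `f * tan(1 deg)` mm per degree of visual angle;
#' linear cell spacing `sqrt(D)` cells/mm under a square-lattice assumption
#' (a hexagonal option `sqrt(2 D / sqrt(3))` is available); SRP = half the
#' cells subtended per degree, since one cycle needs two cells.
#'
#' @param peak_density Peak ganglion-cell density (cells/mm^2), > 0.
#' @param eye An [eye_geometry()] object.
#' @param lattice `"square"` (default) or `"hexagonal"` linear-density
#'   conversion.
#' @return List with `srp_cyc_deg`, `focal_length_mm`, `mm_per_degree`,
#'   `linear_density_cells_mm`.
#' @examples
#' srp(40400, eye_geometry(2.5))$srp_cyc_deg
#' @export
srp <- function(peak_density, eye, lattice = c("square", "hexagonal")) {
  lattice <- match.arg(lattice)
  if (!inherits(eye, "eye_geometry")) stop("eye must be an eye_geometry()", call. = FALSE)
  if (peak_density <= 0) stop("peak density must be positive", call. = FALSE)
  f <- eye$matthiessen_ratio * eye$lens_diameter_mm / 2
  mm_per_deg <- f * tan(pi / 180)
  lin <- switch(lattice,
                square = sqrt(peak_density),
                hexagonal = sqrt(2 * peak_density / sqrt(3)))
  list(srp_cyc_deg = mm_per_deg * lin / 2,
       focal_length_mm = f,
       mm_per_degree = mm_per_deg,
       linear_density_cells_mm = lin)
}

#' Detection distance for a target of known size
#'
#' Distance at which a target subtends one full resolvable cycle:
#' `d = size / tan((1 / srp) degrees)`. The reported distance is floored at
#' the requested decimal precision (whole metres for fish-sized targets, one
#' decimal for stripe-sized ones), the convention under which the published
#' distance chain (26, 16, 1.6, 1 m) is self-consistent.
#'
#' @param target_size_m Target extent (m), > 0.
#' @param srp_cyc_deg Spatial resolving power (cycles/degree), > 0.
#' @param digits Decimal places for the floored report (default 0).
#' @return List with `distance_m` (floored report) and `exact_m`.
#' @examples
#' detection_distance(0.08, 5.77)$distance_m   # 26
#' detection_distance(0.005, 5.77, digits = 1)$distance_m  # 1.6
#' @export
detection_distance <- function(target_size_m, srp_cyc_deg, digits = 0) {
  if (target_size_m <= 0 || srp_cyc_deg <= 0) {
    stop("target size and SRP must be positive", call. = FALSE)
  }
  d <- target_size_m / tan((1 / srp_cyc_deg) * pi / 180)
  scale <- 10^digits
  list(distance_m = floor(d * scale) / scale, exact_m = d)
}
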