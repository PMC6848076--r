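#' Evenly spaced spectral grid
#'
#' Builds the wavelength grid (nm) on which all modelling runs. The default
#' 300--800 nm at 1 nm covers the measured range of reef-fish ocular media and
#' resolves every lambda-max comparison the downstream models make.
#'
#' @param start_nm First wavelength (nm).
#' @param stop_nm Last wavelength (nm); must exceed `start_nm`.
#' @param step_nm Grid increment (nm); must be positive.
#' @return Numeric vector of wavelengths `start_nm, start_nm + step_nm, ...`.
#' @examples
#' wl <- spectral_grid()
#' range(wl)
#' @export
spectral_grid <- function(start_nm = 300, stop_nm = 800, step_nm = 1) {
  if (!is.numeric(start_nm) || !is.numeric(stop_nm) || !is.numeric(step_nm)) {
    stop("grid bounds and step must be numeric", call. = FALSE)
  }
  if (start_nm >= stop_nm) stop("start_nm must be < stop_nm", call. = FALSE)
  if (step_nm <= 0) stop("step_nm must be > 0", call. = FALSE)
  seq(start_nm, stop_nm, by = step_nm)
}

#' Spectrum kinds understood by the package
#' @keywords internal
spectrum_kinds <- c("reflectance", "irradiance", "radiance",
                    "transmission", "absorbance", "sensitivity")

#' Construct a spectrum
#'
#' A spectrum is a wavelength-indexed nonnegative function: the universal
#' currency of the optical modules (reflectance R(lambda), irradiance
#' I(lambda), lens transmission T(lambda), pigment absorbance, receptor
#' sensitivity).
#'
#' @param wl Numeric vector of wavelengths (nm), strictly increasing.
#' @param value Numeric vector of the same length, all values >= 0.
#' @param kind One of `r paste(spectrum_kinds, collapse = ", ")`.
#' @return An object of class `"spec"`: a data frame with columns `wl` and
#'   `value` and a `kind` attribute.
#' @examples
#' s <- spec(400:700, rep(0.1, 301), "reflectance")
#' @export
spec <- function(wl, value, kind = spectrum_kinds) {
  kind <- match.arg(kind)
  wl <- as.numeric(wl)
  value <- as.numeric(value)
  if (length(wl) != length(value)) {
    stop("wavelength and value vectors differ in length", call. = FALSE)
  }
  if (length(wl) < 1) stop("a spectrum needs at least one point", call. = FALSE)
  if (any(!is.finite(wl)) || any(!is.finite(value))) {
    stop("non-finite wavelength or value in spectrum", call. = FALSE)
  }
  if (any(diff(wl) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  neg <- which(value < 0)
  if (length(neg)) {
    stop(sprintf("negative value at row %d (wl = %g nm); measured spectra must be nonnegative",
                 neg[1], wl[neg[1]]), call. = FALSE)
  }
  structure(data.frame(wl = wl, value = value),
            kind = kind, class = c("spec", "data.frame"))
}

#' @export
print.spec <- function(x, ...) {
  cat(sprintf("<spectrum: %s, %d points, %g-%g nm>\n",
              attr(x, "kind"), nrow(x), min(x$wl), max(x$wl)))
  invisible(x)
}

#' Kind of a spectrum
#' @param s A `spec` object.
#' @return Character scalar.
#' @export
spec_kind <- function(s) attr(s, "kind")

assert_spec <- function(s, arg = deparse(substitute(s))) {
  if (!inherits(s, "spec")) {
    stop(sprintf("'%s' must be a spectrum built with spec()", arg), call. = FALSE)
  }
  invisible(s)
}

assert_same_grid <- function(s1, s2) {
  if (nrow(s1) != nrow(s2) || any(abs(s1$wl - s2$wl) > 1e-9)) {
    stop("spectra are not on the same wavelength grid; resample() first",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a spectrum from a two-column delimited file
#'
#' Accepts comma- or tab-separated files with columns (wavelength_nm, value),
#' an optional one-line header, and `#`-prefixed comment lines. Wavelengths
#' must be strictly increasing and values nonnegative; violations raise errors
#' rather than being silently repaired, so instrument artefacts surface.
#'
#' @param path Path to the file.
#' @param kind Spectrum kind (see [spec()]).
#' @return A [spec()] object on the file's native grid.
#' @seealso [write_spectrum()]
#' @export
read_spectrum <- function(path, kind = spectrum_kinds) {
  kind <- match.arg(kind)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("empty spectrum file: ", path, call. = FALSE)
  sep <- if (grepl("\t", lines[[1]])) "\t" else ","
  first <- strsplit(lines[[1]], sep, fixed = TRUE)[[1]]
  has_header <- suppressWarnings(any(is.na(as.numeric(first))))
  tab <- utils::read.table(text = lines, sep = sep, header = has_header,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expected two columns (wavelength_nm, value) in ", path,
                          call. = FALSE)
  wl <- as.numeric(tab[[1]])
  value <- as.numeric(tab[[2]])
  if (any(diff(wl) <= 0)) {
    stop("wavelengths not strictly increasing in ", path, call. = FALSE)
  }
  spec(wl, value, kind)
}

#' Write a spectrum to CSV
#'
#' Writes full double precision so a write/read round trip reproduces values
#' bit-exactly.
#'
#' @param s A `spec` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  assert_spec(s)
  lines <- c("wavelength_nm,value",
             sprintf("%s,%s",
                     formatC(s$wl, digits = 17, format = "g"),
                     formatC(s$value, digits = 17, format = "g")))
  writeLines(lines, path)
  invisible(path)
}

#' Resample a spectrum onto a new grid
#'
#' Linear interpolation; endpoints inside the source span are reproduced
#' exactly. Extrapolation is refused: spectral shapes outside the measured
#' span are unknown.
#'
#' @param s A `spec` object.
#' @param wl_out Target wavelengths (nm), e.g. from [spectral_grid()].
#' @return A `spec` on `wl_out`.
#' @export
resample <- function(s, wl_out) {
  assert_spec(s)
  wl_out <- as.numeric(wl_out)
  if (min(wl_out) < min(s$wl) - 1e-9 || max(wl_out) > max(s$wl) + 1e-9) {
    stop(sprintf("requested grid %g-%g nm extends beyond the measured span %g-%g nm",
                 min(wl_out), max(wl_out), min(s$wl), max(s$wl)), call. = FALSE)
  }
  v <- stats::approx(s$wl, s$value, xout = wl_out, rule = 1)$y
  spec(wl_out, v, spec_kind(s))
}

#' Normalize a spectrum at a reference wavelength
#'
#' Divides all values by the value at `lambda_ref`, so the returned spectrum
#' equals 1 there. Lens transmission curves are conventionally normalized at
#' 700 nm, where ocular media transmit fully.
#'
#' @param s A `spec` object.
#' @param lambda_ref Reference wavelength (nm); must be a grid point.
#' @return A `spec` with value 1 at `lambda_ref`, shape preserved.
#' @export
normalize_at <- function(s, lambda_ref = 700) {
  assert_spec(s)
  i <- which(abs(s$wl - lambda_ref) < 1e-9)
  if (!length(i)) {
    stop(sprintf("%g nm is not a grid point of the spectrum", lambda_ref),
         call. = FALSE)
  }
  ref <- s$value[i[1]]
  if (ref <= 0) {
    stop(sprintf("spectrum is zero at the reference wavelength %g nm", lambda_ref),
         call. = FALSE)
  }
  spec(s$wl, s$value / ref, spec_kind(s))
}

#' Lens transmission T50
#'
#' Finds the wavelength at which a (700 nm-normalized) transmission curve
#' reaches 50% of maximal transmittance. A line is fitted by ordinary least
#' squares to the contiguous run of points with normalized value in
#' \[0.2, 0.8\] around the rising limb and solved at 0.5; this makes the
#' estimate robust to single-point noise on steep curves. Lenses with
#' T50 < 400 nm are classified UV-transmitting, otherwise UV-blocking.
#'
#' If the curve crosses 0.5 on more than one rising limb, the
#' longest-wavelength rising crossing is used with a warning.
#'
#' @param s Transmission spectrum.
#' @param normalize Normalize at `lambda_ref` first (default TRUE).
#' @param lambda_ref Normalization wavelength (nm).
#' @return List with `t50_nm`, `uv_transmitting` (logical), `n_points` used in
#'   the regression.
#' @examples
#' wl <- spectral_grid()
#' tr <- spec(wl, 1 / (1 + exp(-(wl - 358) / 5)), "transmission")
#' t50(tr)$t50_nm
#' @export
t50 <- function(s, normalize = TRUE, lambda_ref = 700) {
  assert_spec(s)
  if (normalize) s <- normalize_at(s, lambda_ref)
  v <- s$value
  wl <- s$wl
  rising <- which(v[-length(v)] < 0.5 & v[-1] >= 0.5)
  if (!length(rising)) {
    stop("transmission curve never rises through 0.5; T50 undefined", call. = FALSE)
  }
  if (length(rising) > 1) {
    warning("multiple rising 0.5 crossings; using the longest-wavelength one")
  }
  cross <- rising[length(rising)]
  in_band <- v >= 0.2 & v <= 0.8
  # contiguous run of in-band points containing the crossing
  lo <- cross
  while (lo > 1 && in_band[lo - 1]) lo <- lo - 1
  hi <- cross + 1
  while (hi < length(v) && in_band[hi + 1]) hi <- hi + 1
  idx <- (lo:hi)[in_band[lo:hi]]
  if (length(idx) >= 2) {
    fit <- stats::lm(v[idx] ~ wl[idx])
    b <- stats::coef(fit)
    est <- (0.5 - b[[1]]) / b[[2]]
  } else {
    # limb steeper than the grid (e.g. a step): first point at or above 0.5
    est <- wl[cross + 1]
  }
  list(t50_nm = unname(est),
       uv_transmitting = unname(est) < 400,
       n_points = length(idx))
}

#' Trapezoidal integral of a spectrum
#' @param s A `spec` object.
#' @return Scalar integral over the grid.
#' @keywords internal
spec_integral <- function(s) {
  assert_spec(s)
  pracma::trapz(s$wl, s$value)
}
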