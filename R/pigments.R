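#' A1 visual pigment template constants
#'
#' Coefficients of the vitamin-A1 rhodopsin absorbance template of
#' Govardovskii et al. (2000): the alpha band in its log-inverse form plus a
#' Gaussian beta band whose position and width scale with lambda-max. The
#' constants are exposed so alternative templates can be configured.
#'
#' @return Named list of template coefficients.
#' @export
a1_template_constants <- function() {
  list(
    # alpha band: S(x) = 1 / (exp(A(a - x)) + exp(B(b - x)) + exp(C(c - x)) + D)
    # with x = lambda_max / lambda and a depending weakly on lambda_max
    A = 69.7, B = 28, C = -14.9, D = 0.674, b = 0.922, c = 1.104,
    # beta band: A_beta * exp(-((lambda - lambda_mbeta) / b_beta)^2)
    A_beta = 0.26,
    lambda_mbeta = function(lmax) 189 + 0.315 * lmax,
    b_beta = function(lmax) -40.5 + 0.195 * lmax
  )
}

#' Define a visual pigment
#'
#' @param name Opsin class label (e.g. SWS1, SWS2B, RH2B, RH2A, LWS, RH1).
#' @param lambda_max Wavelength of maximal absorbance (nm), in 330--620 nm.
#' @param chromophore Chromophore type; only "A1" is supported.
#' @return An object of class `"visual_pigment"`.
#' @examples
#' visual_pigment("RH2A", 520)
#' @export
visual_pigment <- function(name, lambda_max, chromophore = "A1") {
  chromophore <- match.arg(chromophore)
  if (!is.numeric(lambda_max) || lambda_max < 330 || lambda_max > 620) {
    stop("lambda_max must lie in 330-620 nm (template validity range)",
         call. = FALSE)
  }
  structure(list(name = name, lambda_max = lambda_max,
                 chromophore = chromophore),
            class = "visual_pigment")
}

#' @export
print.visual_pigment <- function(x, ...) {
  cat(sprintf("<visual pigment %s: lambda_max %g nm (%s)>\n",
              x$name, x$lambda_max, x$chromophore))
  invisible(x)
}

#' Template absorbance curve for a visual pigment
#'
#' Evaluates the A1 template (alpha + beta band) for a pigment of given
#' lambda-max on a wavelength grid and renormalizes to peak 1.
#'
#' @param pigment A [visual_pigment()] or a numeric lambda-max (nm).
#' @param wl Wavelength grid (nm); default [spectral_grid()].
#' @param constants Template constants; default [a1_template_constants()].
#' @return Peak-normalized absorbance [spec()].
#' @examples
#' ab <- template_absorbance(498)
#' ab$wl[which.max(ab$value)]
#' @export
template_absorbance <- function(pigment, wl = spectral_grid(),
                                constants = a1_template_constants()) {
  lmax <- if (inherits(pigment, "visual_pigment")) pigment$lambda_max
          else as.numeric(pigment)
  if (lmax < 330 || lmax > 620) {
    stop("lambda_max must lie in 330-620 nm (template validity range)",
         call. = FALSE)
  }
  k <- constants
  x <- lmax / wl
  a <- 0.8795 + 0.0459 * exp(-(lmax - 300)^2 / 11940)
  s_alpha <- 1 / (exp(k$A * (a - x)) + exp(k$B * (k$b - x)) +
                  exp(k$C * (k$c - x)) + k$D)
  s_beta <- k$A_beta * exp(-((wl - k$lambda_mbeta(lmax)) / k$b_beta(lmax))^2)
  v <- s_alpha + s_beta
  spec(wl, v / max(v), "absorbance")
}

#' Fit lambda-max to a measured absorbance spectrum
#'
#' Least-squares fit of the A1 template to a peak-normalized absorbance
#' measurement, searched on a 0.1 nm lattice over `search`. Ties are broken
#' toward the shorter wavelength. A best fit at the search boundary is
#' flagged: it usually means the search window misses the true peak.
#'
#' @param absorbance Absorbance [spec()] (any positive scale; it is
#'   peak-normalized internally).
#' @param search Length-2 search interval (nm) for lambda-max.
#' @param step Search lattice spacing (nm).
#' @return List with `lambda_max` (nm), `rss` (residual sum of squares of the
#'   peak-normalized fit) and `boundary` (logical).
#' @examples
#' est <- fit_lambda_max(template_absorbance(498), search = c(450, 550))
#' est$lambda_max
#' @export
fit_lambda_max <- function(absorbance, search = c(350, 570), step = 0.1) {
  assert_spec(absorbance)
  if (any(!is.finite(absorbance$value))) {
    stop("absorbance contains non-finite values", call. = FALSE)
  }
  if (length(search) != 2 || search[1] >= search[2]) {
    stop("search must be an increasing length-2 interval", call. = FALSE)
  }
  if (search[1] < 330 || search[2] > 620) {
    stop("search interval must lie within template validity (330-620 nm)",
         call. = FALSE)
  }
  m <- absorbance$value
  if (max(m) <= 0) stop("absorbance is identically zero", call. = FALSE)
  m <- m / max(m)
  cand <- seq(search[1], search[2], by = step)
  rss <- vapply(cand, function(l) {
    tv <- template_absorbance(l, absorbance$wl)$value
    sum((tv - m)^2)
  }, numeric(1))
  i <- which.min(rss)      # first minimum = shortest wavelength on ties
  boundary <- i == 1L || i == length(cand)
  if (boundary) {
    warning("best fit at the search boundary; widen the search interval")
  }
  list(lambda_max = cand[i], rss = rss[i], boundary = boundary)
}

#' Spectral tuning rule table
#'
#' Site-directed substitution effects used to estimate lambda-max from an
#' opsin amino-acid sequence: a reference opsin with known lambda-max plus
#' additive shifts for (site, variant residue) pairs. Residue numbering
#' follows the reference sequence's own numbering.
#'
#' @param reference_name Label of the reference opsin.
#' @param reference_lambda_max Reference lambda-max (nm).
#' @param rules Data frame with columns `site` (positive integer),
#'   `ref_residue`, `variant_residue` (single letters), `shift_nm` (finite).
#' @return An object of class `"tuning_rules"`.
#' @export
tuning_rules <- function(reference_name, reference_lambda_max, rules) {
  need <- c("site", "ref_residue", "variant_residue", "shift_nm")
  if (!all(need %in% names(rules))) {
    stop("rules must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(rules$site <= 0) || any(rules$site != round(rules$site))) {
    stop("rule sites must be positive integers", call. = FALSE)
  }
  if (any(!is.finite(rules$shift_nm))) stop("shifts must be finite", call. = FALSE)
  key <- paste(rules$site, rules$variant_residue)
  if (anyDuplicated(key)) {
    stop("rules must be keyed uniquely by (site, variant residue)", call. = FALSE)
  }
  structure(list(reference_name = reference_name,
                 reference_lambda_max = reference_lambda_max,
                 rules = rules),
            class = "tuning_rules")
}

#' Read a tuning rule table from CSV
#'
#' @param path CSV with columns site, ref_residue, variant_residue, shift_nm.
#' @param reference_name,reference_lambda_max Reference opsin label and
#'   lambda-max (nm).
#' @return A [tuning_rules()] object.
#' @export
read_tuning_rules <- function(path, reference_name, reference_lambda_max) {
  tuning_rules(reference_name, reference_lambda_max,
               utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Estimate lambda-max from amino-acid residues at tuning sites
#'
#' Adds the substitution shifts of all matched (site, variant) rules to the
#' reference lambda-max. Variants present in the query but not covered by any
#' rule contribute zero and are listed in the report; the per-rule
#' contributions are returned so disagreements between reference species can
#' be inspected.
#'
#' @param residues Named character vector: names are site numbers, values
#'   single-letter residues. Every rule site must be present.
#' @param rules A [tuning_rules()] object.
#' @return List with `lambda_max`, `matched` (data frame of applied rules) and
#'   `unmatched` (data frame of variant residues with no rule).
#' @examples
#' rt <- tuning_rules("ref", 511,
#'   data.frame(site = 122, ref_residue = "E", variant_residue = "Q",
#'              shift_nm = -15))
#' estimate_lambda_max_from_sequence(c("122" = "Q"), rt)$lambda_max
#' @export
estimate_lambda_max_from_sequence <- function(residues, rules) {
  if (!inherits(rules, "tuning_rules")) {
    stop("rules must be a tuning_rules() object", call. = FALSE)
  }
  tab <- rules$rules
  sites <- unique(tab$site)
  have <- as.integer(names(residues))
  missing_sites <- setdiff(sites, have)
  if (length(missing_sites)) {
    stop("query lacks residues for rule site(s): ",
         paste(missing_sites, collapse = ", "), call. = FALSE)
  }
  matched <- tab[0, ]
  unmatched <- data.frame(site = integer(), residue = character())
  for (s in sites) {
    q <- residues[[as.character(s)]]
    ref <- tab$ref_residue[tab$site == s][1]
    if (identical(q, ref)) next
    hit <- tab[tab$site == s & tab$variant_residue == q, ]
    if (nrow(hit)) {
      matched <- rbind(matched, hit)
    } else {
      unmatched <- rbind(unmatched, data.frame(site = s, residue = q))
    }
  }
  list(lambda_max = rules$reference_lambda_max + sum(matched$shift_nm),
       matched = matched, unmatched = unmatched)
}

#' Mix two coexpressed pigment absorbances
#'
#' Models opsin coexpression within one photoreceptor as a single effective
#' pigment: a convex combination of the two peak-normalized absorbance curves,
#' renormalized to peak 1. This matches the single intermediate lambda-max
#' that microspectrophotometry reads out from coexpressing cones.
#'
#' @param p1,p2 Peak-normalized absorbance spectra on the same grid.
#' @param fraction2 Proportion of the second pigment, in \[0, 1\].
#' @return Mixed, peak-normalized absorbance [spec()].
#' @export
mix_coexpressed <- function(p1, p2, fraction2) {
  assert_spec(p1); assert_spec(p2)
  assert_same_grid(p1, p2)
  if (!is.numeric(fraction2) || fraction2 < 0 || fraction2 > 1) {
    stop("fraction2 must lie in [0, 1]", call. = FALSE)
  }
  v <- (1 - fraction2) * p1$value + fraction2 * p2$value
  spec(p1$wl, v / max(v), "absorbance")
}

#' Receptor spectral sensitivity behind the ocular media
#'
#' Pointwise product of pigment absorbance and lens transmission. No
#' renormalization is applied: quantum-catch ratios absorb the overall scale.
#'
#' @param absorbance Pigment absorbance [spec()].
#' @param lens Lens transmission [spec()] on the same grid.
#' @return Sensitivity [spec()].
#' @export
receptor_sensitivity <- function(absorbance, lens) {
  assert_spec(absorbance); assert_spec(lens)
  assert_same_grid(absorbance, lens)
  spec(absorbance$wl, absorbance$value * lens$value, "sensitivity")
}
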