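#' Retina outline polygon
#'
#' Coordinate frame: millimetres, +x temporal, +y dorsal (ventral is -y),
#' origin near the outline centroid. The polygon is closed automatically if
#' the last vertex differs from the first.
#'
#' @param x,y Vertex coordinates (mm).
#' @return An object of class `"retina_outline"` with fields `x`, `y`
#'   (closed ring) and `area` (mm^2).
#' @export
retina_outline <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("an outline needs at least 3 vertices", call. = FALSE)
  }
  if (x[1] != x[length(x)] || y[1] != y[length(y)]) {
    x <- c(x, x[1]); y <- c(y, y[1])
  }
  n <- length(x) - 1
  area <- abs(sum(x[1:n] * y[2:(n + 1)] - x[2:(n + 1)] * y[1:n])) / 2
  if (area <= 0) stop("outline polygon has zero area", call. = FALSE)
  structure(list(x = x, y = y, area = area), class = "retina_outline")
}

#' Read a retina outline from a CSV vertex list
#' @param path CSV with columns x_mm, y_mm (or x, y).
#' @return A [retina_outline()].
#' @export
read_outline <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(tab) <- sub("_mm$", "", names(tab))
  retina_outline(tab$x, tab$y)
}

#' Test whether points fall inside a retina outline
#' @param outline A [retina_outline()].
#' @param x,y Point coordinates (mm).
#' @return Logical vector.
#' @export
in_outline <- function(outline, x, y) {
  bnd <- cbind(outline$x, outline$y)
  mgcv::in.out(bnd, cbind(as.numeric(x), as.numeric(y)))
}

points_in_outline <- function(outline, x, y) in_outline(outline, x, y)

#' Counting-frame site grid
#'
#' Systematically sampled counting-frame counts: at each site (x, y) a frame
#' of area `frame_area` is counted for one or more cell classes; sites tile
#' the retina on a grid of cell area `grid_cell_area`, so each site stands
#' for `grid_cell_area / frame_area` times its count.
#'
#' @param sites Data frame with columns `x`, `y` (mm) and one nonnegative
#'   integer count column per cell class.
#' @param frame_area Counting frame area a (mm^2), > 0.
#' @param grid_cell_area Sampling grid cell area A (mm^2), >= `frame_area`.
#' @return An object of class `"count_grid"`.
#' @export
count_grid <- function(sites, frame_area, grid_cell_area) {
  if (!all(c("x", "y") %in% names(sites))) {
    stop("sites must have x and y columns", call. = FALSE)
  }
  if (frame_area <= 0) stop("frame_area must be positive", call. = FALSE)
  if (frame_area > grid_cell_area) {
    stop("frame_area cannot exceed grid_cell_area", call. = FALSE)
  }
  classes <- setdiff(names(sites), c("x", "y"))
  if (!length(classes)) stop("sites must carry at least one count column", call. = FALSE)
  for (cl in classes) {
    v <- sites[[cl]]
    if (any(v < 0) || any(v != round(v))) {
      stop(sprintf("counts for class '%s' must be nonnegative integers", cl),
           call. = FALSE)
    }
  }
  structure(list(sites = sites, frame_area = frame_area,
                 grid_cell_area = grid_cell_area, classes = classes),
            class = "count_grid")
}

grid_class_counts <- function(g, class) {
  if (!class %in% g$classes) {
    stop(sprintf("class '%s' not present in count grid (have: %s)",
                 class, paste(g$classes, collapse = ", ")), call. = FALSE)
  }
  g$sites[[class]]
}

#' Cell density at a counting site
#' @param count Frame count(s).
#' @param frame_area Frame area (mm^2), > 0.
#' @return Density in cells/mm^2.
#' @export
site_density <- function(count, frame_area) {
  if (frame_area <= 0) stop("frame_area must be positive", call. = FALSE)
  count / frame_area
}

#' Optical-fractionator total cell estimate
#'
#' Design-based estimate of the total cell number over the sampled region:
#' `N = sum(Q) * (A / a)`, the summed frame counts scaled by the inverse
#' areal sampling fraction. (Wholemount counting: the thickness sampling
#' fraction is 1.)
#'
#' @param g A [count_grid()].
#' @param class Cell class to total.
#' @return Estimated total cell count.
#' @export
fractionator_total <- function(g, class) {
  q <- grid_class_counts(g, class)
  sum(q) * g$grid_cell_area / g$frame_area
}

#' Coefficient of error of a fractionator estimate
#'
#' Relative standard error of the mean per-site count:
#' `CE = (sd(q) / sqrt(n)) / mean(q)`. Zero for uniform counts and
#' proportional to `1/sqrt(n)` under site replication. (Scheaffer-type
#' estimators differ in detail; this form is documented as replaceable.)
#'
#' @param g A [count_grid()].
#' @param class Cell class.
#' @return CE, a nonnegative scalar.
#' @export
scheaffer_ce <- function(g, class) {
  q <- grid_class_counts(g, class)
  if (length(q) < 2) stop("CE needs at least 2 sites", call. = FALSE)
  if (mean(q) == 0) stop("mean site count is zero; CE undefined", call. = FALSE)
  (stats::sd(q) / sqrt(length(q))) / mean(q)
}

#' Gaussian-kernel topographic density map
#'
#' Smooths site densities into a raster of cells/mm^2 clipped to the retina
#' outline. Each site contributes the `q_i * (A / a)` cells it stands for as
#' a Gaussian mass of standard deviation `sigma`, renormalized by the kernel
#' mass falling inside the outline so rim sites are not underestimated
#' (edge correction). The area-weighted mean of the map therefore matches
#' the mean site density when the sites tile the outline.
#'
#' @param g A [count_grid()]; sites outside the outline are dropped with a
#'   warning.
#' @param outline A [retina_outline()].
#' @param class Cell class to map.
#' @param sigma Kernel standard deviation (mm); default the sampling grid
#'   spacing `sqrt(A)`, matching the convention of adjusting the smoother to
#'   the grid size.
#' @param step Raster spacing (mm); default `sigma / 4`, must not exceed
#'   `sigma`.
#' @return An object of class `"density_map"`: raster vectors `x`, `y`,
#'   density matrix `z` (rows = x, cols = y; NA outside the outline), logical
#'   `mask`, `sigma`, `step`, `class` and `peak` (from [find_peak()]).
#' @export
kernel_map <- function(g, outline, class, sigma = sqrt(g$grid_cell_area),
                       step = sigma / 4) {
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (step > sigma) stop("raster step must not exceed sigma", call. = FALSE)
  q <- grid_class_counts(g, class)
  sx <- g$sites$x; sy <- g$sites$y
  inside <- points_in_outline(outline, sx, sy)
  if (!any(inside)) stop("no counting sites inside the outline", call. = FALSE)
  if (!all(inside)) {
    warning(sprintf("%d site(s) outside the outline dropped", sum(!inside)))
    sx <- sx[inside]; sy <- sy[inside]; q <- q[inside]
  }
  xs <- seq(min(outline$x), max(outline$x), by = step)
  ys <- seq(min(outline$y), max(outline$y), by = step)
  gridpts <- expand.grid(x = xs, y = ys)
  mask <- matrix(points_in_outline(outline, gridpts$x, gridpts$y),
                 nrow = length(xs))
  z <- matrix(0, nrow = length(xs), ncol = length(ys))
  X <- matrix(xs, nrow = length(xs), ncol = length(ys))
  Y <- matrix(ys, nrow = length(xs), ncol = length(ys), byrow = TRUE)
  cells_per_site <- q / g$frame_area * g$grid_cell_area
  for (i in seq_along(q)) {
    phi <- exp(-((X - sx[i])^2 + (Y - sy[i])^2) / (2 * sigma^2)) /
      (2 * pi * sigma^2)
    m_i <- sum(phi[mask]) * step^2   # kernel mass retained inside the outline
    if (m_i <= 0) next
    z <- z + cells_per_site[i] * phi / m_i
  }
  z[!mask] <- NA_real_
  m <- structure(list(x = xs, y = ys, z = z, mask = mask, sigma = sigma,
                      step = step, class = class, peak = NULL),
                 class = "density_map")
  m$peak <- find_peak(m)
  m
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density map: %s, %dx%d raster, sigma %.3g mm, peak %.0f cells/mm^2 at (%.2f, %.2f)>\n",
              x$class, length(x$x), length(x$y), x$sigma,
              x$peak$density, x$peak$x, x$peak$y))
  invisible(x)
}

#' Peak of a density map
#'
#' Argmax over the masked raster. Ties (e.g. flat maps) are resolved toward
#' the cell nearest the mask centroid, then lexicographically by (x, y), with
#' a warning.
#'
#' @param m A [density_map()][kernel_map].
#' @return List with `x`, `y` (mm) and `density` (cells/mm^2).
#' @export
find_peak <- function(m) {
  zmax <- max(m$z, na.rm = TRUE)
  hits <- which(!is.na(m$z) & abs(m$z - zmax) < 1e-9 * max(1, abs(zmax)),
                arr.ind = TRUE)
  if (nrow(hits) > 1) {
    warning("density peak is tied; breaking toward the mask centroid")
    cx <- mean(m$x[row(m$mask)[m$mask]])
    cy <- mean(m$y[col(m$mask)[m$mask]])
    px <- m$x[hits[, 1]]; py <- m$y[hits[, 2]]
    d2 <- (px - cx)^2 + (py - cy)^2
    ord <- order(d2, px, py)
    hits <- hits[ord[1], , drop = FALSE]
  }
  list(x = m$x[hits[1, 1]], y = m$y[hits[1, 2]], density = zmax)
}

#' Cellwise ratio of two density maps
#'
#' @param m1,m2 Density maps on identical rasters.
#' @param floor Denominator floor (cells/mm^2); cells where `m2 <= floor`
#'   are masked out.
#' @return A density map of ratios (dimensionless).
#' @export
ratio_map <- function(m1, m2, floor = 0) {
  if (length(m1$x) != length(m2$x) || length(m1$y) != length(m2$y) ||
      any(abs(m1$x - m2$x) > 1e-9) || any(abs(m1$y - m2$y) > 1e-9)) {
    stop("density maps are not on the same raster", call. = FALSE)
  }
  z <- m1$z / m2$z
  z[!is.na(m2$z) & m2$z <= floor] <- NA_real_
  out <- m1
  out$z <- z
  out$class <- paste0(m1$class, "/", m2$class)
  out$peak <- find_peak(out)
  out
}

#' Ideal cone mosaic lattice
#'
#' Builds the periodic square mosaic in which every single cone is surrounded
#' by four double cones: each unit cell holds one single cone (cell centre)
#' and two double cones (two edge midpoints), giving a double:single ratio of
#' exactly 2 at every size.
#'
#' @param n_rows,n_cols Number of unit cells in each direction (>= 2).
#' @param spacing Unit-cell edge length (arbitrary units).
#' @return List with `positions` (data frame `x`, `y`, `type`), `n_single`,
#'   `n_double`, `ratio`, `n_rows`, `n_cols`, `spacing`.
#' @export
mosaic_lattice <- function(n_rows, n_cols, spacing = 1) {
  if (n_rows < 2 || n_cols < 2) stop("need at least 2x2 unit cells", call. = FALSE)
  ij <- expand.grid(i = seq_len(n_cols) - 1, j = seq_len(n_rows) - 1)
  singles <- data.frame(x = (ij$i + 0.5) * spacing, y = (ij$j + 0.5) * spacing,
                        type = "single")
  doubles <- rbind(
    data.frame(x = (ij$i + 0.5) * spacing, y = ij$j * spacing, type = "double"),
    data.frame(x = ij$i * spacing, y = (ij$j + 0.5) * spacing, type = "double"))
  pos <- rbind(singles, doubles)
  list(positions = pos,
       n_single = nrow(singles), n_double = nrow(doubles),
       ratio = nrow(doubles) / nrow(singles),
       n_rows = n_rows, n_cols = n_cols, spacing = spacing)
}

#' Audit the nearest neighbours of each single cone in a mosaic
#'
#' Checks, under periodic boundaries, that every single cone's four nearest
#' neighbours are double cones at half the unit-cell spacing.
#'
#' @param lattice A [mosaic_lattice()].
#' @return TRUE if the audit passes; otherwise an error is raised.
#' @export
mosaic_neighbour_audit <- function(lattice) {
  pos <- lattice$positions
  s <- pos[pos$type == "single", ]
  d <- pos[pos$type == "double", ]
  wx <- lattice$n_cols * lattice$spacing
  wy <- lattice$n_rows * lattice$spacing
  for (i in seq_len(nrow(s))) {
    dx <- abs(d$x - s$x[i]); dx <- pmin(dx, wx - dx)
    dy <- abs(d$y - s$y[i]); dy <- pmin(dy, wy - dy)
    dist <- sqrt(dx^2 + dy^2)
    nn <- sort(dist)[1:4]
    if (any(abs(nn - lattice$spacing / 2) > 1e-9)) {
      stop("single cone without four double-cone nearest neighbours at half spacing",
           call. = FALSE)
    }
  }
  TRUE
}

#' Opsin label proportions from FISH channel counts
#'
#' Per-site and pooled fractions from in-situ channel counts: the fraction of
#' double cones with the RH2A/RH2B paired arrangement, the fraction of single
#' cones coexpressing SWS2B with SWS1, and the LWS fraction of double cones,
#' for whichever (numerator, denominator) channel pairs are present. Sites
#' with a zero denominator are skipped for that metric with a warning.
#' Pooled fractions are count-weighted and carry exact binomial 95%
#' confidence intervals.
#'
#' @param g A [count_grid()] with FISH channels (e.g. `single_cone`, `sws1`,
#'   `sws2b`, `double_cone`, `rh2_paired`, `lws`).
#' @param metrics Named list mapping metric name to `c(numerator_class,
#'   denominator_class)`; the default covers the standard channels present.
#' @return List with `per_site` (data frame site, metric, fraction) and
#'   `pooled` (data frame metric, numerator, denominator, fraction, ci_lo,
#'   ci_hi).
#' @export
fish_proportions <- function(g, metrics = NULL) {
  if (is.null(metrics)) {
    all_metrics <- list(
      sws1_of_single = c("sws1", "single_cone"),
      sws2b_coexpression = c("sws2b", "single_cone"),
      rh2_pairing = c("rh2_paired", "double_cone"),
      lws_of_double = c("lws", "double_cone"))
    metrics <- Filter(function(m) all(m %in% g$classes), all_metrics)
  }
  if (!length(metrics)) stop("no usable FISH channel pairs found", call. = FALSE)
  per_site <- list(); pooled <- list()
  for (nm in names(metrics)) {
    num <- grid_class_counts(g, metrics[[nm]][1])
    den <- grid_class_counts(g, metrics[[nm]][2])
    ok <- den > 0
    if (!all(ok)) {
      warning(sprintf("%d site(s) with zero '%s' skipped for %s",
                      sum(!ok), metrics[[nm]][2], nm))
    }
    if (any(num[ok] > den[ok])) {
      stop(sprintf("numerator exceeds denominator for %s", nm), call. = FALSE)
    }
    per_site[[nm]] <- data.frame(site = which(ok), metric = nm,
                                 fraction = num[ok] / den[ok])
    ci <- stats::binom.test(sum(num[ok]), sum(den[ok]))$conf.int
    pooled[[nm]] <- data.frame(metric = nm, numerator = sum(num[ok]),
                               denominator = sum(den[ok]),
                               fraction = sum(num[ok]) / sum(den[ok]),
                               ci_lo = ci[1], ci_hi = ci[2])
  }
  list(per_site = do.call(rbind, per_site),
       pooled = do.call(rbind, pooled))
}

# 4-neighbour connected components of a logical matrix; returns an integer
# label matrix (0 = background)
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    nr <- nrow(mask)
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- (cur - 1L) %% nr + 1L
      j <- (cur - 1L) %/% nr + 1L
      for (nb in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))) {
        if (nb[1] >= 1L && nb[1] <= nr && nb[2] >= 1L && nb[2] <= ncol(mask)) {
          k <- (nb[2] - 1L) * nr + nb[1]
          if (mask[k] && lab[k] == 0L) {
            lab[k] <- nxt
            queue <- c(queue, k)
          }
        }
      }
    }
  }
  lab
}

#' Detect a coexpression region
#'
#' Smooths the coexpressing and total counts of a channel pair with the same
#' Gaussian kernel, forms their ratio (a smoothed coexpression fraction over
#' the outline raster), thresholds it, and extracts the largest 4-connected
#' component. Reports the component's centroid in the temporal/ventral
#' coordinate frame, its area, and its peak fraction.
#'
#' @param g A [count_grid()] with the two channels.
#' @param outline A [retina_outline()].
#' @param num_class,den_class Numerator (coexpressing) and denominator
#'   (total) channel names; defaults `"sws2b"` over `"single_cone"`.
#' @param threshold Fraction threshold in \[0, 1\]; half the plateau
#'   coexpression fraction recovers the disc boundary under symmetric
#'   smoothing.
#' @param sigma,step Kernel and raster parameters. Unlike [kernel_map()],
#'   the default bandwidth is 0.7 of the site spacing: the fraction field is
#'   a ratio of two smoothed counts whose edge effects cancel, so a narrower
#'   kernel lowers boundary bias without the rim artefacts density maps
#'   would suffer.
#' @return List with `found` (logical) and, when found, `centroid_x`,
#'   `centroid_y` (mm), `area_mm2`, `peak_fraction`, `peak_x`, `peak_y`, and
#'   the raster `fraction` map (matrix with NA outside the outline).
#' @export
coexpression_region <- function(g, outline, num_class = "sws2b",
                                den_class = "single_cone", threshold = 0.25,
                                sigma = 0.7 * sqrt(g$grid_cell_area),
                                step = sigma / 4) {
  num <- grid_class_counts(g, num_class)
  den <- grid_class_counts(g, den_class)
  sx <- g$sites$x; sy <- g$sites$y
  inside <- points_in_outline(outline, sx, sy)
  if (!any(inside)) stop("no counting sites inside the outline", call. = FALSE)
  sx <- sx[inside]; sy <- sy[inside]
  num <- num[inside]; den <- den[inside]
  xs <- seq(min(outline$x), max(outline$x), by = step)
  ys <- seq(min(outline$y), max(outline$y), by = step)
  gridpts <- expand.grid(x = xs, y = ys)
  mask <- matrix(points_in_outline(outline, gridpts$x, gridpts$y),
                 nrow = length(xs))
  X <- matrix(xs, nrow = length(xs), ncol = length(ys))
  Y <- matrix(ys, nrow = length(xs), ncol = length(ys), byrow = TRUE)
  zn <- matrix(0, length(xs), length(ys))
  zd <- zn
  for (i in seq_along(num)) {
    phi <- exp(-((X - sx[i])^2 + (Y - sy[i])^2) / (2 * sigma^2))
    zn <- zn + num[i] * phi
    zd <- zd + den[i] * phi
  }
  frac <- ifelse(zd > 0, zn / zd, 0)
  frac[!mask] <- NA_real_
  hit <- !is.na(frac) & frac >= threshold & zd > 0
  if (!any(hit)) {
    return(list(found = FALSE, fraction = frac))
  }
  lab <- label_components(hit)
  sizes <- tabulate(lab[lab > 0])
  main <- which.max(sizes)
  region <- lab == main
  cx <- mean(X[region]); cy <- mean(Y[region])
  pk <- which(region & frac == max(frac[region]), arr.ind = TRUE)[1, , drop = TRUE]
  list(found = TRUE,
       centroid_x = cx, centroid_y = cy,
       area_mm2 = sum(region) * step^2,
       peak_fraction = max(frac[region]),
       peak_x = xs[pk[1]], peak_y = ys[pk[2]],
       fraction = frac)
}

#' Write a density map to CSV with a JSON sidecar
#'
#' @param m A density map.
#' @param path Output CSV path (long format x, y, density); a `.json` sidecar
#'   with sigma, step, class and peak is written alongside.
#' @return `path`, invisibly.
#' @export
write_density_map <- function(m, path) {
  long <- expand.grid(x = m$x, y = m$y)
  long$density <- as.vector(m$z)
  long <- long[!is.na(long$density), ]
  utils::write.csv(long, path, row.names = FALSE)
  side <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(list(class = m$class, sigma = m$sigma, step = m$step,
                            peak = m$peak),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
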