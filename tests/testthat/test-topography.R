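make_square_grid <- function(counts, frame_area = 0.01, cell_area = 1,
                             class = "ganglion") {
  n <- length(counts)
  side <- ceiling(sqrt(n))
  sites <- expand.grid(x = seq_len(side) - 0.5, y = seq_len(side) - 0.5)[1:n, ]
  sites[[class]] <- counts
  count_grid(sites, frame_area, cell_area)
}

test_that("site density and fractionator totals follow the sampling arithmetic", {
  expect_equal(site_density(10, 0.01), 1000)
  expect_equal(site_density(0, 0.01), 0)
  expect_equal(site_density(2 * 7, 0.01), 2 * site_density(7, 0.01))

  g <- make_square_grid(rep(10, 4))
  expect_equal(fractionator_total(g, "ganglion"), 40 * 100)
  g2 <- make_square_grid(rep(20, 4))
  expect_equal(fractionator_total(g2, "ganglion"),
               2 * fractionator_total(g, "ganglion"))
  expect_error(fractionator_total(g, "amacrine"), "not present")
  expect_error(count_grid(data.frame(x = 1, y = 1, gc = -1), 0.01, 1),
               "nonnegative")
  expect_error(count_grid(data.frame(x = 1, y = 1, gc = 1), 2, 1),
               "exceed")
})

test_that("the error coefficient is the relative SEM of site counts", {
  expect_equal(scheaffer_ce(make_square_grid(c(5, 5, 5, 5)), "ganglion"), 0)
  # hand-checked: sd(0,10) = 7.071, SEM = 5, mean = 5
  expect_equal(scheaffer_ce(make_square_grid(c(0, 10)), "ganglion"), 1.0)
  # ~1/sqrt(n) under site replication
  ce100 <- scheaffer_ce(make_square_grid(rep(c(0, 10), 50)), "ganglion")
  ce400 <- scheaffer_ce(make_square_grid(rep(c(0, 10), 200)), "ganglion")
  expect_equal(ce100 / ce400, 2, tolerance = 0.01)
  expect_error(scheaffer_ce(make_square_grid(5), "ganglion"), "2 sites")
})

test_that("kernel maps place mass at the sites and conserve mean density", {
  outline <- retina_outline(c(-2, 2, 2, -2), c(-2, -2, 2, 2))
  # single site: unimodal with the maximum at the site
  g1 <- count_grid(data.frame(x = 0.5, y = -0.4, gc = 20), 0.01, 1)
  m1 <- kernel_map(g1, outline, "gc", sigma = 0.5, step = 0.1)
  expect_equal(m1$peak$x, 0.5, tolerance = 0.05)
  expect_equal(m1$peak$y, -0.4, tolerance = 0.05)
  # two well-separated equal sites: two equal local maxima
  g2 <- count_grid(data.frame(x = c(-1.2, 1.2), y = c(0, 0), gc = c(20, 20)),
                   0.01, 1)
  m2 <- kernel_map(g2, outline, "gc", sigma = 0.3, step = 0.1)
  at <- function(x, y) m2$z[which.min(abs(m2$x - x)), which.min(abs(m2$y - y))]
  expect_equal(at(-1.2, 0), at(1.2, 0), tolerance = 0.01)
  expect_gt(at(-1.2, 0), at(0, 0))
  expect_error(kernel_map(g1, outline, "gc", sigma = 0.1, step = 0.2), "step")
  far <- count_grid(data.frame(x = 50, y = 50, gc = 1), 0.01, 1)
  expect_error(kernel_map(far, outline, "gc"), "no counting sites")
})

test_that("kernel map mean density matches mean site density and bounds the peak", {
  rc <- gen_retina_counts(seed = 21)
  m <- kernel_map(rc$grid, rc$outline, "ganglion")
  map_mean <- mean(m$z, na.rm = TRUE)
  site_mean <- mean(rc$grid$sites$ganglion) / rc$grid$frame_area
  expect_lt(abs(map_mean - site_mean) / site_mean, 0.05)
  # smoothing cannot overshoot the densest site when sigma >= site spacing
  max_site <- max(rc$grid$sites$ganglion) / rc$grid$frame_area
  expect_lt(m$peak$density, max_site * 1.05)
})

test_that("maps and peaks rotate with the coordinate frame", {
  rc <- gen_retina_counts(seed = 33)
  m <- kernel_map(rc$grid, rc$outline, "ganglion")
  rot <- rc$grid$sites
  rot_x <- -rot$y; rot_y <- rot$x   # rigid 90-degree rotation
  rot$x <- rot_x; rot$y <- rot_y
  g_rot <- count_grid(rot, rc$grid$frame_area, rc$grid$grid_cell_area)
  out_rot <- retina_outline(-rc$outline$y, rc$outline$x)
  m_rot <- kernel_map(g_rot, out_rot, "ganglion")
  expect_equal(fractionator_total(g_rot, "ganglion"),
               fractionator_total(rc$grid, "ganglion"))
  expect_equal(m_rot$peak$density, m$peak$density, tolerance = 0.02)
  expect_equal(c(m_rot$peak$x, m_rot$peak$y), c(-m$peak$y, m$peak$x),
               tolerance = 0.26)
})

test_that("find_peak breaks ties toward the mask centroid", {
  outline <- retina_outline(c(-1, 1, 1, -1), c(-1, -1, 1, 1))
  g <- count_grid(data.frame(x = 0.2, y = 0.2, gc = 10), 0.01, 1)
  m <- kernel_map(g, outline, "gc", sigma = 0.5, step = 0.25)
  flat <- m
  flat$z[flat$mask] <- 1  # force a flat map
  expect_warning(pk <- find_peak(flat), "tied")
  expect_lt(abs(pk$x), 0.26)
  expect_lt(abs(pk$y), 0.26)
})

test_that("ratio maps divide cellwise and propagate the mask", {
  outline <- retina_outline(c(-2, 2, 2, -2), c(-2, -2, 2, 2))
  sites <- expand.grid(x = seq(-1.5, 1.5, 0.5), y = seq(-1.5, 1.5, 0.5))
  sites$cone <- 40L
  sites$gc <- 20L
  g <- count_grid(sites, 0.01, 0.25)
  mc <- kernel_map(g, outline, "cone", sigma = 0.5, step = 0.25)
  mg <- kernel_map(g, outline, "gc", sigma = 0.5, step = 0.25)
  expect_warning(r <- ratio_map(mc, mg), "tied")  # constant ratio -> flat peak
  expect_equal(mean(r$z, na.rm = TRUE), 2, tolerance = 1e-6)
  expect_identical(is.na(r$z), is.na(mg$z))
  expect_error(ratio_map(mc, kernel_map(g, outline, "gc", sigma = 0.5, step = 0.2)),
               "raster")
})

test_that("synthetic cone and ganglion surfaces recover the configured ratio", {
  rc <- gen_retina_counts(seed = 8, cone_gc_ratio = 2)
  mc <- kernel_map(rc$grid, rc$outline, "total_cone")
  mg <- kernel_map(rc$grid, rc$outline, "ganglion")
  r <- ratio_map(mc, mg, floor = 100)
  expect_equal(mean(r$z, na.rm = TRUE), 2, tolerance = 0.05)
})

test_that("the ideal cone mosaic has a 2:1 double:single ratio at any size", {
  for (dims in list(c(2, 3), c(10, 10), c(7, 13))) {
    lat <- mosaic_lattice(dims[1], dims[2])
    expect_identical(lat$ratio, 2)
    expect_identical(lat$n_double, 2L * lat$n_single)
    expect_true(mosaic_neighbour_audit(lat))
  }
  lat <- mosaic_lattice(10, 10)
  expect_identical(lat$n_single, 100L)
  expect_identical(lat$n_double, 200L)
  expect_error(mosaic_lattice(1, 5), "at least")
})

test_that("FISH proportions pool site fractions with their counts", {
  sites <- data.frame(x = c(0, 1), y = c(0, 0),
                      single_cone = c(10L, 20L), sws1 = c(10L, 20L),
                      sws2b = c(3L, 0L),
                      double_cone = c(100L, 50L), rh2_paired = c(99L, 50L),
                      lws = c(1L, 0L))
  g <- count_grid(sites, 0.01, 1)
  fp <- fish_proportions(g)
  pooled <- fp$pooled
  expect_equal(pooled$fraction[pooled$metric == "rh2_pairing"], 149 / 150)
  per <- fp$per_site
  expect_equal(per$fraction[per$metric == "rh2_pairing" & per$site == 1], 0.99)
  expect_equal(per$fraction[per$metric == "sws2b_coexpression" & per$site == 1], 0.3)
  # pooled fraction equals the count-weighted mean of site fractions
  w <- sites$double_cone / sum(sites$double_cone)
  expect_equal(pooled$fraction[pooled$metric == "rh2_pairing"],
               sum(w * sites$rh2_paired / sites$double_cone))
  # zero denominators are skipped with a warning
  sites0 <- rbind(sites, data.frame(x = 2, y = 0, single_cone = 0L, sws1 = 0L,
                                    sws2b = 0L, double_cone = 0L,
                                    rh2_paired = 0L, lws = 0L))
  w <- capture_warnings(fp0 <- fish_proportions(count_grid(sites0, 0.01, 1)))
  expect_true(all(grepl("skipped", w)))
  expect_equal(fp0$pooled, fp$pooled)  # skipped sites contribute nothing
})

test_that("coexpression region handles the empty and the saturating threshold", {
  fc <- gen_fish_counts(seed = 2, coexp_fraction = 0)
  none <- coexpression_region(fc$grid, fc$outline)
  expect_false(none$found)
  fc2 <- gen_fish_counts(seed = 2)
  all_of_it <- coexpression_region(fc2$grid, fc2$outline, threshold = 0)
  expect_true(all_of_it$found)
  expect_equal(all_of_it$area_mm2, fc2$outline$area, tolerance = 0.05)
})

test_that("coexpression region recovers a constructed temporal disc", {
  fc <- gen_fish_counts(seed = 4, spacing = 0.25, coexp_radius = 0.5,
                        coexp_centre = c(2.6, 0), coexp_fraction = 0.5)
  reg <- coexpression_region(fc$grid, fc$outline)
  expect_true(reg$found)
  expect_lt(sqrt((reg$centroid_x - 2.6)^2 + reg$centroid_y^2), 0.25)
  expect_lt(abs(reg$area_mm2 - pi * 0.5^2) / (pi * 0.5^2), 0.3)
  expect_gt(reg$peak_fraction, 0.3)
})
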