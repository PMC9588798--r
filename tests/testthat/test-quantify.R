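test_that("3D Gaussian smoothing preserves constants, mass, and cuts noise", {
  const <- density_map(array(3.7, c(15, 15, 15)), voxel = 1)
  expect_lt(max(abs(smooth_map(const, 3)$values - 3.7)), 1e-10)
  expect_identical(smooth_map(const, 0), const)
  expect_error(smooth_map(const, -1), ">= 0")
  # impulse response: a centred spike becomes a 3D Gaussian of the stated
  # width with its sum preserved
  v <- array(0, c(31, 31, 31)); v[16, 16, 16] <- 1
  imp <- smooth_map(density_map(v, 1), 3)
  expect_equal(sum(imp$values), 1, tolerance = 1e-6)
  x <- (-15):15
  g1 <- exp(-x^2 / 18); g1 <- g1 / sum(g1)
  expected <- outer(g1, outer(g1, g1))
  expect_lt(max(abs(imp$values - expected)), 1e-6)
  # white noise loses variance
  set.seed(9)
  noise <- density_map(array(rnorm(30^3), c(30, 30, 30)), 1)
  expect_lt(stats::var(as.numeric(smooth_map(noise, 3)$values)),
            stats::var(as.numeric(noise$values)))
})

test_that("8-bit conversion follows the min-max rescale with round-half-up", {
  sec <- structure(list(image = matrix(c(0, 1, 1, 0), 2), s = 0:1, t = 0:1,
                        pixel = 1, point = c(0, 0, 0),
                        u = c(1, 0, 0), v = c(0, 1, 0)),
                   class = "cross_section")
  expect_equal(as.numeric(to_8bit(sec)$image), c(0, 255, 255, 0))
  sec$image <- matrix(5, 2, 2)
  expect_equal(as.numeric(to_8bit(sec)$image), rep(0, 4))
  sec$image <- matrix(c(0, 0.5, 1, 1), 2)
  expect_equal(sort(unique(as.numeric(to_8bit(sec)$image))), c(0, 128, 255))
})

test_that("cross-sections reproduce axis-aligned slices and interpolate ramps", {
  set.seed(2)
  arr <- array(rnorm(17^3), c(17, 17, 17))
  m <- density_map(arr, voxel = 2, origin = c(-16, -16, -16))
  sec <- extract_cross_section(m, point = c(0, 0, 0), u = c(1, 0, 0),
                               v = c(0, 1, 0), half_extent = 16)
  expect_equal(sec$image, arr[, , 9], tolerance = 1e-12, ignore_attr = TRUE)
  # linear ramp: a plane offset by half a voxel interpolates mid-values
  ramp <- density_map(array(rep(1:17, times = 17 * 17), c(17, 17, 17)),
                      voxel = 2, origin = c(-16, -16, -16))
  off <- extract_cross_section(ramp, point = c(-1, 0, 0), u = c(0, 1, 0),
                               v = c(0, 0, 1), half_extent = 10)
  expect_lt(max(abs(off$image - 8.5)), 1e-12)
  # a spherically symmetric map yields a rotationally symmetric section
  # (finely sampled so interpolation error stays below the bound)
  g <- grid_spec(center = c(0, 0, 0), half_extent = 20, voxel = 0.5)
  sph <- render_density(model_from_xyz(matrix(0, 1, 3)), g, atom_sigma = 4)
  sec2 <- extract_cross_section(sph, c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                                half_extent = 12)
  prof <- angular_profile(sec2, c(0, 0), radius = 8, window = 180, step = 5)
  expect_lt(diff(range(prof$values)), 1e-6)
  expect_error(extract_cross_section(m, point = c(500, 0, 0),
                                     u = c(0, 1, 0), v = c(0, 0, 1),
                                     half_extent = 5), "geometry error")
})

test_that("circle fitting is exact through 3 points and robust to noise", {
  th3 <- c(0.3, 1.7, 4.1)
  f <- fit_arc_circle(cbind(5 + 10 * cos(th3), 5 + 10 * sin(th3)))
  expect_equal(f$center, c(5, 5), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(f$radius, 10, tolerance = 1e-8)
  expect_lt(f$residual, 1e-8)
  set.seed(6)
  th <- runif(50, 0, 2 * pi)
  noisy <- cbind(-3 + 20 * cos(th), 7 + 20 * sin(th)) +
    matrix(rnorm(100, sd = 0.2), 50, 2)
  f2 <- fit_arc_circle(noisy)
  expect_lt(abs(f2$radius - 20), 0.2)
  # half-arc only still recovers the centre
  th_half <- seq(0.1, pi - 0.1, length.out = 40)
  f3 <- fit_arc_circle(cbind(-3 + 20 * cos(th_half), 7 + 20 * sin(th_half)))
  expect_lt(sqrt(sum((f3$center - c(-3, 7))^2)), 0.5)
  expect_error(fit_arc_circle(cbind(1:5, 2 * (1:5) + 3)), "collinear")
})

test_that("angular profiles locate blobs on the ring", {
  g <- grid_spec(center = c(0, 0, 0), half_extent = 40, voxel = 1)
  th0 <- 35
  blob <- render_density(model_from_xyz(
    matrix(c(25 * cos(th0 * pi / 180), 25 * sin(th0 * pi / 180), 0), 1)), g, 3)
  sec <- extract_cross_section(blob, c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                               half_extent = 32)
  pr <- angular_profile(sec, c(0, 0), radius = 25, window = 80, step = 1)
  expect_lt(abs(pr$angles[which.max(pr$values)] - th0), 1.01)
  expect_error(angular_profile(sec, c(0, 0), radius = 200), "bounds")
})

test_that("background statistics use the n-1 sample convention", {
  sec <- structure(list(image = matrix(c(10, 12, 14, 99), 2),
                        s = c(0, 1), t = c(0, 1), pixel = 1,
                        point = c(0, 0, 0), u = c(1, 0, 0), v = c(0, 1, 0)),
                   class = "cross_section")
  mask <- matrix(c(FALSE, FALSE, FALSE, TRUE), 2)
  b <- background_stats(sec, mask = mask)
  expect_equal(b$mean, 12)
  expect_equal(b$sd, 2)
  expect_equal(b$n, 3)
  # large-sample recovery of N(0, 1)
  set.seed(8)
  big <- structure(list(image = matrix(rnorm(1e4), 100),
                        s = seq_len(100), t = seq_len(100), pixel = 1,
                        point = c(0, 0, 0), u = c(1, 0, 0), v = c(0, 1, 0)),
                   class = "cross_section")
  b2 <- background_stats(big)
  expect_lt(abs(b2$mean), 0.05)
  expect_lt(abs(b2$sd - 1), 0.05)
  expect_error(background_stats(sec, exclude_radius = 10), "sampling error")
})

test_that("the SNR ratio reproduces its defining arithmetic", {
  b <- structure(list(mean = 12, sd = 2, n = 3), class = "background_stats")
  expect_equal(snr_ratio(12, b), 0)
  expect_equal(snr_ratio(12 + 2 * 2, b), 2)     # the boundary criterion
  expect_equal(snr_ratio(20, b), 4)
  b0 <- structure(list(mean = 5, sd = 0, n = 10), class = "background_stats")
  expect_error(snr_ratio(7, b0), "degenerate")
})

test_that("motion boundaries handle step, plateau and smooth profiles", {
  mkprof <- function(v, step = 1, window = 60) {
    structure(list(angles = seq(-window, window, step), values = v,
                   radius = 50, center = c(0, 0)), class = "angular_profile")
  }
  bkg <- structure(list(mean = 10, sd = 1, n = 100), class = "background_stats")
  ang <- seq(-60, 60, 1)
  # step profile: mean + 3 sd inside +-40, background outside
  v_step <- ifelse(abs(ang) <= 40, 13, 10)
  b <- motion_boundary(mkprof(v_step), bkg)
  expect_lt(abs(b$negative - 40), 1.01)
  expect_lt(abs(b$positive - 40), 1.01)
  expect_false(any(b$at_window_edge))
  # Gaussian-shaped profile: interpolated crossing matches the closed form
  sig <- 18
  v_g <- 10 + 8 * exp(-ang^2 / (2 * sig^2))
  bg <- motion_boundary(mkprof(v_g), bkg)
  crossing <- sig * sqrt(2 * log(8 / 2))   # where mean + 8 e^... = mean + 2 sd
  expect_lt(abs(bg$positive - crossing), 0.5)
  expect_lt(abs(bg$negative - crossing), 0.5)
  # identically at threshold: boundary at the window edge, flagged
  v_flat <- rep(12, length(ang))
  bf <- motion_boundary(mkprof(v_flat), bkg)
  expect_equal(bf$positive, 60)
  expect_true(all(bf$at_window_edge))
  # never exceeds the criterion: no-signal error
  expect_error(motion_boundary(mkprof(rep(10.5, length(ang))), bkg),
               "no-signal")
  # raising the threshold never widens the measured range
  set.seed(10)
  v_comb <- 10 + 6 * exp(-outer(ang, seq(-40, 40, 10), function(a, c)
    (a - c)^2 / 18) ) %*% rep(1, 9)
  prof_c <- mkprof(as.numeric(v_comb))
  b2 <- motion_boundary(prof_c, bkg, threshold = 2)
  b4 <- motion_boundary(prof_c, bkg, threshold = 4)
  expect_lte(b4$positive, b2$positive)
  expect_lte(b4$negative, b2$negative)
})

test_that("boundaries are invariant under positive rescaling of the map", {
  one <- one_axis_hinge(30)
  mr1 <- motion_range(one$pm$map, one$toy$frame, axes = "out_of_plane")
  scaled <- one$pm$map
  scaled$values <- scaled$values * 137.5
  mr2 <- motion_range(scaled, one$toy$frame, axes = "out_of_plane")
  expect_equal(mr1$sections$boundary, mr2$sections$boundary, tolerance = 1e-9)
  # through 8-bit quantisation the boundaries move by less than 2 degrees
  mr8 <- motion_range(scaled, one$toy$frame, axes = "out_of_plane",
                      use_8bit = TRUE)
  expect_lt(max(abs(mr8$sections$boundary - mr1$sections$boundary)), 2)
})

test_that("arc ridge points recover the pivot as the shared arc centre", {
  one <- one_axis_hinge(40)
  sm <- smooth_map(one$pm$map, 3)
  fr <- one$toy$frame
  sec <- extract_cross_section(sm, fr$pivot, fr$zero_axis, fr$normal)
  pts <- arc_ridge_points(sec, c(0, 0), radius = 0.91 * 110, window = 38)
  expect_gte(nrow(pts), 3)
  ft <- fit_arc_circle(pts)
  # centre within 3 voxels of the true pivot
  expect_lt(sqrt(sum(ft$center^2)), 3 * one$pm$map$voxel)
  expect_lt(abs(ft$radius - 0.91 * 110), 5)
})

test_that("detected arc radii sit at the pseudo-domain radii in order", {
  one <- one_axis_hinge(30)
  sm <- smooth_map(one$pm$map, 3)
  arcs <- detect_arc_radii(sm, one$toy$frame)
  expect_gte(nrow(arcs), 3)
  expect_true(all(diff(arcs$radius) > 0))
  got <- utils::tail(arcs$radius, 2)
  expect_lt(abs(got[1] - 0.59 * 110), 3)
  expect_lt(abs(got[2] - 0.91 * 110), 3)
})
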