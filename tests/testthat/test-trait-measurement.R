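## Direct rasterisation of analytic shapes (independent of the scene
## generator) for descriptor recovery checks.
raster_ellipse <- function(a_px, b_px, angle_deg = 0, pad = 3) {
  th <- angle_deg * pi / 180
  lim <- ceiling(max(a_px, b_px)) + pad
  g <- expand.grid(r = -lim:lim, c = -lim:lim)
  xr <- g$c * cos(th) + (-g$r) * sin(th)
  yr <- -g$c * sin(th) + (-g$r) * cos(th)
  sel <- (xr / a_px)^2 + (yr / b_px)^2 <= 1
  list(rows = g$r[sel] + lim + 1L, cols = g$c[sel] + lim + 1L)
}

test_that("perimeter tracing counts chain steps with sqrt(2) diagonals", {
  sq <- expand.grid(r = 1:10, c = 1:10)
  expect_equal(trace_perimeter(sq$r, sq$c), 36)
  expect_equal(trace_perimeter(5L, 7L), 4)
  circ <- raster_ellipse(50, 50)
  expect_equal(trace_perimeter(circ$rows, circ$cols), 2 * pi * 50,
               tolerance = 0.05)
  ## GU conversion is linear
  expect_equal(trace_perimeter(sq$r, sq$c, gu_per_px = 0.01), 0.36)
})

test_that("moment ellipse fit recovers axes and angle of rasterised ellipses", {
  e <- raster_ellipse(60, 30)
  f <- fit_ellipse(e$rows, e$cols)
  expect_equal(f$major, 120, tolerance = 0.02)
  expect_equal(f$minor, 60, tolerance = 0.02)
  expect_lt(min(f$angle_deg, 180 - f$angle_deg), 2)
  ## rotation equivariance
  f45 <- fit_ellipse(raster_ellipse(60, 30, 45)$rows,
                     raster_ellipse(60, 30, 45)$cols)
  expect_equal(f45$angle_deg, 45, tolerance = 2)
  ## isotropy of a circle
  fc <- fit_ellipse(raster_ellipse(40, 40)$rows, raster_ellipse(40, 40)$cols)
  expect_equal(fc$major / fc$minor, 1, tolerance = 0.02)
  expect_true(fc$angle_deg >= 0 && fc$angle_deg < 180)
  ## area-preserving normalisation: pi*major*minor/4 = pixel count
  n <- length(e$rows)
  expect_equal(pi * f$major * f$minor / 4, n, tolerance = 1e-12)
})

test_that("circularity follows 4*pi*A/P^2 with a cap at 1", {
  expect_identical(circularity(pi, 2 * pi), 1)
  s <- 3.2
  expect_equal(circularity(s^2, 4 * s), pi / 4)
  expect_identical(circularity(10, 1), 1)  # coarse-raster overshoot capped
  expect_error(circularity(-1, 2), "positive")
  expect_error(circularity(1, 0), "positive")
})

test_that("Feret diameter equals the brute-force pairwise maximum", {
  f <- feret(c(0L, 4L), c(0L, 3L))
  expect_equal(f$max_caliper, 5)
  bar <- feret(rep(1L, 20), 1:20)
  expect_equal(bar$feret_angle_deg, 0)
  expect_equal(bar$max_caliper, 19)
  ## random components (via flood-filled random masks): exact equality
  set.seed(31)
  checked <- 0
  for (rep in 1:30) {
    m <- matrix(runif(20 * 20) < 0.45, 20, 20)
    lab <- flood_fill_label(m)
    for (k in seq_len(max(lab))) {
      idx <- which(lab == k, arr.ind = TRUE)
      if (nrow(idx) < 2) next
      got <- feret(idx[, 1], idx[, 2])$max_caliper
      expect_equal(got, brute_feret(idx[, 1], idx[, 2]), tolerance = 1e-12)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 50)
})

test_that("solidity is area over corner-hull area", {
  rect <- expand.grid(r = 1:6, c = 1:9)
  expect_equal(solidity(rect$r, rect$c), 1)
  ## plus sign of five unit squares: hull is an octagon of area 7
  expect_equal(solidity(c(0, 1, 1, 1, 2), c(1, 0, 1, 2, 1)), 5 / 7,
               tolerance = 1e-12)
  expect_equal(solidity(3L, 3L), 1)  # single pixel
  ## boundary roughening strictly decreases solidity
  sm <- measure_single_spot(radius_gu = 0.12, aspect = 1.5, rough = 0, seed = 9)
  ro <- measure_single_spot(radius_gu = 0.12, aspect = 1.5, rough = 0.5, seed = 9)
  expect_lt(ro$spots$solidity, sm$spots$solidity)
})

test_that("roundness is the exact inverse of aspect ratio under the fit", {
  expect_equal(roundness(pi * 25, 10), 1)
  ## analytic 2:1 ellipse: A = pi*a*b, major = 2a -> 4A/(pi*(2a)^2) = b/a
  expect_equal(roundness(pi * 40 * 20, 80), 0.5)
  set.seed(8)
  for (rep in 1:20) {
    e <- raster_ellipse(runif(1, 15, 40), runif(1, 8, 15), runif(1, 0, 180))
    f <- fit_ellipse(e$rows, e$cols)
    n <- length(e$rows)
    expect_equal(roundness(n, f$major) * (f$major / f$minor), 1,
                 tolerance = 1e-9)
  }
})

test_that("mode shade packs RGB and breaks ties toward smaller values", {
  uni <- array(0L, c(2, 2, 3))
  uni[, , 1] <- 1L; uni[, , 2] <- 2L; uni[, , 3] <- 3L
  expect_equal(mode_shade(uni), 66051)
  white <- array(255L, c(3, 3, 3))
  expect_equal(mode_shade(white), 16777215)
  ## tie-break: equal counts of (0,0,0) and (0,0,1) plus one extra black
  tie <- array(0L, c(1, 5, 3))
  tie[1, 4:5, 3] <- 1L
  expect_equal(mode_shade(tie), 0)
})

test_that("profiles aggregate per-spot records arithmetically", {
  m <- measure_single_spot(radius_gu = 0.1)
  col <- m$scene$image
  prof <- aggregate_profile(m$spots, col)
  expect_identical(prof$number, 1L)
  expect_equal(prof$area, m$spots$area)
  expect_equal(prof$circularity, m$spots$circularity)
  ## hand mean of two spots
  two <- m$spots[c(1, 1), ]
  two$area <- c(0.02, 0.06)
  expect_equal(aggregate_profile(two, col)$area, 0.04)
  expect_error(aggregate_profile(m$spots[0, ], col), "no measurable spots")
  ## a field of identical circles stays circular after extraction
  p <- coat_scene_params(rect_width_px = 900, rect_height_px = 600,
                         n_spots = 20, mean_radius_gu = 0.045, radius_cv = 0,
                         aspect_ratio_mean = 1, boundary_roughness = 0,
                         noise_sd = 0, edge_margin_gu = 0.1, seed = 33)
  sc <- gen_coat_image(p)
  ex <- extract_spots(sc$image, sc$rect)
  pr <- aggregate_profile(measure_spots(ex$spot_map), ex$color_rect)
  ## chain-code perimeters overestimate smooth contours (~5%), bounding
  ## digitised-circle circularity near 0.9; the corrected estimator
  ## recovers near-1 circularity
  expect_gte(pr$circularity, 0.90)
  prs <- aggregate_profile(measure_spots(ex$spot_map,
                                         perimeter_method = "smoothed"),
                           ex$color_rect)
  expect_gte(prs$circularity, 0.95)
  ## every isolated interior circle is one retained spot
  expect_gte(pr$number, sum(!sc$truth$overlaps & !sc$truth$touches_edge))
})

test_that("all bounded descriptors stay in range on random components", {
  set.seed(55)
  count <- 0
  for (rep in 1:8) {
    p <- coat_scene_params(rect_width_px = 500, rect_height_px = 375,
                           n_spots = 18, mean_radius_gu = 0.05,
                           radius_cv = 0.35, aspect_ratio_mean = 1.8,
                           boundary_roughness = 0.4, noise_sd = 4,
                           edge_margin_gu = 0, seed = 100 + rep)
    sc <- gen_coat_image(p)
    sp <- measure_spots(extract_spots(sc$image, sc$rect)$spot_map)
    if (!nrow(sp)) next
    count <- count + nrow(sp)
    expect_true(all(sp$circularity > 0 & sp$circularity <= 1))
    expect_true(all(sp$roundness > 0 & sp$roundness <= 1))
    expect_true(all(sp$solidity > 0 & sp$solidity <= 1))
    expect_true(all(sp$aspect_ratio >= 1))
    expect_true(all(sp$ellipse_angle_deg >= 0 & sp$ellipse_angle_deg < 180))
    expect_true(all(sp$feret_angle_deg >= 0 & sp$feret_angle_deg < 180))
    expect_true(all(sp$area > 0 & sp$perimeter > 0))
    expect_true(all(sp$max_caliper >= 0.95 * sp$ellipse_major |
                      sp$area < 25 * (1 / 375)^2))
    expect_equal(sp$roundness * sp$aspect_ratio, rep(1, nrow(sp)),
                 tolerance = 1e-9)
  }
  expect_gt(count, 80)
})

test_that("trait profiles are repeatable across rendering resolutions", {
  profs <- lapply(1:2, function(s) {
    p <- coat_scene_params(rect_width_px = 400 * s, rect_height_px = 300 * s,
                           n_spots = 6, mean_radius_gu = 0.09,
                           radius_cv = 0.15, aspect_ratio_mean = 1.6,
                           boundary_roughness = 0, noise_sd = 0,
                           edge_margin_gu = 0.2, seed = 61)
    sc <- gen_coat_image(p)
    ex <- extract_spots(sc$image, sc$rect)
    aggregate_profile(measure_spots(ex$spot_map), ex$color_rect)
  })
  for (tr in c("area", "perimeter", "circularity", "max_caliper",
               "aspect_ratio", "roundness", "solidity"))
    expect_equal(profs[[1]][[tr]], profs[[2]][[tr]], tolerance = 0.03)
  expect_identical(profs[[1]]$number, profs[[2]]$number)
})
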