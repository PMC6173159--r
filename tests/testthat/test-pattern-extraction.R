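rgb_raster <- function(r, g = r, b = r) {
  h <- nrow(r); w <- ncol(r)
  a <- array(0L, c(h, w, 3))
  a[, , 1] <- r; a[, , 2] <- g; a[, , 3] <- b
  storage.mode(a) <- "integer"
  a
}

test_that("cropping respects half-open pixel coordinates and bounds", {
  img <- rgb_raster(matrix(1:300 %% 256, 300, 400)[1:300, 1:400])
  full <- crop_to_rectangle(img, analysis_rect(0, 0, 400, 300))
  expect_identical(full, img)
  cr <- crop_to_rectangle(img, analysis_rect(10, 20, 110, 100))
  expect_identical(dim(cr), c(80L, 100L, 3L))
  expect_identical(cr[1, 1, 1], img[21, 11, 1])
  expect_error(crop_to_rectangle(img, analysis_rect(0, 0, 401, 300)), "x1")
  expect_error(crop_to_rectangle(img, analysis_rect(0, 0, 400, 301)), "y1")
})

test_that("greyscale conversion uses the stated luminance weights", {
  px <- function(r, g, b) rgb_raster(matrix(r, 1, 1), matrix(g, 1, 1),
                                     matrix(b, 1, 1))
  expect_equal(as.vector(to_grayscale(px(255, 255, 255))), 255)
  expect_equal(as.vector(to_grayscale(px(0, 0, 0))), 0)
  expect_equal(as.vector(to_grayscale(px(100, 150, 200))), 141)
  bad <- array(0.5, c(2, 2, 3))
  expect_error(to_grayscale(bad), "8-bit")
})

test_that("contrast stretch maps tail quantiles to the full range", {
  full <- matrix(c(0, 255, 100, 30), 2, 2)
  expect_equal(enhance_contrast(full, 0), as_full <- {
    storage.mode(full) <- "integer"; full
  })
  two <- matrix(c(50, 100), 10, 10)
  st <- enhance_contrast(two, 0)
  expect_true(all(sort(unique(as.vector(st))) == c(0, 255)))
  ## ramp: lowest/highest tail fractions clipped, checked against sorting
  ramp <- matrix(0:999 %% 256, 40, 25)
  ramp <- matrix(round(seq(10, 240, length.out = 1000)), 40, 25)
  fr <- 0.02
  st2 <- enhance_contrast(ramp, fr)
  v <- sort(as.vector(ramp))
  lo <- v[ceiling(fr / 2 * length(v))]
  hi <- v[floor((1 - fr / 2) * length(v)) + 1]
  expect_true(all(st2[ramp <= lo] == 0))
  expect_true(all(st2[ramp >= hi] == 255))
  expect_warning(enhance_contrast(matrix(7, 5, 5)), "constant")
})

test_that("isodata threshold is the iterated-intermeans fixed point", {
  two <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  expect_identical(isodata_threshold(two), 105L)
  ## dark blob on light ground: perfect separation
  g <- matrix(220L, 60, 60); g[20:35, 20:35] <- 40L
  t0 <- isodata_threshold(g)
  expect_true(all(g[g <= t0] == 40) && all(g[g > t0] == 220))
  ## brute-force fixed-point oracle on random bimodal mixtures
  set.seed(4)
  for (rep in 1:5) {
    v <- as_uint <- pmin(pmax(round(c(rnorm(400, 70, 15), rnorm(600, 180, 20))), 0), 255)
    img <- matrix(v, 25, 40)
    t_iter <- isodata_threshold(img)
    fixed <- vapply(0:254, function(t) {
      lo <- v[v <= t]; hi <- v[v > t]
      length(lo) > 0 && length(hi) > 0 &&
        round((mean(lo) + mean(hi)) / 2) == t
    }, logical(1))
    expect_true(fixed[t_iter + 1L])
  }
  expect_error(isodata_threshold(matrix(5, 3, 3)), "constant")
})

test_that("binarisation marks the dark phase as foreground", {
  g <- matrix(200L, 8, 8)
  expect_equal(sum(binarize(g, 100)$mask), 0)
  expect_equal(sum(binarize(g, 200)$mask), 64)
  ## synthetic circle: foreground equals the rendered mask exactly
  m <- measure_single_spot(radius_gu = 0.12)
  sc <- m$scene
  gray <- to_grayscale(sc$image)
  thr <- isodata_threshold(gray)
  mask <- binarize(gray, thr, height_px = sc$rect$height_px)
  expect_identical(unname(mask$mask), unname(to_grayscale(sc$image) < 100))
  expect_equal(mask$gu_per_px, 1 / 300)
})

test_that("labelling is 8-connected and matches a flood-fill oracle", {
  ## diagonal touch: one component
  m <- matrix(FALSE, 4, 4); m[1, 1] <- m[2, 2] <- TRUE
  lab <- label_spots(structure(list(mask = m, gu_per_px = 1),
                               class = "pattern_mask"))
  expect_identical(lab$n_spots, 1L)
  ## three disjoint blobs
  m3 <- matrix(FALSE, 10, 10)
  m3[1:2, 1:2] <- TRUE; m3[5:6, 5:6] <- TRUE; m3[9, 9] <- TRUE
  expect_identical(label_spots(structure(list(mask = m3, gu_per_px = 1),
                                         class = "pattern_mask"))$n_spots, 3L)
  ## random masks: exact agreement with the oracle after canonical relabel
  set.seed(10)
  for (rep in 1:200) {
    mm <- matrix(runif(15 * 12) < 0.4, 15, 12)
    got <- label_spots(structure(list(mask = mm, gu_per_px = 1),
                                 class = "pattern_mask"))$labels
    expect_identical(got, canon_labels(flood_fill_label(mm)))
  }
})

test_that("spot filters drop edge-cut components and speckles, idempotently", {
  h <- 100  # 1 GU = 100 px; 1 px^2 = 1e-4 GU^2
  m <- matrix(FALSE, h, 120)
  m[1, 5] <- TRUE             # edge-cut component
  m[50:53, 50:53] <- TRUE     # interior, 16 px = 1.6e-3 GU^2: retained
  m[70, 80] <- TRUE           # interior single pixel = 1e-4 GU^2: retained
  mask <- structure(list(mask = m, gu_per_px = 1 / h), class = "pattern_mask")
  lab <- label_spots(mask)
  filt <- apply_spot_filters(lab, min_area_gu2 = 1e-5)
  expect_identical(filt$n_spots, 2L)
  expect_true(any(filt$filter_log$reason == "edge-cut"))
  ## speckle rule at the documented threshold: 0.000009 GU^2 removed
  h2 <- 1000  # 1 px^2 = 1e-6 GU^2
  m2 <- matrix(FALSE, h2, 50)
  m2[500:502, 10:12] <- TRUE       # 9 px = 9e-6 GU^2 < 1e-5: speckle
  m2[600:609, 20:21] <- TRUE       # 20 px = 2e-5 GU^2: retained
  lab2 <- label_spots(structure(list(mask = m2, gu_per_px = 1 / h2),
                                class = "pattern_mask"))
  filt2 <- apply_spot_filters(lab2, min_area_gu2 = 1e-5)
  expect_identical(filt2$n_spots, 1L)
  expect_true(any(filt2$filter_log$reason == "speckle"))
  ## idempotence
  again <- apply_spot_filters(filt, min_area_gu2 = 1e-5)
  expect_identical(again$labels, filt$labels)
  expect_identical(again$n_spots, filt$n_spots)
  ## all-removed is legal
  m0 <- matrix(FALSE, 70, 70); m0[1, 1] <- TRUE
  f0 <- apply_spot_filters(label_spots(structure(list(mask = m0, gu_per_px = 1 / 70),
                                                 class = "pattern_mask")))
  expect_identical(f0$n_spots, 0L)
})

test_that("GU measurements are invariant to image resolution", {
  profs <- lapply(c(200, 400), function(hpx) {
    p <- coat_scene_params(rect_width_px = round(hpx * 4 / 3),
                           rect_height_px = hpx, n_spots = 8,
                           mean_radius_gu = 0.06, radius_cv = 0.2,
                           aspect_ratio_mean = 1.5, boundary_roughness = 0,
                           noise_sd = 0, edge_margin_gu = 0.15, seed = 21)
    sc <- gen_coat_image(p)
    ex <- extract_spots(sc$image, sc$rect)
    aggregate_profile(measure_spots(ex$spot_map), ex$color_rect)
  })
  expect_identical(profs[[1]]$number, profs[[2]]$number)
  expect_equal(profs[[1]]$area, profs[[2]]$area, tolerance = 0.02)
})
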