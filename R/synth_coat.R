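## Synthetic spotted-coat scenes with analytic ground truth.
##
## Spots are dark elliptical blobs on a lighter ground, optionally with
## lobed/incised boundaries produced by radial perturbation of the ellipse
## boundary polygon (amplitude = roughness x minor semi-axis, smoothed
## random harmonics). Geometry is sampled in GU coordinates, so the same
## seed renders the same scene at any pixel resolution.

#' Parameters of a synthetic coat scene
#'
#' @param rect_width_px,rect_height_px Rectangle size in pixels
#'   (`rect_height_px >= 64`; 1 GU = `rect_height_px`).
#' @param n_spots Number of spots to render (>= 0).
#' @param mean_radius_gu Mean equivalent radius (geometric mean of the
#'   semi-axes) in GU.
#' @param radius_cv Coefficient of variation of the radius (lognormal).
#' @param aspect_ratio_mean Mean ellipse aspect ratio (>= 1).
#' @param boundary_roughness In `[0, 1]`: 0 gives smooth ellipses; larger
#'   values give lobed/incised perimeters (radial perturbation with
#'   amplitude `roughness * minor semi-axis`).
#' @param spot_shade,background_shade Grey levels 0-255; spots must be
#'   darker than the ground.
#' @param illumination_gradient Maximum fractional brightness change across
#'   the rectangle (linear, left to right).
#' @param noise_sd Gaussian pixel noise SD in grey levels.
#' @param edge_margin_gu Keep spot centers at least this far (GU) from the
#'   rectangle edges; 0 allows spots to straddle the edge (they are then
#'   flagged `touches_edge` and removed by the edge filter downstream).
#' @param seed Integer seed; fixed seed gives bit-identical scenes.
#' @return A `coat_scene_params` list.
#' @export
coat_scene_params <- function(rect_width_px = 400, rect_height_px = 300,
                              n_spots = 15, mean_radius_gu = 0.07,
                              radius_cv = 0.25, aspect_ratio_mean = 1.7,
                              boundary_roughness = 0.15,
                              spot_shade = 60, background_shade = 190,
                              illumination_gradient = 0, noise_sd = 0,
                              edge_margin_gu = 0, seed = 1L) {
  stop_if_not_scalar_num(rect_height_px, "rect_height_px", 64, integer = TRUE)
  stop_if_not_scalar_num(rect_width_px, "rect_width_px", 8, integer = TRUE)
  stop_if_not_scalar_num(n_spots, "n_spots", 0, integer = TRUE)
  stop_if_not_scalar_num(mean_radius_gu, "mean_radius_gu", 1e-6)
  stop_if_not_scalar_num(radius_cv, "radius_cv", 0)
  stop_if_not_scalar_num(aspect_ratio_mean, "aspect_ratio_mean", 1)
  stop_if_not_scalar_num(boundary_roughness, "boundary_roughness", 0, 1)
  stop_if_not_scalar_num(spot_shade, "spot_shade", 0, 255)
  stop_if_not_scalar_num(background_shade, "background_shade", 0, 255)
  if (spot_shade >= background_shade)
    stop("spots must be darker than the coat ground (spot_shade < background_shade)")
  stop_if_not_scalar_num(illumination_gradient, "illumination_gradient", 0, 1)
  stop_if_not_scalar_num(noise_sd, "noise_sd", 0)
  stop_if_not_scalar_num(edge_margin_gu, "edge_margin_gu", 0)
  structure(as.list(environment()), class = "coat_scene_params")
}

## Smooth periodic radial perturbation: a few random-phase harmonics,
## normalised to max |.| = 1 over the evaluation grid.
.radial_noise <- function(theta, n_harmonics = 3:7) {
  amp <- stats::rnorm(length(n_harmonics))
  phase <- stats::runif(length(n_harmonics), 0, 2 * pi)
  f <- rowSums(sapply(seq_along(n_harmonics), function(i)
    amp[i] * cos(n_harmonics[i] * theta + phase[i])))
  f / max(abs(f))
}

## Boundary polygon of one spot in GU coordinates (y-up), n_vertices points.
.spot_polygon <- function(cx, cy, a, b, angle, roughness, n_vertices = 720L) {
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  ## ellipse in polar form about its center
  r_ell <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  if (roughness > 0) r_ell <- pmax(r_ell + roughness * b * .radial_noise(theta),
                                   0.05 * b)
  x <- r_ell * cos(theta); y <- r_ell * sin(theta)
  ca <- cos(angle); sa <- sin(angle)
  list(x = cx + ca * x - sa * y, y = cy + sa * x + ca * y)
}

## Even-odd point-in-polygon test, vectorised over query points.
.in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Generate a synthetic coat scene
#'
#' Renders `n_spots` dark blobs on a lighter ground into an 8-bit RGB raster
#' and returns analytic ground truth for each spot: for smooth ellipses the
#' closed-form area, numerically exact perimeter and axes; for roughened
#' boundaries, numerically integrated polygon area and perimeter. Spots that
#' overlap another spot or the rectangle edge are flagged so recovery tests
#' can exclude them (overlapping blobs merge into one raster component).
#'
#' @param params A [coat_scene_params()] object.
#' @return List with `image` (integer `h x w x 3` array), `rect` (an
#'   [analysis_rect()] covering the raster) and `truth` (data frame with one
#'   row per requested spot: `center_x_gu, center_y_gu, analytic_area,
#'   analytic_perimeter, major_axis, minor_axis, orientation_deg,
#'   touches_edge, overlaps`).
#' @export
gen_coat_image <- function(params) {
  stopifnot(inherits(params, "coat_scene_params"))
  p <- params
  set.seed(p$seed)
  h <- p$rect_height_px; w <- p$rect_width_px
  w_gu <- w / h
  gray <- matrix(p$background_shade, h, w)
  if (p$illumination_gradient > 0) {
    ramp <- 1 + p$illumination_gradient * ((seq_len(w) - 1) / (w - 1) - 0.5)
    gray <- gray * matrix(ramp, h, w, byrow = TRUE)
  }
  spot_px <- vector("list", p$n_spots)
  truth <- NULL
  if (p$n_spots > 0) {
    sdlog <- sqrt(log(1 + p$radius_cv^2))
    radius <- stats::rlnorm(p$n_spots, log(p$mean_radius_gu) - sdlog^2 / 2, sdlog)
    ar <- rep(p$aspect_ratio_mean, p$n_spots)
    a <- radius * sqrt(ar)        # semi-axes with geometric mean = radius
    b <- radius / sqrt(ar)
    if (any(a > 0.5))
      stop("requested spot radius exceeds half the rectangle height")
    ang <- stats::runif(p$n_spots, 0, pi)
    m <- min(p$edge_margin_gu, w_gu / 2 - 1e-6, 0.5 - 1e-6)
    cx <- stats::runif(p$n_spots, m, w_gu - m)
    cy <- stats::runif(p$n_spots, m, 1 - m)
    rows_list <- vector("list", p$n_spots)
    tr <- vector("list", p$n_spots)
    for (i in seq_len(p$n_spots)) {
      poly <- .spot_polygon(cx[i], cy[i], a[i], b[i], ang[i],
                            p$boundary_roughness)
      ## analytic truth
      if (p$boundary_roughness == 0) {
        area <- pi * a[i] * b[i]
        perim <- polyline_length(poly$x, poly$y)  # 720-gon: error < 1e-4
      } else {
        area <- polygon_area(poly$x, poly$y)
        perim <- polyline_length(poly$x, poly$y)
      }
      ## rasterise: pixel centers inside the polygon. Pixel (r, c) center in
      ## GU (y-down image row r maps to y_up = 1 - (r - 0.5)/h).
      pxv <- poly$x * h   # polygon in pixel coordinates (x right, y down)
      pyv <- (1 - poly$y) * h
      rlo <- max(1L, floor(min(pyv) + 0.5)); rhi <- min(h, ceiling(max(pyv) + 0.5))
      clo <- max(1L, floor(min(pxv) + 0.5)); chi <- min(w, ceiling(max(pxv) + 0.5))
      touches <- any(pyv < 0.5) || any(pyv > h - 0.5) ||
        any(pxv < 0.5) || any(pxv > w - 0.5)
      if (rlo > rhi || clo > chi) {
        rows_list[[i]] <- cbind(integer(), integer())
      } else {
        grid <- expand.grid(r = rlo:rhi, c = clo:chi)
        ins <- .in_polygon(grid$c - 0.5, grid$r - 0.5, pxv, pyv)
        rows_list[[i]] <- cbind(grid$r[ins], grid$c[ins])
      }
      tr[[i]] <- data.frame(
        spot = i, center_x_gu = cx[i], center_y_gu = cy[i],
        analytic_area = area, analytic_perimeter = perim,
        major_axis = 2 * a[i], minor_axis = 2 * b[i],
        orientation_deg = (ang[i] * 180 / pi) %% 180,
        touches_edge = touches, overlaps = FALSE)
    }
    truth <- do.call(rbind, tr)
    ## flag overlapping/adjacent spot pairs (they merge into one component)
    occ <- matrix(0L, h, w)
    for (i in seq_len(p$n_spots)) {
      px <- rows_list[[i]]
      if (nrow(px) == 0L) next
      ## dilate by 1 px (8-neighbourhood) to catch merged-by-adjacency pairs
      hit <- integer(0)
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- px[, 1L] + dr; c2 <- px[, 2L] + dc
        ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
        hit <- c(hit, occ[cbind(r2[ok], c2[ok])])
      }
      hit <- unique(hit[hit > 0L])
      if (length(hit)) {
        truth$overlaps[c(i, hit)] <- TRUE
      }
      occ[px] <- i
      gray[px] <- p$spot_shade
    }
  }
  if (p$noise_sd > 0)
    gray <- gray + stats::rnorm(length(gray), 0, p$noise_sd)
  img <- as_uint8(array(rep(as.vector(gray), 3L), c(h, w, 3L)))
  list(image = img,
       rect = analysis_rect(0L, 0L, w, h),
       truth = if (is.null(truth)) data.frame() else truth)
}
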