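## Pattern extraction: colour photograph + analysis rectangle -> filtered,
## labelled spot map in giraffe units. The chain mirrors a standard
## image-analysis workflow: crop, 8-bit greyscale, linear contrast stretch,
## automatic (iterated intermeans) threshold, binarise with spots as the dark
## phase, 8-connected component labelling, then removal of edge-cut spots and
## speckles below 1e-5 GU^2.

#' Crop an image to the analysis rectangle
#'
#' @param image RGB array (`h x w x 3`) or greyscale matrix.
#' @param rect An [analysis_rect()]. Coordinates are 0-based half-open.
#' @return The cropped raster, dimensions `(y1-y0) x (x1-x0)`.
#' @export
crop_to_rectangle <- function(image, rect) {
  stopifnot(inherits(rect, "analysis_rect"))
  d <- dim(image)
  h <- d[1L]; w <- d[2L]
  if (rect$x0 < 0) stop("rectangle out of bounds: x0 < 0")
  if (rect$y0 < 0) stop("rectangle out of bounds: y0 < 0")
  if (rect$x1 > w) stop(sprintf("rectangle out of bounds: x1 = %d > image width %d",
                                rect$x1, w))
  if (rect$y1 > h) stop(sprintf("rectangle out of bounds: y1 = %d > image height %d",
                                rect$y1, h))
  rows <- (rect$y0 + 1L):rect$y1
  cols <- (rect$x0 + 1L):rect$x1
  if (length(d) == 3L) image[rows, cols, , drop = FALSE] else
    image[rows, cols, drop = FALSE]
}

#' Convert an RGB raster to 8-bit greyscale
#'
#' Uses the Rec. 601 luminance weights: `round(0.299 R + 0.587 G + 0.114 B)`.
#'
#' @param image Integer RGB array with 8-bit channels.
#' @return Integer greyscale matrix, values 0-255.
#' @export
to_grayscale <- function(image) {
  check_rgb8(image)
  as_uint8(0.299 * image[, , 1L] + 0.587 * image[, , 2L] + 0.114 * image[, , 3L])
}

#' Linear contrast stretch with tail saturation
#'
#' Rescales intensities so that the `saturated_fraction/2` and
#' `1 - saturated_fraction/2` quantiles map to 0 and 255, clipping outside.
#' With `saturated_fraction = 0` this stretches the observed min/max to the
#' full range. A constant image is returned unchanged with a warning.
#'
#' @param gray Integer greyscale matrix.
#' @param saturated_fraction Total fraction of pixels allowed to saturate
#'   (half per tail), in `[0, 0.5)`. Default 0.0035 per tail (0.7% total is
#'   split as 0.35% per tail when `saturated_fraction = 0.007`).
#' @return Integer greyscale matrix spanning 0-255.
#' @export
enhance_contrast <- function(gray, saturated_fraction = 0.007) {
  stop_if_not_scalar_num(saturated_fraction, "saturated_fraction", 0, 0.5 - 1e-12)
  v <- as.vector(gray)
  lo <- stats::quantile(v, saturated_fraction / 2, type = 1, names = FALSE)
  hi <- stats::quantile(v, 1 - saturated_fraction / 2, type = 1, names = FALSE)
  if (hi <= lo) {
    warning("constant (or near-constant) image: no contrast stretch possible")
    return(gray)
  }
  as_uint8((gray - lo) * (255 / (hi - lo)))
}

#' Automatic threshold by iterated intermeans (isodata)
#'
#' Finds the fixed point `t = round((mean(levels <= t) + mean(levels > t))/2)`,
#' iterating from the mid-range of occupied grey levels. This is the classic
#' isodata automatic threshold.
#'
#' @param gray Integer greyscale matrix with at least two distinct levels.
#' @return Integer threshold in 0-254; pixels `<= t` are the dark phase.
#' @export
isodata_threshold <- function(gray) {
  v <- as.integer(gray)
  counts <- tabulate(v + 1L, nbins = 256L)
  levels <- which(counts > 0L) - 1L
  if (length(levels) < 2L) stop("constant image: no threshold exists")
  t_cur <- floor((min(levels) + max(levels)) / 2)
  lev <- 0:255
  csum_n <- cumsum(counts)
  csum_s <- cumsum(counts * lev)
  n_tot <- csum_n[256L]; s_tot <- csum_s[256L]
  for (i in 1:256) {
    n_lo <- csum_n[t_cur + 1L]
    if (n_lo == 0L || n_lo == n_tot) { # empty side: step toward the data
      t_cur <- if (n_lo == 0L) t_cur + 1L else t_cur - 1L
      next
    }
    m_lo <- csum_s[t_cur + 1L] / n_lo
    m_hi <- (s_tot - csum_s[t_cur + 1L]) / (n_tot - n_lo)
    t_new <- round((m_lo + m_hi) / 2)
    if (t_new == t_cur) return(as.integer(t_cur))
    t_cur <- t_new
  }
  as.integer(t_cur) # cycle safeguard; in practice the iteration converges
}

#' Binarise a greyscale raster into a spot mask
#'
#' Spots are the darker phase: foreground is `intensity <= threshold`.
#'
#' @param gray Integer greyscale matrix.
#' @param threshold Integer in 0-255.
#' @param height_px Height of the analysis rectangle in pixels; defaults to
#'   `nrow(gray)` (the usual case where `gray` is the cropped rectangle).
#' @return A `pattern_mask`: list with logical matrix `mask` and scalar
#'   `gu_per_px = 1/height_px`.
#' @export
binarize <- function(gray, threshold, height_px = nrow(gray)) {
  stop_if_not_scalar_num(threshold, "threshold", 0, 255)
  structure(list(mask = gray <= threshold,
                 gu_per_px = 1 / height_px),
            class = "pattern_mask")
}

## Vectorised 8-connected component labelling via the pixel adjacency graph.
## Returns an integer matrix (0 = background), labels 1..K in raster-scan
## order (left-to-right, top-to-bottom) of each component's first pixel.
label_components8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  labels <- matrix(0L, h, w)
  idx <- which(mask)             # column-major linear indices of foreground
  if (length(idx) == 0L)
    return(labels)
  pos <- integer(h * w); pos[idx] <- seq_along(idx)
  row <- ((idx - 1L) %% h) + 1L
  col <- ((idx - 1L) %/% h) + 1L
  edge_to <- function(dr, dc) {
    ok <- row + dr >= 1L & row + dr <= h & col + dc >= 1L & col + dc <= w
    nb <- idx[ok] + dr + dc * h
    keep <- mask[nb]
    cbind(pos[idx[ok][keep]], pos[nb[keep]])
  }
  edges <- rbind(edge_to(1L, 0L), edge_to(0L, 1L), edge_to(1L, 1L), edge_to(-1L, 1L))
  g <- igraph::graph_from_edgelist(rbind(edges, cbind(seq_along(idx), seq_along(idx))),
                                   directed = FALSE)
  comp <- igraph::components(g)$membership[seq_along(idx)]
  ## relabel in raster-scan order of first pixel
  key <- (row - 1L) * w + col
  first_key <- vapply(split(key, comp), min, numeric(1))
  relabel <- integer(length(first_key))
  relabel[order(first_key)] <- seq_along(first_key)
  labels[idx] <- relabel[comp]
  labels
}

#' Label spots in a binary pattern mask
#'
#' 8-connected component labelling (two blobs touching only diagonally are one
#' spot, matching particle-analysis semantics). Labels are assigned 1..K in
#' raster-scan order of each component's first pixel.
#'
#' @param mask A `pattern_mask` from [binarize()].
#' @return A `spot_map`: list with integer matrix `labels` (0 = background),
#'   `n_spots`, `gu_per_px` and an empty `filter_log`.
#' @export
label_spots <- function(mask) {
  stopifnot(inherits(mask, "pattern_mask"))
  labels <- label_components8(mask$mask)
  structure(list(labels = labels,
                 n_spots = max(labels),
                 gu_per_px = mask$gu_per_px,
                 filter_log = data.frame(label = integer(), area_gu2 = numeric(),
                                         status = character(), reason = character(),
                                         stringsAsFactors = FALSE)),
            class = "spot_map")
}

#' @export
print.spot_map <- function(x, ...) {
  cat(sprintf("Spot map: %d x %d px, %d spot(s), 1 px = %.6f GU\n",
              nrow(x$labels), ncol(x$labels), x$n_spots, x$gu_per_px))
  if (nrow(x$filter_log)) {
    rem <- sum(x$filter_log$status == "removed")
    cat(sprintf("  filters applied: %d component(s) removed\n", rem))
  }
  invisible(x)
}

#' Filter labelled spots: edge-cut and speckle removal
#'
#' Removes every component owning at least one pixel on the rectangle border
#' (incomplete spots) and every component whose area is below `min_area_gu2`
#' (speckles; default 1e-5 GU^2). Retained components are relabelled 1..K in
#' their original order. Idempotent. The `filter_log` records every decision.
#'
#' @param labeled A `spot_map` from [label_spots()].
#' @param min_area_gu2 Minimum retained spot area in GU^2.
#' @return A filtered `spot_map` with `n_spots` = number retained.
#' @export
apply_spot_filters <- function(labeled, min_area_gu2 = 1e-5) {
  stopifnot(inherits(labeled, "spot_map"))
  stop_if_not_scalar_num(min_area_gu2, "min_area_gu2", 0)
  lab <- labeled$labels
  k <- max(lab)
  if (k == 0L) return(labeled)
  h <- nrow(lab); w <- ncol(lab)
  border_labels <- unique(c(lab[1L, ], lab[h, ], lab[, 1L], lab[, w]))
  border_labels <- border_labels[border_labels > 0L]
  npix <- tabulate(lab[lab > 0L], nbins = k)
  area <- npix * labeled$gu_per_px^2
  edge_cut <- seq_len(k) %in% border_labels
  speckle <- area < min_area_gu2
  keep <- !edge_cut & !speckle
  log <- data.frame(label = seq_len(k),
                    area_gu2 = area,
                    status = ifelse(keep, "retained", "removed"),
                    reason = ifelse(edge_cut, "edge-cut",
                             ifelse(speckle, "speckle", "")),
                    stringsAsFactors = FALSE)
  relabel <- integer(k)
  relabel[keep] <- seq_len(sum(keep))
  new_lab <- lab
  new_lab[lab > 0L] <- relabel[lab[lab > 0L]]
  structure(list(labels = new_lab,
                 n_spots = sum(keep),
                 gu_per_px = labeled$gu_per_px,
                 filter_log = rbind(labeled$filter_log, log)),
            class = "spot_map")
}

#' Full extraction chain for one photograph
#'
#' Convenience wrapper: crop, greyscale, contrast stretch, isodata threshold,
#' binarise, label, filter.
#'
#' @param image RGB array (8-bit channels).
#' @param rect An [analysis_rect()].
#' @param saturated_fraction Passed to [enhance_contrast()].
#' @param min_area_gu2 Passed to [apply_spot_filters()].
#' @return List with the filtered `spot_map`, the cropped colour rectangle
#'   (`color_rect`), and the threshold used.
#' @export
extract_spots <- function(image, rect, saturated_fraction = 0.007,
                          min_area_gu2 = 1e-5) {
  color_rect <- crop_to_rectangle(image, rect)
  gray <- to_grayscale(color_rect)
  gray <- enhance_contrast(gray, saturated_fraction)
  thr <- isodata_threshold(gray)
  mask <- binarize(gray, thr, height_px = rect$height_px)
  map <- apply_spot_filters(label_spots(mask), min_area_gu2)
  list(spot_map = map, color_rect = color_rect, threshold = thr)
}
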