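## Independent oracles used across the suite. Deliberately naive
## implementations: they must not share code paths with the package.

## 8-connected component labelling by stack-based flood fill.
flood_fill_label <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (r0 in seq_len(h)) for (c0 in seq_len(w)) {
    if (!mask[r0, c0] || lab[r0, c0] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(r0, c0)); lab[r0, c0] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; cc <- p[2] + dc
        if (r >= 1 && r <= h && cc >= 1 && cc <= w &&
            mask[r, cc] && lab[r, cc] == 0L) {
          lab[r, cc] <- nxt
          stack[[length(stack) + 1L]] <- c(r, cc)
        }
      }
    }
  }
  lab
}

## Relabel a labelling canonically: 1..K in raster-scan order (row-major) of
## each component's first pixel, to compare labelings from different schemes.
canon_labels <- function(lab) {
  h <- nrow(lab)
  idx <- which(lab > 0L)
  if (!length(idx)) return(lab)
  row <- ((idx - 1L) %% h) + 1L
  col <- ((idx - 1L) %/% h) + 1L
  key <- (row - 1L) * ncol(lab) + col
  first <- tapply(key, lab[idx], min)
  relab <- integer(max(lab))
  relab[as.integer(names(first))[order(first)]] <- seq_along(first)
  out <- lab
  out[idx] <- relab[lab[idx]]
  out
}

## Brute-force maximum pairwise distance over all component pixel centers.
brute_feret <- function(rows, cols) {
  d <- 0
  n <- length(rows)
  for (i in seq_len(n - 1)) {
    di <- sqrt((rows[i] - rows[(i + 1):n])^2 + (cols[i] - cols[(i + 1):n])^2)
    d <- max(d, di)
  }
  d
}

## Closed-form Cormack-Jolly-Seber conditional negative log-likelihood.
## phi: n x (T-1) survival matrix; p: length-T detection vector.
cjs_nll <- function(hist, f, phi, p) {
  T <- ncol(hist); tot <- 0
  for (i in seq_len(nrow(hist))) {
    y <- hist[i, ]; fi <- f[i]
    l <- max(which(y == 1))
    chi <- 1
    if (l < T) for (j in (T - 1):l)
      chi <- (1 - phi[i, j]) + phi[i, j] * (1 - p[j + 1]) * chi
    ll <- 0
    if (l > fi) for (j in fi:(l - 1))
      ll <- ll + log(phi[i, j]) + y[j + 1] * log(p[j + 1]) +
        (1 - y[j + 1]) * log(1 - p[j + 1])
    tot <- tot - ll - log(chi)
  }
  tot
}

## Hand-build an encounter_histories object from a history matrix.
make_eh <- function(hist, schedule, group = NULL, covariates = NULL,
                    freq = NULL) {
  hist <- matrix(as.integer(hist), nrow = nrow(hist))
  K <- schedule$n_secondary
  first_ev <- apply(hist, 1L, function(x) which.max(x == 1L))
  structure(list(histories = hist, schedule = schedule,
                 first_primary = (first_ev - 1L) %/% K + 1L,
                 first_event = first_ev, group = group,
                 covariates = covariates %||%
                   data.frame(row.names = seq_len(nrow(hist))),
                 freq = freq %||% rep(1L, nrow(hist)), truth = NULL),
            class = "encounter_histories")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Render one interior spot scene and measure it through the full chain.
measure_single_spot <- function(radius_gu = 0.1, aspect = 1, rough = 0,
                                hpx = 300, wpx = 400, seed = 42) {
  p <- coat_scene_params(rect_width_px = wpx, rect_height_px = hpx,
                         n_spots = 1, mean_radius_gu = radius_gu,
                         radius_cv = 0, aspect_ratio_mean = aspect,
                         boundary_roughness = rough, noise_sd = 0,
                         edge_margin_gu = min(0.45, 3 * radius_gu), seed = seed)
  sc <- gen_coat_image(p)
  ex <- extract_spots(sc$image, sc$rect)
  list(spots = measure_spots(ex$spot_map), truth = sc$truth, scene = sc,
       map = ex$spot_map)
}
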