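## Coat-pattern phenotype definition: z-scoring, PCA of the ten measured
## traits, k-means phenotype groups, gap-statistic choice of group number,
## and lumping of overlapping groups.

#' Z-score a trait matrix
#'
#' Column-wise standardisation (SD with n-1 denominator). Colour (mode
#' shade) is conventionally excluded before this step, leaving the ten
#' measured traits.
#'
#' @param raw Numeric matrix or data frame, animals x traits.
#' @return Matrix of z-scores with the input dimnames.
#' @export
standardize_traits <- function(raw) {
  X <- as.matrix(raw)
  if (nrow(X) < 2L) stop("need at least 2 animals to standardise")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds < 1e-12)) {
    bad <- colnames(X)[sds < 1e-12]
    if (is.null(bad)) bad <- which(sds < 1e-12)
    stop("constant trait column(s): ", paste(bad, collapse = ", "))
  }
  scale(X)[, , drop = FALSE]
}

#' Principal components analysis of standardised traits
#'
#' Eigendecomposition of the correlation matrix (equivalently the
#' covariance of the z-scores). Loading vectors are sign-flipped so the
#' largest-magnitude entry of each is positive; the contribution of a trait
#' to a dimension is `100 * loading^2` (unit-norm loadings, so
#' contributions per dimension sum to 100).
#'
#' @param X Standardised trait matrix (see [standardize_traits()]).
#' @return Object of class `trait_pca`: `eigenvalues`, `percent_variance`,
#'   `loadings`, `scores`, `contributions`.
#' @export
trait_pca <- function(X) {
  X <- as.matrix(X)
  Cm <- stats::cor(X)
  eg <- eigen(Cm, symmetric = TRUE)
  val <- pmax(eg$values, 0)
  vec <- eg$vectors
  for (i in seq_len(ncol(vec))) {
    j <- which.max(abs(vec[, i]))
    if (vec[j, i] < 0) vec[, i] <- -vec[, i]
  }
  dimnames(vec) <- list(colnames(X), paste0("Dim", seq_len(ncol(vec))))
  structure(list(eigenvalues = val,
                 percent_variance = 100 * val / sum(val),
                 loadings = vec,
                 scores = X %*% vec,
                 contributions = 100 * vec^2),
            class = "trait_pca")
}

#' @export
print.trait_pca <- function(x, ...) {
  cat("PCA of standardised spot traits\n")
  pv <- round(x$percent_variance, 1)
  for (i in seq_len(min(4L, length(pv))))
    cat(sprintf("  Dim%d: eigenvalue %.3f, %.1f%% of variance\n",
                i, x$eigenvalues[i], pv[i]))
  invisible(x)
}

#' K-means phenotype groups
#'
#' Best of `n_restarts` seeded Lloyd k-means runs by total within-cluster
#' sum of squares.
#'
#' @param X Numeric matrix, animals x traits.
#' @param k Number of groups (1 <= k <= n).
#' @param seed Seed controlling the restarts.
#' @param n_restarts Random restarts (default 50).
#' @return Object of class `cluster_model`: `k`, `centers`, `assignment`,
#'   `tot_withinss`, `seed`, `n_restarts`.
#' @export
kmeans_fit <- function(X, k, seed = 20120101, n_restarts = 50) {
  X <- as.matrix(X)
  stop_if_not_scalar_num(k, "k", 1, nrow(X), integer = TRUE)
  set.seed(derive_seed(seed, "kmeans"))
  if (k == 1L) {
    ctr <- matrix(colMeans(X), 1L)
    colnames(ctr) <- colnames(X)
    return(structure(list(k = 1L, centers = ctr,
                          assignment = rep(1L, nrow(X)),
                          tot_withinss = sum(sweep(X, 2L, colMeans(X))^2),
                          seed = seed, n_restarts = n_restarts),
                     class = "cluster_model"))
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    km <- tryCatch(suppressWarnings(
      stats::kmeans(X, centers = k, iter.max = 300, algorithm = "Lloyd")),
      error = function(e) NULL)
    if (is.null(km) || length(unique(km$cluster)) < k) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best))
    stop("k-means failed to produce ", k, " non-empty clusters")
  structure(list(k = as.integer(k), centers = best$centers,
                 assignment = as.integer(best$cluster),
                 tot_withinss = best$tot.withinss,
                 seed = seed, n_restarts = n_restarts),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("k-means phenotype model: k = %d, within-SS = %.4f, sizes: %s\n",
              x$k, x$tot_withinss,
              paste(tabulate(x$assignment, x$k), collapse = ", ")))
  invisible(x)
}

#' Gap statistic for the number of phenotype groups
#'
#' Compares `log W_k` (total within-cluster SS) with its expectation under
#' `B` reference data sets drawn uniformly over each feature's observed
#' range. `gap_k = mean_b log W*_kb - log W_k` and
#' `s_k = sd_b(log W*) * sqrt(1 + 1/B)`. The chosen k is the smallest k
#' with `gap_k >= gap_{k+1} - s_{k+1}`; the full curve is returned because
#' the criterion can be multi-modal in practice.
#'
#' @param X Numeric matrix.
#' @param k_max Largest k to evaluate.
#' @param B Number of reference data sets (>= 10).
#' @param seed Seed (reference draws and k-means restarts).
#' @param n_restarts K-means restarts per k.
#' @return Object of class `gap_curve`: data frame `curve` with
#'   `k, logW, ElogW, gap, s`, and `chosen_k`.
#' @export
gap_statistic <- function(X, k_max = 6, B = 50, seed = 20120101,
                          n_restarts = 10) {
  X <- as.matrix(X)
  stop_if_not_scalar_num(k_max, "k_max", 1, nrow(X) - 1, integer = TRUE)
  stop_if_not_scalar_num(B, "B", 10, integer = TRUE)
  logW <- vapply(seq_len(k_max), function(k)
    log(kmeans_fit(X, k, seed = derive_seed(seed, paste0("gapobs", k)),
                   n_restarts = n_restarts)$tot_withinss), numeric(1))
  rng_lo <- apply(X, 2L, min); rng_hi <- apply(X, 2L, max)
  logWstar <- matrix(NA_real_, B, k_max)
  for (bb in seq_len(B)) {
    set.seed(derive_seed(seed, paste0("gapref", bb)))
    Xb <- sapply(seq_len(ncol(X)), function(j)
      stats::runif(nrow(X), rng_lo[j], rng_hi[j]))
    for (k in seq_len(k_max))
      logWstar[bb, k] <- log(kmeans_fit(Xb, k,
                                        seed = derive_seed(seed, paste0("gapref", bb, "k", k)),
                                        n_restarts = n_restarts)$tot_withinss)
  }
  ElogW <- colMeans(logWstar)
  gap <- ElogW - logW
  s <- apply(logWstar, 2L, stats::sd) * sqrt(1 + 1 / B)
  chosen <- k_max
  for (k in seq_len(k_max - 1L)) {
    if (gap[k] >= gap[k + 1L] - s[k + 1L]) { chosen <- k; break }
  }
  structure(list(curve = data.frame(k = seq_len(k_max), logW = logW,
                                    ElogW = ElogW, gap = gap, s = s),
                 chosen_k = as.integer(chosen), B = as.integer(B),
                 seed = seed),
            class = "gap_curve")
}

#' @export
print.gap_curve <- function(x, ...) {
  cat(sprintf("Gap statistic (B = %d): chosen k = %d\n", x$B, x$chosen_k))
  print(round(x$curve, 4))
  invisible(x)
}

#' @describeIn gap_statistic Plot the gap curve with 1-SE bars.
#' @param x A `gap_curve`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.gap_curve <- function(x, ...) {
  cv <- x$curve
  graphics::plot(cv$k, cv$gap, type = "b", xlab = "number of groups k",
                 ylab = "gap statistic", ...)
  graphics::arrows(cv$k, cv$gap - cv$s, cv$k, cv$gap + cv$s,
                   angle = 90, code = 3, length = 0.04)
  graphics::abline(v = x$chosen_k, lty = 2)
  invisible(x)
}

#' Lump phenotype groups
#'
#' Merges groups according to `merge_map` (a vector mapping each old label
#' to its new label; new labels must form `1..k_new` collectively).
#' Centers are recomputed as the merged-group means of the data.
#'
#' @param model A `cluster_model`.
#' @param merge_map Integer vector of length `model$k`, e.g. `c(1, 1, 2, 3)`
#'   lumps old groups 1 and 2.
#' @param X The data matrix the model was fitted to (for center and
#'   within-SS recomputation).
#' @return A new `cluster_model` with `k = max(merge_map)`.
#' @export
lump_groups <- function(model, merge_map, X) {
  stopifnot(inherits(model, "cluster_model"))
  X <- as.matrix(X)
  if (length(merge_map) != model$k)
    stop("merge_map must give a new label for each of the ", model$k, " groups")
  new_k <- max(merge_map)
  if (!setequal(merge_map, seq_len(new_k)))
    stop("merge_map must be a surjection onto 1..", new_k)
  assign_new <- merge_map[model$assignment]
  ctr <- do.call(rbind, lapply(seq_len(new_k), function(g)
    colMeans(X[assign_new == g, , drop = FALSE])))
  wss <- sum(vapply(seq_len(new_k), function(g) {
    sum(sweep(X[assign_new == g, , drop = FALSE], 2L, ctr[g, ])^2)
  }, numeric(1)))
  structure(list(k = as.integer(new_k), centers = ctr,
                 assignment = as.integer(assign_new), tot_withinss = wss,
                 seed = model$seed, n_restarts = model$n_restarts),
            class = "cluster_model")
}
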