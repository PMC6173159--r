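## Synthetic trait tables with known ground truth: mother-offspring pairs,
## repeated measurements, and clustered trait matrices.

#' Generate mother-offspring trait pairs with a known regression slope
#'
#' Mothers are drawn from `N(trait_mean, trait_var)`; each calf value is
#' `trait_mean + po_slope * (mother - trait_mean) + e`, with the noise
#' variance chosen so the calf variance also equals `trait_var`. The
#' expected OLS slope of calf on mother is therefore `po_slope`, and the
#' implied narrow-sense heritability is `2 * po_slope`.
#'
#' @param n_pairs Number of pairs (>= 3).
#' @param trait_mean,trait_var Trait mean and variance (`trait_var > 0`).
#' @param po_slope Expected parent-offspring regression slope in `[0, 1]`.
#' @param seed Integer seed.
#' @return Data frame `(pair_id, mother_value, calf_value)`.
#' @export
gen_po_pairs <- function(n_pairs, trait_mean = 0, trait_var = 1,
                         po_slope = 0.5, seed = 1L) {
  stop_if_not_scalar_num(n_pairs, "n_pairs", 3, integer = TRUE)
  stop_if_not_scalar_num(trait_var, "trait_var", 1e-12)
  stop_if_not_scalar_num(po_slope, "po_slope", 0, 1)
  set.seed(seed)
  mother <- stats::rnorm(n_pairs, trait_mean, sqrt(trait_var))
  noise_var <- trait_var * (1 - po_slope^2)
  calf <- trait_mean + po_slope * (mother - trait_mean) +
    stats::rnorm(n_pairs, 0, sqrt(noise_var))
  data.frame(pair_id = seq_len(n_pairs), mother_value = mother,
             calf_value = calf)
}

#' Generate repeated trait measurements with known repeatability
#'
#' Individual means have variance `R_true * total_var`; within-individual
#' residuals have variance `(1 - R_true) * total_var`, so the intraclass
#' correlation (repeatability) is `R_true`.
#'
#' @param n_individuals Number of individuals (>= 2).
#' @param n_reps Measurements per individual (>= 2).
#' @param R_true True repeatability in `[0, 1]`.
#' @param total_var Total phenotypic variance.
#' @param trait_mean Grand mean.
#' @param seed Integer seed.
#' @return Data frame `(individual_id, photo_id, trait_name, value)`.
#' @export
gen_repeat_measurements <- function(n_individuals, n_reps, R_true,
                                    total_var = 1, trait_mean = 0, seed = 1L) {
  stop_if_not_scalar_num(n_individuals, "n_individuals", 2, integer = TRUE)
  stop_if_not_scalar_num(n_reps, "n_reps", 2, integer = TRUE)
  stop_if_not_scalar_num(R_true, "R_true", 0, 1)
  stop_if_not_scalar_num(total_var, "total_var", 1e-12)
  set.seed(seed)
  mu <- stats::rnorm(n_individuals, trait_mean, sqrt(R_true * total_var))
  value <- rep(mu, each = n_reps) +
    stats::rnorm(n_individuals * n_reps, 0, sqrt((1 - R_true) * total_var))
  data.frame(individual_id = rep(sprintf("ind%03d", seq_len(n_individuals)),
                                 each = n_reps),
             photo_id = rep(seq_len(n_reps), n_individuals),
             trait_name = "trait",
             value = value)
}

#' Generate a clustered trait matrix with true labels
#'
#' Spherical unit-variance Gaussian clusters whose centers are `separation`
#' (within-cluster) standard deviations apart: centers are drawn at random
#' directions and rescaled so the minimum pairwise center distance equals
#' `separation`.
#'
#' @param k Number of clusters (>= 1).
#' @param n_per_cluster Points per cluster.
#' @param separation Center separation in within-cluster SD units.
#' @param n_dims Number of trait dimensions.
#' @param seed Integer seed.
#' @return List with matrix `X` (`k * n_per_cluster` rows) and integer
#'   vector `labels`.
#' @export
gen_clustered_traits <- function(k, n_per_cluster = 50, separation = 6,
                                 n_dims = 4, seed = 1L) {
  stop_if_not_scalar_num(k, "k", 1, integer = TRUE)
  stop_if_not_scalar_num(n_per_cluster, "n_per_cluster", 1, integer = TRUE)
  stop_if_not_scalar_num(separation, "separation", 0)
  stop_if_not_scalar_num(n_dims, "n_dims", 1, integer = TRUE)
  set.seed(seed)
  centers <- matrix(0, k, n_dims)
  if (k > 1) {
    centers <- matrix(stats::rnorm(k * n_dims), k, n_dims)
    dmin <- min(stats::dist(centers))
    if (dmin < 1e-8) stop("degenerate random centers; use another seed")
    centers <- centers * (separation / dmin)
  }
  labels <- rep(seq_len(k), each = n_per_cluster)
  X <- centers[labels, , drop = FALSE] +
    matrix(stats::rnorm(k * n_per_cluster * n_dims), ncol = n_dims)
  colnames(X) <- sprintf("trait%d", seq_len(n_dims))
  list(X = X, labels = labels)
}
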