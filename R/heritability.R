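## Repeatability, mother-offspring regression with heritability, Bonferroni
## control, and regression diagnostics.

#' Mother-offspring (parent-offspring) regression
#'
#' Ordinary least squares of the calf value on the mother value for one
#' trait. Under single-parent-offspring regression the narrow-sense
#' heritability is twice the slope, `h2 = 2 * slope`, with
#' `SE(h2) = 2 * SE(slope)`.
#'
#' @param pairs Data frame with columns `mother_value` and `calf_value`
#'   (one row per pair, no missing values), at least 3 rows.
#' @param trait Optional trait label carried into the result.
#' @return Object of class `po_regression`: `slope`, `slope_se`,
#'   `intercept`, `F_stat`, `df`, `p_value`, `heritability`,
#'   `heritability_se`, `n`, and the underlying `lm` fit.
#' @export
po_regression <- function(pairs, trait = NULL) {
  stopifnot(is.data.frame(pairs),
            all(c("mother_value", "calf_value") %in% names(pairs)))
  pairs <- pairs[stats::complete.cases(pairs[, c("mother_value", "calf_value")]), ]
  n <- nrow(pairs)
  if (n < 3L) stop("parent-offspring regression needs at least 3 complete pairs")
  if (stats::var(pairs$mother_value) < 1e-300)
    stop("zero variance in mother values: regression undefined")
  fit <- stats::lm(calf_value ~ mother_value, data = pairs)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2L])
  se <- sm$coefficients[2L, 2L]
  Fst <- sm$fstatistic[[1L]]
  pval <- stats::pf(Fst, 1, n - 2, lower.tail = FALSE)
  structure(list(trait = trait, n = n,
                 slope = slope, slope_se = se,
                 intercept = unname(stats::coef(fit)[1L]),
                 F_stat = Fst, df = base::c(1L, n - 2L), p_value = pval,
                 heritability = po_heritability(slope),
                 heritability_se = 2 * se,
                 fit = fit),
            class = "po_regression")
}

#' Heritability implied by a single-parent-offspring regression slope
#'
#' A parent-offspring regression on one parent estimates half the additive
#' genetic variance fraction, so `h2 = 2 * slope`.
#'
#' @param slope Regression slope of offspring on single parent.
#' @return Narrow-sense heritability estimate.
#' @examples
#' po_heritability(0.52)  # 1.04
#' @export
po_heritability <- function(slope) 2 * slope

#' @export
print.po_regression <- function(x, ...) {
  cat(sprintf("Parent-offspring regression%s (n = %d pairs)\n",
              if (is.null(x$trait)) "" else paste0(" [", x$trait, "]"), x$n))
  cat(sprintf("  slope = %.4f (SE %.4f), F(1,%d) = %.3f, p = %.4g\n",
              x$slope, x$slope_se, x$df[2L], x$F_stat, x$p_value))
  cat(sprintf("  heritability h2 = 2 x slope = %.4f (SE %.4f)\n",
              x$heritability, x$heritability_se))
  invisible(x)
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha Family-wise level, in (0, 1).
#' @param m_tests Number of tests (>= 1).
#' @return `alpha / m_tests`, with a `rounded` attribute at 4 decimals.
#' @examples
#' bonferroni_alpha(0.05, 11)  # 0.004545..., rounded 0.0045
#' @export
bonferroni_alpha <- function(alpha, m_tests) {
  stop_if_not_scalar_num(alpha, "alpha", 1e-12, 1 - 1e-12)
  stop_if_not_scalar_num(m_tests, "m_tests", 1, integer = TRUE)
  out <- alpha / m_tests
  attr(out, "rounded") <- round(out, 4)
  out
}

## Unbalanced one-way ANOVA group-size coefficient (k0): the effective
## number of measurements per individual.
.k0 <- function(ni) {
  a <- length(ni); N <- sum(ni)
  (N - sum(ni^2) / N) / (a - 1)
}

#' Repeatability (intraclass correlation) of a trait
#'
#' One-way ANOVA estimator of the within-individual correlation among
#' repeated measurements: `R = (MS_A - MS_W) / (MS_A + (k0 - 1) MS_W)` with
#' `k0` the unbalanced-design group-size coefficient. Negative point
#' estimates are truncated to 0. The p-value is the ANOVA F test; the SE
#' comes from a seeded parametric bootstrap under the fitted variance
#' components.
#'
#' @param table Data frame with columns `individual_id` and `value` (long
#'   format; a `trait_name` column is filtered on if `trait` is given).
#' @param trait Optional trait name to select from `trait_name`.
#' @param n_boot Parametric bootstrap replicates for the SE (default 1000).
#' @param seed Bootstrap seed.
#' @return Object of class `repeatability`: `R`, `R_se`, `p_value`,
#'   variance components `sigma2_ind`, `sigma2_res`, and bootstrap draws.
#' @export
repeatability <- function(table, trait = NULL, n_boot = 1000, seed = 1L) {
  stopifnot(is.data.frame(table), "individual_id" %in% names(table),
            "value" %in% names(table))
  if (!is.null(trait) && "trait_name" %in% names(table))
    table <- table[table$trait_name == trait, ]
  table <- table[!is.na(table$value), ]
  cnt <- table(table$individual_id)
  drop <- names(cnt)[cnt < 2L]
  if (length(drop)) {
    warning(sprintf("dropping %d individual(s) with fewer than 2 measurements",
                    length(drop)))
    table <- table[!table$individual_id %in% drop, ]
  }
  if (nrow(table) == 0L || length(unique(table$individual_id)) < 2L)
    stop("repeatability needs at least 2 individuals with 2+ measurements each")
  est <- .repeat_anova(table$individual_id, table$value)
  ## parametric bootstrap under the fitted one-way Gaussian model
  set.seed(derive_seed(seed, "repeatability_boot"))
  ni <- as.vector(table(table$individual_id))
  mu <- mean(table$value)
  boots <- numeric(n_boot)
  for (bb in seq_len(n_boot)) {
    m <- stats::rnorm(length(ni), mu, sqrt(est$sigma2_ind))
    v <- rep(m, ni) + stats::rnorm(sum(ni), 0, sqrt(est$sigma2_res))
    boots[bb] <- .repeat_anova(rep(seq_along(ni), ni), v)$R
  }
  structure(list(R = est$R, R_se = stats::sd(boots), p_value = est$p_value,
                 sigma2_ind = est$sigma2_ind, sigma2_res = est$sigma2_res,
                 n_individuals = length(ni), n_obs = sum(ni),
                 boot = boots),
            class = "repeatability")
}

.repeat_anova <- function(id, value) {
  id <- factor(id)
  ## suppressed warning: lm flags "essentially perfect fit" when the
  ## within-individual variance is exactly zero (legal here: R = 1)
  aovt <- suppressWarnings(stats::anova(stats::lm(value ~ id)))
  MSA <- aovt$`Mean Sq`[1L]; MSW <- aovt$`Mean Sq`[2L]
  k0 <- .k0(as.vector(table(id)))
  R_raw <- (MSA - MSW) / (MSA + (k0 - 1) * MSW)
  s2i <- max((MSA - MSW) / k0, 0)
  s2r <- MSW
  pv <- if (MSW <= 0) {        # perfect repeats: F degenerate, evidence maximal
    0
  } else aovt$`Pr(>F)`[1L]
  list(R = max(R_raw, 0), p_value = pv, sigma2_ind = s2i, sigma2_res = s2r)
}

#' @export
print.repeatability <- function(x, ...) {
  cat(sprintf("Repeatability R = %.4f (bootstrap SE %.4f), ANOVA p = %.4g\n",
              x$R, x$R_se, x$p_value))
  cat(sprintf("  %d individuals, %d measurements; var(ind) = %.4g, var(res) = %.4g\n",
              x$n_individuals, x$n_obs, x$sigma2_ind, x$sigma2_res))
  invisible(x)
}

#' Regression diagnostics: residual normality and heteroscedasticity
#'
#' Shapiro-Wilk test of the residuals, and the Breusch-Pagan score test of
#' the squared standardised residuals against the fitted values (chi-square
#' with 1 df; the non-constant-variance score test).
#'
#' @param fit An `lm` or `po_regression` object.
#' @return List with `normality_p`, `heteroscedasticity_p`, and the test
#'   statistics; degenerate residuals (all equal) report `NA` with a
#'   warning instead of failing.
#' @export
regression_diagnostics <- function(fit) {
  if (inherits(fit, "po_regression")) fit <- fit$fit
  stopifnot(inherits(fit, "lm"))
  e <- stats::residuals(fit)
  n <- length(e)
  if (n < 5L) {
    warning("fewer than 5 residuals: diagnostics skipped")
    return(list(normality_p = NA_real_, heteroscedasticity_p = NA_real_,
                shapiro_W = NA_real_, bp_statistic = NA_real_))
  }
  if (stats::sd(e) < 1e-12) {
    warning("degenerate (constant) residuals: diagnostics not defined")
    return(list(normality_p = NA_real_, heteroscedasticity_p = NA_real_,
                shapiro_W = NA_real_, bp_statistic = NA_real_))
  }
  es <- if (n > 5000) e[seq(1L, n, length.out = 5000L)] else e  # test's n cap
  sw <- stats::shapiro.test(es)
  ## score test: regress u = e^2 / mean(e^2) on the fitted values;
  ## statistic = SS_reg / 2 ~ chi^2_1 under homoscedasticity
  u <- e^2 / mean(e^2)
  z <- stats::fitted(fit)
  aux <- stats::lm(u ~ z)
  ssreg <- sum((stats::fitted(aux) - mean(u))^2)
  stat <- ssreg / 2
  list(normality_p = sw$p.value,
       heteroscedasticity_p = stats::pchisq(stat, 1, lower.tail = FALSE),
       shapiro_W = unname(sw$statistic),
       bp_statistic = stat)
}

#' Trait-by-trait similarity summary
#'
#' Convenience wrapper producing the summary-table shape of the study:
#' per trait the mean, SD, CV, repeatability (with SE and p) when repeated
#' measurements are supplied, and the PO slope, SE, heritability, F and p.
#'
#' @param pair_tables Named list of pair data frames (one per trait), each
#'   with `mother_value`/`calf_value`.
#' @param repeat_tables Optional named list of repeated-measures tables.
#' @param n_boot,seed Passed to [repeatability()].
#' @return Data frame with one row per trait.
#' @export
similarity_summary <- function(pair_tables, repeat_tables = NULL,
                               n_boot = 1000, seed = 1L) {
  rows <- lapply(names(pair_tables), function(tr) {
    pr <- pair_tables[[tr]]
    po <- po_regression(pr, trait = tr)
    vals <- base::c(pr$mother_value, pr$calf_value)
    out <- data.frame(trait = tr, mean = mean(vals), sd = stats::sd(vals),
                      cv = stats::sd(vals) / abs(mean(vals)),
                      R = NA_real_, R_se = NA_real_, R_p = NA_real_,
                      slope = po$slope, slope_se = po$slope_se,
                      heritability = po$heritability, F_stat = po$F_stat,
                      p_value = po$p_value)
    if (!is.null(repeat_tables) && tr %in% names(repeat_tables)) {
      rp <- repeatability(repeat_tables[[tr]], n_boot = n_boot, seed = seed)
      out$R <- rp$R; out$R_se <- rp$R_se; out$R_p <- rp$p_value
    }
    out
  })
  do.call(rbind, rows)
}
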