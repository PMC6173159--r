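## Robust-design encounter-history simulation with known ground truth.

#' Robust-design survey schedule
#'
#' Nested sampling design: closed secondary events inside open primary
#' occasions separated by one season (4 months). Either give `n_primary`
#' directly, or a `start`/`end` month range with `occasions_per_year`
#' occasions anchored at February/June/October (the study design of three
#' occasions per year); the number of events is then
#' `n_primary * n_secondary`.
#'
#' @param n_primary Number of primary occasions (>= 2), or NULL to derive
#'   from dates.
#' @param n_secondary Secondary events per primary occasion (>= 1).
#' @param start,end Months as `"YYYY-MM"` strings (used when `n_primary` is
#'   NULL): all occasion months within the closed range are counted.
#' @param occasions_per_year Occasions per year when deriving from dates.
#' @return A `survey_schedule` with fields `n_primary`, `n_secondary`,
#'   `n_events` and `interval_months`.
#' @examples
#' survey_schedule(start = "2012-01", end = "2016-02")$n_events  # 26
#' @export
survey_schedule <- function(n_primary = NULL, n_secondary = 2,
                            start = NULL, end = NULL,
                            occasions_per_year = 3) {
  stop_if_not_scalar_num(n_secondary, "n_secondary", 1, integer = TRUE)
  if (is.null(n_primary)) {
    if (is.null(start) || is.null(end))
      stop("give either n_primary or a start/end month range")
    s <- as.Date(paste0(start, "-01")); e <- as.Date(paste0(end, "-01"))
    interval <- 12 / occasions_per_year
    months <- seq(2, by = interval, length.out = occasions_per_year) # Feb anchor
    all_m <- seq(s, e, by = "month")
    n_primary <- sum(as.integer(format(all_m, "%m")) %in% months)
  }
  stop_if_not_scalar_num(n_primary, "n_primary", 2, integer = TRUE)
  structure(list(n_primary = as.integer(n_primary),
                 n_secondary = as.integer(n_secondary),
                 n_events = as.integer(n_primary * n_secondary),
                 interval_months = 4),
            class = "survey_schedule")
}

#' The survey schedule of the motivating giraffe study
#'
#' 13 primary occasions (three per year, Jan 2012 to Feb 2016) of two
#' secondary events each: 26 survey events.
#' @export
giraffe_schedule <- function() survey_schedule(start = "2012-01", end = "2016-02")

#' Simulation design for robust-design encounter histories
#'
#' @param schedule A [survey_schedule()].
#' @param n_released_per_occasion Neonates entering per primary occasion.
#' @param s_intercept Logit of seasonal apparent survival at age 0 for the
#'   reference group.
#' @param s_age_slope Logit-linear age (seasons) slope of survival.
#' @param group_logits Additive group offsets on the survival logit; first
#'   element must be 0 (reference). Length = number of groups.
#' @param beta_cov Survival-logit coefficient of the individual covariate.
#' @param cov_window Ages (seasons since birth, interval start) at which the
#'   covariate acts; NULL = all ages.
#' @param gamma_prime Pr(stay unavailable | was outside), in `[0,1]`.
#' @param gamma_dprime Pr(become unavailable | was inside), in `[0,1]`.
#' @param p_per_occasion First-capture detection probability per primary
#'   occasion (scalar recycled to `n_primary`).
#' @param c_per_occasion Within-primary recapture probability per primary
#'   occasion (scalar recycled).
#' @param covariate_mean,covariate_sd Distribution of the individual
#'   covariate.
#' @param seed Integer seed.
#' @return A `cmr_sim_design` list.
#' @export
cmr_sim_design <- function(schedule = giraffe_schedule(),
                           n_released_per_occasion = 20,
                           s_intercept = stats::qlogis(0.85),
                           s_age_slope = 0,
                           group_logits = 0,
                           beta_cov = 0, cov_window = NULL,
                           gamma_prime = 0.1, gamma_dprime = 0.1,
                           p_per_occasion = 0.6, c_per_occasion = 0.6,
                           covariate_mean = 0, covariate_sd = 1,
                           seed = 1L) {
  stopifnot(inherits(schedule, "survey_schedule"))
  if (group_logits[1L] != 0) stop("first group offset must be 0 (reference)")
  stop_if_not_scalar_num(gamma_prime, "gamma_prime", 0, 1)
  stop_if_not_scalar_num(gamma_dprime, "gamma_dprime", 0, 1)
  T <- schedule$n_primary
  p <- rep_len(p_per_occasion, T); c <- rep_len(c_per_occasion, T)
  if (any(p < 0 | p > 1 | c < 0 | c > 1))
    stop("detection probabilities must lie in [0,1]")
  structure(list(schedule = schedule,
                 n_released_per_occasion = n_released_per_occasion,
                 s_intercept = s_intercept, s_age_slope = s_age_slope,
                 group_logits = group_logits, beta_cov = beta_cov,
                 cov_window = cov_window,
                 gamma_prime = gamma_prime, gamma_dprime = gamma_dprime,
                 p_per_occasion = p, c_per_occasion = c,
                 covariate_mean = covariate_mean, covariate_sd = covariate_sd,
                 seed = seed),
            class = "cmr_sim_design")
}

#' Simulate robust-design encounter histories
#'
#' Individuals enter as neonates (age 0) at their cohort occasion in the
#' available (inside) state. Between primary occasions they survive with the
#' age/group/covariate-dependent seasonal probability S, then move between
#' the inside and outside states with temporary-emigration probabilities
#' gamma'' (inside to outside) and gamma' (outside stays outside). Inside
#' animals are detected per secondary event with p (before their first
#' capture of that primary) or c (after); outside and dead animals are never
#' detected. Only individuals first detected during their birth occasion are
#' retained (neonate first captures), and histories are conditioned on that
#' first capture.
#'
#' @param design A [cmr_sim_design()].
#' @return An `encounter_histories` object: 0/1 matrix `histories`
#'   (`n x n_events`), `schedule`, `first_primary`, `first_event`, `group`
#'   factor, `covariates` data frame, `freq`, and a `truth` list with the
#'   simulated state matrix and parameters.
#' @export
gen_encounter_histories <- function(design) {
  stopifnot(inherits(design, "cmr_sim_design"))
  set.seed(design$seed)
  sch <- design$schedule
  T <- sch$n_primary; K <- sch$n_secondary
  n_groups <- length(design$group_logits)
  cohort <- rep(seq_len(T), each = design$n_released_per_occasion)
  n <- length(cohort)
  group <- sample.int(n_groups, n, replace = TRUE)
  cov <- stats::rnorm(n, design$covariate_mean, design$covariate_sd)
  states <- matrix(NA_integer_, n, T)     # 1 inside, 2 outside, 3 dead
  hist <- matrix(0L, n, T * K)
  for (j in seq_len(T)) {
    newly <- cohort == j
    states[newly, j] <- 1L
    at_risk <- !is.na(states[, j]) & states[, j] == 1L
    ## detection within primary j
    captured <- rep(FALSE, n)
    for (s in seq_len(K)) {
      pr <- ifelse(captured, design$c_per_occasion[j], design$p_per_occasion[j])
      det <- at_risk & (stats::runif(n) < pr)
      hist[, (j - 1L) * K + s] <- as.integer(det)
      captured <- captured | det
    }
    if (j < T) {
      alive <- !is.na(states[, j]) & states[, j] != 3L
      age <- j - cohort
      lp <- design$s_intercept + design$s_age_slope * age +
        design$group_logits[group]
      if (design$beta_cov != 0) {
        w <- if (is.null(design$cov_window)) 1 else as.numeric(age %in% design$cov_window)
        lp <- lp + design$beta_cov * cov * w
      }
      S <- stats::plogis(lp)
      surv <- alive & (stats::runif(n) < S)
      inside <- states[, j] == 1L
      u <- stats::runif(n)
      nxt <- rep(NA_integer_, n)
      nxt[alive & !surv] <- 3L
      nxt[surv & inside] <- ifelse(u[surv & inside] < design$gamma_dprime, 2L, 1L)
      nxt[surv & !inside] <- ifelse(u[surv & !inside] < design$gamma_prime, 2L, 1L)
      states[, j + 1L] <- nxt
    }
  }
  ## retain neonate first captures; condition on first capture
  birth_cols <- function(b) (b - 1L) * K + seq_len(K)
  first_ev <- apply(hist, 1L, function(x) if (any(x == 1L)) which.max(x == 1L) else NA_integer_)
  keep <- !is.na(first_ev) & ((first_ev - 1L) %/% K + 1L) == cohort
  hist <- hist[keep, , drop = FALSE]
  structure(list(histories = hist,
                 schedule = sch,
                 first_primary = cohort[keep],
                 first_event = first_ev[keep],
                 group = factor(group[keep]),
                 covariates = data.frame(cov = cov[keep]),
                 freq = rep(1L, sum(keep)),
                 truth = list(states = states[keep, , drop = FALSE],
                              design = design,
                              all_states = states, all_cohort = cohort)),
            class = "encounter_histories")
}

#' @export
print.encounter_histories <- function(x, ...) {
  cat(sprintf("Encounter histories: %d individuals, %d primaries x %d events = %d columns\n",
              nrow(x$histories), x$schedule$n_primary, x$schedule$n_secondary,
              x$schedule$n_events))
  if (!is.null(x$group)) cat(sprintf("  groups: %s\n",
                                     paste(levels(x$group), collapse = ", ")))
  if (!is.null(x$covariates) && ncol(x$covariates))
    cat(sprintf("  covariates: %s\n", paste(names(x$covariates), collapse = ", ")))
  invisible(x)
}
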