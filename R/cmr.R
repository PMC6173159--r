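## Robust-design capture-mark-recapture likelihood and multimodel inference.
##
## The observation model follows the classic robust design: open intervals
## between primary occasions (apparent survival S, temporary emigration
## gamma''/gamma') and closed secondary events within occasions (first
## capture p, within-primary recapture c). The likelihood conditions on each
## individual's first capture and runs a forward pass over the hidden states
## {alive inside, alive outside, dead}; outside and dead animals are never
## detected. All probabilities use the logit link. Model terms:
##   S, gamma', gamma'': formulas in A (age in seasons since first capture,
##     at interval start), group, and windowed covariates cov/cov2;
##   p, c: formulas in t (primary-occasion factor) or constant.

.window_ages <- function(window) {
  switch(window,
         first_season = 0L,
         first_year   = 0:2,
         first_3yr    = 0:8,
         all          = NULL,
         stop("unknown covariate window: ", window))
}

## Compile design matrices for one model on one data set.
rd_compile <- function(data, S = ~A, gamma_prime = ~1, gamma_dprime = ~1,
                       p = ~1, c = ~1,
                       covariate = NULL, covariate_form = "linear",
                       covariate_window = "all", standardize_covariate = TRUE,
                       share_gamma = FALSE) {
  stopifnot(inherits(data, "encounter_histories"))
  T <- data$schedule$n_primary
  K <- data$schedule$n_secondary
  n <- nrow(data$histories)
  f <- data$first_primary
  ## interval-level frame: all (individual, interval j -> j+1), j = 1..T-1,
  ## laid out column-major to match matrix(lp, n, T-1)
  A <- pmax(rep(1:(T - 1), each = n) - rep(f, T - 1), 0L)
  ivl <- data.frame(A = A)
  if (!is.null(data$group)) ivl$group <- rep(data$group, T - 1)
  if (!is.null(covariate)) {
    if (!covariate %in% names(data$covariates))
      stop("covariate '", covariate, "' not found in the data")
    z <- data$covariates[[covariate]]
    if (stats::sd(z) < 1e-12) stop("covariate '", covariate, "' is constant")
    if (standardize_covariate) z <- as.vector(scale(z))
    w_ages <- .window_ages(covariate_window)
    w <- if (is.null(w_ages)) 1 else as.numeric(A %in% w_ages)
    ivl$cov <- rep(z, T - 1) * w
    ivl$cov2 <- ivl$cov * rep(z, T - 1)  # windowed quadratic term
    S <- stats::update(S, if (covariate_form == "quadratic")
      ~ . + cov + cov2 else ~ . + cov)
  }
  occ <- data.frame(t = factor(seq_len(T), levels = seq_len(T)))
  Xs  <- stats::model.matrix(S, ivl)
  Xg1 <- stats::model.matrix(gamma_prime, ivl)
  Xg2 <- stats::model.matrix(gamma_dprime, ivl)
  if (share_gamma) Xg1 <- Xg1[, 0, drop = FALSE]  # gamma' tied to gamma''
  Xp  <- stats::model.matrix(p, occ)
  Xc  <- stats::model.matrix(c, occ)
  k <- base::c(S = ncol(Xs), gp = ncol(Xg1), gpp = ncol(Xg2),
               p = ncol(Xp), c = ncol(Xc))
  list(data = data, T = T, K = K, n = n, f = f,
       Xs = Xs, Xg1 = Xg1, Xg2 = Xg2, Xp = Xp, Xc = Xc, k = k,
       share_gamma = share_gamma,
       formulas = list(S = S, gamma_prime = gamma_prime,
                       gamma_dprime = gamma_dprime, p = p, c = c),
       covariate = covariate, covariate_form = covariate_form,
       covariate_window = covariate_window)
}

## Split the packed beta vector into blocks.
.rd_split <- function(beta, k) {
  ends <- cumsum(k)
  starts <- base::c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_along(k), function(i)
    if (k[i] == 0L) numeric(0) else beta[starts[i]:ends[i]])
}

#' Negative log-likelihood of a robust-design model
#'
#' Forward pass over the hidden states {alive inside, alive outside, dead},
#' conditional on first capture. Exposed mainly for testing (likelihood
#' normalisation, reduction to the Cormack-Jolly-Seber model); model fitting
#' goes through [fit_rd()].
#'
#' @param beta Packed coefficient vector (S, gamma', gamma'', p, c blocks).
#' @param compiled A compiled model as produced internally by [fit_rd()]
#'   (list with design matrices); see [fit_rd()]'s `compiled` element.
#' @return Scalar negative log-likelihood.
#' @export
rd_negloglik <- function(beta, compiled) {
  cm <- compiled
  if (length(beta) != sum(cm$k)) stop("beta has wrong length")
  b <- .rd_split(beta, cm$k)
  n <- cm$n; T <- cm$T; K <- cm$K
  Smat <- matrix(stats::plogis(cm$Xs %*% b[[1L]]), n, T - 1)
  G2 <- matrix(stats::plogis(cm$Xg2 %*% b[[3L]]), n, T - 1)
  G1 <- if (isTRUE(cm$share_gamma)) G2 else
    matrix(stats::plogis(cm$Xg1 %*% b[[2L]]), n, T - 1)
  pv <- as.vector(stats::plogis(cm$Xp %*% b[[4L]]))
  cv <- as.vector(stats::plogis(cm$Xc %*% b[[5L]]))
  hist <- cm$data$histories
  f <- cm$f
  fe_within <- cm$data$first_event - (f - 1L) * K  # first-capture event within its primary
  ain <- aout <- adead <- numeric(n)
  for (j in seq_len(T)) {
    cols <- (j - 1L) * K + seq_len(K)
    Y <- hist[, cols, drop = FALSE]
    any_det <- rowSums(Y) > 0L
    ## emission for the inside state
    e_in <- rep(1, n)
    captured <- rep(FALSE, n)
    newly <- f == j
    captured[newly] <- FALSE
    for (s in seq_len(K)) {
      y <- Y[, s]
      skip <- newly & s <= fe_within     # events up to & incl. first capture
      pr <- pv[j] + (cv[j] - pv[j]) * captured
      contrib <- y * pr + (1 - y) * (1 - pr)
      contrib[skip] <- 1
      e_in <- e_in * contrib
      captured <- captured | y == 1L
      captured[skip] <- TRUE
    }
    e_abs <- as.numeric(!any_det)        # outside/dead emission
    ain[newly] <- e_in[newly]
    aout[newly] <- 0; adead[newly] <- 0
    old <- f < j
    ain[old] <- ain[old] * e_in[old]
    aout[old] <- aout[old] * e_abs[old]
    adead[old] <- adead[old] * e_abs[old]
    if (j < T) {
      S <- Smat[, j]; g1 <- G1[, j]; g2 <- G2[, j]
      nin <- S * ((1 - g2) * ain + (1 - g1) * aout)
      nout <- S * (g2 * ain + g1 * aout)
      ndead <- adead + (1 - S) * (ain + aout)
      ain <- nin; aout <- nout; adead <- ndead
    }
  }
  L <- ain + aout + adead
  if (any(!is.finite(L)) || any(L <= 0)) {
    bad <- which(!is.finite(L) | L <= 0)[1L]
    return(1e10 + bad)  # penalised, flagged by index for debugging
  }
  -sum(cm$data$freq * log(L))
}

#' Fit a robust-design capture-mark-recapture model
#'
#' Maximum likelihood by quasi-Newton (BFGS) from a zero-initialised
#' coefficient vector plus seeded jittered restarts; standard errors from
#' the inverse Hessian; AICc with effective sample size equal to the number
#' of individual histories (configurable).
#'
#' @param data An `encounter_histories` object.
#' @param S,gamma_prime,gamma_dprime Formulas in `A` (age in seasons since
#'   first capture) and `group` for the survival and temporary-emigration
#'   logits, e.g. `S = ~ A + group`.
#' @param p,c Formulas in `t` (primary-occasion factor) for first-capture
#'   and recapture probabilities, e.g. `p = ~ t`.
#' @param covariate Name of an individual covariate column to add to the S
#'   predictor (z-scored unless `standardize_covariate = FALSE`).
#' @param covariate_form `"linear"` or `"quadratic"` (linear + quadratic
#'   jointly, standard polynomial nesting).
#' @param covariate_window Ages at which the covariate acts:
#'   `"first_season"` (age 0), `"first_year"` (ages 0-2), `"first_3yr"`
#'   (ages 0-8) or `"all"`.
#' @param standardize_covariate Z-score the covariate before fitting.
#' @param share_gamma Constrain gamma' = gamma'' (random rather than
#'   Markovian temporary emigration). The unconstrained model can explain
#'   mortality as permanent absence (gamma' near 1 with S near 1), a known
#'   weak-identifiability ridge; the constraint removes it.
#' @param n_restarts Jittered restarts after the zero start (default 5).
#' @param seed Seed for the restart jitter.
#' @param ess Effective sample size for AICc: `"individuals"` (default,
#'   sum of history frequencies) or `"events"`.
#' @param c_hat Overdispersion (variance inflation) factor: values > 1 scale
#'   the variance matrix by `c_hat` and replace AICc by QAICc
#'   (`-2 lnL / c_hat` in place of the deviance). Default 1 (off).
#' @param model_name Optional label used in model tables.
#' @return An object of class `rd_fit` with `beta`, `vcov`, `logLik`, `K`,
#'   `AICc`, `convergence`, the compiled design (`compiled`) and formulas.
#' @seealso [rd_real()], [akaike_weights()], [model_average()], [lrt_rd()]
#' @export
fit_rd <- function(data, S = ~A, gamma_prime = ~1, gamma_dprime = ~1,
                   p = ~1, c = ~1,
                   covariate = NULL, covariate_form = "linear",
                   covariate_window = "all", standardize_covariate = TRUE,
                   share_gamma = FALSE,
                   n_restarts = 5, seed = 1L, ess = "individuals",
                   c_hat = 1, model_name = NULL) {
  ess <- match.arg(ess, base::c("individuals", "events"))
  cm <- rd_compile(data, S, gamma_prime, gamma_dprime, p, c,
                   covariate, covariate_form, covariate_window,
                   standardize_covariate, share_gamma)
  kk <- sum(cm$k)
  starts <- list(rep(0, kk))
  if (n_restarts > 0) {
    set.seed(derive_seed(seed, "rd_restarts"))
    for (r in seq_len(n_restarts))
      starts[[r + 1L]] <- stats::rnorm(kk, 0, 0.5)
  }
  best <- NULL
  for (st in starts) {
    opt <- try(stats::optim(st, rd_negloglik, compiled = cm, method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-9)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value - 1e-8) best <- opt
  }
  if (is.null(best)) stop("optimisation failed from every start")
  hess <- try(stats::optimHess(best$par, rd_negloglik, compiled = cm),
              silent = TRUE)
  V <- matrix(NA_real_, kk, kk)
  if (!inherits(hess, "try-error")) {
    Vt <- try(solve(hess), silent = TRUE)
    if (!inherits(Vt, "try-error")) V <- Vt
  }
  lbl <- function(prefix, X) if (ncol(X) == 0L) character(0) else
    paste0(prefix, colnames(X))
  nm <- base::c(lbl("S:", cm$Xs), lbl("gp:", cm$Xg1), lbl("gpp:", cm$Xg2),
                lbl("p:", cm$Xp), lbl("c:", cm$Xc))
  beta <- stats::setNames(best$par, nm)
  dimnames(V) <- list(nm, nm)
  n_eff <- if (ess == "individuals") sum(cm$data$freq) else
    sum(cm$data$freq) * cm$data$schedule$n_events
  ll <- -best$value
  stopifnot(c_hat >= 1)
  if (c_hat > 1) V <- V * c_hat
  aicc <- -2 * ll / c_hat + 2 * kk + 2 * kk * (kk + 1) / max(n_eff - kk - 1, 1e-8)
  structure(list(beta = beta, vcov = V, logLik = ll, K = kk,
                 AICc = aicc, n = cm$n, ess = n_eff,
                 convergence = best$convergence,
                 gradient_norm = NA_real_,
                 compiled = cm,
                 model_name = model_name %||% .rd_name(cm)),
            class = "rd_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.rd_name <- function(cm) {
  f <- function(x) paste(deparse(x[[2L]]), collapse = "")
  nm <- sprintf("S(%s) gp(%s) gpp(%s) p(%s) c(%s)",
                f(cm$formulas$S), f(cm$formulas$gamma_prime),
                f(cm$formulas$gamma_dprime), f(cm$formulas$p),
                f(cm$formulas$c))
  if (!is.null(cm$covariate))
    nm <- paste0(nm, sprintf(" [%s %s, %s]", cm$covariate,
                             cm$covariate_form, cm$covariate_window))
  nm
}

#' @export
print.rd_fit <- function(x, ...) {
  cat("Robust-design CMR fit:", x$model_name, "\n")
  cat(sprintf("  K = %d, logLik = %.3f, AICc = %.3f (ESS = %d), n = %d\n",
              x$K, x$logLik, x$AICc, x$ess, x$n))
  if (x$convergence != 0) cat("  WARNING: optimiser did not report convergence\n")
  invisible(x)
}

#' @export
coef.rd_fit <- function(object, ...) object$beta

#' @export
vcov.rd_fit <- function(object, ...) object$vcov

#' @export
logLik.rd_fit <- function(object, ...) {
  structure(object$logLik, df = object$K, nobs = object$ess, class = "logLik")
}

#' @export
summary.rd_fit <- function(object, ...) {
  se <- sqrt(pmax(diag(object$vcov), 0))
  z <- object$beta / se
  tab <- data.frame(estimate = object$beta, se = se,
                    lcl = object$beta - 1.96 * se,
                    ucl = object$beta + 1.96 * se,
                    significant = sign(object$beta - 1.96 * se) ==
                      sign(object$beta + 1.96 * se) & se > 0)
  structure(list(model = object$model_name, K = object$K,
                 logLik = object$logLik, AICc = object$AICc,
                 coefficients = tab), class = "summary.rd_fit")
}

#' @export
print.summary.rd_fit <- function(x, ...) {
  cat("Model:", x$model, "\n")
  cat(sprintf("K = %d  logLik = %.3f  AICc = %.3f\n", x$K, x$logLik, x$AICc))
  print(round(x$coefficients[, 1:4], 4))
  invisible(x)
}

#' Real-scale parameter estimates with delta-method intervals
#'
#' Back-transforms a linear combination of coefficients to the probability
#' scale for given ages/groups/occasions, with SEs by the delta method and
#' 95% intervals computed on the logit scale. The significance flag tests
#' whether the relevant beta CI excludes zero.
#'
#' @param fit An `rd_fit`.
#' @param parameter One of `"S"`, `"gamma_prime"`, `"gamma_dprime"`, `"p"`,
#'   `"c"`.
#' @param newdata Data frame of predictor values: `A`, `group`, `cov`,
#'   `cov2` for S/gamma parameters; `t` for p/c. Defaults supply age 0 /
#'   occasion 1 baselines.
#' @return Data frame with `estimate`, `se`, `lcl`, `ucl` per row of
#'   `newdata`.
#' @export
rd_real <- function(fit, parameter = "S", newdata = NULL) {
  stopifnot(inherits(fit, "rd_fit"))
  cm <- fit$compiled
  blocks <- c("S", "gamma_prime", "gamma_dprime", "p", "c")
  bi <- match(match.arg(parameter, blocks), blocks)
  b <- .rd_split(fit$beta, cm$k)[[bi]]
  Vfull <- fit$vcov
  ends <- cumsum(cm$k); starts <- c(1L, utils::head(ends, -1L) + 1L)
  sel <- starts[bi]:ends[bi]
  V <- Vfull[sel, sel, drop = FALSE]
  fm <- cm$formulas[[bi]]
  if (is.null(newdata)) {
    newdata <- if (bi <= 3L) data.frame(A = 0) else data.frame(t = factor(1))
  }
  if (bi > 3L) newdata$t <- factor(newdata$t, levels = seq_len(cm$T))
  ## complete model frame with unused variables at baseline
  tv <- all.vars(fm)
  for (v in setdiff(tv, names(newdata))) {
    newdata[[v]] <- switch(v,
      A = 0,
      group = factor(levels(cm$data$group)[1L], levels = levels(cm$data$group)),
      cov = 0, cov2 = 0,
      stop("cannot default variable '", v, "'"))
  }
  if ("group" %in% names(newdata) && !is.factor(newdata$group))
    newdata$group <- factor(newdata$group, levels = levels(cm$data$group))
  X <- stats::model.matrix(fm, newdata)
  lp <- as.vector(X %*% b)
  se_lp <- sqrt(pmax(rowSums((X %*% V) * X), 0))
  est <- stats::plogis(lp)
  data.frame(estimate = est,
             se = est * (1 - est) * se_lp,
             lcl = stats::plogis(lp - 1.96 * se_lp),
             ucl = stats::plogis(lp + 1.96 * se_lp))
}

#' @rdname rd_real
#' @param object,... Standard predict arguments (`parameter`, `newdata`).
#' @export
predict.rd_fit <- function(object, parameter = "S", newdata = NULL, ...) {
  rd_real(object, parameter, newdata)
}

.same_data <- function(fits) {
  h0 <- fits[[1L]]$compiled$data$histories
  all(vapply(fits, function(f) identical(f$compiled$data$histories, h0),
             logical(1)))
}

#' Akaike weights of a model set
#'
#' `w_i = exp(-Delta_i/2) / sum_j exp(-Delta_j/2)` over AICc differences.
#' All models must be fitted to identical data.
#'
#' @param fits List of `rd_fit` objects.
#' @return Numeric vector of weights summing to 1.
#' @export
akaike_weights <- function(fits) {
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, logical(1), "rd_fit")))
  if (!.same_data(fits)) stop("models were fitted to different data sets")
  aicc <- vapply(fits, `[[`, numeric(1), "AICc")
  d <- aicc - min(aicc)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Model-selection table (AICc ranking)
#'
#' @param fits List of `rd_fit` objects on identical data.
#' @return Data frame with `model`, `K`, `AICc`, `dAICc`, `weight`, sorted
#'   by AICc (ties broken by smaller K).
#' @export
model_table <- function(fits) {
  w <- akaike_weights(fits)
  tab <- data.frame(model = vapply(fits, `[[`, character(1), "model_name"),
                    K = vapply(fits, `[[`, numeric(1), "K"),
                    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
                    AICc = vapply(fits, `[[`, numeric(1), "AICc"),
                    weight = w)
  tab <- tab[order(tab$AICc, tab$K), ]
  tab$dAICc <- tab$AICc - tab$AICc[1L]
  rownames(tab) <- NULL
  tab[, c("model", "K", "logLik", "AICc", "dAICc", "weight")]
}

#' Model-averaged real-parameter estimates
#'
#' Averages real-scale estimates across a model set with Akaike weights;
#' unconditional variance by the Burnham-Anderson formula
#' `sum w_i (var_i + (theta_i - theta_bar)^2)`.
#'
#' @param fits List of `rd_fit` objects on identical data.
#' @param parameter,newdata Passed to [rd_real()] for each model.
#' @return Data frame with `estimate`, `se`, `lcl`, `ucl` per row of
#'   `newdata`.
#' @export
model_average <- function(fits, parameter = "S", newdata = NULL) {
  w <- akaike_weights(fits)
  ests <- lapply(fits, rd_real, parameter = parameter, newdata = newdata)
  est_mat <- sapply(ests, `[[`, "estimate")
  var_mat <- sapply(ests, function(e) e$se^2)
  if (is.null(dim(est_mat))) { est_mat <- rbind(est_mat); var_mat <- rbind(var_mat) }
  theta <- as.vector(est_mat %*% w)
  uncond <- as.vector((var_mat + (est_mat - theta)^2) %*% w)
  se <- sqrt(uncond)
  data.frame(estimate = theta, se = se,
             lcl = pmax(theta - 1.96 * se, 0),
             ucl = pmin(theta + 1.96 * se, 1))
}

#' Spot-trait covariate effect on survival
#'
#' Fits the covariate model `{S(A + covariate) gp(A) gpp(A) p(.) c(.)}`
#' (structure configurable) for a trait entering the survival predictor
#' linearly or quadratically within an age window, and reports the
#' covariate beta with its 95% CI and a significance flag (CI excludes
#' zero).
#'
#' @inheritParams fit_rd
#' @param trait Covariate column name.
#' @param form `"linear"` or `"quadratic"`.
#' @param window `"first_season"`, `"first_year"` or `"first_3yr"`.
#' @return The `rd_fit` with an added `covariate_effect` data frame
#'   (`term`, `beta`, `se`, `lcl`, `ucl`, `significant`).
#' @export
covariate_effect_models <- function(data, trait, form = "linear",
                                    window = "first_season",
                                    S = ~A, gamma_prime = ~1, gamma_dprime = ~1,
                                    p = ~1, c = ~1, ...) {
  fit <- fit_rd(data, S = S, gamma_prime = gamma_prime,
                gamma_dprime = gamma_dprime, p = p, c = c,
                covariate = trait, covariate_form = form,
                covariate_window = window, ...)
  terms <- grep("^S:cov", names(fit$beta), value = TRUE)
  se <- sqrt(pmax(diag(fit$vcov)[terms], 0))
  eff <- data.frame(term = terms, beta = fit$beta[terms], se = se,
                    lcl = fit$beta[terms] - 1.96 * se,
                    ucl = fit$beta[terms] + 1.96 * se)
  eff$significant <- eff$lcl > 0 | eff$ucl < 0
  rownames(eff) <- NULL
  fit$covariate_effect <- eff
  fit
}

#' Likelihood-ratio test of nested robust-design models
#'
#' @param fit_null,fit_alt Nested `rd_fit` objects on identical data (the
#'   null's terms must be a subset of the alternative's in every parameter
#'   block).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
lrt_rd <- function(fit_null, fit_alt) {
  stopifnot(inherits(fit_null, "rd_fit"), inherits(fit_alt, "rd_fit"))
  if (!.same_data(list(fit_null, fit_alt)))
    stop("models were fitted to different data sets")
  for (blk in names(fit_null$compiled$formulas)) {
    t0 <- attr(stats::terms(fit_null$compiled$formulas[[blk]]), "term.labels")
    t1 <- attr(stats::terms(fit_alt$compiled$formulas[[blk]]), "term.labels")
    if (!all(t0 %in% t1))
      stop("models are not nested (block ", blk, ")")
  }
  df <- fit_alt$K - fit_null$K
  if (df <= 0) {
    if (fit_alt$K == fit_null$K)
      return(list(statistic = max(0, 2 * (fit_alt$logLik - fit_null$logLik)),
                  df = 0L, p_value = 1))
    stop("alternative model has fewer parameters than the null")
  }
  stat <- max(0, 2 * (fit_alt$logLik - fit_null$logLik))
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}
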