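test_that("MARK-style .inp files round-trip exactly", {
  eh <- gen_encounter_histories(cmr_sim_design(
    schedule = survey_schedule(4, 2), n_released_per_occasion = 12, seed = 5))
  path <- tempfile(fileext = ".inp")
  write_inp(eh, path)
  back <- read_inp(path)
  expect_identical(back$histories, unname(eh$histories))
  expect_identical(back$freq, eh$freq)
  expect_identical(back$first_primary, eh$first_primary)
  expect_identical(as.integer(back$group), as.integer(eh$group))
  expect_equal(back$covariates$cov, eh$covariates$cov, tolerance = 1e-12)
  ## hand-written dialect features
  p2 <- tempfile(fileext = ".inp")
  writeLines(c("/* two individuals, 4 events */",
               "1100 1 0.2;",
               "/* a comment line */",
               "0011 3 0.5;"), p2)
  got <- read_inp(p2, survey_schedule(2, 2))
  expect_identical(nrow(got$histories), 2L)
  expect_identical(got$freq, c(1L, 3L))
  expect_identical(got$first_event, c(1L, 3L))
  expect_equal(got$covariates$cov1, c(0.2, 0.5))
  ## parse errors carry line numbers
  p3 <- tempfile(fileext = ".inp")
  writeLines("11a0 1;", p3)
  expect_error(read_inp(p3, survey_schedule(2, 2)), "non-binary")
  writeLines("110 1;", p3)
  expect_error(read_inp(p3, survey_schedule(2, 2)), "length")
  writeLines("1100 0;", p3)
  expect_error(read_inp(p3, survey_schedule(2, 2)), "frequency")
})

test_that("the robust-design likelihood is a proper probability model", {
  sch <- survey_schedule(3, 2)
  base <- make_eh(matrix(c(1, 0, 0, 0, 0, 0), 1), sch)
  set.seed(77)
  for (rep in 1:5) {
    betas <- rnorm(5, 0, 1.2)  # S, gamma', gamma'', p, c intercepts
    tot <- 0
    for (code in 0:31) {
      h <- c(1L, as.integer(intToBits(code))[1:5])
      eh <- make_eh(matrix(h, 1), sch)
      cm <- spotmetrics:::rd_compile(eh, S = ~1, gamma_prime = ~1,
                                     gamma_dprime = ~1, p = ~1, c = ~1)
      tot <- tot + exp(-rd_negloglik(betas, cm))
    }
    expect_equal(tot, 1, tolerance = 1e-10)
  }
  ## single-release closed form: one interval, one later event,
  ## gamma = 0: P(detected at event of primary 2) = S*p
  sch1 <- survey_schedule(2, 1)
  S <- plogis(0.4); p <- plogis(-0.3)
  l1 <- exp(-rd_negloglik(c(0.4, -50, -50, -0.3, 0),
                          spotmetrics:::rd_compile(make_eh(matrix(c(1, 1), 1), sch1),
                                                   S = ~1, p = ~1)))
  l0 <- exp(-rd_negloglik(c(0.4, -50, -50, -0.3, 0),
                          spotmetrics:::rd_compile(make_eh(matrix(c(1, 0), 1), sch1),
                                                   S = ~1, p = ~1)))
  expect_equal(l1, S * p, tolerance = 1e-10)
  expect_equal(l0, 1 - S * p, tolerance = 1e-10)
})

test_that("with one event per occasion and no emigration the likelihood is CJS", {
  sch <- survey_schedule(6, 1)
  des <- cmr_sim_design(schedule = sch, n_released_per_occasion = 30,
                        s_intercept = qlogis(0.8), s_age_slope = 0.1,
                        gamma_prime = 0, gamma_dprime = 0,
                        p_per_occasion = 0.5, c_per_occasion = 0.5, seed = 3)
  eh <- gen_encounter_histories(des)
  cm <- spotmetrics:::rd_compile(eh, S = ~A, p = ~t, c = ~1)
  pvec <- c(0.45, 0.5, 0.55, 0.6, 0.5, 0.4)
  bp <- c(qlogis(0.45), qlogis(pvec[-1]) - qlogis(0.45))
  beta <- c(0.9, 0.12, -50, -50, bp, 0)
  Tn <- 6
  phi <- matrix(plogis(0.9 + 0.12 * pmax(
    outer(rep(1, nrow(eh$histories)), 1:(Tn - 1)) - eh$first_primary, 0)),
    ncol = Tn - 1)
  expect_equal(rd_negloglik(beta, cm),
               cjs_nll(eh$histories, eh$first_primary, phi, pvec),
               tolerance = 1e-8)
})

test_that("maximum likelihood recovers simulated survival within 0.03", {
  errs <- vapply(1:3, function(s) {
    des <- cmr_sim_design(n_released_per_occasion = 220,
                          s_intercept = qlogis(0.85), s_age_slope = 0.2,
                          gamma_prime = 0.1, gamma_dprime = 0.1,
                          p_per_occasion = 0.6, c_per_occasion = 0.6,
                          seed = 40 + s)
    eh <- gen_encounter_histories(des)
    expect_gt(nrow(eh$histories), 2000)
    fit <- fit_rd(eh, S = ~A, share_gamma = TRUE, n_restarts = 0)
    abs(rd_real(fit, "S", data.frame(A = 0))$estimate - 0.85)
  }, numeric(1))
  expect_lte(median(errs), 0.03)
  ## nested models never lose likelihood
  des <- cmr_sim_design(n_released_per_occasion = 40, seed = 9)
  eh <- gen_encounter_histories(des)
  f0 <- fit_rd(eh, S = ~1, share_gamma = TRUE, n_restarts = 0)
  f1 <- fit_rd(eh, S = ~A, share_gamma = TRUE, n_restarts = 0)
  expect_gte(f1$logLik, f0$logLik - 1e-6)
  l <- lrt_rd(f0, f1)
  expect_gte(l$statistic, 0)
  expect_identical(l$df, 1L)
  expect_identical(lrt_rd(f0, f0)$p_value, 1)
  f2 <- fit_rd(eh, S = ~1, gamma_dprime = ~A, share_gamma = TRUE,
               n_restarts = 0)
  expect_error(lrt_rd(f1, f2), "not nested")
})

test_that("AICc weights and model averaging follow the closed forms", {
  des <- cmr_sim_design(schedule = survey_schedule(5, 2),
                        n_released_per_occasion = 25, seed = 12)
  eh <- gen_encounter_histories(des)
  f0 <- fit_rd(eh, S = ~1, share_gamma = TRUE, n_restarts = 0)
  f1 <- fit_rd(eh, S = ~A, share_gamma = TRUE, n_restarts = 0)
  w <- akaike_weights(list(f0, f1))
  expect_equal(sum(w), 1)
  expect_equal(akaike_weights(list(f0, f0)), c(0.5, 0.5))
  ## delta = (0, 2) closed form
  g0 <- f0; g1 <- f0
  g1$AICc <- g0$AICc + 2
  w2 <- akaike_weights(list(g0, g1))
  expect_equal(w2, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(round(w2, 3), c(0.731, 0.269))
  ## model averaging: hand formula and convexity
  g1$beta <- g0$beta  # same data, shifted AICc only
  est <- model_average(list(g0, g1), "S", data.frame(A = 0))
  single <- rd_real(g0, "S", data.frame(A = 0))
  expect_equal(est$estimate, single$estimate, tolerance = 1e-12)
  avg <- model_average(list(f0, f1), "S", data.frame(A = 0:3))
  r0 <- rd_real(f0, "S", data.frame(A = 0:3))$estimate
  r1 <- rd_real(f1, "S", data.frame(A = 0:3))$estimate
  expect_true(all(avg$estimate >= pmin(r0, r1) - 1e-12 &
                    avg$estimate <= pmax(r0, r1) + 1e-12))
  ## hand evaluation of the unconditional variance on synthetic inputs
  w3 <- c(0.5, 0.5); th <- c(0.8, 0.9)
  expect_equal(sum(w3 * th), 0.85)
  expect_equal(sum(w3 * (0 + (th - 0.85)^2)), 0.0025)
  other <- gen_encounter_histories(cmr_sim_design(
    schedule = survey_schedule(5, 2), n_released_per_occasion = 25, seed = 99))
  f_other <- fit_rd(other, S = ~1, share_gamma = TRUE, n_restarts = 0)
  expect_error(akaike_weights(list(f0, f_other)), "different data")
})

test_that("spot-trait covariates on survival are recovered with correct form", {
  des <- cmr_sim_design(n_released_per_occasion = 300,
                        s_intercept = qlogis(0.80), s_age_slope = 0.25,
                        beta_cov = -0.5, cov_window = 0L,
                        gamma_prime = 0.1, gamma_dprime = 0.1, seed = 42)
  eh <- gen_encounter_histories(des)
  fit <- covariate_effect_models(eh, "cov", form = "linear",
                                 window = "first_season", share_gamma = TRUE,
                                 n_restarts = 0)
  eff <- fit$covariate_effect
  expect_lt(abs(eff$beta - (-0.5)), 0.15)
  expect_true(eff$significant)
  ## a null covariate is not flagged (CI covers zero)
  des0 <- cmr_sim_design(n_released_per_occasion = 120,
                         s_intercept = qlogis(0.8), beta_cov = 0, seed = 8)
  eh0 <- gen_encounter_histories(des0)
  fit0 <- covariate_effect_models(eh0, "cov", form = "linear",
                                  window = "first_season", share_gamma = TRUE,
                                  n_restarts = 0)
  expect_false(fit0$covariate_effect$significant)
  ## quadratic adds exactly one parameter
  fq <- covariate_effect_models(eh0, "cov", form = "quadratic",
                                window = "first_season", share_gamma = TRUE,
                                n_restarts = 0)
  expect_identical(fq$K, fit0$K + 1L)
  expect_error(covariate_effect_models(eh0, "nope"), "not found")
})

test_that("the phenotype-group model set runs and ranks by AICc", {
  gl <- c(0, 0.3, -0.2, 0.4)
  des <- cmr_sim_design(schedule = survey_schedule(8, 2),
                        n_released_per_occasion = 40,
                        s_intercept = qlogis(0.82), s_age_slope = 0.2,
                        group_logits = gl, seed = 33)
  eh4 <- gen_encounter_histories(des)
  eh3 <- eh4
  levels(eh3$group) <- c("1", "1", "2", "3")   # lump the two overlapping groups
  fits <- list(
    fit_rd(eh4, S = ~A, n_restarts = 0, model_name = "A + 1 group"),
    fit_rd(eh3, S = ~A + group, n_restarts = 0, model_name = "A + 3 groups"),
    fit_rd(eh4, S = ~A + group, n_restarts = 0, model_name = "A + 4 groups"),
    fit_rd(eh3, S = ~A * group, n_restarts = 0, model_name = "A x 3 groups"),
    fit_rd(eh4, S = ~A * group, n_restarts = 0, model_name = "A x 4 groups"))
  tab <- model_table(fits)
  expect_identical(nrow(tab), 5L)
  expect_equal(sum(tab$weight), 1)
  expect_equal(tab$dAICc[1], 0)
  expect_true(all(diff(tab$AICc) >= 0))
  expect_true(all(is.finite(tab$AICc)))
  ## additive vs multiplicative bookkeeping: interaction adds k-1 slopes
  expect_identical(fits[[5]]$K - fits[[3]]$K, 3L)
  ## overdispersion adjustment: QAICc shrinks the deviance, SEs inflate
  fq <- fit_rd(eh4, S = ~A, n_restarts = 0, c_hat = 1.5)
  f1 <- fits[[1]]
  expect_equal(fq$logLik, f1$logLik, tolerance = 1e-6)
  expect_equal(fq$AICc,
               -2 * fq$logLik / 1.5 + 2 * fq$K +
                 2 * fq$K * (fq$K + 1) / (fq$ess - fq$K - 1),
               tolerance = 1e-8)
  expect_equal(diag(fq$vcov), 1.5 * diag(f1$vcov), tolerance = 1e-3)
})
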