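test_that("the initial richness model reports the environment-by-richness interaction", {
  exp <- quick_experiment("sorting_only", seed = 33)
  fit <- fit_initial_richness_model(exp$yields, exp$design)
  expect_s3_class(fit, "trend_fit")
  expect_true("environment:logS" %in% fit$anova$term)
  # all P values recompute from their statistics and df
  cf <- fit$coefficients
  expect_equal(cf$p_value, 2 * pt(-abs(cf$statistic), cf$df),
               tolerance = 1e-6)
  # spruce yields uniformly lower than beech
  sp <- cf[cf$term == "environmentspruce", ]
  expect_lt(sp$estimate, 0)
  expect_lt(sp$p_value, 0.001)
})

test_that("an inflated pH5 richness slope is detected as an interaction", {
  hits <- vapply(1:10, function(s) {
    exp <- quick_experiment("sorting_only", seed = 700 + s,
                            lambda = c(beech = 0.78, ph5 = 0.35,
                                       spruce = 0.86),
                            theta1 = c(beech = 0.90, ph5 = 0.74,
                                       spruce = 1.37))
    fit <- fit_initial_richness_model(exp$yields, exp$design)
    fit$anova$p_value[fit$anova$term == "environment:logS"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("initial richness model errors on degenerate designs", {
  exp <- quick_experiment(seed = 34)
  no_env <- exp$yields[exp$yields$environment != "spruce", ]
  expect_error(fit_initial_richness_model(no_env, exp$design),
               "missing environment")
  monos_only <- exp$yields[exp$yields$composition_id %in%
                             sprintf("C%02d", 1:12), ]
  expect_error(fit_initial_richness_model(monos_only, exp$design),
               "constant")
})

test_that("the time mixed model runs over the full week course and simplifies", {
  cfg <- simulation_config("interaction_evolution", weeks = c(0, 1, 2, 4, 5),
                           seed = 35, include_transfers = FALSE)
  exp <- simulate_experiment(cfg)
  fit <- fit_time_mixed_model(exp$yields, exp$design)
  expect_s3_class(fit, "trend_fit")
  expect_true(length(fit$retained) >= 1)
  expect_true("week" %in% all.vars(stats::formula(fit$fit)))
  expect_error(fit_time_mixed_model(
    exp$yields[exp$yields$week == 0, ], exp$design), "two or more weeks")
})

test_that("zero between-microcosm variance does not break the mixed model", {
  # yields constructed so the fixed effects capture the mean exactly and no
  # microcosm-level variance exists: the random effect sits at the boundary
  exp <- quick_experiment("neutral_additive", seed = 36,
                          weeks = c(0, 2, 5))
  members <- composition_members(exp$design)
  rich <- vapply(members, length, integer(1))
  y <- exp$yields
  set.seed(360)
  y$yield <- 0.2 + 0.1 * log(rich[y$composition_id]) + 0.01 * y$week +
    stats::rnorm(nrow(y), 0, 0.02)
  fit <- fit_time_mixed_model(y, exp$design)
  re_sd <- as.numeric(nlme::VarCorr(fit$fit)["(Intercept)", "StdDev"])
  res_sd <- as.numeric(nlme::VarCorr(fit$fit)["Residual", "StdDev"])
  expect_true(is.finite(re_sd))
  expect_lt(re_sd, res_sd / 3)  # collapses towards the boundary, no crash
})

test_that("the extinction GLM recovers its generating logistic model", {
  exp <- quick_experiment("sorting_only", seed = 37)
  fit <- extinction_glm(exp$survival, exp$microcosms)
  cf <- fit$coefficients
  truth <- calibrate_extinction()
  sl <- cf[cf$term == "logS", ]
  expect_lt(abs(sl$estimate - truth$slope), 2.5 * sl$se)
  expect_gt(predicted_extinction(fit, 12, "beech"), 0.5)
  expect_lt(predicted_extinction(fit, 1, "beech"), 0.15)
})

test_that("a zero richness slope is recovered as null", {
  flat <- list(intercept = stats::setNames(rep(stats::qlogis(0.3), 3),
                                           environments()), slope = 0)
  exp <- quick_experiment("sorting_only", seed = 38, extinction = flat)
  # restrict to richness >= 3, where the forced >=1-survivor conditioning
  # perturbs the extinction rate by well under a percentage point
  keep <- exp$microcosms$microcosm_id[exp$microcosms$richness >= 3]
  fit <- extinction_glm(exp$survival[exp$survival$microcosm_id %in% keep, ],
                        exp$microcosms)
  sl <- fit$coefficients[fit$coefficients$term == "logS", ]
  expect_lt(abs(sl$estimate), 2.5 * sl$se)
})

test_that("the isolate trend recovers the decline with source richness", {
  exp <- quick_experiment("sorting_only", seed = 39)
  fit <- isolate_yield_trend(exp$isolates)
  sl <- fit$richness_slope
  expect_lt(sl$estimate, 0)
  expect_lt(abs(sl$estimate - (-0.05)), 2.5 * sl$se)
  expect_equal(sl$p_value, 2 * pt(-abs(sl$statistic), sl$df),
               tolerance = 1e-6)
  # null decline gives a null slope
  e0 <- quick_experiment("sorting_only", seed = 40, isolate_decline = 0)
  f0 <- isolate_yield_trend(e0$isolates)
  expect_lt(abs(f0$richness_slope$estimate), 2.5 * f0$richness_slope$se)
})

test_that("isolate trend guards its inputs", {
  exp <- quick_experiment("sorting_only", seed = 41)
  iso <- exp$isolates
  iso$ancestral_yield[1] <- 0
  expect_message(isolate_yield_trend(iso), "excluding 1")
  one_level <- exp$isolates[exp$isolates$source_richness == 1, ]
  expect_error(isolate_yield_trend(one_level), "more than one richness")
})
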