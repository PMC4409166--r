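test_that("the baseline recovers slope 1, intercept 0 on exactly additive data", {
  exp <- exact_additive_experiment(seed = 11)
  d0 <- community_frame(exp$yields, exp$design, week = 0)
  m0 <- suppressWarnings(fit_baseline(d0))
  for (env in environments()) {
    for (S in c(2, 6, 12)) {
      si <- baseline_slope_intercept(m0, env, S)
      expect_equal(si$slope, 1, tolerance = 1e-8)
      expect_equal(si$intercept, 0, tolerance = 1e-8)
    }
  }
})

test_that("a constructed half-additive relationship is recovered exactly", {
  d <- synthetic_frame(slope = c(beech = 0.5, ph5 = 0.5, spruce = 0.5),
                       noise = 0, seed = 2)
  m <- suppressWarnings(fit_baseline(d))
  expect_equal(baseline_slope_intercept(m, "ph5", 3)$slope, 0.5,
               tolerance = 1e-8)
})

test_that("a decaying interaction curve yields a negative slope-by-richness interaction", {
  exp <- quick_experiment("sorting_only", seed = 17)
  d0 <- community_frame(exp$yields, exp$design, week = 0)
  m0 <- fit_baseline(d0)
  s2 <- baseline_slope_intercept(m0, "beech", 2)$slope
  s12 <- baseline_slope_intercept(m0, "beech", 12)$slope
  expect_lt(s12, s2)   # slope shallower at higher richness
})

test_that("baseline preconditions are enforced", {
  d <- synthetic_frame(seed = 3)
  d$richness[1] <- 1
  expect_error(fit_baseline(d), "communities only")
  d2 <- synthetic_frame(seed = 3)
  d2$dup <- d2$addsum   # aliased column
  expect_error(fit_baseline(d2, formula = yield ~ addsum + dup),
               "collinear")
})

test_that("backward AIC elimination respects marginality and never worsens AIC", {
  d <- synthetic_frame(seed = 4, noise = 0.05,
                       slope = c(beech = 0.8, ph5 = 0.8, spruce = 0.8))
  full <- stats::lm(yield ~ addsum * environment * logS, data = d)
  step <- simplify_by_aic(full, data = d)
  expect_lte(step$aic, stats::AIC(full) + 1e-8)
  # marginality: any retained interaction implies its main effects retained
  for (term in step$retained) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    if (length(parts) > 1) {
      for (p in parts) expect_true(p %in% step$retained)
    }
  }
  # single-term model returned as-is when the term is real
  lone <- stats::lm(yield ~ addsum, data = d)
  step1 <- simplify_by_aic(lone, data = d)
  expect_equal(step1$retained, "addsum")
})

test_that("elimination retains true effects and usually removes null ones", {
  keep <- vapply(1:10, function(s) {
    d <- synthetic_frame(seed = s + 900, logS_slope = -0.1, noise = 0.03)
    m <- fit_baseline(d)
    all(c("addsum:environment", "addsum:logS") %in% m$retained_terms)
  }, logical(1))
  expect_true(all(keep))
  dropped3way <- vapply(1:20, function(s) {
    d <- synthetic_frame(seed = s + 400, noise = 0.05,
                         slope = c(beech = 0.8, ph5 = 0.8, spruce = 0.8))
    m <- fit_baseline(d)
    !"addsum:environment:logS" %in% m$retained_terms
  }, logical(1))
  expect_gte(mean(dropped3way), 0.7)
})

test_that("counterfactual predictions obey the frozen-coefficient contract", {
  exp <- quick_experiment("sorting_only", seed = 18)
  d0 <- community_frame(exp$yields, exp$design, week = 0)
  m0 <- fit_baseline(d0)
  p1 <- counterfactual_prediction(m0, "extinction_only", exp$yields,
                                  exp$design, exp$survival)
  # inject wrong-by-construction coefficients: predictions must track them
  m_bad <- m0
  m_bad$fit$coefficients <- m0$fit$coefficients * 2
  p_bad <- counterfactual_prediction(m_bad, "extinction_only", exp$yields,
                                     exp$design, exp$survival)
  expect_equal(p_bad$predicted, 2 * p1$predicted, tolerance = 1e-10)
})

test_that("counterfactual identities hold in the no-change limits", {
  # no extinction: the extinction-only sum equals the week-0 additive sum
  exp <- quick_experiment("neutral_additive", seed = 19, noise_sd = 0,
                          microcosm_sd = 0)
  d0 <- community_frame(exp$yields, exp$design, week = 0)
  m0 <- suppressWarnings(fit_baseline(d0))
  p <- counterfactual_prediction(m0, "extinction_only", exp$yields,
                                 exp$design, exp$survival)
  expect_equal(p$predicted[match(d0$microcosm_id, p$microcosm_id)],
               unname(stats::fitted(m0$fit)), tolerance = 1e-10)
  # no evolution: week-5 monoculture sums equal week-0 sums exactly
  p2 <- counterfactual_prediction(m0, "additive_mono", exp$yields,
                                  exp$design, exp$survival)
  expect_equal(p2$addsum[match(d0$microcosm_id, p2$microcosm_id)],
               d0$addsum, tolerance = 1e-12)
  # slope-1 model: losing a species of yield a drops the prediction by a
  d <- data.frame(addsum = c(0.4, 0.6, 0.8, 1.0, 0.5, 0.7, 0.9, 1.1),
                  environment = factor(rep("beech", 8),
                                       levels = environments()),
                  logS = log(2), richness = 2)
  d$yield <- d$addsum
  m <- suppressWarnings(fit_baseline(d, formula = yield ~ addsum))
  base <- predict(m, data.frame(addsum = 0.6, environment = "beech",
                                logS = log(2)))
  drop <- predict(m, data.frame(addsum = 0.4, environment = "beech",
                                logS = log(2)))
  expect_equal(base - drop, 0.2, tolerance = 1e-8)
})

test_that("missing isolates for surviving species raise a named error", {
  exp <- quick_experiment("sorting_only", seed = 20)
  victim <- which(exp$isolates$source_richness >= 2)[1]
  iso <- exp$isolates[-victim, ]  # drop one surviving species' isolate row
  d0 <- community_frame(exp$yields, exp$design, week = 0)
  m0 <- fit_baseline(d0)
  expect_error(
    counterfactual_prediction(m0, "additive_isolate", exp$yields, exp$design,
                              exp$survival, iso),
    exp$isolates$species_id[victim])
})

test_that("evaluation regression matches a brute-force least-squares oracle", {
  set.seed(8)
  pred <- runif(10, -0.2, 0.4)
  obs <- 0.8 * pred + rnorm(10, 0, 0.05)
  row <- evaluate_counterfactual(obs, pred, model = 1, label = "oracle")
  # brute force: normal equations, residual sums, Gaussian log-likelihood
  X <- cbind(1, pred)
  beta <- solve(t(X) %*% X, t(X) %*% obs)
  rss <- sum((obs - X %*% beta)^2)
  tss <- sum((obs - mean(obs))^2)
  r2 <- 1 - rss / tss
  n <- 10
  adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  aic <- n * log(2 * pi * rss / n) + n + 2 * 3
  expect_equal(row$slope, beta[2], tolerance = 1e-8)
  expect_equal(row$adjusted_r2, adj, tolerance = 1e-8)
  expect_equal(row$aic, aic, tolerance = 1e-8)
  se <- sqrt(rss / (n - 2) * solve(t(X) %*% X)[2, 2])
  expect_equal(row$t, beta[2] / se, tolerance = 1e-8)
  expect_equal(row$p_value, 2 * pt(-abs(row$t), n - 2), tolerance = 1e-8)
})

test_that("perfect and degenerate evaluations behave as documented", {
  x <- c(0.1, 0.2, 0.3, 0.45, 0.7)
  perfect <- suppressWarnings(evaluate_counterfactual(x, x))
  expect_equal(perfect$slope, 1, tolerance = 1e-10)
  expect_equal(perfect$adjusted_r2, 1, tolerance = 1e-10)
  flat <- evaluate_counterfactual(x, rep(0.2, 5))
  expect_true(is.na(flat$adjusted_r2))
  expect_match(flat$flag, "zero-variance")
  expect_error(evaluate_counterfactual(x[1:2], x[1:2]), "at least 3")
})

test_that("doubling theta doubles the refitted week-5 slope", {
  cfg <- simulation_config("interaction_evolution", noise_sd = 0,
                           microcosm_sd = 0, seed = 4,
                           include_transfers = FALSE)
  exp <- simulate_experiment(cfg)
  d0 <- community_frame(exp$yields, exp$design, week = 0)
  m0 <- fit_baseline(d0)
  d5 <- community_frame(exp$yields, exp$design, week = 5, a_week = 5)
  m4 <- refit_with_time(d5, "richness")
  for (S in c(2, 6)) {
    r <- baseline_slope_intercept(m4, "beech", S)$slope /
      baseline_slope_intercept(m0, "beech", S)$slope
    expect_equal(r, 2, tolerance = 1e-6)
  }
})

test_that("the composition model nests the richness model (raw R-squared)", {
  for (s in c(23, 24)) {
    exp <- quick_experiment("mixed", seed = s)
    d5 <- community_frame(exp$yields, exp$design, week = 5, a_week = 5)
    m4 <- refit_with_time(d5, "richness")
    m5 <- suppressWarnings(refit_with_time(d5, "composition"))
    expect_gte(summary(m5$fit)$r.squared, summary(m4$fit)$r.squared - 1e-10)
  }
})

test_that("the ledger reproduces the worked decomposition and conserves shares", {
  led <- decompose_variance(c(m1 = 0.0035, m2 = 0.177, m4 = 0.320,
                              m5 = 0.795))
  expect_equal(led$pct_extinction, 0.35)
  expect_equal(led$pct_additive, 17.7)
  expect_equal(led$pct_interaction_systematic, 14.3)
  expect_equal(led$pct_interaction_composition, 47.5)
  expect_equal(led$pct_residual, 20.5)
  # conservation holds for arbitrary inputs
  set.seed(30)
  for (i in 1:20) {
    r <- sort(runif(3))
    led_i <- decompose_variance(c(m1 = runif(1), m2 = r[1], m4 = r[2],
                                  m5 = r[3]))
    expect_equal(led_i$pct_additive + led_i$pct_interaction_systematic +
                   led_i$pct_interaction_composition + led_i$pct_residual,
                 100, tolerance = 1e-10)
  }
  same <- decompose_variance(c(m1 = 0.2, m2 = 0.2, m4 = 0.2, m5 = 0.2))
  expect_equal(same$pct_interaction_systematic, 0)
  expect_equal(same$pct_interaction_composition, 0)
  full <- decompose_variance(c(m1 = 0.1, m2 = 0.3, m4 = 0.6, m5 = 1))
  expect_equal(full$pct_residual, 0)
  expect_warning(decompose_variance(c(m1 = 0.1, m2 = 0.3, m4 = 0.6,
                                      m5 = 0.5)), "negative increment")
  expect_error(decompose_variance(c(m1 = 0.1, m2 = 0.3)), "m4")
})

test_that("the full partition analysis produces a five-row table and ledger", {
  exp <- quick_experiment("additive_evolution", seed = 25)
  pr <- partition_analysis(exp$yields, exp$design, exp$survival,
                           exp$isolates)
  expect_equal(pr$evaluation$model, 1:5)
  expect_s3_class(pr$ledger, "partition_ledger")
  expect_true(pr$additive_model %in% c("m2", "m3"))
  # without isolates model 3 is flagged and the rest completes
  pr2 <- partition_analysis(exp$yields, exp$design, exp$survival,
                            isolates = NULL)
  expect_match(pr2$evaluation$flag[3], "unavailable")
  expect_equal(pr2$additive_model, "m2")
  expect_false(anyNA(unlist(pr2$ledger)))
})

test_that("excluding extinct species is a no-op without extinction and raises the sorting share with it", {
  neu <- quick_experiment("additive_evolution", seed = 26)
  main <- partition_analysis(neu$yields, neu$design, neu$survival,
                             neu$isolates)
  sens <- sensitivity_exclude_extinct(neu$yields, neu$design, neu$survival,
                                      neu$isolates)
  expect_equal(unlist(sens$ledger), unlist(main$ledger), tolerance = 1e-10)
  srt <- quick_experiment("sorting_only", seed = 26)
  main_s <- partition_analysis(srt$yields, srt$design, srt$survival,
                               srt$isolates)
  sens_s <- sensitivity_exclude_extinct(srt$yields, srt$design,
                                        srt$survival, srt$isolates)
  # with extinction the masking changes the analysis but the ledger stays
  # valid and conserved
  expect_false(isTRUE(all.equal(unlist(sens_s$ledger),
                                unlist(main_s$ledger))))
  expect_equal(sens_s$ledger$pct_additive +
                 sens_s$ledger$pct_interaction_systematic +
                 sens_s$ledger$pct_interaction_composition +
                 sens_s$ledger$pct_residual, 100, tolerance = 1e-8)
  expect_true(sens_s$exclude_extinct)
})

test_that("identical yields at both weeks give a near-zero likelihood ratio", {
  exp <- quick_experiment("neutral_additive", seed = 27)
  y0 <- exp$yields[exp$yields$week == 0, ]
  y5 <- y0
  y5$week <- 5
  still <- rbind(y0, y5)
  # degenerate duplicated data can push lme off its feet; the documented
  # behaviour is a flagged fall-back to the fixed-effects likelihood ratio
  res <- suppressWarnings(time_interaction_test(still, exp$design))
  expect_lt(res$statistic, 1e-4)
  expect_gt(res$p_value, 0.999)
})

test_that("the per-species model flags the species whose contribution changed", {
  drift <- c(2, rep(1, 11))   # only sp01 doubles
  cfg <- simulation_config("additive_evolution", yield_drift = drift,
                           noise_sd = 0.03, microcosm_sd = 0.02, seed = 28,
                           include_transfers = FALSE)
  exp <- simulate_experiment(cfg)
  fit <- per_species_coefficient_model(exp$yields, exp$design)
  tr <- fit$time_trends
  expect_equal(nrow(tr), 12L)
  top <- tr$species_id[which.max(tr$t)]
  expect_equal(top, "sp01")
  expect_lt(tr$p_value[tr$species_id == "sp01"], 0.05)
  # neutral: trends centred on zero
  neu <- quick_experiment("neutral_additive", seed = 29)
  fit0 <- per_species_coefficient_model(neu$yields, neu$design)
  expect_lt(abs(mean(fit0$time_trends$estimate)), 0.05)
})
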