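test_that("the neutral noise-free scenario is exactly additive", {
  exp <- exact_additive_experiment(seed = 3)
  idx <- interaction_indices(exp$yields, exp$design, week = 0)
  expect_equal(idx$ratio, rep(1, nrow(idx)), tolerance = 1e-12)
  idx5 <- interaction_indices(exp$yields, exp$design, week = 5,
                              additive_source = "mono")
  expect_equal(idx5$ratio, rep(1, nrow(idx5)), tolerance = 1e-12)
})

test_that("simulated experiments are deterministic given the seed", {
  a <- quick_experiment("mixed", seed = 21)
  b <- quick_experiment("mixed", seed = 21)
  expect_identical(a$yields, b$yields)
  expect_identical(a$survival, b$survival)
  expect_identical(a$isolates, b$isolates)
  expect_false(identical(a$yields, quick_experiment("mixed", seed = 22)$yields))
})

test_that("the roster has 333 microcosm yield rows per time point", {
  exp <- quick_experiment(seed = 2)
  expect_equal(sum(exp$yields$week == 0), 333L)
  expect_equal(sum(exp$yields$week == 5), 333L)
})

test_that("sorting_only freezes theta and monoculture yields in truth", {
  exp <- quick_experiment("sorting_only", seed = 4)
  expect_equal(exp$truth$interaction_drift, 1)
  expect_true(all(unlist(exp$truth$yield_drift) == 1))
  expect_true(exp$truth$extinction_on)
  ne <- quick_experiment("neutral_additive", seed = 4)
  expect_false(ne$truth$extinction_on)
  expect_true(all(unlist(ne$truth$theta1) == 1))
})

test_that("survival is near-certain in monocultures and ~74% extinct at 12 species", {
  cfg <- simulation_config("sorting_only", seed = 1)
  set.seed(10)
  mono <- replicate(300, simulate_survival(cfg, "sp01", "beech"))
  expect_gte(mean(mono), 0.99)  # forced >= 1 survivor makes monocultures safe
  p_ext <- stats::plogis(cfg$extinction$intercept[["beech"]] +
                           cfg$extinction$slope * log(12))
  expect_equal(p_ext, 0.74, tolerance = 1e-8)
  # zero slope makes survival independent of richness
  flat <- simulation_config("sorting_only", seed = 1,
                            extinction = list(
                              intercept = stats::setNames(rep(stats::qlogis(0.3), 3),
                                                          environments()),
                              slope = 0))
  # compare at richness 6 vs 12, where the forced >=1-survivor resampling
  # is negligible and cannot mask a slope
  set.seed(11)
  s6 <- replicate(400, mean(simulate_survival(flat, sprintf("sp%02d", 1:6),
                                              "beech")))
  s12 <- replicate(400, mean(simulate_survival(flat, sprintf("sp%02d", 1:12),
                                               "beech")))
  expect_equal(mean(s6), mean(s12), tolerance = 0.05)
})

test_that("at least one species survives every community", {
  exp <- quick_experiment("sorting_only", seed = 6)
  by_mic <- tapply(exp$survival$survived, exp$survival$microcosm_id, sum)
  expect_true(all(by_mic >= 1))
})

test_that("monoculture yield drift scales expected week-5 yields", {
  drift <- c(1.3, rep(1, 11))
  cfg <- simulation_config("additive_evolution", yield_drift = drift,
                           noise_sd = 0, microcosm_sd = 0, seed = 8,
                           include_transfers = FALSE)
  params <- simulation_params(cfg)
  m0 <- simulate_monoculture_yields(cfg, week = 0, params = params)
  m5 <- simulate_monoculture_yields(cfg, week = 5, params = params)
  r <- m5$yield / m0$yield
  expect_equal(r[m5$species_id == "sp01"], rep(1.3, 9))
  expect_equal(r[m5$species_id != "sp01"], rep(1, 9 * 11))
})

test_that("community yields are additive when theta is 1 and respond to member yields", {
  cfg <- simulation_config("neutral_additive", noise_sd = 0, microcosm_sd = 0,
                           seed = 1, include_transfers = FALSE)
  params <- simulation_params(cfg)
  mem <- c("sp01", "sp02")
  y <- simulate_community_yield(cfg, mem, "beech", week = 0,
                                microcosm_effect = 1, params = params)
  expect_equal(y, sum(params$base_yields[mem, "beech"]), tolerance = 1e-12)
  # monotone in any member's base yield
  params2 <- params
  params2$base_yields["sp01", "beech"] <-
    params$base_yields["sp01", "beech"] + 0.1
  y2 <- simulate_community_yield(cfg, mem, "beech", week = 0,
                                 microcosm_effect = 1, params = params2)
  expect_gt(y2, y)
})

test_that("default interaction calibration matches the diculture and 12-species anchors", {
  cfg <- simulation_config("sorting_only", seed = 1)
  th <- function(S, env) cfg$theta1[[env]] * S^(-cfg$lambda[[env]])
  expect_equal(th(2, "beech"), 0.523, tolerance = 1e-10)
  expect_equal(th(2, "ph5"), 0.580, tolerance = 1e-10)
  expect_equal(th(2, "spruce"), 0.751, tolerance = 1e-10)
  for (env in environments()) {
    expect_gte(th(12, env), 0.099)
    expect_lte(th(12, env), 0.161)
  }
})

test_that("extinct species never yield isolates and the decline acts on log richness", {
  exp <- quick_experiment("sorting_only", seed = 12)
  dead <- exp$survival[exp$survival$survived == 0L, ]
  key_iso <- paste(exp$isolates$microcosm_id, exp$isolates$species_id)
  expect_false(any(paste(dead$microcosm_id, dead$species_id) %in% key_iso))
  # null decline: mean relative yield flat in richness
  cfg0 <- simulation_config("sorting_only", isolate_decline = 0, noise_sd = 0,
                            microcosm_sd = 0, seed = 13,
                            include_transfers = FALSE)
  e0 <- simulate_experiment(cfg0)
  rel <- e0$isolates$yield / e0$isolates$ancestral_yield
  expect_equal(as.numeric(tapply(rel, e0$isolates$source_richness, mean)),
               rep(1, length(unique(e0$isolates$source_richness))),
               tolerance = 1e-10)
})

test_that("OD series round-trip is unbiased within 0.5% under noise", {
  set.seed(99)
  target <- 0.55
  draws <- replicate(1000, compute_yield(
    simulate_od_series(target, od_start = 0.01, noise_sd = 0.05)$od))
  expect_lt(abs(mean(draws) - target) / target, 0.005)
})

test_that("written experiments round-trip through the CSV readers", {
  exp <- quick_experiment("mixed", seed = 31)
  dir <- withr::local_tempdir()
  write_experiment(exp, dir)
  expect_true(file.exists(file.path(dir, "truth.json")))
  y <- read_yield_table(file.path(dir, "yields.csv"))
  expect_equal(nrow(y), nrow(exp$yields))
  d <- read_design_table(file.path(dir, "design.csv"))
  expect_equal(nrow(d), nrow(exp$design))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$scenario, "mixed")
})
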