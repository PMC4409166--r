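# Simulator for serial-transfer community-evolution experiments. Community
# yields are generated as a single multiplicative interaction factor
# theta(S, E) on the additive sum of monoculture yields; extinction is
# Bernoulli per species with a logistic dependence on log richness; evolution
# enters as per-species multiplicative drift of monoculture yields and/or
# multiplicative drift of theta by the final week. Each mechanism can be
# switched on or off through named scenarios.

.EEP_SCENARIOS <- c("sorting_only", "additive_evolution",
                    "interaction_evolution", "mixed", "neutral_additive")

# interaction curve theta(S,E) = theta1(E) * S^(-lambda(E)), calibrated so
# that diculture communities average 52.3/58.0/75.1 % of the additive
# expectation in beech/ph5/spruce, and 12-species communities fall inside
# the observed 9.9-16.1 % band (13/15/16 % targets).
.eep_theta_defaults <- function() {
  r2 <- c(beech = 0.523, ph5 = 0.580, spruce = 0.751)
  r12 <- c(beech = 0.130, ph5 = 0.150, spruce = 0.160)
  lambda <- log(r2 / r12) / log(6)
  theta1 <- r2 * 2^lambda
  list(theta1 = theta1, lambda = lambda)
}

#' Calibrate the logistic extinction model
#'
#' Solves for a shared slope on log richness and per-environment intercepts
#' such that the extinction probability is `p1` in monocultures (beech) and
#' `p12` in 12-species communities in each environment.
#'
#' @param p12 Named vector of extinction probabilities at richness 12, one
#'   per environment. Defaults reproduce the 74/84/86 % calibration.
#' @param p1 Extinction probability at richness 1 (beech); near zero.
#' @param s_max Richness at which `p12` applies.
#' @return List with `intercept` (named per-environment, logit scale for the
#'   extinction probability) and `slope` (coefficient on log richness).
#' @export
calibrate_extinction <- function(p12 = c(beech = 0.74, ph5 = 0.84, spruce = 0.86),
                                 p1 = 0.01, s_max = 12) {
  slope <- (stats::qlogis(p12[["beech"]]) - stats::qlogis(p1)) / log(s_max)
  intercept <- stats::qlogis(p12) - slope * log(s_max)
  list(intercept = intercept, slope = slope)
}

#' Configure a simulated serial-transfer experiment
#'
#' Bundles the experimental design with the generating mechanisms. The
#' `scenario` selects which mechanisms act between week 0 and week 5:
#'
#' * `"sorting_only"` — species go extinct (logistic in log richness), but
#'   neither monoculture yields nor interaction strengths change;
#' * `"additive_evolution"` — per-species multiplicative drift of
#'   monoculture yields, no extinction, interactions unchanged;
#' * `"interaction_evolution"` — the interaction factor theta is multiplied
#'   by `interaction_drift` by week 5, nothing else changes;
#' * `"mixed"` — all three mechanisms act;
#' * `"neutral_additive"` — theta is identically 1 and nothing changes over
#'   time (the null for calibration studies).
#'
#' Unset parameters take scenario-appropriate defaults calibrated to the
#' tree-hole community system: mean base yields uniform on
#' `base_yield_range` (spruce scaled by `spruce_factor`), interaction decay
#' giving dicultures ~52-75 % and 12-species mixes ~10-16 % of additive, and
#' extinction rising from ~1 % in monocultures to 74-86 % at richness 12.
#'
#' @param scenario One of the five scenario names.
#' @param design A [design_spec()].
#' @param base_yield_range Range of mean monoculture yields (absorbance) in
#'   beech; pH 5 shares beech means, spruce is scaled by `spruce_factor`.
#' @param spruce_factor Multiplier on base yields in the spruce environment.
#' @param theta1,lambda Named per-environment interaction-curve parameters
#'   (`theta(S,E) = theta1[E] * S^-lambda[E]`); `NULL` uses the calibrated
#'   defaults (or 1 and 0 under `"neutral_additive"`).
#' @param yield_drift Per-species multiplicative change of monoculture yield
#'   by week 5; `NULL` draws one value per species from
#'   `Normal(drift_mean, drift_sd)` (truncated to `[0.5, 2.5]`) in scenarios
#'   with additive evolution, otherwise all 1.
#' @param drift_mean,drift_sd Distribution of drawn yield drifts.
#' @param interaction_drift Multiplicative change of theta by week 5; `NULL`
#'   means 2 in scenarios with interaction evolution, otherwise 1.
#' @param extinction `NULL` for the scenario default (calibrated model in
#'   `"sorting_only"`/`"mixed"`, none otherwise), `FALSE` for no extinction,
#'   or a list as returned by [calibrate_extinction()].
#' @param isolate_decline Slope of isolate relative yield on log source
#'   richness (<= 0: isolates from diverse communities grow less).
#' @param noise_sd Residual measurement noise, as a fraction of the expected
#'   yield.
#' @param microcosm_sd SD of the multiplicative per-microcosm effect shared
#'   across weeks (the random-intercept analogue).
#' @param detection_limit Relative abundance below which a species is scored
#'   extinct (documentation of the plating assay; the Bernoulli extinction
#'   model subsumes it).
#' @param weeks Integer observation weeks (0 = first growth period after the
#'   environmental split, 5 = final week).
#' @param od_start Starting OD of simulated growth curves.
#' @param include_transfers Whether [simulate_experiment()] also generates
#'   per-period OD reading series.
#' @param seed Integer seed; every simulated quantity is deterministic given
#'   the config.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(scenario = "sorting_only",
                              design = design_spec(),
                              base_yield_range = c(0.1, 0.4),
                              spruce_factor = 0.5,
                              theta1 = NULL, lambda = NULL,
                              yield_drift = NULL,
                              drift_mean = 1.3, drift_sd = 0.15,
                              interaction_drift = NULL,
                              extinction = NULL,
                              isolate_decline = -0.05,
                              noise_sd = 0.05,
                              microcosm_sd = 0.03,
                              detection_limit = 1e-4,
                              weeks = c(0L, 5L),
                              od_start = 0.01,
                              include_transfers = TRUE,
                              seed = 1L) {
  scenario <- match.arg(scenario, .EEP_SCENARIOS)
  th <- .eep_theta_defaults()
  if (scenario == "neutral_additive") {
    if (is.null(theta1)) theta1 <- stats::setNames(rep(1, 3), environments())
    if (is.null(lambda)) lambda <- stats::setNames(rep(0, 3), environments())
  } else {
    if (is.null(theta1)) theta1 <- th$theta1
    if (is.null(lambda)) lambda <- th$lambda
  }
  if (is.null(interaction_drift)) {
    interaction_drift <-
      if (scenario %in% c("interaction_evolution", "mixed")) 2 else 1
  }
  extinction_on <- NULL
  if (is.null(extinction)) {
    extinction_on <- scenario %in% c("sorting_only", "mixed")
    extinction <- calibrate_extinction()
  } else if (identical(extinction, FALSE)) {
    extinction_on <- FALSE
    extinction <- calibrate_extinction()
  } else {
    stopifnot(is.list(extinction),
              all(c("intercept", "slope") %in% names(extinction)))
    extinction_on <- TRUE
  }
  stopifnot(noise_sd >= 0, microcosm_sd >= 0,
            all(weeks >= 0), od_start > 0)
  structure(
    list(scenario = scenario, design = design,
         base_yield_range = base_yield_range, spruce_factor = spruce_factor,
         theta1 = theta1, lambda = lambda,
         yield_drift = yield_drift, drift_mean = drift_mean,
         drift_sd = drift_sd, interaction_drift = interaction_drift,
         extinction = extinction, extinction_on = extinction_on,
         isolate_decline = isolate_decline, noise_sd = noise_sd,
         microcosm_sd = microcosm_sd, detection_limit = detection_limit,
         weeks = as.integer(sort(unique(weeks))), od_start = od_start,
         include_transfers = include_transfers, seed = as.integer(seed)),
    class = "simulation_config")
}

#' Resolve the drawn parameters of a simulation
#'
#' Draws (deterministically from `config$seed`) the quantities that are
#' random at the level of the experiment rather than the observation: mean
#' base yields per species and environment, and per-species yield drifts.
#'
#' @param config A [simulation_config()].
#' @return List with `base_yields` (species x environment matrix of mean
#'   week-0 monoculture yields) and `yield_drift` (named per-species vector).
#' @export
simulation_params <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  species <- config$design$species
  set.seed(config$seed + 101L)
  beech <- stats::runif(length(species), config$base_yield_range[1],
                        config$base_yield_range[2])
  base <- cbind(beech = beech, ph5 = beech,
                spruce = beech * config$spruce_factor)
  rownames(base) <- species
  drift <- config$yield_drift
  if (is.null(drift)) {
    if (config$scenario %in% c("additive_evolution", "mixed")) {
      drift <- pmin(pmax(stats::rnorm(length(species), config$drift_mean,
                                      config$drift_sd), 0.5), 2.5)
    } else {
      drift <- rep(1, length(species))
    }
  }
  drift <- stats::setNames(rep(drift, length.out = length(species)), species)
  list(base_yields = base, yield_drift = drift)
}

# interaction factor at a given week (linear interpolation of the drift)
.eep_theta_at <- function(config, richness, environment, week) {
  env <- as.character(environment)
  th0 <- config$theta1[env] * richness^(-config$lambda[env])
  unname(th0 * (1 + (config$interaction_drift - 1) * week / 5))
}

#' Simulate end-of-experiment survival for one community
#'
#' Each member survives independently with probability
#' `1 - plogis(alpha_E + gamma * log S)`; the draw is repeated until at
#' least one species survives (an empty microcosm is never observed). When
#' the config's scenario has no extinction, all members survive.
#'
#' @param config A [simulation_config()].
#' @param members Character vector of member species.
#' @param environment Environment label.
#' @return Named integer vector of 0/1 survival indicators.
#' @export
simulate_survival <- function(config, members, environment) {
  s <- length(members)
  env <- as.character(normalize_environment(environment))
  if (!config$extinction_on) {
    return(stats::setNames(rep(1L, s), members))
  }
  p_ext <- stats::plogis(config$extinction$intercept[[env]] +
                           config$extinction$slope * log(s))
  repeat {
    surv <- stats::rbinom(s, 1L, 1 - p_ext)
    if (any(surv == 1L)) break
  }
  stats::setNames(as.integer(surv), members)
}

#' Simulate monoculture yield observations
#'
#' Expected monoculture yield of species i at week w is
#' `a_i0 * (1 + (drift_i - 1) * w/5)`; observations add the shared
#' multiplicative microcosm effect and Gaussian noise with SD
#' `noise_sd * expectation`, clamped at zero.
#'
#' @param config A [simulation_config()].
#' @param week Observation week.
#' @param params Optional pre-resolved [simulation_params()].
#' @return Data frame with columns `species_id`, `environment`, `replicate`,
#'   `week`, `yield`.
#' @export
simulate_monoculture_yields <- function(config, week = 5,
                                        params = simulation_params(config)) {
  species <- config$design$species
  grid <- expand.grid(replicate = seq_len(config$design$replicates),
                      environment = environments(), species_id = species,
                      stringsAsFactors = FALSE)
  a0 <- params$base_yields[cbind(grid$species_id, grid$environment)]
  expected <- a0 * (1 + (params$yield_drift[grid$species_id] - 1) * week / 5)
  me <- pmax(1 + stats::rnorm(nrow(grid), 0, config$microcosm_sd), 0.2)
  y <- pmax(expected * me + stats::rnorm(nrow(grid), 0,
                                         config$noise_sd * expected), 0)
  data.frame(species_id = grid$species_id, environment = grid$environment,
             replicate = grid$replicate, week = week, yield = unname(y),
             stringsAsFactors = FALSE)
}

#' Simulate one community yield observation
#'
#' The expected community yield is the interaction factor `theta(S, E, w)`
#' times the additive sum of (true mean) member yields at that week, with
#' extinct members removed at week 5. Observation noise and the microcosm
#' effect enter as in [simulate_monoculture_yields()].
#'
#' @param config A [simulation_config()].
#' @param members Character vector of member species.
#' @param environment Environment label.
#' @param week Observation week.
#' @param survival Named 0/1 vector from [simulate_survival()]; required
#'   when `week == 5` and extinction is active.
#' @param microcosm_effect Shared multiplicative microcosm effect (default
#'   drawn).
#' @param params Optional pre-resolved [simulation_params()].
#' @return Single non-negative yield.
#' @export
simulate_community_yield <- function(config, members, environment, week,
                                     survival = NULL,
                                     microcosm_effect = NULL,
                                     params = simulation_params(config)) {
  env <- as.character(normalize_environment(environment))
  s <- length(members)
  a_w <- params$base_yields[members, env] *
    (1 + (params$yield_drift[members] - 1) * week / 5)
  keep <- rep(1, s)
  if (week == 5) {
    if (is.null(survival)) {
      survival <- simulate_survival(config, members, env)
    }
    keep <- as.numeric(survival[members])
  }
  expected <- .eep_theta_at(config, s, env, week) * sum(a_w * keep)
  if (is.null(microcosm_effect)) {
    microcosm_effect <- pmax(1 + stats::rnorm(1, 0, config$microcosm_sd), 0.2)
  }
  max(expected * microcosm_effect +
        stats::rnorm(1, 0, config$noise_sd * expected), 0)
}

#' Simulate a logistic OD reading series for one growth period
#'
#' Produces daily OD readings following a normalised sigmoid from `od_start`
#' to `od_start + target_yield`, saturating exactly at the final reading, so
#' [compute_yield()] on the noise-free series recovers `target_yield`
#' exactly. Noise (if any) perturbs the realised amplitude once per series
#' (measurement noise shared across readings), and the series is clamped at
#' zero.
#'
#' @param target_yield Non-negative target biomass gain.
#' @param od_start Starting OD.
#' @param noise_sd Amplitude noise as a fraction of `target_yield`.
#' @param days Reading days after the start.
#' @param rate,midpoint Sigmoid shape parameters (per day; day of half rise).
#' @return Data frame with columns `day` (0 = start) and `od`.
#' @export
simulate_od_series <- function(target_yield, od_start = 0.01, noise_sd = 0,
                               days = 1:5, rate = 2.2, midpoint = 2) {
  stopifnot(target_yield >= 0, od_start > 0)
  tt <- c(0, days)
  f <- stats::plogis(rate * (tt - midpoint))
  g <- (f - f[1]) / (f[length(f)] - f[1])
  amp <- target_yield
  if (noise_sd > 0) {
    amp <- target_yield + stats::rnorm(1, 0, noise_sd * target_yield)
  }
  data.frame(day = tt, od = pmax(od_start + amp * g, 0))
}

#' Simulate isolate growth-assay yields
#'
#' For every surviving species of every microcosm, the isolate's monoculture
#' yield is the species' true week-5 mean yield scaled by
#' `1 + isolate_decline * log(S)` of the source community, with measurement
#' noise; the matched ancestral isolate's yield is the week-0 mean with
#' measurement noise. Extinct species yield no row.
#'
#' @param config A [simulation_config()].
#' @param survival Survival table (`microcosm_id`, `species_id`, `survived`).
#' @param microcosms Microcosm roster from [expand_microcosms()].
#' @param params Optional pre-resolved [simulation_params()].
#' @return Isolate data frame (see [read_isolate_table()]).
#' @export
simulate_isolate_yields <- function(config, survival, microcosms,
                                    params = simulation_params(config)) {
  rows <- survival[survival$survived == 1L, , drop = FALSE]
  m <- match(rows$microcosm_id, microcosms$microcosm_id)
  env <- microcosms$environment[m]
  s <- microcosms$richness[m]
  a5 <- params$base_yields[cbind(rows$species_id, env)] *
    params$yield_drift[rows$species_id]
  b <- a5 * (1 + config$isolate_decline * log(s))
  b <- pmax(b * (1 + stats::rnorm(nrow(rows), 0, config$noise_sd)), 0)
  anc <- params$base_yields[cbind(rows$species_id, env)]
  anc <- pmax(anc * (1 + stats::rnorm(nrow(rows), 0, config$noise_sd)), 1e-6)
  data.frame(microcosm_id = rows$microcosm_id, species_id = rows$species_id,
             environment = env, source_richness = s,
             yield = unname(b), ancestral_yield = unname(anc),
             stringsAsFactors = FALSE)
}

#' Simulate a complete serial-transfer experiment
#'
#' Generates the design, microcosm roster, yield observations at every
#' requested week (communities and monocultures), the end-of-experiment
#' survival matrix, isolate growth assays, optional OD reading series, and a
#' `truth` record of the generating scenario and parameters for recovery
#' studies. All output is deterministic given the config (design and
#' parameter draws use fixed sub-seeds derived from `config$seed`).
#'
#' @param config A [simulation_config()].
#' @return Object of class `eep_experiment`: a list with elements `config`,
#'   `design`, `microcosms`, `yields`, `survival`, `isolates`, `transfers`
#'   (or `NULL`), and `truth`.
#' @export
simulate_experiment <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  design <- generate_design(config$design)   # seeded by design spec
  microcosms <- expand_microcosms(design, config$design$replicates)
  members <- composition_members(design)
  params <- simulation_params(config)        # seeded by config seed

  set.seed(config$seed + 202L)
  me <- stats::setNames(
    pmax(1 + stats::rnorm(nrow(microcosms), 0, config$microcosm_sd), 0.2),
    microcosms$microcosm_id)

  # survival (all microcosms; monocultures always retain their species)
  surv_list <- lapply(seq_len(nrow(microcosms)), function(i) {
    mem <- members[[microcosms$composition_id[i]]]
    sv <- simulate_survival(config, mem, microcosms$environment[i])
    data.frame(microcosm_id = microcosms$microcosm_id[i],
               species_id = mem, survived = unname(sv),
               stringsAsFactors = FALSE)
  })
  survival <- do.call(rbind, surv_list)

  # yields for every microcosm x week
  yields <- do.call(rbind, lapply(config$weeks, function(w) {
    exp_w <- vapply(seq_len(nrow(microcosms)), function(i) {
      mem <- members[[microcosms$composition_id[i]]]
      env <- microcosms$environment[i]
      s <- length(mem)
      a_w <- params$base_yields[mem, env] *
        (1 + (params$yield_drift[mem] - 1) * w / 5)
      keep <- rep(1, s)
      if (w == 5) {
        sv <- survival[survival$microcosm_id == microcosms$microcosm_id[i], ]
        keep <- as.numeric(sv$survived[match(mem, sv$species_id)])
      }
      th <- if (s >= 2) .eep_theta_at(config, s, env, w) else 1
      th * sum(a_w * keep)
    }, numeric(1))
    y <- pmax(exp_w * me[microcosms$microcosm_id] +
                stats::rnorm(nrow(microcosms), 0, config$noise_sd * exp_w), 0)
    data.frame(microcosm_id = microcosms$microcosm_id,
               composition_id = microcosms$composition_id,
               environment = microcosms$environment,
               replicate = microcosms$replicate,
               week = w, yield = unname(y), stringsAsFactors = FALSE)
  }))
  row.names(yields) <- NULL

  set.seed(config$seed + 303L)
  isolates <- simulate_isolate_yields(config, survival, microcosms, params)

  transfers <- NULL
  if (isTRUE(config$include_transfers)) {
    set.seed(config$seed + 404L)
    transfers <- do.call(rbind, lapply(seq_len(nrow(yields)), function(i) {
      ser <- simulate_od_series(yields$yield[i], od_start = config$od_start)
      data.frame(microcosm_id = yields$microcosm_id[i],
                 period_index = match(yields$week[i], config$weeks),
                 day = ser$day, od = ser$od, stringsAsFactors = FALSE)
    }))
  }

  truth <- list(
    scenario = config$scenario, seed = config$seed,
    theta1 = as.list(config$theta1), lambda = as.list(config$lambda),
    interaction_drift = config$interaction_drift,
    yield_drift = as.list(params$yield_drift),
    extinction_on = config$extinction_on,
    extinction_intercept = as.list(config$extinction$intercept),
    extinction_slope = config$extinction$slope,
    isolate_decline = config$isolate_decline,
    noise_sd = config$noise_sd, microcosm_sd = config$microcosm_sd,
    weeks = config$weeks)

  structure(list(config = config, design = design, microcosms = microcosms,
                 yields = yields, survival = survival, isolates = isolates,
                 transfers = transfers, truth = truth),
            class = "eep_experiment")
}

#' Write a simulated experiment to a directory of plain-text files
#'
#' Writes `design.csv`, `yields.csv`, `survival.csv`, `isolates.csv`,
#' `transfers.csv` (when present) and the `truth.json` sidecar.
#'
#' @param experiment An `eep_experiment` from [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "eep_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_design_table(experiment$design, file.path(dir, "design.csv"))
  write_yield_table(experiment$yields, file.path(dir, "yields.csv"))
  write_survival_table(experiment$survival, file.path(dir, "survival.csv"))
  write_isolate_table(experiment$isolates, file.path(dir, "isolates.csv"))
  if (!is.null(experiment$transfers)) {
    utils::write.csv(experiment$transfers, file.path(dir, "transfers.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(experiment$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
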