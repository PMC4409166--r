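# Shared fixtures: small simulated experiments reused across test files.

# fast experiment (no OD series) for a given scenario
quick_experiment <- function(scenario = "sorting_only", seed = 1, ...) {
  simulate_experiment(simulation_config(scenario = scenario, seed = seed,
                                        include_transfers = FALSE, ...))
}

# noise-free, exactly additive experiment: community yield == additive sum
exact_additive_experiment <- function(seed = 1) {
  simulate_experiment(simulation_config(
    scenario = "neutral_additive", noise_sd = 0, microcosm_sd = 0,
    seed = seed, include_transfers = FALSE))
}

# synthetic community frame with known slope structure, for model tests
synthetic_frame <- function(n = 300, seed = 1,
                            slope = c(beech = 0.9, ph5 = 0.5, spruce = 0.2),
                            logS_slope = 0, noise = 0.03) {
  set.seed(seed)
  d <- data.frame(
    addsum = stats::runif(n, 0.3, 2),
    environment = factor(sample(environments(), n, TRUE),
                         levels = environments()),
    logS = log(sample(c(2, 3, 6, 12), n, TRUE)))
  d$richness <- exp(d$logS)
  b <- slope[as.character(d$environment)]
  d$yield <- (b + logS_slope * d$logS) * d$addsum + stats::rnorm(n, 0, noise)
  d
}
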