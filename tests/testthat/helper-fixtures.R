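# shared fixtures; everything is generated in code at test time

# lighter tuning grids for repeated fits in property-style tests
quick_config <- function(folds = 5, ...) {
  zoo_config(folds = folds, enet_alpha = c(0, 0.5, 1), enet_nlambda = 30,
             rf_mtry_frac = c(1 / 3, 1), rf_num_trees = 200, ...)
}

# one simulated training study (design blocks + responses) under a scenario
make_training_data <- function(seed = 1, n_blocks = 4, replicates = 3,
                               scenario = default_scenario()) {
  design <- generate_dsd(scenario$k)
  blocks <- dsd_blocks(design, n_blocks, seed = seed)
  profiles <- sample_donor_profiles(n_blocks, scenario, seed = seed + 1)
  responses <- simulate_responses(profiles, blocks, replicates = replicates,
                                  seed = seed + 2)
  list(design = design, blocks = blocks, profiles = profiles,
       responses = responses, ids = design_factors(design),
       scenario = scenario)
}

# donor-response training table for one donor (coded columns + value)
donor_cell <- function(td, donor = "d01", response = "expansion_d6") {
  dsd <- td$blocks[td$blocks$run_role == "dsd_formulation",
                   c("block_id", "run_id", td$ids)]
  dplyr::inner_join(
    td$responses[td$responses$donor_id == donor &
                 td$responses$response == response, ],
    dsd, by = c("block_id", "run_id"))
}

# independent AIC oracle used against the stepwise fits:
# AIC = n log(RSS/n) + 2p with p counting coefficients incl. intercept
aic_of_terms <- function(Xs, y, terms) {
  X1 <- cbind(1, Xs[, terms, drop = FALSE])
  fit <- stats::lm.fit(X1, y)
  rss <- sum(fit$residuals^2)
  n <- length(y)
  n * log(rss / n) + 2 * fit$rank
}

# scaled feature matrix exactly as the fitting path builds it
scaled_features <- function(formulations, equation) {
  F <- build_features(formulations, equation)
  mu <- colMeans(F)
  sd <- apply(F, 2, stats::sd)
  sd[sd < 1e-12] <- 1
  sweep(sweep(F, 2, mu, "-"), 2, sd, "/")
}
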