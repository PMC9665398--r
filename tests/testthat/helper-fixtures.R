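# Shared fixtures, built in code at test time.

# tiny 3-scenario design exercising both program contrasts and price
tiny_scenarios <- function() {
  data.frame(scenario_id = 1:3,
             model_a = c("PEDESTRIANS", "PEDESTRIANS", "OCCUPANTS"),
             price_a = c(15, 19, 15),
             model_b = c("MOST", "MOST", "MOST"),
             price_b = c(15, 15, 19),
             stringsAsFactors = FALSE)
}

tiny_records <- function() {
  data.frame(participant_id = rep(c("P1", "P2"), each = 3),
             country = "UK",
             scenario_id = rep(1:3, 2),
             choice = c("A", "A", "A", "A", "B", "A"),
             stringsAsFactors = FALSE)
}

# Recovery fits are expensive; share them between the criterion blocks that
# interrogate the same fitted posterior.
.fit_cache <- new.env(parent = emptyenv())

recovery_fit <- function(preset, seed = 1) {
  key <- paste0(preset, "_", seed)
  if (is.null(.fit_cache[[key]])) {
    pop <- population_preset(preset, seed = seed)
    ind <- draw_individuals(pop)
    rec <- simulate_choices(ind, generate_choice_design(), seed = seed + 1L)
    post <- sample_posterior(rec, generate_choice_design(),
                             model_config(n_chains = 3, n_samples = 4000,
                                          n_burnin = 1000, seed = seed))
    .fit_cache[[key]] <- list(pop = pop, individuals = ind, records = rec,
                              posterior = post, wtp = wtp_report(post))
  }
  .fit_cache[[key]]
}
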