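# Seeded synthetic-survey generator. The generator mirrors the statistical
# structure the analysis assumes: a normal hierarchy for individual utilities
# and sensitivities, probit choices, frame-congruent categorical switching and
# a latent-normal Likert mechanism.

#' Population specification for the choice hierarchy
#'
#' Defines the population-level distribution individuals are drawn from:
#' `ped_i, occ_i ~ N(hped, 1/ht)` and `tau_i ~ N(htau, 1/ht2)` truncated
#' below at zero (a negative sensitivity would invert every preference, so
#' the generator excludes it; the fitted model keeps the untruncated
#' hierarchy).
#'
#' @param hped,hocc Population mean utilities of the PEDESTRIANS and
#'   OCCUPANTS programs (GBP thousands; MOST is the 0 reference).
#' @param htau Population mean sensitivity (per GBP thousand).
#' @param ht Precision of the ped/occ individual distributions (> 0).
#' @param ht2 Precision of the tau individual distribution (> 0).
#' @param n_participants Number of participants (>= 1).
#' @param seed Integer seed for reproducible draws.
#' @param country Survey population label, `"UK"` or `"JP"`.
#' @return A list of class `dce_population_spec`.
#' @export
population_spec <- function(hped, hocc, htau, ht = 0.1, ht2 = 100,
                            n_participants = 186, seed = 1, country = "UK") {
  if (!is.numeric(ht) || ht <= 0 || !is.numeric(ht2) || ht2 <= 0)
    stop("precisions `ht` and `ht2` must be positive", call. = FALSE)
  if (n_participants < 1) stop("`n_participants` must be >= 1", call. = FALSE)
  country <- match.arg(country, countries())
  structure(list(hped = hped, hocc = hocc, htau = htau, ht = ht, ht2 = ht2,
                 n_participants = as.integer(n_participants),
                 seed = as.integer(seed), country = country),
            class = "dce_population_spec")
}

# inverse-CDF draw from N(mean, sd) truncated below at `lower`; vectorised and
# deterministic under the active RNG stream
rtruncnorm_lower <- function(n, mean, sd, lower = 0) {
  p_lo <- stats::pnorm(lower, mean, sd)
  u <- stats::runif(n, p_lo, 1)
  stats::qnorm(u, mean, sd)
}

#' Draw individual-level parameters from the population
#'
#' @param spec A [population_spec()].
#' @return Data frame with `participant_id`, `country`, `ped`, `occ`, `tau`;
#'   identical output for identical `(spec, seed)`.
#' @export
draw_individuals <- function(spec) {
  stopifnot(inherits(spec, "dce_population_spec"))
  set.seed(spec$seed)
  n <- spec$n_participants
  sd_u <- 1 / sqrt(spec$ht)
  sd_t <- 1 / sqrt(spec$ht2)
  data.frame(
    participant_id = sprintf("P%04d", seq_len(n)),
    country = spec$country,
    ped = stats::rnorm(n, spec$hped, sd_u),
    occ = stats::rnorm(n, spec$hocc, sd_u),
    tau = rtruncnorm_lower(n, spec$htau, sd_t, 0),
    stringsAsFactors = FALSE
  )
}

#' Simulate discrete-choice records
#'
#' For every (individual, scenario) pair, draws a single Bernoulli choice of
#' car A with probability `pnorm(tau_i * delta_u)` (see
#' [choice_probability()]).
#'
#' @param individuals Data frame from [draw_individuals()] (columns
#'   `participant_id`, `ped`, `occ`, `tau`, optionally `country`).
#' @param scenarios Scenario table as from [generate_choice_design()].
#' @param seed Integer seed.
#' @return Data frame of choice records (`participant_id`, `country`,
#'   `scenario_id`, `choice`).
#' @export
simulate_choices <- function(individuals, scenarios, seed = 1) {
  if (is.null(scenarios) || nrow(scenarios) == 0L)
    stop("`scenarios` must be non-empty", call. = FALSE)
  set.seed(seed)
  n <- nrow(individuals)
  S <- nrow(scenarios)
  du <- outer(individuals$ped,
              (scenarios$model_a == "PEDESTRIANS") - (scenarios$model_b == "PEDESTRIANS")) +
    outer(individuals$occ,
          (scenarios$model_a == "OCCUPANTS") - (scenarios$model_b == "OCCUPANTS")) +
    matrix(scenarios$price_b - scenarios$price_a, n, S, byrow = TRUE)
  p_a <- stats::pnorm(individuals$tau * du)
  pick_a <- matrix(stats::runif(n * S), n, S) < p_a
  country <- if (!is.null(individuals$country)) individuals$country else "UK"
  data.frame(
    participant_id = rep(individuals$participant_id, times = S),
    country = rep(country, times = S),
    scenario_id = rep(scenarios$scenario_id, each = n),
    choice = ifelse(as.vector(pick_a), "A", "B"),
    stringsAsFactors = FALSE
  )
}

#' Categorical-preference specification
#'
#' `base_probs` is the population distribution of the latent (unframed)
#' program preference over `MOST, OCCUPANTS, PEDESTRIANS, RANDOM`;
#' `frame_shift` is the probability that a framed question switches a
#' respondent to the frame-congruent option (OCCUPANTS under
#' FAMILY_PASSENGER, PEDESTRIANS under FAMILY_PEDESTRIAN).
#'
#' @param base_probs Probability vector of length 4 summing to 1, in the
#'   order of [preference_choices()].
#' @param frame_shift Switching probability in `[0, 1]`.
#' @return A list of class `dce_categorical_spec`.
#' @export
categorical_spec <- function(base_probs = c(0.45, 0.2, 0.25, 0.1),
                             frame_shift = 0.3) {
  if (length(base_probs) != 4L || any(base_probs < 0) ||
      abs(sum(base_probs) - 1) > 1e-8)
    stop("`base_probs` must be 4 non-negative probabilities summing to 1",
         call. = FALSE)
  if (frame_shift < 0 || frame_shift > 1)
    stop("`frame_shift` must lie in [0, 1]", call. = FALSE)
  structure(list(base_probs = base_probs, frame_shift = frame_shift),
            class = "dce_categorical_spec")
}

#' Simulate categorical preference responses under all four framings
#'
#' Each participant has one latent unframed preference drawn from
#' `base_probs`; the UNFRAMED response reports it directly, each family
#' framing switches to its congruent option with probability `frame_shift`
#' and otherwise keeps the latent draw, and the MORAL response (which
#' algorithm *should* all cars have) is an independent draw from
#' `base_probs`.
#'
#' @param spec A [categorical_spec()].
#' @param n Number of participants.
#' @param seed Integer seed.
#' @param country Country label for the output table.
#' @return Long data frame (`participant_id`, `country`, `frame`, `choice`),
#'   one row per participant and frame.
#' @export
simulate_preferences <- function(spec, n, seed = 1, country = "UK") {
  stopifnot(inherits(spec, "dce_categorical_spec"))
  set.seed(seed)
  opts <- preference_choices()
  ids <- sprintf("P%04d", seq_len(n))
  latent <- sample(opts, n, replace = TRUE, prob = spec$base_probs)
  congruent <- c(FAMILY_PASSENGER = "OCCUPANTS", FAMILY_PEDESTRIAN = "PEDESTRIANS")
  framed <- lapply(names(congruent), function(f) {
    switch_to <- stats::runif(n) < spec$frame_shift
    ifelse(switch_to, congruent[[f]], latent)
  })
  moral <- sample(opts, n, replace = TRUE, prob = spec$base_probs)
  data.frame(
    participant_id = rep(ids, 4),
    country = country,
    frame = rep(frames(), each = n),
    choice = c(latent, framed[[1]], framed[[2]], moral),
    stringsAsFactors = FALSE
  )
}

#' Likert willingness specification
#'
#' Willingness to purchase is a latent normal `N(baseline_mean,
#' baseline_sd^2)` per participant, clipped to `[1, 7]` and rounded to the
#' integer scale. Under a mandate condition the latent value drops by
#' `mandate_drop` (before discretisation) if and only if the mandated
#' program differs from the participant's preferred (unframed) program —
#' mandates only deter buyers who wanted something else.
#'
#' @param baseline_mean,baseline_sd Latent-normal location and scale
#'   (`baseline_sd > 0`).
#' @param mandate_drop Expected latent decrement when the preferred program
#'   is unavailable.
#' @return A list of class `dce_likert_spec`.
#' @export
likert_spec <- function(baseline_mean = 5.2, baseline_sd = 1.5,
                        mandate_drop = 1.2) {
  if (baseline_sd <= 0) stop("`baseline_sd` must be positive", call. = FALSE)
  structure(list(baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 mandate_drop = mandate_drop), class = "dce_likert_spec")
}

#' Simulate Likert purchase-willingness responses
#'
#' @param spec A [likert_spec()].
#' @param preferences Preference table from [simulate_preferences()] (the
#'   UNFRAMED rows supply each participant's preferred program).
#' @param seed Integer seed.
#' @return Long data frame (`participant_id`, `country`, `condition`,
#'   `response`), one row per participant and condition, responses in 1..7.
#' @export
simulate_likert <- function(spec, preferences, seed = 1) {
  stopifnot(inherits(spec, "dce_likert_spec"))
  set.seed(seed)
  unframed <- preferences[preferences$frame == "UNFRAMED", , drop = FALSE]
  n <- nrow(unframed)
  latent <- stats::rnorm(n, spec$baseline_mean, spec$baseline_sd)
  discretise <- function(x) as.integer(round(pmin(pmax(x, 1), 7)))
  rows <- lapply(conditions(), function(cond) {
    if (cond == "BASELINE") {
      resp <- discretise(latent)
    } else {
      hit <- mandated_program(cond) != unframed$choice
      resp <- discretise(latent - spec$mandate_drop * hit)
    }
    data.frame(participant_id = unframed$participant_id,
               country = unframed$country,
               condition = cond, response = resp, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate a complete synthetic survey
#'
#' Runs the three generators with independent streams split from a master
#' seed (choices, preferences and Likert tables can therefore be regenerated
#' independently) and returns all tables the downstream analysis consumes.
#'
#' @param pop A [population_spec()]; its `seed` is overridden by `seed`.
#' @param cat_spec A [categorical_spec()].
#' @param lik_spec A [likert_spec()].
#' @param scenarios Scenario table; defaults to the canonical 36-scenario
#'   design.
#' @param seed Master integer seed.
#' @return List with `individuals`, `scenarios`, `choices`, `preferences`,
#'   `likert`.
#' @export
simulate_survey <- function(pop, cat_spec = categorical_spec(),
                            lik_spec = likert_spec(),
                            scenarios = generate_choice_design(), seed = 1) {
  pop$seed <- as.integer(seed)
  individuals <- draw_individuals(pop)
  choices <- simulate_choices(individuals, scenarios, seed = seed + 1L)
  preferences <- simulate_preferences(cat_spec, pop$n_participants,
                                      seed = seed + 2L, country = pop$country)
  likert <- simulate_likert(lik_spec, preferences, seed = seed + 3L)
  list(individuals = individuals, scenarios = scenarios, choices = choices,
       preferences = preferences, likert = likert)
}
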