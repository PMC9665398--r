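test_that("individual draws follow the population distributions", {
  spec <- population_spec(hped = -10.7, hocc = -3.17, htau = 0.291,
                          ht = 1, ht2 = 100, n_participants = 10000, seed = 42)
  ind <- draw_individuals(spec)
  # Monte-Carlo agreement with the stated normal (3 standard errors)
  expect_lt(abs(mean(ind$ped) - (-10.7)), 3 / sqrt(10000))
  expect_lt(abs(mean(ind$occ) - (-3.17)), 3 / sqrt(10000))
  expect_lt(abs(sd(ind$ped) - 1), 0.05)
  # sensitivity truncated below zero
  expect_true(all(ind$tau > 0))
  # determinism and the degenerate high-precision limit
  expect_identical(ind, draw_individuals(spec))
  tight <- draw_individuals(population_spec(-10.7, -3.17, 0.291, ht = 1e8,
                                            ht2 = 1e8, n_participants = 50,
                                            seed = 1))
  expect_true(all(abs(tight$ped + 10.7) < 0.01))
  expect_error(population_spec(0, 0, 0.3, ht = -1), "positive")
})

test_that("simulated choice frequencies match the probit probabilities", {
  scen <- generate_choice_design()
  # deterministic limit: huge sensitivity, cheaper same-program car always wins
  one <- data.frame(participant_id = "P1", ped = 0, occ = 0, tau = 1000)
  s_price <- scen[scen$model_a == "MOST" & scen$model_b == "MOST" &
                    scen$price_a == 15 & scen$price_b == 23, ]
  rec <- simulate_choices(one, s_price, seed = 1)
  expect_equal(rec$choice, "A")  # delta_u = +8, P(A) ~ 1
  # balanced limit: delta_u = 0 scenario chooses A about half the time
  s0 <- data.frame(scenario_id = 1L, model_a = "MOST", price_a = 15,
                   model_b = "OCCUPANTS", price_b = 15)  # occ = 0: delta_u = 0
  many <- data.frame(participant_id = sprintf("P%04d", 1:4000),
                     ped = 0, occ = 0, tau = 0.3)
  f <- mean(simulate_choices(many, s0, seed = 2)$choice == "A")
  expect_lt(abs(f - 0.5), 3 * 0.5 / sqrt(4000))
  # full design at fixed preferences: per-scenario frequencies track
  # pnorm(tau * delta_u) within 3 binomial standard errors
  n <- 5000
  fixed <- data.frame(participant_id = sprintf("P%04d", 1:n),
                      ped = -10.7, occ = -3.17, tau = 0.291)
  rec <- simulate_choices(fixed, scen, seed = 3)
  du <- utility_difference(
    data.frame(program = scen$model_a, price = scen$price_a),
    data.frame(program = scen$model_b, price = scen$price_b), -10.7, -3.17)
  p <- choice_probability(du, 0.291)
  freq <- tapply(rec$choice == "A", rec$scenario_id, mean)[as.character(scen$scenario_id)]
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(freq - p) < pmax(3 * se, 1e-6)))
})

test_that("framed preferences mix toward the congruent option", {
  # full-shift and no-shift limits
  all_shift <- simulate_preferences(categorical_spec(frame_shift = 1), 500, seed = 1)
  expect_true(all(all_shift$choice[all_shift$frame == "FAMILY_PASSENGER"] ==
                    "OCCUPANTS"))
  expect_true(all(all_shift$choice[all_shift$frame == "FAMILY_PEDESTRIAN"] ==
                    "PEDESTRIANS"))
  no_shift <- simulate_preferences(categorical_spec(frame_shift = 0), 500, seed = 2)
  un <- no_shift$choice[no_shift$frame == "UNFRAMED"]
  fp <- no_shift$choice[no_shift$frame == "FAMILY_PASSENGER"]
  expect_identical(un, fp)  # same latent draw underlies both
  # mixture arithmetic: P(OCCUPANTS | family-passenger frame) = pi + (1-pi)/4
  n <- 20000
  mix <- simulate_preferences(categorical_spec(base_probs = rep(0.25, 4),
                                               frame_shift = 0.4), n, seed = 3)
  share <- mean(mix$choice[mix$frame == "FAMILY_PASSENGER"] == "OCCUPANTS")
  expected <- 0.4 + 0.6 * 0.25
  expect_lt(abs(share - expected), 3 * sqrt(expected * (1 - expected) / n))
})

test_that("likert generator applies the mandate drop to non-preferrers only", {
  prefs <- simulate_preferences(categorical_spec(), 400, seed = 4)
  # null effect: no drop leaves every condition identical to baseline
  null <- simulate_likert(likert_spec(mandate_drop = 0), prefs, seed = 5)
  base <- null$response[null$condition == "BASELINE"]
  for (cond in c("MANDATE_MOST", "MANDATE_PED", "MANDATE_OCC"))
    expect_identical(null$response[null$condition == cond], base)
  # clipping boundary
  hi <- simulate_likert(likert_spec(baseline_mean = 9, baseline_sd = 0.1,
                                    mandate_drop = 0), prefs, seed = 6)
  expect_true(all(hi$response == 7L))
  # expectation arithmetic in the pre-clipping regime:
  # 30% prefer the mandated program, so the mean drops by 0.7 * drop
  n <- 20000
  ids <- sprintf("P%05d", 1:n)
  prefer <- rep(c("MOST", "PEDESTRIANS"), times = c(0.3 * n, 0.7 * n))
  pref30 <- data.frame(participant_id = ids, country = "UK",
                       frame = "UNFRAMED", choice = prefer)
  lik <- simulate_likert(likert_spec(baseline_mean = 5.1, baseline_sd = 0.6,
                                     mandate_drop = 1.5), pref30, seed = 7)
  m_base <- mean(lik$response[lik$condition == "BASELINE"])
  m_mand <- mean(lik$response[lik$condition == "MANDATE_MOST"])
  expect_lt(abs((m_base - m_mand) - 0.7 * 1.5), 0.05)
})

test_that("a full synthetic survey is seed-deterministic and io-valid", {
  pop <- population_spec(-2, 1, 0.3, ht = 0.5, ht2 = 100, n_participants = 12,
                         seed = 1, country = "JP")
  s1 <- simulate_survey(pop, seed = 9)
  s2 <- simulate_survey(pop, seed = 9)
  expect_identical(s1, s2)
  dir <- withr::local_tempdir()
  write_choice_table(file.path(dir, "choices.csv"), s1$scenarios, s1$choices)
  write_preference_table(file.path(dir, "preferences.csv"), s1$preferences)
  write_likert_table(file.path(dir, "likert.csv"), s1$likert)
  expect_equal(read_choice_table(file.path(dir, "choices.csv"))$records,
               s1$choices)
  expect_equal(read_preference_table(file.path(dir, "preferences.csv")),
               s1$preferences, ignore_attr = TRUE)
  expect_equal(read_likert_table(file.path(dir, "likert.csv")),
               s1$likert, ignore_attr = TRUE)
})

test_that("simulated data are most likely under the generating parameters", {
  scen <- generate_choice_design()
  pop <- population_spec(-6, -2, 0.3, ht = 0.4, ht2 = 100,
                         n_participants = 150, seed = 11)
  ind <- draw_individuals(pop)
  rec <- simulate_choices(ind, scen, seed = 12)
  ll_true <- log_likelihood(rec, scen, ind)
  for (shift in c(-3, 3)) {
    bent <- ind
    bent$ped <- bent$ped + shift
    expect_gt(ll_true, log_likelihood(rec, scen, bent))
    bent <- ind
    bent$tau <- pmax(bent$tau + shift / 10, 1e-3)
    expect_gt(ll_true, log_likelihood(rec, scen, bent))
  }
})
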