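# Willingness-to-pay reporting and posterior predictive checks.

#' Willingness-to-pay report
#'
#' Converts population-level program utilities into price premiums in whole
#' pounds: `premium = -1000 * utility` (utilities are in GBP thousands). The
#' reference program MOST has premium 0 by construction. A positive premium
#' means the population prefers MOST and would need that price discount on
#' the alternative before accepting it; a negative premium means the
#' alternative is preferred and commands that price increase.
#'
#' Individual-level premium distributions are computed from the posterior
#' means of each participant's `Ped_i` and `Occ_i`. The report also flags a
#' posterior in which the (untruncated) sensitivity hierarchy places more
#' than 1% mass on negative individual sensitivities, which would signal a
#' poorly identified sensitivity scale.
#'
#' @param posterior A `dce_posterior` from [sample_posterior()] containing
#'   individual-level draws.
#' @return An object of class `dce_wtp`: list with `premiums` (data frame:
#'   program, premium, hdi_lower, hdi_upper in GBP), `individual_premiums`
#'   (data frame per participant), `tau_negative_mass` and
#'   `tau_hierarchy_flag`.
#' @export
wtp_report <- function(posterior) {
  stopifnot(inherits(posterior, "dce_posterior"))
  mass <- posterior$config$hdi_mass
  premium_row <- function(program, draws_k) {
    prem <- -1000 * draws_k
    h <- hdi(prem, mass)
    data.frame(program = program, premium = mean(prem),
               hdi_lower = h[1], hdi_upper = h[2], stringsAsFactors = FALSE)
  }
  hped <- posterior_draws(posterior, "HPed")
  hocc <- posterior_draws(posterior, "HOcc")
  premiums <- rbind(
    data.frame(program = "MOST", premium = 0, hdi_lower = 0, hdi_upper = 0,
               stringsAsFactors = FALSE),
    premium_row("PEDESTRIANS", hped),
    premium_row("OCCUPANTS", hocc))

  ids <- posterior$participants
  individual_premiums <- NULL
  if (length(ids)) {
    pm <- function(prefix) vapply(ids, function(id)
      mean(posterior_draws(posterior, paste0(prefix, "[", id, "]"))), numeric(1))
    individual_premiums <- data.frame(
      participant_id = ids,
      premium_pedestrians = -1000 * pm("Ped"),
      premium_occupants = -1000 * pm("Occ"),
      stringsAsFactors = FALSE)
    rownames(individual_premiums) <- NULL
  }

  htau <- posterior_draws(posterior, "Htau")
  ht2 <- posterior_draws(posterior, "Ht2")
  neg_mass <- mean(stats::pnorm(0, htau, 1 / sqrt(ht2)))
  structure(list(premiums = premiums,
                 individual_premiums = individual_premiums,
                 tau_negative_mass = neg_mass,
                 tau_hierarchy_flag = neg_mass > 0.01),
            class = "dce_wtp")
}

#' @export
print.dce_wtp <- function(x, ...) {
  cat("Willingness-to-pay premiums (GBP; positive = disfavoured vs MOST)\n")
  print(x$premiums, row.names = FALSE, digits = 4)
  cat(sprintf("P(individual sensitivity < 0 | hierarchy): %.3f%s\n",
              x$tau_negative_mass,
              if (x$tau_hierarchy_flag) "  [FLAG: > 1% mass below 0]" else ""))
  invisible(x)
}

#' Posterior predictive check of per-scenario choice shares
#'
#' For each scenario, averages the probit choice probability
#' `pnorm(tau_i * delta_u_i)` over individuals and a thinned set of
#' posterior draws, and compares it with the empirical share of A-choices.
#' The hit rate is the fraction of records whose predicted majority side
#' (predicted probability above one half) matches the observed choice.
#'
#' @param posterior A `dce_posterior` with individual-level draws.
#' @param records The choice records the model was fitted to.
#' @param scenarios Scenario table.
#' @param max_draws Number of thinned posterior draws used (default 200).
#' @return List with `per_scenario` (data frame: scenario_id,
#'   observed_share, predicted_share, n) and `hit_rate`.
#' @export
posterior_predictive_check <- function(posterior, records, scenarios,
                                       max_draws = 200) {
  prep <- prepare_choice_data(records, scenarios)
  ids <- prep$participants
  stopifnot(identical(ids, posterior$participants))
  n <- length(ids)
  S <- length(prep$dP)
  d <- dim(posterior$draws)
  total <- d[1] * d[3]
  use <- unique(round(seq(1, total, length.out = min(max_draws, total))))

  pool <- function(prefix) {
    a <- posterior$draws[, paste0(prefix, "[", ids, "]"), , drop = FALSE]
    matrix(aperm(a, c(1, 3, 2)), ncol = n)  # rows pool (iteration, chain)
  }
  ped_d <- pool("Ped")
  occ_d <- pool("Occ")
  tau_d <- pool("Tau")

  dPm <- matrix(prep$dP, n, S, byrow = TRUE)
  P <- matrix(0, n, S)
  for (r in use) {
    U <- dPm + outer(ped_d[r, ], prep$aPed) + outer(occ_d[r, ], prep$aOcc)
    P <- P + stats::pnorm(tau_d[r, ] * U)
  }
  P <- P / length(use)

  seen <- prep$seen
  obs_a <- prep$sgn == 1
  per_scenario <- data.frame(
    scenario_id = scenarios$scenario_id,
    observed_share = colSums(obs_a & seen) / pmax(colSums(seen), 1),
    predicted_share = colSums(P * seen) / pmax(colSums(seen), 1),
    n = colSums(seen))
  hit <- (P > 0.5) == obs_a
  list(per_scenario = per_scenario,
       hit_rate = sum(hit[seen]) / sum(seen))
}
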