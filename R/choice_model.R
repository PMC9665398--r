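# Hierarchical probit choice model: utilities, likelihood, priors.
#
# Utilities are on the GBP-thousands scale. The reference program MOST has
# utility 0; PEDESTRIANS and OCCUPANTS carry population-level utilities whose
# negation (times 1000) is the price premium a buyer implicitly pays to avoid
# them (see wtp_report).

program_utility <- function(program, ped, occ) {
  ifelse(program == "PEDESTRIANS", ped,
         ifelse(program == "OCCUPANTS", occ, 0))
}

#' Utility difference between two car offers
#'
#' The signed utility difference favouring car A:
#' `(price_b - price_a) + (prog_a - prog_b)`, where a cheaper car A or a
#' better-liked program on car A both push the value positive. Program
#' utilities are `0` for `MOST` (the reference), `ped` for `PEDESTRIANS` and
#' `occ` for `OCCUPANTS`, all in GBP thousands. Antisymmetric under swapping
#' the two cars.
#'
#' @param car_a,car_b Data frames (or one-row lists) with `program`/`model`
#'   and `price` columns; vectorised over rows.
#' @param ped,occ Program utilities in GBP thousands.
#' @return Numeric utility difference(s) in GBP thousands.
#' @export
utility_difference <- function(car_a, car_b, ped, occ) {
  prog_a <- if (!is.null(car_a$program)) car_a$program else car_a$model
  prog_b <- if (!is.null(car_b$program)) car_b$program else car_b$model
  (car_b$price - car_a$price) +
    program_utility(prog_a, ped, occ) - program_utility(prog_b, ped, occ)
}

#' Probit choice probability
#'
#' Maps a scaled utility difference to the probability of choosing the first
#' car through the inverse probit (standard normal CDF) link:
#' `p = pnorm(tau * delta_u)`. `tau` measures how sharply choices switch as
#' the utility difference moves through zero; lower values widen the
#' "unsure" region.
#'
#' @param delta_u Utility difference(s), GBP thousands.
#' @param tau Sensitivity (per GBP thousand).
#' @return Probability of choosing car A.
#' @export
choice_probability <- function(delta_u, tau) {
  stats::pnorm(tau * delta_u)
}

#' Bernoulli log-likelihood of observed choices
#'
#' Each record is a single Bernoulli trial with success probability
#' `pnorm(tau_i * delta_u)` for choosing car A, where the participant's own
#' `(ped_i, occ_i, tau_i)` enter the utility and the link. Returns `0` for an
#' empty record set and `-Inf` (not an error) when an observed choice has
#' probability zero.
#'
#' @param records Data frame with `participant_id`, `scenario_id`, `choice`.
#' @param scenarios Scenario table as from [generate_choice_design()].
#' @param individuals Data frame with `participant_id`, `ped`, `occ`, `tau`.
#' @return Total log-likelihood (scalar).
#' @export
log_likelihood <- function(records, scenarios, individuals) {
  if (is.null(records) || nrow(records) == 0L) return(0)
  ms <- match(records$scenario_id, scenarios$scenario_id)
  mi <- match(records$participant_id, individuals$participant_id)
  if (anyNA(ms)) stop("record refers to unknown scenario_id", call. = FALSE)
  if (anyNA(mi)) stop("record refers to unknown participant_id", call. = FALSE)
  du <- utility_difference(
    data.frame(program = scenarios$model_a[ms], price = scenarios$price_a[ms]),
    data.frame(program = scenarios$model_b[ms], price = scenarios$price_b[ms]),
    individuals$ped[mi], individuals$occ[mi])
  sgn <- ifelse(records$choice == "A", 1, -1)
  # log of the literal Bernoulli probability: an observed choice whose
  # probability underflows to 0 yields -Inf rather than an error
  sum(log(stats::pnorm(sgn * individuals$tau[mi] * du)))
}

#' Prior and hierarchy settings
#'
#' Hyperpriors: the population mean utilities `HPed`, `HOcc` are normal with
#' mean 0 and precision `mu_prec` (default 1/10, i.e. variance 10 on the
#' GBP-thousands scale — weakly informative); the population sensitivity
#' mean `Htau` and the two population precisions `Ht` (shared by the Ped and
#' Occ hierarchies) and `Ht2` (the tau hierarchy) are gamma with shape
#' `gamma_shape` and rate `gamma_rate` (default 1/2, 1/2).
#'
#' @param mu_prec Prior precision of the population mean utilities.
#' @param gamma_shape,gamma_rate Gamma hyperprior shape and rate.
#' @return A list of class `dce_prior`.
#' @export
prior_spec <- function(mu_prec = 0.1, gamma_shape = 0.5, gamma_rate = 0.5) {
  stopifnot(mu_prec > 0, gamma_shape > 0, gamma_rate > 0)
  structure(list(mu_prec = mu_prec, gamma_shape = gamma_shape,
                 gamma_rate = gamma_rate), class = "dce_prior")
}

#' Joint log-prior of hyperparameters and individual parameters
#'
#' Sums the hyperprior log-densities (normal for `HPed`, `HOcc`; gamma for
#' `Htau`, `Ht`, `Ht2`) and, for each individual, the hierarchical normal
#' terms `ped_i ~ N(HPed, 1/Ht)`, `occ_i ~ N(HOcc, 1/Ht)`,
#' `tau_i ~ N(Htau, 1/Ht2)`. Returns `-Inf` when any gamma-distributed
#' quantity is non-positive.
#'
#' @param hyper Named list/vector with `HPed`, `HOcc`, `Htau`, `Ht`, `Ht2`.
#' @param individuals Data frame with `ped`, `occ`, `tau` columns, or `NULL`.
#' @param prior A [prior_spec()].
#' @return Log-prior density (scalar; may be `-Inf`).
#' @export
log_prior <- function(hyper, individuals = NULL, prior = prior_spec()) {
  h <- as.list(hyper)
  if (h$Htau <= 0 || h$Ht <= 0 || h$Ht2 <= 0) return(-Inf)
  sd_mu <- 1 / sqrt(prior$mu_prec)
  lp <- stats::dnorm(h$HPed, 0, sd_mu, log = TRUE) +
    stats::dnorm(h$HOcc, 0, sd_mu, log = TRUE) +
    stats::dgamma(h$Htau, prior$gamma_shape, rate = prior$gamma_rate, log = TRUE) +
    stats::dgamma(h$Ht, prior$gamma_shape, rate = prior$gamma_rate, log = TRUE) +
    stats::dgamma(h$Ht2, prior$gamma_shape, rate = prior$gamma_rate, log = TRUE)
  if (!is.null(individuals) && nrow(individuals) > 0) {
    sd_u <- 1 / sqrt(h$Ht)
    sd_t <- 1 / sqrt(h$Ht2)
    lp <- lp +
      sum(stats::dnorm(individuals$ped, h$HPed, sd_u, log = TRUE)) +
      sum(stats::dnorm(individuals$occ, h$HOcc, sd_u, log = TRUE)) +
      sum(stats::dnorm(individuals$tau, h$Htau, sd_t, log = TRUE))
  }
  lp
}
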