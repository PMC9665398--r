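# Metropolis-within-Gibbs sampler for the hierarchical probit choice model.
#
# Parameter blocks per sweep:
#   1-3. ped, occ, tau individual vectors: Gaussian random-walk Metropolis,
#        proposed jointly across individuals and accepted per individual
#        (valid because the likelihood and hierarchy factorise over i).
#   4-5. HPed, HOcc: exact normal-normal Gibbs draws.
#   6.   Htau: scalar random-walk Metropolis against gamma prior x normal
#        hierarchy (the gamma support constraint breaks conjugacy).
#   7-8. Ht, Ht2: exact normal-gamma Gibbs draws.
# Proposal scales adapt during burn-in only; the retained chain is a valid
# fixed-kernel chain.

#' MCMC configuration
#'
#' @param n_chains Number of chains (>= 2, so R-hat is defined).
#' @param n_samples Total iterations per chain, including burn-in.
#' @param n_burnin Burn-in iterations discarded per chain
#'   (`0 <= n_burnin < n_samples`); proposal adaptation happens only here.
#' @param seed Integer master seed; chain k uses `seed + k - 1`.
#' @param rhat_threshold Convergence flag threshold for reporting.
#' @param hdi_mass Posterior mass of reported highest-density intervals.
#' @return A list of class `dce_model_config`.
#' @export
model_config <- function(n_chains = 3, n_samples = 5000, n_burnin = 1000,
                         seed = 1, rhat_threshold = 1.1, hdi_mass = 0.95) {
  if (n_chains < 2) stop("`n_chains` must be >= 2", call. = FALSE)
  if (!(n_samples > n_burnin && n_burnin >= 0))
    stop("need n_samples > n_burnin >= 0", call. = FALSE)
  if (!(hdi_mass > 0 && hdi_mass < 1))
    stop("`hdi_mass` must lie strictly between 0 and 1", call. = FALSE)
  structure(list(n_chains = as.integer(n_chains),
                 n_samples = as.integer(n_samples),
                 n_burnin = as.integer(n_burnin),
                 seed = as.integer(seed),
                 rhat_threshold = rhat_threshold,
                 hdi_mass = hdi_mass), class = "dce_model_config")
}

# Reshape records into per-individual matrices used by the chain kernel.
prepare_choice_data <- function(records, scenarios) {
  participants <- sort(unique(records$participant_id))
  n <- length(participants)
  S <- nrow(scenarios)
  ms <- match(records$scenario_id, scenarios$scenario_id)
  if (anyNA(ms)) stop("record refers to unknown scenario_id", call. = FALSE)
  mi <- match(records$participant_id, participants)
  sgn <- matrix(0, n, S)
  sgn[cbind(mi, ms)] <- ifelse(records$choice == "A", 1, -1)
  list(participants = participants,
       sgn = sgn,
       seen = sgn != 0,
       dP = scenarios$price_b - scenarios$price_a,
       aPed = (scenarios$model_a == "PEDESTRIANS") -
         (scenarios$model_b == "PEDESTRIANS"),
       aOcc = (scenarios$model_a == "OCCUPANTS") -
         (scenarios$model_b == "OCCUPANTS"))
}

# One chain; returns an iterations x parameters matrix (post burn-in) plus
# acceptance rates. All randomness comes from the seed set by the caller.
run_chain <- function(prep, config, prior) {
  n <- length(prep$participants)
  S <- length(prep$dP)
  n_keep <- config$n_samples - config$n_burnin
  sd_mu <- 1 / sqrt(prior$mu_prec)
  gs <- prior$gamma_shape
  gr <- prior$gamma_rate
  prior_gamma_mean <- gs / gr

  if (n == 0L) {
    # no data: every conditional collapses to the prior, so draw it directly
    draws <- cbind(HPed = stats::rnorm(n_keep, 0, sd_mu),
                   HOcc = stats::rnorm(n_keep, 0, sd_mu),
                   Htau = stats::rgamma(n_keep, gs, rate = gr),
                   Ht = stats::rgamma(n_keep, gs, rate = gr),
                   Ht2 = stats::rgamma(n_keep, gs, rate = gr))
    return(list(draws = draws, acceptance = c(ped = NA, occ = NA, tau = NA,
                                              htau = NA)))
  }

  dPm <- matrix(prep$dP, n, S, byrow = TRUE)
  sgn <- prep$sgn
  aPed <- prep$aPed
  aOcc <- prep$aOcc

  # initial state: hypers at prior means, individuals at population means,
  # jittered per chain
  HPed <- stats::rnorm(1, 0, 0.25)
  HOcc <- stats::rnorm(1, 0, 0.25)
  Htau <- abs(prior_gamma_mean + stats::rnorm(1, 0, 0.1))
  Ht <- abs(prior_gamma_mean + stats::rnorm(1, 0, 0.1))
  Ht2 <- abs(prior_gamma_mean + stats::rnorm(1, 0, 0.1))
  ped <- HPed + stats::rnorm(n, 0, 0.5)
  occ <- HOcc + stats::rnorm(n, 0, 0.5)
  tau <- pmax(Htau + stats::rnorm(n, 0, 0.1), 1e-3)

  row_ll <- function(U, tau) {
    rowSums(stats::pnorm(sgn * (tau * U), log.p = TRUE) * prep$seen)
  }
  U <- dPm + outer(ped, aPed) + outer(occ, aOcc)
  ll <- row_ll(U, tau)
  if (any(!is.finite(ll)))
    stop("non-finite log-likelihood at initialisation", call. = FALSE)

  sd_ped <- 1; sd_occ <- 1; sd_tau <- 0.05; sd_htau <- 0.05
  acc <- c(ped = 0, occ = 0, tau = 0, htau = 0)
  acc_win <- acc
  n_prop <- 0L
  adapt_every <- 25L
  kept <- matrix(NA_real_, n_keep, 5L + 3L * n)
  colnames(kept) <- c("HPed", "HOcc", "Htau", "Ht", "Ht2",
                      paste0("Ped[", prep$participants, "]"),
                      paste0("Occ[", prep$participants, "]"),
                      paste0("Tau[", prep$participants, "]"))

  for (iter in seq_len(config$n_samples)) {
    sd_pop_u <- 1 / sqrt(Ht)
    sd_pop_t <- 1 / sqrt(Ht2)

    # ped block
    prop <- ped + sd_ped * stats::rnorm(n)
    Up <- U + outer(prop - ped, aPed)
    llp <- row_ll(Up, tau)
    logr <- (llp - ll) +
      stats::dnorm(prop, HPed, sd_pop_u, log = TRUE) -
      stats::dnorm(ped, HPed, sd_pop_u, log = TRUE)
    take <- log(stats::runif(n)) < logr
    if (any(take)) {
      ped[take] <- prop[take]
      U[take, ] <- Up[take, , drop = FALSE]
      ll[take] <- llp[take]
    }
    acc_win["ped"] <- acc_win["ped"] + mean(take)

    # occ block
    prop <- occ + sd_occ * stats::rnorm(n)
    Up <- U + outer(prop - occ, aOcc)
    llp <- row_ll(Up, tau)
    logr <- (llp - ll) +
      stats::dnorm(prop, HOcc, sd_pop_u, log = TRUE) -
      stats::dnorm(occ, HOcc, sd_pop_u, log = TRUE)
    take <- log(stats::runif(n)) < logr
    if (any(take)) {
      occ[take] <- prop[take]
      U[take, ] <- Up[take, , drop = FALSE]
      ll[take] <- llp[take]
    }
    acc_win["occ"] <- acc_win["occ"] + mean(take)

    # tau block (hierarchy untruncated: negative proposals are legal and
    # priced by the likelihood)
    prop <- tau + sd_tau * stats::rnorm(n)
    llp <- row_ll(U, prop)
    logr <- (llp - ll) +
      stats::dnorm(prop, Htau, sd_pop_t, log = TRUE) -
      stats::dnorm(tau, Htau, sd_pop_t, log = TRUE)
    take <- log(stats::runif(n)) < logr
    if (any(take)) {
      tau[take] <- prop[take]
      ll[take] <- llp[take]
    }
    acc_win["tau"] <- acc_win["tau"] + mean(take)

    # HPed, HOcc: conjugate normal draws
    post_prec <- prior$mu_prec + n * Ht
    HPed <- stats::rnorm(1, Ht * sum(ped) / post_prec, 1 / sqrt(post_prec))
    HOcc <- stats::rnorm(1, Ht * sum(occ) / post_prec, 1 / sqrt(post_prec))

    # Htau: random-walk Metropolis on the gamma-prior x normal-hierarchy
    # conditional
    hprop <- Htau + sd_htau * stats::rnorm(1)
    if (hprop > 0) {
      logr <- stats::dgamma(hprop, gs, rate = gr, log = TRUE) -
        stats::dgamma(Htau, gs, rate = gr, log = TRUE) +
        sum(stats::dnorm(tau, hprop, sd_pop_t, log = TRUE)) -
        sum(stats::dnorm(tau, Htau, sd_pop_t, log = TRUE))
      if (log(stats::runif(1)) < logr) {
        Htau <- hprop
        acc_win["htau"] <- acc_win["htau"] + 1
      }
    }

    # Ht, Ht2: conjugate gamma draws
    Ht <- stats::rgamma(1, gs + n,
                        rate = gr + 0.5 * (sum((ped - HPed)^2) +
                                             sum((occ - HOcc)^2)))
    Ht2 <- stats::rgamma(1, gs + n / 2,
                         rate = gr + 0.5 * sum((tau - Htau)^2))

    n_prop <- n_prop + 1L
    if (iter <= config$n_burnin && n_prop == adapt_every) {
      rate <- acc_win / adapt_every
      tune <- function(sd, r) min(max(sd * exp(0.8 * (r - 0.4)), 1e-4), 50)
      sd_ped <- tune(sd_ped, rate["ped"])
      sd_occ <- tune(sd_occ, rate["occ"])
      sd_tau <- tune(sd_tau, rate["tau"])
      sd_htau <- tune(sd_htau, rate["htau"])
      acc <- acc + acc_win
      acc_win[] <- 0
      n_prop <- 0L
    }
    if (iter > config$n_burnin)
      kept[iter - config$n_burnin, ] <- c(HPed, HOcc, Htau, Ht, Ht2, ped, occ, tau)
  }
  list(draws = kept,
       acceptance = (acc + acc_win) / config$n_samples)
}

#' Sample the posterior of the hierarchical probit choice model
#'
#' Runs `n_chains` independent Metropolis-within-Gibbs chains targeting the
#' posterior of the five population-level parameters (`HPed`, `HOcc`,
#' `Htau`, `Ht`, `Ht2`) and all individual-level `(Ped_i, Occ_i, Tau_i)`.
#' With an empty record set the target collapses to the prior, which is then
#' sampled directly (a prior-predictive run). Identical data, configuration
#' and seed give identical draws.
#'
#' @param records Choice records (`participant_id`, `scenario_id`, `choice`);
#'   may have zero rows for a prior-only run.
#' @param scenarios Scenario table as from [generate_choice_design()].
#' @param config A [model_config()].
#' @param prior A [prior_spec()].
#' @return An object of class `dce_posterior`: list with `draws` (array
#'   iterations x parameters x chains), `rhat` (named vector, classic
#'   Gelman-Rubin), `acceptance`, `participants`, `config`, `prior`.
#' @export
sample_posterior <- function(records, scenarios, config = model_config(),
                             prior = prior_spec()) {
  stopifnot(inherits(config, "dce_model_config"))
  if (is.null(records)) records <- data.frame(participant_id = character(),
                                              scenario_id = integer(),
                                              choice = character())
  prep <- if (nrow(records) > 0) prepare_choice_data(records, scenarios) else
    list(participants = character(), dP = scenarios$price_b - scenarios$price_a)
  chains <- vector("list", config$n_chains)
  for (k in seq_len(config$n_chains)) {
    set.seed(config$seed + k - 1L)
    chains[[k]] <- run_chain(prep, config, prior)
  }
  n_keep <- config$n_samples - config$n_burnin
  pnames <- colnames(chains[[1]]$draws)
  draws <- array(NA_real_, dim = c(n_keep, length(pnames), config$n_chains),
                 dimnames = list(NULL, pnames,
                                 paste0("chain", seq_len(config$n_chains))))
  for (k in seq_len(config$n_chains)) draws[, , k] <- chains[[k]]$draws
  rh <- vapply(seq_along(pnames),
               function(j) rhat(draws[, j, , drop = TRUE]), numeric(1))
  names(rh) <- pnames
  structure(list(draws = draws, rhat = rh,
                 acceptance = lapply(chains, `[[`, "acceptance"),
                 participants = prep$participants,
                 config = config, prior = prior),
            class = "dce_posterior")
}

#' @export
print.dce_posterior <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("Hierarchical probit posterior: %d chains x %d iterations, %d parameters\n",
              d[3], d[1], d[2]))
  hyp <- c("HPed", "HOcc", "Htau", "Ht", "Ht2")
  s <- summarise_posterior(x, hyp)
  print(s, row.names = FALSE, digits = 4)
  worst <- max(x$rhat, na.rm = TRUE)
  cat(sprintf("max R-hat (all %d parameters): %.4f\n", d[2], worst))
  invisible(x)
}

#' Posterior summary table
#'
#' Means, highest-density intervals and R-hat for the requested parameters.
#'
#' @param posterior A `dce_posterior`.
#' @param pars Parameter names; defaults to the five population parameters.
#' @return Data frame with `parameter`, `mean`, `hdi_lower`, `hdi_upper`,
#'   `rhat`.
#' @export
summarise_posterior <- function(posterior,
                                pars = c("HPed", "HOcc", "Htau", "Ht", "Ht2")) {
  mass <- posterior$config$hdi_mass
  rows <- lapply(pars, function(p) {
    x <- as.vector(posterior$draws[, p, ])
    h <- hdi(x, mass)
    data.frame(parameter = p, mean = mean(x), hdi_lower = h[1],
               hdi_upper = h[2], rhat = posterior$rhat[[p]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Extract pooled draws of one parameter
#'
#' @param posterior A `dce_posterior`.
#' @param par Parameter name (e.g. `"HPed"` or `"Ped[P0001]"`).
#' @return Numeric vector pooling all chains.
#' @export
posterior_draws <- function(posterior, par) {
  as.vector(posterior$draws[, par, ])
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (whole-chain) R-hat: with `m` chains of length `n`, the pooled
#' variance estimate `(n-1)/n * W + B/n` is compared to the mean
#' within-chain variance `W`; values near 1 indicate the chains have mixed.
#' Degenerate inputs with zero total variance return 1 by convention.
#'
#' @param chains Matrix of draws, iterations x chains (>= 2 chains, >= 2
#'   iterations).
#' @return R-hat (scalar, >= 1 up to floating-point error).
#' @export
rhat <- function(chains) {
  chains <- as.matrix(chains)
  n <- nrow(chains)
  m <- ncol(chains)
  if (m < 2 || n < 2) stop("need >= 2 chains with >= 2 iterations", call. = FALSE)
  means <- colMeans(chains)
  W <- mean(apply(chains, 2, stats::var))
  B <- n * stats::var(means)
  if (W <= 0) {
    if (B <= 1e-12) return(1)
    return(Inf)
  }
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Highest-density interval
#'
#' Shortest contiguous interval containing `ceiling(mass * n)` of the sorted
#' samples (ties broken toward the lowest window).
#'
#' @param samples Numeric vector (length >= 2).
#' @param mass Probability mass in (0, 1).
#' @return Numeric vector `c(lower, upper)`.
#' @export
hdi <- function(samples, mass = 0.95) {
  if (length(samples) < 2) stop("need >= 2 samples", call. = FALSE)
  if (!(mass > 0 && mass < 1)) stop("`mass` must lie in (0, 1)", call. = FALSE)
  x <- sort(samples)
  n <- length(x)
  k <- ceiling(mass * n)
  if (k >= n) return(c(x[1], x[n]))
  width <- x[seq(k, n)] - x[seq(1, n - k + 1)]
  i <- which.min(width)
  c(x[i], x[i + k - 1])
}
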