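# Independent oracle: posterior mean of HPed by dense grid integration over
# the full 11-dimensional parameter space of a tiny instance, factorised as
# (individual-parameter tensors) x (hyperparameter weights). Written from the
# model's densities directly; shares no code with the MCMC sampler.
#
# gamma(1/2, 1/2) is the chi-square(1) law, so gamma-distributed quantities
# are substituted as X = s^2 with s half-normal, which removes the density
# singularity at 0 and lets a uniform s-grid integrate accurately.

grid_posterior_mean_hped <- function(rec, scen,
                                     n_theta = 61, n_tau = 43,
                                     n_mu = 25, n_s = 14) {
  dP <- scen$price_b - scen$price_a
  aPed <- (scen$model_a == "PEDESTRIANS") - (scen$model_b == "PEDESTRIANS")
  aOcc <- (scen$model_a == "OCCUPANTS") - (scen$model_b == "OCCUPANTS")

  pg <- seq(-25, 25, length.out = n_theta)
  og <- seq(-25, 25, length.out = n_theta)
  tg <- seq(-3, 4, length.out = n_tau)
  sg <- seq(0.035, 3.0, length.out = n_s)
  ds <- sg[2] - sg[1]
  gam_x <- sg^2
  gam_w <- 2 * stats::dnorm(sg) * ds
  mug <- seq(-10, 10, length.out = n_mu)
  dmu <- mug[2] - mug[1]

  ids <- unique(rec$participant_id)
  ped_flat <- pg[rep(seq_len(n_theta), n_theta)]
  occ_flat <- og[rep(seq_len(n_theta), each = n_theta)]
  Lmat <- lapply(ids, function(id) {
    r <- rec[rec$participant_id == id, ]
    s <- match(r$scenario_id, scen$scenario_id)
    sgn <- ifelse(r$choice == "A", 1, -1)
    L <- matrix(0, n_theta * n_theta, n_tau)
    for (ti in seq_len(n_tau)) {
      ll <- 0
      for (k in seq_along(s)) {
        du <- dP[s[k]] + aPed[s[k]] * ped_flat + aOcc[s[k]] * occ_flat
        ll <- ll + stats::pnorm(sgn[k] * tg[ti] * du, log.p = TRUE)
      }
      L[, ti] <- exp(ll)
    }
    L
  })

  num <- 0
  den <- 0
  pr_mu <- stats::dnorm(mug, 0, sqrt(10)) * dmu
  dp_w <- pg[2] - pg[1]
  do_w <- og[2] - og[1]
  dt_w <- tg[2] - tg[1]
  for (iHt in seq_len(n_s)) {
    sd_u <- 1 / sqrt(gam_x[iHt])
    WP <- outer(pg, mug, function(x, m) stats::dnorm(x, m, sd_u)) * dp_w
    WO <- outer(og, mug, function(x, m) stats::dnorm(x, m, sd_u)) * do_w
    for (iHt2 in seq_len(n_s)) {
      sd_t <- 1 / sqrt(gam_x[iHt2])
      for (iHtau in seq_len(n_s)) {
        wT <- stats::dnorm(tg, gam_x[iHtau], sd_t) * dt_w
        M <- lapply(Lmat, function(L) {
          T1 <- matrix(L %*% wT, n_theta, n_theta)
          crossprod(WP, T1) %*% WO
        })
        joint <- Reduce(`*`, M)
        pw <- outer(pr_mu, pr_mu) * joint *
          (gam_w[iHt] * gam_w[iHt2] * gam_w[iHtau])
        den <- den + sum(pw)
        num <- num + sum(mug * rowSums(pw))
      }
    }
  }
  num / den
}
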