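## shared fixtures: the trial-application parameter point, a tiny trial,
## and reduced MCMC settings for fast fits

scenario1_params <- function(n_arms = 5) {
  model_params(k = 2, phi0 = -2.5, phi1 = -30, phi2 = 5,
               sigma_s = 6, sigma_e = 5, n_arms = n_arms)
}

scenario3_params <- function(n_arms = 5) {
  model_params(k = 2, phi0 = -2.5, phi1 = -30, phi2 = 5,
               delta0 = 0.5, delta1 = 2, delta2 = 0,
               sigma_s = 6, sigma_s_star = sqrt(13),
               sigma_e = 5, sigma_e_star = sqrt(11), n_arms = 5)
}

## 2 arms x n subjects x 4 visits, small enough for second-scale fits
tiny_trial <- function(n = 6, seed = 1, missing_frac = 0) {
  spec <- scenario_spec(phi = c(-2.5, -30, 5), delta = c(0.5, 2, 0),
                        sigma_s2 = 9, sigma_s_star2 = 4,
                        sigma_e2 = 4, sigma_e_star2 = 2,
                        doses = c(0, 15), n_per_arm = n,
                        name = "tiny")
  sched <- visit_schedule(days = c(0, 14, 28, 42, 56),
                          decentralized = c(FALSE, TRUE, TRUE, FALSE))
  dat <- simulate_outcomes(spec, sched, seed = seed)
  if (missing_frac > 0) {
    set.seed(seed + 1)
    dat$y[sample(nrow(dat), round(missing_frac * nrow(dat)))] <- NA
  }
  list(data = dat, spec = spec, schedule = sched)
}

fast_mcmc <- function(seed = 1)
  mcmc_config(n_burnin = 400, n_iter = 800, thin = 2, seed = seed,
              n_adapt = 200)

fit_quietly <- function(...) suppressWarnings(fit_itp(...))

## minimal posterior object for estimand computations: point mass or
## supplied draws at given Emax / rate values
fake_fit <- function(phi0, phi1, phi2, k, doses = c(0, 1, 5, 10, 15),
                     n_draws = length(phi0)) {
  A <- length(doses)
  kd <- matrix(rep(k, length.out = n_draws * A), nrow = n_draws)
  colnames(kd) <- sprintf("k[%d]", seq_len(A))
  draws <- cbind(phi0 = rep_len(phi0, n_draws), phi1 = rep_len(phi1, n_draws),
                 phi2 = rep_len(phi2, n_draws), kd)
  structure(list(draws = draws,
                 arms = data.frame(arm = seq_len(A) - 1L, dose = doses)),
            class = "itp_fit")
}
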