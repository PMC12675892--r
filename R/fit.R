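#' MCMC settings
#'
#' Defaults match the trial-application analysis settings: 5000 burn-in iterations, 10000
#' sampling iterations with a thinning interval of 2, one chain. Reduced
#' settings (e.g. 1000 burn-in, 2000 iterations) are appropriate for
#' simulation studies and tests.
#'
#' @param n_burnin burn-in iterations.
#' @param n_iter sampling iterations (retained draws = `n_iter / thin`
#'   per chain).
#' @param thin thinning interval (>= 1).
#' @param n_chains number of chains (seeded `seed`, `seed + 1`, ...).
#' @param seed integer RNG seed; fits are bit-reproducible given the
#'   seed.
#' @param n_adapt sampler adaptation iterations before burn-in.
#' @export
mcmc_config <- function(n_burnin = 5000, n_iter = 10000, thin = 2,
                        n_chains = 1, seed = 1, n_adapt = 500) {
  vals <- c(n_burnin, n_iter, thin, n_chains, seed, n_adapt)
  if (any(vals != round(vals)) || any(c(n_burnin, n_iter, n_chains, n_adapt) < 1) ||
      thin < 1)
    stop("MCMC settings must be positive integers (thin >= 1)")
  structure(list(n_burnin = as.integer(n_burnin), n_iter = as.integer(n_iter),
                 thin = as.integer(thin), n_chains = as.integer(n_chains),
                 seed = as.integer(seed), n_adapt = as.integer(n_adapt)),
            class = "mcmc_config")
}

.fit_monitors <- function(priors, variant) {
  if (variant == "standard") {
    base <- c("k", "phi0", "phi1", "phi2", "sigma_s", "sigma_e")
    if (priors$hierarchy) base <- c(base, "mu_k", "sigma_k")
    return(base)
  }
  base <- c("k", "z", "phi0", "phi1", "phi2", "delta",
            "sigma_s", "sigma_sstar", "sigma_e", "sigma_estar")
  if (priors$hierarchy) base <- c(base, "mu_k", "sigma_k")
  base <- switch(priors$selection,
    spike_slab = c(base, "wk", "wh"),
    always_on = c(base, "wk", "wh"),
    horseshoe = c(base, "tau_hs_z", "tau_hs_d"))
  base
}

#' Fit the DCT-ITP model or a comparator variant
#'
#' Runs MCMC for the Bayesian DCT-ITP model (`variant = "dct"`) or one
#' of the three comparator analyses: `"o"` fits the standard ITP model
#' to the onsite records only, `"m"` fits it to all records while
#' ignoring the decentralization indicator (naive pooling), and `"t"`
#' fits it to an all-onsite (traditional) trial. Missing outcomes are
#' treated as unknowns and sampled inside the chain (Bayesian data
#' augmentation): at each iteration every missing outcome is drawn from
#' its conditional predictive distribution given the current parameters
#' and the subject's random effects, and the parameter update then
#' conditions on the completed data.
#'
#' @param data a [trial_data()].
#' @param priors a [prior_config()].
#' @param mcmc an [mcmc_config()].
#' @param variant `"dct"`, `"o"`, `"m"`, or `"t"`.
#' @param quiet suppress JAGS progress output.
#' @return an object of class `itp_fit` with elements `draws` (matrix of
#'   retained draws, one column per scalar parameter), `imputed` (draws
#'   of the missing outcomes) with `imputed_map` locating them,
#'   `inclusion` (posterior inclusion probabilities of the shared rate
#'   shift and of delta0..delta2; `NA` under the horseshoe prior),
#'   `geweke` (two-sided p-values), `variant`, `arms`, and the configs.
#' @export
fit_itp <- function(data, priors = default_prior_config(),
                    mcmc = mcmc_config(), variant = c("dct", "o", "m", "t"),
                    quiet = TRUE) {
  variant <- match.arg(variant)
  data <- as_trial_data(data)
  stopifnot(inherits(priors, "prior_config"), inherits(mcmc, "mcmc_config"))

  if (variant == "o") {
    data <- data[data$decentralized == 0L, , drop = FALSE]
    if (nrow(data) == 0L) stop("no onsite records for the onsite-only fit")
  } else if (variant == "m") {
    data$decentralized <- 0L
  } else if (variant == "t") {
    if (any(data$decentralized == 1L))
      stop("the traditional-trial variant requires all-onsite data")
  }

  all_missing <- tapply(is.na(data$y), data$subject_id, all)
  if (any(all_missing)) {
    drop_ids <- names(all_missing)[all_missing]
    warning("dropping ", length(drop_ids),
            " subject(s) with no observed outcomes")
    data <- data[!data$subject_id %in% drop_ids, , drop = FALSE]
  }

  subj_ids <- unique(data$subject_id)
  subj <- match(data$subject_id, subj_ids)
  A <- max(data$arm) + 1L
  model_variant <- if (variant == "dct") "dct" else "standard"
  code <- dct_itp_jags_code(priors, model_variant)

  jd <- list(N = nrow(data), J = length(subj_ids), A = A,
             y = data$y, subj = subj, arm = data$arm + 1L,
             dose = data$dose_mg, t = data$std_time, fu_zero = 0L)
  if (model_variant == "dct") jd$I <- data$decentralized

  inits <- lapply(seq_len(mcmc$n_chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = mcmc$seed + ch - 1L,
         phi0 = priors$mu_phi0, phi1 = priors$mu_phi1,
         phi2 = priors$mmax / 4)
  })

  run <- function() {
    jm <- rjags::jags.model(textConnection(code), data = jd, inits = inits,
                            n.chains = mcmc$n_chains, n.adapt = mcmc$n_adapt,
                            quiet = TRUE)
    stats::update(jm, mcmc$n_burnin, progress.bar = "none")
    monitors <- .fit_monitors(priors, model_variant)
    has_missing <- anyNA(data$y)
    if (has_missing) monitors <- c(monitors, "y")
    rjags::coda.samples(jm, monitors, n.iter = mcmc$n_iter, thin = mcmc$thin,
                        progress.bar = "none")
  }
  samples <- if (quiet) suppressWarnings(run()) else run()

  draws <- do.call(rbind, lapply(samples, as.matrix))
  ycols <- grep("^y\\[", colnames(draws))
  imputed_map <- data.frame(subject_id = character(), visit = integer())
  imputed <- matrix(numeric(), nrow = nrow(draws), ncol = 0)
  if (length(ycols)) {
    idx <- as.integer(sub("^y\\[(\\d+)\\]$", "\\1", colnames(draws)[ycols]))
    keep <- is.na(data$y[idx])
    imputed <- draws[, ycols[keep], drop = FALSE]
    imputed_map <- data.frame(subject_id = data$subject_id[idx[keep]],
                              visit = data$visit[idx[keep]])
    colnames(imputed) <- sprintf("y[%s,%d]", imputed_map$subject_id,
                                 imputed_map$visit)
    draws <- draws[, -ycols, drop = FALSE]
  }

  inclusion <- c(w_kappa = NA_real_, w0 = NA_real_, w1 = NA_real_,
                 w2 = NA_real_)
  if (model_variant == "dct" && priors$selection != "horseshoe") {
    inclusion <- c(w_kappa = mean(draws[, "wk"]),
                   w0 = mean(draws[, "wh[1]"]),
                   w1 = mean(draws[, "wh[2]"]),
                   w2 = mean(draws[, "wh[3]"]))
  }

  diag_cols <- setdiff(colnames(draws), c("wk", "wh[1]", "wh[2]", "wh[3]"))
  gw <- suppressWarnings(
    geweke_diagnostic(as.matrix(samples[[1]])[, diag_cols, drop = FALSE]))

  arms <- unique(data.frame(arm = data$arm, dose = data$dose_mg))
  arms <- arms[order(arms$arm), ]
  rownames(arms) <- NULL

  structure(list(draws = draws, imputed = imputed, imputed_map = imputed_map,
                 inclusion = inclusion, geweke = gw, variant = variant,
                 arms = arms, mcmc = mcmc, priors = priors,
                 n_subjects = length(subj_ids)),
            class = "itp_fit")
}

#' @export
print.itp_fit <- function(x, ...) {
  cat(sprintf("DCT-ITP fit (variant '%s'): %d draws x %d parameters, %d subjects\n",
              x$variant, nrow(x$draws), ncol(x$draws), x$n_subjects))
  for (p in c("phi0", "phi1", "phi2")) {
    cat(sprintf("  %s: mean %.3f [%.3f, %.3f]\n", p, mean(x$draws[, p]),
                stats::quantile(x$draws[, p], 0.025),
                stats::quantile(x$draws[, p], 0.975)))
  }
  if (!anyNA(x$inclusion))
    cat("  inclusion probabilities:",
        paste(sprintf("%s=%.2f", names(x$inclusion), x$inclusion),
              collapse = ", "), "\n")
  if (ncol(x$imputed))
    cat(sprintf("  %d missing outcomes imputed by data augmentation\n",
                ncol(x$imputed)))
  invisible(x)
}

#' Impute missing outcomes from one posterior draw
#'
#' Draws each missing outcome from its conditional predictive
#' distribution given a parameter draw and the subject random effects:
#' \deqn{Y = \mu(l,d,I) + \frac{\mu(l,d,I)}{\mu(L,d,I)}(s_j + I s^*_j) +
#'   e + I e^*,} with fresh within-subject noise `e ~ N(0, sigma_e^2)`
#' and `e* ~ N(0, sigma_e*^2)`. This is the imputation step of the data
#' augmentation scheme, exposed for direct use; [fit_itp()] performs it
#' internally at every MCMC iteration. Uses R's RNG (set a seed for
#' reproducibility).
#'
#' @param params a [model_params()] (one draw).
#' @param s,s_star named numeric vectors of subject random effects,
#'   indexed by `subject_id`.
#' @param data a [trial_data()]; rows with `NA` outcome are imputed.
#' @return a data frame with `subject_id`, `visit`, and the imputed `y`.
#' @export
impute_missing <- function(params, s, s_star, data) {
  data <- as_trial_data(data)
  stopifnot(inherits(params, "model_params"))
  rows <- data[is.na(data$y), , drop = FALSE]
  if (nrow(rows) == 0L)
    return(data.frame(subject_id = character(), visit = integer(),
                      y = numeric()))
  sid <- as.character(rows$subject_id)
  if (any(!sid %in% names(s)) || any(!sid %in% names(s_star)))
    stop("random effects missing for some subjects")
  I <- rows$decentralized
  a <- vapply(seq_len(nrow(rows)), function(i)
    time_effect(rows$std_time[i], rows$arm[i], I[i], params), numeric(1))
  mu <- a * dose_effect(rows$dose_mg, I, params)
  y <- mu + a * (s[sid] + I * s_star[sid]) +
    stats::rnorm(nrow(rows), 0, params$sigma_e) +
    I * stats::rnorm(nrow(rows), 0, params$sigma_e_star)
  data.frame(subject_id = rows$subject_id, visit = rows$visit,
             y = unname(y))
}

#' Geweke convergence diagnostic
#'
#' Compares the mean of the first 10% of a chain with the mean of the
#' last 50% via a z-score with spectral-density variance estimates, and
#' returns the two-sided p-value. Small p-values indicate that the chain
#' has not reached its stationary distribution.
#'
#' @param x a numeric vector (one chain) or a matrix / `mcmc` object
#'   (one column per parameter) of at least 20 iterations.
#' @return named vector of two-sided p-values; a constant chain yields
#'   p = 1 with a warning.
#' @export
geweke_diagnostic <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1,
                                   dimnames = list(NULL, "par"))
  x <- as.matrix(x)
  if (nrow(x) < 20L) stop("chain too short for the Geweke diagnostic (need >= 20)")
  vapply(colnames(x), function(nm) {
    v <- x[, nm]
    if (stats::var(v) == 0) {
      warning("constant chain for '", nm, "': degenerate variance, p = 1")
      return(1)
    }
    z <- tryCatch(
      coda::geweke.diag(coda::mcmc(v), frac1 = 0.1, frac2 = 0.5)$z,
      error = function(e) NA_real_)
    if (!is.finite(z)) return(NA_real_)
    2 * stats::pnorm(-abs(z))
  }, numeric(1))
}

#' Export a fit to disk
#'
#' Writes the retained draws (plus any imputed-outcome draws) as CSV and
#' a JSON summary with posterior means, 2.5%/97.5% quantiles, inclusion
#' probabilities, and Geweke p-values.
#'
#' @param fit an `itp_fit`.
#' @param dir output directory (created if needed).
#' @export
write_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "itp_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(fit$draws),
                   file.path(dir, "draws.csv"), row.names = FALSE)
  if (ncol(fit$imputed))
    utils::write.csv(as.data.frame(fit$imputed),
                     file.path(dir, "imputed.csv"), row.names = FALSE)
  sm <- list(
    variant = fit$variant,
    posterior_mean = as.list(colMeans(fit$draws)),
    q025 = as.list(apply(fit$draws, 2, stats::quantile, 0.025)),
    q975 = as.list(apply(fit$draws, 2, stats::quantile, 0.975)),
    inclusion = as.list(fit$inclusion),
    geweke_p = as.list(fit$geweke)
  )
  jsonlite::write_json(sm, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
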