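#' Prior configuration for the DCT-ITP model
#'
#' Collects every prior hyperparameter of the Bayesian DCT-ITP analysis.
#' The defaults reproduce the trial-application settings: a hierarchical
#' normal prior with half-Cauchy heterogeneity scale on the active-dose
#' rates k(1..D), an independent N(2, 2^2) prior on the placebo rate
#' k(0), shared spike-and-slab priors on the decentralized rate shifts
#' z(d) (one inclusion weight for all doses) and independent
#' spike-and-slab priors on the Emax shifts delta0..delta2, a functional
#' uniform prior on the ED50 phi2 restricted to `[0, mmax]`, and
#' half-Cauchy priors on all four residual SDs.
#'
#' @param k0_mean,k0_sd independent normal prior for the placebo rate
#'   k(0); defaults N(2, 2^2).
#' @param theta_kappa,tau_kappa,zeta_kappa hierarchy for k(1..D):
#'   `k(d) ~ N(mu_k, sigma_k^2)`, `mu_k ~ N(theta_kappa, tau_kappa^2)`,
#'   `sigma_k ~ HC(0, zeta_kappa)`. Defaults all 2.
#' @param theta_z,tau_z,zeta_z same hierarchy for the slab of the rate
#'   shifts z(0..D). Defaults 0, 1, 1.
#' @param w_kappa_prior Bernoulli success probability for the shared
#'   z-inclusion indicator (default 0.5, the neutral prior).
#' @param w_h_prior length-3 vector of inclusion probabilities for
#'   delta0, delta1, delta2 (default 0.5 each).
#' @param mu_phi0,sigma_phi0,mu_phi1,sigma_phi1 normal priors for phi0
#'   and phi1; defaults N(-2, 20) and N(-30, 20) (variance 20).
#' @param mmax support bound (mg) of the ED50 prior; default 20.
#' @param mu_h,sigma_h slab means and SDs of delta0..delta2; defaults
#'   0 and 4.
#' @param zeta_s,zeta_s_star,zeta_e,zeta_e_star half-Cauchy scales for
#'   the residual SDs; default 2.
#' @param selection `"spike_slab"` (default), `"horseshoe"`, or
#'   `"always_on"` (inclusion indicators fixed at 1, i.e. Bayesian
#'   variable selection deactivated).
#' @param hierarchy if `FALSE`, the hierarchical borrowing across doses
#'   is removed: every k(d) gets an independent N(2, 2^2) prior and every
#'   slab z-tilde(d) an independent N(0, 1) prior.
#' @param xi_lambda,xi_h,xi_z,xi_delta half-Cauchy scales of the
#'   horseshoe local/global scale parameters (default 1).
#' @param fu_variant `"sqrt"` (default; the functional uniform prior
#'   proportional to the square root of the squared-gradient integral,
#'   which is proper on `[0, mmax]`) or `"as_printed"` (the integral
#'   itself, improper at 0).
#' @return an object of class `prior_config`.
#' @export
prior_config <- function(k0_mean = 2, k0_sd = 2,
                         theta_kappa = 2, tau_kappa = 2, zeta_kappa = 2,
                         theta_z = 0, tau_z = 1, zeta_z = 1,
                         w_kappa_prior = 0.5, w_h_prior = c(0.5, 0.5, 0.5),
                         mu_phi0 = -2, sigma_phi0 = sqrt(20),
                         mu_phi1 = -30, sigma_phi1 = sqrt(20),
                         mmax = 20,
                         mu_h = c(0, 0, 0), sigma_h = c(4, 4, 4),
                         zeta_s = 2, zeta_s_star = 2,
                         zeta_e = 2, zeta_e_star = 2,
                         selection = c("spike_slab", "horseshoe", "always_on"),
                         hierarchy = TRUE,
                         xi_lambda = 1, xi_h = 1, xi_z = 1, xi_delta = 1,
                         fu_variant = c("sqrt", "as_printed")) {
  selection <- match.arg(selection)
  fu_variant <- match.arg(fu_variant)
  w_h_prior <- rep_len(w_h_prior, 3L)
  mu_h <- rep_len(mu_h, 3L)
  sigma_h <- rep_len(sigma_h, 3L)
  sds <- c(k0_sd, tau_kappa, zeta_kappa, tau_z, zeta_z, sigma_phi0,
           sigma_phi1, sigma_h, zeta_s, zeta_s_star, zeta_e, zeta_e_star,
           xi_lambda, xi_h, xi_z, xi_delta)
  if (any(!is.finite(sds)) || any(sds <= 0))
    stop("all SD / scale hyperparameters must be positive")
  if (any(c(w_kappa_prior, w_h_prior) < 0) || any(c(w_kappa_prior, w_h_prior) > 1))
    stop("spike weights must lie in [0, 1]")
  if (mmax <= 0) stop("'mmax' must be positive")
  structure(
    list(k0_mean = k0_mean, k0_sd = k0_sd,
         theta_kappa = theta_kappa, tau_kappa = tau_kappa,
         zeta_kappa = zeta_kappa,
         theta_z = theta_z, tau_z = tau_z, zeta_z = zeta_z,
         w_kappa_prior = w_kappa_prior, w_h_prior = w_h_prior,
         mu_phi0 = mu_phi0, sigma_phi0 = sigma_phi0,
         mu_phi1 = mu_phi1, sigma_phi1 = sigma_phi1,
         mmax = mmax, mu_h = mu_h, sigma_h = sigma_h,
         zeta_s = zeta_s, zeta_s_star = zeta_s_star,
         zeta_e = zeta_e, zeta_e_star = zeta_e_star,
         selection = selection, hierarchy = isTRUE(hierarchy),
         xi_lambda = xi_lambda, xi_h = xi_h, xi_z = xi_z,
         xi_delta = xi_delta, fu_variant = fu_variant),
    class = "prior_config"
  )
}

#' @rdname prior_config
#' @export
default_prior_config <- function() prior_config()

#' @export
print.prior_config <- function(x, ...) {
  cat("DCT-ITP prior configuration\n")
  cat(sprintf("  selection: %s, hierarchy: %s, ED50 prior variant: %s\n",
              x$selection, if (x$hierarchy) "on" else "off", x$fu_variant))
  cat(sprintf("  k(0) ~ N(%g, %g^2); k(1..D) hierarchy (theta, tau, zeta) = (%g, %g, %g)\n",
              x$k0_mean, x$k0_sd, x$theta_kappa, x$tau_kappa, x$zeta_kappa))
  cat(sprintf("  z slab hierarchy (theta, tau, zeta) = (%g, %g, %g), w_kappa ~ Ber(%g)\n",
              x$theta_z, x$tau_z, x$zeta_z, x$w_kappa_prior))
  cat(sprintf("  phi0 ~ N(%g, %g), phi1 ~ N(%g, %g), phi2 in [0, %g]\n",
              x$mu_phi0, x$sigma_phi0^2, x$mu_phi1, x$sigma_phi1^2, x$mmax))
  cat(sprintf("  delta slabs N(%s; %s^2), w_h ~ Ber(%s)\n",
              paste(x$mu_h, collapse = ","), paste(x$sigma_h, collapse = ","),
              paste(x$w_h_prior, collapse = ",")))
  cat(sprintf("  residual SD scales (s, s*, e, e*) = (%g, %g, %g, %g)\n",
              x$zeta_s, x$zeta_s_star, x$zeta_e, x$zeta_e_star))
  invisible(x)
}

#' Half-Cauchy log density
#'
#' Zero-centered half-Cauchy with scale `scale`:
#' `log(2 / (pi * scale * (1 + (x/scale)^2)))` for `x >= 0`, `-Inf`
#' otherwise.
#'
#' @param x evaluation points.
#' @param scale positive scale parameter.
#' @export
half_cauchy_logpdf <- function(x, scale) {
  if (scale <= 0) stop("'scale' must be positive")
  out <- rep(-Inf, length(x))
  ok <- x >= 0
  out[ok] <- log(2 / (pi * scale * (1 + (x[ok] / scale)^2)))
  out
}

## closed form of G(c) = integral_0^M x^2 / (x + c)^4 dx
.fu_integral <- function(c, M) {
  1 / (3 * c) - (1 / (M + c) - c / (M + c)^2 + c^2 / (3 * (M + c)^3))
}

#' Functional uniform log prior for the ED50
#'
#' Unnormalized log density of the functional uniform prior on the Emax
#' ED50 parameter, restricted to `[0, mmax]`. The density is built from
#' \deqn{G(\phi_2) = \int_0^{m_{max}} \frac{x^2}{(x + \phi_2)^4}\,dx}
#' (available in closed form), either as \eqn{\sqrt{G}} (default, a
#' proper prior) or as \eqn{G} itself (`"as_printed"`, which diverges at
#' 0). Values outside the support return `-Inf` rather than an error.
#'
#' @param phi2 evaluation points (mg).
#' @param mmax support bound (mg).
#' @param variant `"sqrt"` or `"as_printed"`.
#' @return unnormalized log density, vectorized over `phi2`.
#' @export
functional_uniform_logpdf <- function(phi2, mmax = 20,
                                      variant = c("sqrt", "as_printed")) {
  variant <- match.arg(variant)
  if (mmax <= 0) stop("'mmax' must be positive")
  out <- rep(-Inf, length(phi2))
  ok <- phi2 >= 0 & phi2 <= mmax
  lg <- log(.fu_integral(phi2[ok], mmax))   # +Inf at phi2 = 0
  out[ok] <- if (variant == "sqrt") 0.5 * lg else lg
  out
}

#' Spike-and-slab log prior for the decentralization parameters
#'
#' Joint log prior of the rate shifts z(0..D) and Emax shifts
#' delta0..delta2 conditional on binary inclusion indicators. All doses
#' share a single indicator `w_kappa`: with `w_kappa = 0` every z(d) is
#' exactly zero (Dirac spike, contributing only the Bernoulli mass);
#' with `w_kappa = 1` the z(d) follow the slab normal with the supplied
#' mean/SD. Each delta_h has its own independent indicator and slab
#' `N(mu_h, sigma_h^2)`.
#'
#' @param z numeric vector of rate shifts (one per arm).
#' @param delta length-3 vector (delta0, delta1, delta2).
#' @param w_kappa binary indicator shared by all z(d).
#' @param w_h length-3 binary indicators for the delta_h.
#' @param config a [prior_config()].
#' @param slab_mean_z,slab_sd_z conditioning values of the hierarchical
#'   slab mean and SD for z (defaults: the hierarchy's prior means).
#' @return the scalar log prior (`-Inf` if a spiked coefficient is
#'   non-zero).
#' @export
spike_slab_logprior <- function(z, delta, w_kappa, w_h,
                                config = default_prior_config(),
                                slab_mean_z = config$theta_z,
                                slab_sd_z = config$tau_z) {
  if (!w_kappa %in% c(0, 1) || any(!w_h %in% c(0, 1)))
    stop("inclusion indicators must be binary")
  w_h <- rep_len(w_h, 3L)
  lp <- stats::dbinom(w_kappa, 1, config$w_kappa_prior, log = TRUE) +
    sum(stats::dbinom(w_h, 1, config$w_h_prior, log = TRUE))
  if (w_kappa == 0) {
    if (any(z != 0)) return(-Inf)
  } else {
    lp <- lp + sum(stats::dnorm(z, slab_mean_z, slab_sd_z, log = TRUE))
  }
  for (h in 1:3) {
    if (w_h[h] == 0) {
      if (delta[h] != 0) return(-Inf)
    } else {
      lp <- lp + stats::dnorm(delta[h], config$mu_h[h], config$sigma_h[h],
                              log = TRUE)
    }
  }
  lp
}

#' Horseshoe log prior for the decentralization parameters
#'
#' Alternative continuous-shrinkage prior: each z(d) is normal with SD
#' `lambda_d[d] * tau_z`, each delta_h normal with SD
#' `lambda_h[h] * tau_delta`, and all local and global scales carry
#' half-Cauchy priors with the configured `xi` scales (default 1, which
#' concentrates roughly half the prior mass of each coefficient near
#' zero, comparable to a Ber(0.5) spike).
#'
#' @param z,delta coefficient values as in [spike_slab_logprior()].
#' @param lambda_d,lambda_h local scales (per arm / per delta).
#' @param tau_z,tau_delta global scales.
#' @param config a [prior_config()].
#' @return the scalar log prior including the scale priors.
#' @export
horseshoe_logprior <- function(z, delta, lambda_d, lambda_h,
                               tau_z, tau_delta,
                               config = default_prior_config()) {
  scales <- c(lambda_d, lambda_h, tau_z, tau_delta)
  if (any(scales < 0)) stop("horseshoe scales must be non-negative")
  lambda_d <- rep_len(lambda_d, length(z))
  lambda_h <- rep_len(lambda_h, 3L)
  sum(stats::dnorm(z, 0, lambda_d * tau_z, log = TRUE)) +
    sum(stats::dnorm(delta, 0, lambda_h * tau_delta, log = TRUE)) +
    sum(half_cauchy_logpdf(lambda_d, config$xi_lambda)) +
    sum(half_cauchy_logpdf(lambda_h, config$xi_h)) +
    half_cauchy_logpdf(tau_z, config$xi_z) +
    half_cauchy_logpdf(tau_delta, config$xi_delta)
}

#' Read / write a prior configuration as YAML
#'
#' Every field defaults to the trial-application value, so an empty file
#' (or one setting only a few fields) reproduces the default analysis.
#'
#' @param path YAML file path.
#' @export
read_prior_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  unknown <- setdiff(names(vals), names(formals(prior_config)))
  if (length(unknown))
    stop("unknown prior fields: ", paste(unknown, collapse = ", "))
  do.call(prior_config, vals)
}

#' @rdname read_prior_config
#' @param config a [prior_config()].
#' @export
write_prior_config <- function(config, path) {
  stopifnot(inherits(config, "prior_config"))
  vals <- unclass(config)
  vals$hierarchy <- isTRUE(vals$hierarchy)
  yaml::write_yaml(vals, path)
  invisible(path)
}
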