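## Deterministic layer of the DCT-ITP model: time-effect, terminal dose
## effect, longitudinal mean, subject-level covariance, and the marginal
## observed-data log-likelihood.

#' Model parameters for the DCT-ITP model
#'
#' One point in parameter space for the decentralized integrated
#' two-component prediction (DCT-ITP) model. The longitudinal mean is
#' \deqn{\mu(l, d, I) = \kappa(t_l, d, I)\,\lambda(d, I),}
#' the product of a time-effect fraction and a terminal (last-visit) dose
#' effect, and the observation model is
#' \deqn{Y_{jl} = \mu(l,d_j,I_l) + \frac{\mu(l,d_j,I_l)}{\mu(L,d_j,I_l)}
#'   (s_j + I_l s^*_j) + e_{jl} + I_l e^*_{jl},}
#' with independent normal random effects and errors. The starred
#' components load only on decentralized (\eqn{I=1}) measurements.
#'
#' @param k rate parameter per arm `d = 0..D` (placebo first), on the
#'   standardized-time scale. A scalar is recycled across arms.
#' @param z decentralized shift of the rate per arm; recycled like `k`.
#' @param phi0,phi1,phi2 three-parameter Emax terminal dose effect:
#'   `phi0` placebo response (kg), `phi1` maximum dose effect (kg),
#'   `phi2` ED50 (mg, must be positive).
#' @param delta0,delta1,delta2 decentralized shifts of the Emax
#'   parameters; `phi2 + delta2` must stay positive.
#' @param sigma_s,sigma_s_star between-subject SD and its decentralized
#'   add-on (kg, non-negative).
#' @param sigma_e,sigma_e_star within-subject SD and its decentralized
#'   add-on (kg, non-negative).
#' @param n_arms number of arms (placebo included); defaults to the
#'   length of `k` / `z`, and scalars are recycled to this length.
#' @return an object of class `model_params`.
#' @examples
#' model_params(k = 2, phi0 = -2.5, phi1 = -30, phi2 = 5,
#'              sigma_s = 6, sigma_e = 5)
#' @export
model_params <- function(k, z = 0, phi0, phi1, phi2,
                         delta0 = 0, delta1 = 0, delta2 = 0,
                         sigma_s = 0, sigma_s_star = 0,
                         sigma_e = 0, sigma_e_star = 0,
                         n_arms = NULL) {
  n_arm <- n_arms %||% max(length(k), length(z))
  k <- rep_len(as.numeric(k), n_arm)
  z <- rep_len(as.numeric(z), n_arm)
  sds <- c(sigma_s, sigma_s_star, sigma_e, sigma_e_star)
  if (any(!is.finite(sds)) || any(sds < 0))
    stop("residual SDs must be finite and non-negative")
  if (!is.finite(phi2) || phi2 <= 0)
    stop("'phi2' (ED50) must be positive")
  if (phi2 + delta2 <= 0)
    stop("'phi2 + delta2' must be positive")
  structure(
    list(k = k, z = z,
         phi0 = phi0, phi1 = phi1, phi2 = phi2,
         delta0 = delta0, delta1 = delta1, delta2 = delta2,
         sigma_s = sigma_s, sigma_s_star = sigma_s_star,
         sigma_e = sigma_e, sigma_e_star = sigma_e_star),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("DCT-ITP model parameters\n")
  cat("  k:", format(x$k, digits = 4), " z:", format(x$z, digits = 4), "\n")
  cat(sprintf("  Emax: phi0=%g phi1=%g phi2=%g (deltas %g, %g, %g)\n",
              x$phi0, x$phi1, x$phi2, x$delta0, x$delta1, x$delta2))
  cat(sprintf("  SDs: sigma_s=%g (+%g dec), sigma_e=%g (+%g dec)\n",
              x$sigma_s, x$sigma_s_star, x$sigma_e, x$sigma_e_star))
  invisible(x)
}

## exponential-decay time-effect kernel with the removable singularity at
## r = 0 filled in by its limit kappa(t) = t
.kappa <- function(t, r) {
  small <- abs(r) < 1e-10
  out <- numeric(length(t))
  r <- rep_len(r, length(t))
  small <- rep_len(small, length(t))
  out[small] <- t[small]
  if (any(!small))
    out[!small] <- (1 - exp(-r[!small] * t[!small])) / (1 - exp(-r[!small]))
  out
}

.check_t <- function(t) {
  ## jittered terminal visits can standardize slightly above 1 (the
  ## denominator is the last *scheduled* day); allow a small overshoot
  if (any(t < -1e-12) || any(t > 1.05))
    stop("standardized time must lie in [0, 1] (small jitter overshoot allowed)")
}

#' Time-effect fraction
#'
#' Fraction of the terminal response attained at standardized time `t`
#' for arm `d`, \eqn{\kappa(t) = (1 - e^{-rt}) / (1 - e^{-r})} with
#' effective rate \eqn{r = k(d) + I\,z(d)}. As \eqn{r \to 0} the fraction
#' tends to `t`, and the implementation uses that limit for
#' \eqn{|r| < 10^{-10}}.
#'
#' @param t standardized time(s) in `[0, 1]`.
#' @param d arm index, 0 = placebo.
#' @param I decentralization indicator (0 or 1), recycled against `t`.
#' @param params a [model_params()].
#' @return numeric vector of fractions; \eqn{\kappa(1) = 1} for any rate.
#' @export
time_effect <- function(t, d, I, params) {
  stopifnot(inherits(params, "model_params"))
  .check_t(t)
  if (d < 0 || d >= length(params$k)) stop("arm index out of range")
  r <- params$k[d + 1L] + I * params$z[d + 1L]
  .kappa(t, r)
}

#' Terminal dose effect (Emax)
#'
#' Mean response at the final visit for dosage `md`,
#' \deqn{\lambda(m, I) = (\phi_0 + I\delta_0) +
#'   \frac{(\phi_1 + I\delta_1)\, m}{(\phi_2 + I\delta_2) + m}.}
#'
#' @param md dosage in mg (non-negative; vectorized).
#' @param I decentralization indicator (0 or 1).
#' @param params a [model_params()].
#' @return terminal mean response in kg.
#' @examples
#' p <- model_params(k = 2, phi0 = -2.5, phi1 = -30, phi2 = 5)
#' dose_effect(15, 0, p)  # -25
#' @export
dose_effect <- function(md, I, params) {
  stopifnot(inherits(params, "model_params"))
  if (any(md < 0)) stop("dosage must be non-negative")
  den <- (params$phi2 + I * params$delta2) + md
  if (any(den <= 0)) stop("Emax denominator (phi2 + I*delta2 + md) must be positive")
  (params$phi0 + I * params$delta0) +
    (params$phi1 + I * params$delta1) * md / den
}

#' Longitudinal mean response
#'
#' \eqn{\mu(t, d, I) = \kappa(t, d, I)\,\lambda(m_d, I)}: zero at
#' baseline, equal to the terminal dose effect at \eqn{t = 1}.
#'
#' @inheritParams time_effect
#' @param md dosage of arm `d` in mg.
#' @return mean change from baseline in kg.
#' @export
mean_response <- function(t, md, d, I, params) {
  time_effect(t, d, I, params) * dose_effect(md, I, params)
}

#' Marginal covariance of one subject's repeated measurements
#'
#' Integrating the subject random effects out of the DCT-ITP observation
#' model gives, for visits l and l' of one subject on arm d,
#' \deqn{\mathrm{Cov}(Y_l, Y_{l'}) = a_l a_{l'} \sigma_s^2 +
#'   a_l a_{l'} I_l I_{l'} \sigma_{s*}^2 +
#'   1\{l = l'\}(\sigma_e^2 + I_l \sigma_{e*}^2),}
#' with loadings \eqn{a_l = \mu(l,d,I_l)/\mu(L,d,I_l)} taken against the
#' scheduled terminal time (\eqn{t_L = 1}) with the same indicator in
#' numerator and denominator, so the dose effect cancels and
#' \eqn{a_l = \kappa(t_l, d, I_l)}. The decentralized between-subject
#' component loads only across decentralized visits, and the
#' decentralized within-subject component only inflates decentralized
#' diagonals.
#'
#' @param schedule a [visit_schedule()]; the post-baseline visits define
#'   the covariance dimensions.
#' @param d arm index.
#' @param md dosage of the arm (mg); needed only to verify the terminal
#'   mean is non-zero.
#' @param params a [model_params()].
#' @param t,I optional standardized times and indicators overriding the
#'   schedule's (e.g. a subject's jittered times or an observed subset).
#' @return a list with elements `sigma` (the covariance matrix) and
#'   `loadings`, of class `subject_covariance`.
#' @export
subject_covariance <- function(schedule, d, md, params, t = NULL, I = NULL) {
  stopifnot(inherits(params, "model_params"))
  if (is.null(t)) {
    stopifnot(inherits(schedule, "visit_schedule"))
    t <- schedule$std_time[-1]
    I <- as.integer(schedule$decentralized[-1])
  }
  I <- rep_len(as.integer(I), length(t))
  for (Iv in unique(I)) {
    if (abs(dose_effect(md, Iv, params)) < 1e-12)
      stop("terminal mean response is zero; loadings are undefined")
  }
  a <- mapply(function(ti, Ii) time_effect(ti, d, Ii, params), t, I)
  sig <- outer(a, a) * params$sigma_s^2 +
    outer(a * I, a * I) * params$sigma_s_star^2 +
    diag(params$sigma_e^2 + I * params$sigma_e_star^2, length(a))
  structure(list(sigma = sig, loadings = a, t = t, I = I),
            class = "subject_covariance")
}

## log density of a multivariate normal via Cholesky; errors on a
## numerically singular covariance
.dmvnorm_log <- function(y, mu, sigma) {
  ch <- tryCatch(chol(sigma), error = function(e)
    stop("singular subject covariance: ", conditionMessage(e)))
  v <- backsolve(ch, y - mu, transpose = TRUE)
  -0.5 * length(y) * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(v^2)
}

#' Observed-data log-likelihood of the DCT-ITP model
#'
#' Sums, over subjects, the multivariate-normal log density of the
#' observed (non-missing) outcomes, with mean \eqn{\mu(t, d, I)} and the
#' marginal covariance of [subject_covariance()] restricted to the
#' observed visits. This is the random-effects model with \eqn{s_j} and
#' \eqn{s^*_j} integrated out analytically.
#'
#' @param data a [trial_data()] long-format data frame; missing outcomes
#'   (`NA`) are simply excluded from their subject's marginal density.
#' @param params a [model_params()].
#' @return the scalar log-likelihood.
#' @export
itp_log_likelihood <- function(data, params) {
  data <- as_trial_data(data)
  stopifnot(inherits(params, "model_params"))
  ll <- 0
  for (sid in unique(data$subject_id)) {
    rows <- data[data$subject_id == sid & !is.na(data$y), , drop = FALSE]
    if (nrow(rows) == 0L) next
    d <- rows$arm[1]
    mu <- mean_response(rows$std_time, rows$dose_mg, d, rows$decentralized, params)
    sc <- subject_covariance(NULL, d, rows$dose_mg[1], params,
                             t = rows$std_time, I = rows$decentralized)
    ll <- ll + .dmvnorm_log(rows$y, mu, sc$sigma)
  }
  ll
}
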