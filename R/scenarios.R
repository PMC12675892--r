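#' Missingness mechanism configuration
#'
#' Outcome-dependent (MAR) dropout and intermittent missingness for the
#' trial simulator. Over post-treatment visits l = 1..L, a still-active
#' subject drops out with probability
#' `plogis(alpha0 + alpha1 * Y_{l-1} + alpha2 * log(t_l))` (dropout is
#' absorbing: all later visits are missing), and an active subject's
#' visit is intermittently missing with probability
#' `plogis((beta0 + I_l * delta_beta0) + (beta1 + I_l * delta_beta1) *
#' Y_{l-1} + beta2 * log(t_l))`. `Y_{l-1}` is the subject's generated
#' (true) outcome at the previous scheduled visit (0 at baseline), and
#' `t_l` is the scheduled visit time, entered into the log term on the
#' day scale by default (`log_time = "days"`); with
#' `log_time = "standardized"` the standardized time is used instead.
#' On the day scale the defaults yield, under the trial-application
#' configuration, an accumulated dropout rate of about 10% at the last
#' visit, an average intermittent missingness of about 16% among active
#' visits, and an overall missingness of about 20% per visit.
#'
#' The `"mixed_mcar_mar_dropout"` mechanism is the sensitivity-analysis
#' variant combining three roughly 10% components: intermittent
#' missingness completely at random at rate `mcar_rate`, MAR
#' intermittent missingness with `beta0` shifted to `beta0_mixed`
#' (calibrated to about 10% under the trial-application configuration),
#' and outcome-independent random dropout with per-visit hazard
#' `dropout_hazard` (calibrated so the accumulated rate is about 10%).
#'
#' @param alpha0,alpha1,alpha2 dropout logistic coefficients.
#' @param beta0,delta_beta0,beta1,delta_beta1,beta2 intermittent
#'   missingness logistic coefficients; the `delta_` terms apply to
#'   decentralized visits only.
#' @param mechanism `"mar_default"` or `"mixed_mcar_mar_dropout"`.
#' @param log_time scale of the visit time inside the log terms:
#'   `"days"` (default) or `"standardized"`.
#' @param mcar_rate extra completely-at-random missingness among active
#'   visits (used by the mixed mechanism; may also be set with the
#'   default mechanism).
#' @param beta0_mixed,dropout_hazard mixed-mechanism parameters.
#' @export
missingness_config <- function(alpha0 = -5.05, alpha1 = -0.02, alpha2 = 0.05,
                               beta0 = -3.25, delta_beta0 = -0.3,
                               beta1 = -0.15, delta_beta1 = 0, beta2 = 0.05,
                               mechanism = c("mar_default",
                                             "mixed_mcar_mar_dropout"),
                               log_time = c("days", "standardized"),
                               mcar_rate = 0,
                               beta0_mixed = -3.8,
                               dropout_hazard = 1 - (1 - 0.10)^(1 / 12)) {
  mechanism <- match.arg(mechanism)
  log_time <- match.arg(log_time)
  if (mcar_rate < 0 || mcar_rate >= 1) stop("'mcar_rate' must be in [0, 1)")
  if (mechanism == "mixed_mcar_mar_dropout" && mcar_rate == 0)
    mcar_rate <- 0.10
  structure(list(alpha0 = alpha0, alpha1 = alpha1, alpha2 = alpha2,
                 beta0 = beta0, delta_beta0 = delta_beta0,
                 beta1 = beta1, delta_beta1 = delta_beta1, beta2 = beta2,
                 mechanism = mechanism, log_time = log_time,
                 mcar_rate = mcar_rate,
                 beta0_mixed = beta0_mixed, dropout_hazard = dropout_hazard),
            class = "missingness_config")
}

#' Generation-side truth for a simulated trial scenario
#'
#' Defines how outcomes are generated: the onsite and decentralized
#' terminal dose-response curves, the time-effect rates, the variance
#' components, the arm layout, and the missingness mechanism. Three
#' dose-response families are supported: `"emax"` (the DCT-ITP
#' parameterization with shifts `delta0..delta2`), `"quadratic"` (onsite
#' and decentralized quadratic polynomials in the dosage), and
#' `"linear_decentralized"` (quadratic onsite, linear decentralized).
#' For the polynomial families the Emax terminal effect is replaced by
#' the polynomial, but the time-effect and the loading/variance
#' structure are unchanged.
#'
#' @param family dose-response family.
#' @param phi Emax parameters `c(phi0, phi1, phi2)` (emax family).
#' @param delta decentralized Emax shifts `c(delta0, delta1, delta2)`.
#' @param onsite_coef,dec_coef polynomial coefficients (intercept first)
#'   for the polynomial families.
#' @param k time-effect rate per arm (recycled).
#' @param z decentralized rate shift per arm (recycled).
#' @param sigma_s2,sigma_s_star2,sigma_e2,sigma_e_star2 variance
#'   components (between-subject, its decentralized add-on,
#'   within-subject, its decentralized add-on).
#' @param doses arm dosages in mg, placebo (0) first.
#' @param n_per_arm subjects per arm.
#' @param schedule_id a [make_schedule()] schema id.
#' @param missingness a [missingness_config()].
#' @param name label.
#' @export
scenario_spec <- function(family = c("emax", "quadratic",
                                     "linear_decentralized"),
                          phi = c(-2.5, -30, 5), delta = c(0, 0, 0),
                          onsite_coef = NULL, dec_coef = NULL,
                          k = 2, z = 0,
                          sigma_s2 = 36, sigma_s_star2 = 0,
                          sigma_e2 = 25, sigma_e_star2 = 0,
                          doses = c(0, 1, 5, 10, 15), n_per_arm = 24,
                          schedule_id = "default12",
                          missingness = missingness_config(),
                          name = NULL) {
  family <- match.arg(family)
  if (doses[1] != 0) stop("the first arm must be the placebo (dose 0)")
  if (any(c(sigma_s2, sigma_s_star2, sigma_e2, sigma_e_star2) < 0))
    stop("variance components must be non-negative")
  if (family != "emax" && (is.null(onsite_coef) || is.null(dec_coef)))
    stop("polynomial families need 'onsite_coef' and 'dec_coef'")
  A <- length(doses)
  structure(list(family = family, phi = phi, delta = delta,
                 onsite_coef = onsite_coef, dec_coef = dec_coef,
                 k = rep_len(k, A), z = rep_len(z, A),
                 sigma_s2 = sigma_s2, sigma_s_star2 = sigma_s_star2,
                 sigma_e2 = sigma_e2, sigma_e_star2 = sigma_e_star2,
                 doses = doses, n_per_arm = n_per_arm,
                 schedule_id = schedule_id, missingness = missingness,
                 name = name %||% family),
            class = "scenario_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Scenario '%s' (%s family): %d arms x %d subjects\n",
              x$name, x$family, length(x$doses), x$n_per_arm))
  cat("  doses (mg):", paste(x$doses, collapse = ", "), "\n")
  if (x$family == "emax") {
    cat(sprintf("  phi = (%s), delta = (%s)\n",
                paste(x$phi, collapse = ", "),
                paste(x$delta, collapse = ", ")))
  } else {
    cat("  onsite coef:", paste(x$onsite_coef, collapse = ", "),
        " dec coef:", paste(x$dec_coef, collapse = ", "), "\n")
  }
  cat(sprintf("  k = (%s), z = (%s)\n", paste(x$k, collapse = ", "),
              paste(x$z, collapse = ", ")))
  cat(sprintf("  variances: s %g (+%g dec), e %g (+%g dec)\n",
              x$sigma_s2, x$sigma_s_star2, x$sigma_e2, x$sigma_e_star2))
  invisible(x)
}

#' Terminal dose-response curve of a scenario
#'
#' @param spec a [scenario_spec()].
#' @param md dosage (mg, vectorized).
#' @param I decentralization indicator.
#' @return terminal mean response in kg.
#' @export
scenario_lambda <- function(spec, md, I = 0) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (spec$family == "emax") {
    p <- spec$phi; d <- spec$delta
    (p[1] + I * d[1]) + (p[2] + I * d[2]) * md / ((p[3] + I * d[3]) + md)
  } else {
    coef <- if (I == 0 || all(I == 0)) spec$onsite_coef else spec$dec_coef
    if (length(unique(I)) > 1L)
      return(vapply(seq_along(md), function(i)
        scenario_lambda(spec, md[i], I[i]), numeric(1)))
    drop(outer(md, seq_along(coef) - 1, `^`) %*% coef)
  }
}

#' The eight simulation scenarios
#'
#' Generation-side truths for the simulation study, keyed `"1"`..`"8"`:
#' 1. onsite and decentralized measurements identical;
#' 2. unbiased decentralized measurements with inflated variability;
#' 3. the motivating configuration — decentralized shift of the Emax
#'    curve (delta0 = 0.5, delta1 = 2) plus inflated variability;
#' 4. the opposite shift (delta0 = -0.5, delta1 = -2);
#' 5.-6. shifts in every Emax parameter and in the time-effect rate
#'    (scenario 6 with a dose-varying rate shift z(d) = 0, 0.5, 1, 1.5,
#'    2);
#' 7. both curves quadratic in the dosage (model misspecification);
#' 8. quadratic onsite curve, linear decentralized curve.
#'
#' All scenarios use 5 arms at 0, 1, 5, 10, 15 mg with 24 subjects per
#' arm, the `default12` schedule, and the default missingness
#' configuration.
#'
#' @return a named list of [scenario_spec()] objects.
#' @export
scenario_registry <- function() {
  list(
    "1" = scenario_spec(name = "1"),
    "2" = scenario_spec(name = "2", sigma_s_star2 = 13, sigma_e_star2 = 11),
    "3" = scenario_spec(name = "3", delta = c(0.5, 2, 0),
                        sigma_s_star2 = 13, sigma_e_star2 = 11),
    "4" = scenario_spec(name = "4", delta = c(-0.5, -2, 0),
                        sigma_s_star2 = 13, sigma_e_star2 = 11),
    "5" = scenario_spec(name = "5", phi = c(-2.5, -25.5, 2),
                        delta = c(0, 5.5, 0.5), k = 1, z = -0.5,
                        sigma_s2 = 64, sigma_s_star2 = 36,
                        sigma_e2 = 36, sigma_e_star2 = 28),
    "6" = scenario_spec(name = "6", phi = c(-2.5, -28, 6),
                        delta = c(-0.5, -2, -0.5), k = 1,
                        z = c(0, 0.5, 1, 1.5, 2),
                        sigma_s2 = 64, sigma_s_star2 = 36,
                        sigma_e2 = 36, sigma_e_star2 = 28),
    "7" = scenario_spec(name = "7", family = "quadratic",
                        onsite_coef = c(-1, -2.2, 0.05),
                        dec_coef = c(-1, -2, 0.037),
                        k = 2, z = 1,
                        sigma_s2 = 81, sigma_s_star2 = 40,
                        sigma_e2 = 64, sigma_e_star2 = 36),
    "8" = scenario_spec(name = "8", family = "linear_decentralized",
                        onsite_coef = c(-1, -2.1, 0.05),
                        dec_coef = c(-4, -1.4),
                        k = 2, z = 0,
                        sigma_s2 = 25, sigma_s_star2 = 11,
                        sigma_e2 = 36, sigma_e_star2 = 13)
  )
}

#' Read / write a scenario specification as YAML
#'
#' @param path YAML file path.
#' @export
read_scenario_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  if (!is.null(vals$missingness))
    vals$missingness <- do.call(missingness_config, vals$missingness)
  unknown <- setdiff(names(vals), names(formals(scenario_spec)))
  if (length(unknown))
    stop("unknown scenario fields: ", paste(unknown, collapse = ", "))
  do.call(scenario_spec, vals)
}

#' @rdname read_scenario_yaml
#' @param spec a [scenario_spec()].
#' @export
write_scenario_yaml <- function(spec, path) {
  stopifnot(inherits(spec, "scenario_spec"))
  vals <- unclass(spec)
  vals$missingness <- unclass(vals$missingness)
  vals$missingness$mcar_rate <- as.numeric(vals$missingness$mcar_rate)
  yaml::write_yaml(vals, path)
  invisible(path)
}
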