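## Generation of the JAGS model code for the DCT-ITP model and for the
## standard (single-source) ITP model used by the O/M/T comparator fits.
## All prior hyperparameters are inlined as literals so the generated
## string fully specifies the model.

.num <- function(x) sprintf("%.17g", x)

## functional uniform prior on phi2 via the Poisson zeros trick on the
## closed-form integral G; phi2 is clamped at 1e-3 inside the density so
## the improper spike of the as-printed variant cannot produce a negative
## Poisson rate, and the offset 30 keeps the rate positive over [0, mmax]
.fu_block <- function(priors) {
  coefficient <- if (priors$fu_variant == "sqrt") "0.5" else "1.0"
  paste0(
    "  phi2 ~ dunif(0, ", .num(priors$mmax), ")\n",
    "  fu_c <- max(phi2, 1.0E-3)\n",
    "  fu_G <- 1/(3*fu_c) - (1/(", .num(priors$mmax), "+fu_c)",
    " - fu_c/pow(", .num(priors$mmax), "+fu_c,2)",
    " + pow(fu_c,2)/(3*pow(", .num(priors$mmax), "+fu_c,3)))\n",
    "  fu_zero ~ dpois(30 - ", coefficient, "*log(fu_G))\n"
  )
}

.k_block <- function(priors) {
  out <- paste0("  k[1] ~ dnorm(", .num(priors$k0_mean), ", ",
                .num(1 / priors$k0_sd^2), ")\n")
  if (priors$hierarchy) {
    paste0(out,
      "  for (a in 2:A) { k[a] ~ dnorm(mu_k, 1/pow(sigma_k,2)) }\n",
      "  mu_k ~ dnorm(", .num(priors$theta_kappa), ", ",
      .num(1 / priors$tau_kappa^2), ")\n",
      "  sigma_k ~ dt(0, ", .num(1 / priors$zeta_kappa^2), ", 1) T(0,)\n")
  } else {
    ## ablation: independent N(2, 2^2) rates, no borrowing
    paste0(out,
      "  for (a in 2:A) { k[a] ~ dnorm(2, 0.25) }\n")
  }
}

.z_delta_block <- function(priors) {
  slab_z <- if (priors$hierarchy) {
    paste0(
      "  for (a in 1:A) { ztilde[a] ~ dnorm(mu_z, 1/pow(sigma_z,2)) }\n",
      "  mu_z ~ dnorm(", .num(priors$theta_z), ", ",
      .num(1 / priors$tau_z^2), ")\n",
      "  sigma_z ~ dt(0, ", .num(1 / priors$zeta_z^2), ", 1) T(0,)\n")
  } else {
    "  for (a in 1:A) { ztilde[a] ~ dnorm(0, 1) }\n"
  }
  dtl <- paste0(
    "  for (h in 1:3) { dtl[h] ~ dnorm(mu_h[h], 1/pow(sigma_h[h],2)) }\n",
    "  mu_h[1] <- ", .num(priors$mu_h[1]), "\n",
    "  mu_h[2] <- ", .num(priors$mu_h[2]), "\n",
    "  mu_h[3] <- ", .num(priors$mu_h[3]), "\n",
    "  sigma_h[1] <- ", .num(priors$sigma_h[1]), "\n",
    "  sigma_h[2] <- ", .num(priors$sigma_h[2]), "\n",
    "  sigma_h[3] <- ", .num(priors$sigma_h[3]), "\n")
  switch(priors$selection,
    spike_slab = paste0(
      slab_z,
      "  wk ~ dbern(", .num(priors$w_kappa_prior), ")\n",
      "  for (a in 1:A) { z[a] <- wk * ztilde[a] }\n",
      dtl,
      "  for (h in 1:3) {\n",
      "    wh[h] ~ dbern(p_wh[h])\n",
      "    delta[h] <- wh[h] * dtl[h]\n",
      "  }\n",
      "  p_wh[1] <- ", .num(priors$w_h_prior[1]), "\n",
      "  p_wh[2] <- ", .num(priors$w_h_prior[2]), "\n",
      "  p_wh[3] <- ", .num(priors$w_h_prior[3]), "\n"),
    always_on = paste0(
      slab_z,
      "  wk <- 1\n",
      "  for (a in 1:A) { z[a] <- ztilde[a] }\n",
      dtl,
      "  for (h in 1:3) { wh[h] <- 1 \n    delta[h] <- dtl[h] }\n"),
    horseshoe = paste0(
      "  for (a in 1:A) {\n",
      "    lam_z[a] ~ dt(0, ", .num(1 / priors$xi_lambda^2), ", 1) T(0,)\n",
      "    z[a] ~ dnorm(0, 1/pow(lam_z[a]*tau_hs_z, 2))\n",
      "  }\n",
      "  tau_hs_z ~ dt(0, ", .num(1 / priors$xi_z^2), ", 1) T(0,)\n",
      "  for (h in 1:3) {\n",
      "    lam_h[h] ~ dt(0, ", .num(1 / priors$xi_h^2), ", 1) T(0,)\n",
      "    delta[h] ~ dnorm(0, 1/pow(lam_h[h]*tau_hs_d, 2))\n",
      "  }\n",
      "  tau_hs_d ~ dt(0, ", .num(1 / priors$xi_delta^2), ", 1) T(0,)\n")
  )
}

.hc_sd <- function(name, zeta) {
  paste0("  ", name, " ~ dt(0, ", .num(1 / zeta^2), ", 1) T(0,)\n")
}

#' Generate the JAGS model code
#'
#' Writes the full Bayesian model — likelihood, random effects, and all
#' priors implied by a [prior_config()] — as JAGS code. `variant = "dct"`
#' is the full DCT-ITP model with decentralization shifts and inflated
#' decentralized variances; `variant = "standard"` is the single-source
#' modified ITP model used for the onsite-only, pooled, and traditional
#' comparator fits. In the likelihood, the per-record subject-effect
#' loading is the time-effect fraction at the record's (possibly
#' jittered) standardized time, i.e. the mean at the record divided by
#' the mean at the scheduled terminal time with the same indicator. The
#' Emax denominator is floored at 0.05 mg as a numerical guard against
#' slab draws with `phi2 + delta2 + m <= 0`.
#'
#' @param priors a [prior_config()].
#' @param variant `"dct"` or `"standard"`.
#' @return a single string of JAGS model code.
#' @export
dct_itp_jags_code <- function(priors = default_prior_config(),
                              variant = c("dct", "standard")) {
  variant <- match.arg(variant)
  stopifnot(inherits(priors, "prior_config"))
  if (variant == "dct") {
    paste0(
      "model {\n",
      "  for (i in 1:N) {\n",
      "    r[i] <- k[arm[i]] + I[i]*z[arm[i]]\n",
      "    kp[i] <- (1 - exp(-r[i]*t[i])) / (1 - exp(-r[i]))\n",
      "    den[i] <- max(phi2 + I[i]*delta[3] + dose[i], 0.05)\n",
      "    lm[i] <- (phi0 + I[i]*delta[1]) + (phi1 + I[i]*delta[2])*dose[i]/den[i]\n",
      "    m[i] <- kp[i]*lm[i] + kp[i]*(s[subj[i]] + I[i]*sstar[subj[i]])\n",
      "    y[i] ~ dnorm(m[i], 1/(pow(sigma_e,2) + I[i]*pow(sigma_estar,2)))\n",
      "  }\n",
      "  for (j in 1:J) {\n",
      "    s[j] ~ dnorm(0, 1/pow(sigma_s,2))\n",
      "    sstar[j] ~ dnorm(0, 1/pow(sigma_sstar,2))\n",
      "  }\n",
      .k_block(priors),
      .z_delta_block(priors),
      "  phi0 ~ dnorm(", .num(priors$mu_phi0), ", ",
      .num(1 / priors$sigma_phi0^2), ")\n",
      "  phi1 ~ dnorm(", .num(priors$mu_phi1), ", ",
      .num(1 / priors$sigma_phi1^2), ")\n",
      .fu_block(priors),
      .hc_sd("sigma_s", priors$zeta_s),
      .hc_sd("sigma_sstar", priors$zeta_s_star),
      .hc_sd("sigma_e", priors$zeta_e),
      .hc_sd("sigma_estar", priors$zeta_e_star),
      "}\n"
    )
  } else {
    paste0(
      "model {\n",
      "  for (i in 1:N) {\n",
      "    kp[i] <- (1 - exp(-k[arm[i]]*t[i])) / (1 - exp(-k[arm[i]]))\n",
      "    lm[i] <- phi0 + phi1*dose[i]/(max(phi2 + dose[i], 0.05))\n",
      "    m[i] <- kp[i]*lm[i] + kp[i]*s[subj[i]]\n",
      "    y[i] ~ dnorm(m[i], 1/pow(sigma_e,2))\n",
      "  }\n",
      "  for (j in 1:J) { s[j] ~ dnorm(0, 1/pow(sigma_s,2)) }\n",
      .k_block(priors),
      "  phi0 ~ dnorm(", .num(priors$mu_phi0), ", ",
      .num(1 / priors$sigma_phi0^2), ")\n",
      "  phi1 ~ dnorm(", .num(priors$mu_phi1), ", ",
      .num(1 / priors$sigma_phi1^2), ")\n",
      .fu_block(priors),
      .hc_sd("sigma_s", priors$zeta_s),
      .hc_sd("sigma_e", priors$zeta_e),
      "}\n"
    )
  }
}
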