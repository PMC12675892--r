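test_that("default prior configuration carries the trial-application values", {
  cfg <- default_prior_config()
  expect_equal(cfg$mu_phi1, -30)
  expect_equal(cfg$sigma_phi0^2, 20)
  expect_equal(cfg$sigma_phi1^2, 20)
  expect_equal(cfg$mmax, 20)
  expect_equal(cfg$k0_mean, 2)
  expect_equal(cfg$k0_sd, 2)
  expect_equal(c(cfg$theta_kappa, cfg$tau_kappa, cfg$zeta_kappa), c(2, 2, 2))
  expect_equal(c(cfg$theta_z, cfg$tau_z, cfg$zeta_z), c(0, 1, 1))
  expect_equal(cfg$w_kappa_prior, 0.5)
  expect_equal(cfg$w_h_prior, rep(0.5, 3))
  expect_equal(cfg$mu_h, rep(0, 3))
  expect_equal(cfg$sigma_h, rep(4, 3))
  expect_equal(c(cfg$zeta_s, cfg$zeta_s_star, cfg$zeta_e, cfg$zeta_e_star),
               rep(2, 4))
  expect_identical(cfg$selection, "spike_slab")
  expect_true(cfg$hierarchy)
})

test_that("functional uniform prior: closed form vs quadrature, shape, support", {
  G_quad <- function(c, M)
    stats::integrate(function(x) x^2 / (x + c)^4, 0, M, rel.tol = 1e-13)$value
  for (c in c(0.5, 2, 5, 12, 19)) {
    expect_equal(exp(functional_uniform_logpdf(c, 20, "as_printed")),
                 G_quad(c, 20), tolerance = 1e-10)
  }
  ## sqrt variant is half the log
  expect_equal(functional_uniform_logpdf(5, 20, "sqrt"),
               0.5 * functional_uniform_logpdf(5, 20, "as_printed"))
  ## strictly decreasing on (0, mmax]
  grid <- seq(0.1, 20, length.out = 80)
  expect_true(all(diff(functional_uniform_logpdf(grid, 20)) < 0))
  ## indicator support
  expect_identical(functional_uniform_logpdf(21, 20), -Inf)
  expect_identical(functional_uniform_logpdf(-0.5, 20), -Inf)
})

test_that("half-Cauchy log density matches the closed form", {
  x <- c(0, 0.3, 1, 4, 10)
  for (zeta in c(1, 2)) {
    expect_equal(half_cauchy_logpdf(x, zeta),
                 log(2 / (pi * zeta * (1 + (x / zeta)^2))))
    ## equivalently a doubled Cauchy density on the half-line
    expect_equal(half_cauchy_logpdf(x, zeta),
                 log(2) + stats::dcauchy(x, 0, zeta, log = TRUE))
  }
  expect_identical(half_cauchy_logpdf(-1, 2), -Inf)
  expect_error(half_cauchy_logpdf(1, -2), "positive")
})

test_that("spike-and-slab prior: Dirac spike, shared z indicator, slab density", {
  cfg <- default_prior_config()
  z <- c(0.4, -0.2, 0.1, 0, 0.3)
  delta <- c(0.5, 2, 0)
  ## spiked z with non-zero values has zero density
  expect_identical(spike_slab_logprior(z, c(0, 0, 0), 0, c(0, 0, 0), cfg), -Inf)
  ## w_kappa = 0 with z identically 0 contributes only the Bernoulli mass
  expect_equal(spike_slab_logprior(rep(0, 5), rep(0, 3), 0, c(0, 0, 0), cfg),
               4 * log(0.5))
  ## full slab: manual computation
  lp <- spike_slab_logprior(z, delta, 1, c(1, 1, 1), cfg,
                            slab_mean_z = 0, slab_sd_z = 1)
  manual <- 4 * log(0.5) + sum(stats::dnorm(z, 0, 1, log = TRUE)) +
    sum(stats::dnorm(delta, 0, 4, log = TRUE))
  expect_equal(lp, manual)
  ## always-on ablation: forcing the weights to 1 keeps every slab active
  cfg1 <- prior_config(w_kappa_prior = 1, w_h_prior = 1)
  expect_true(is.finite(spike_slab_logprior(z, delta, 1, c(1, 1, 1), cfg1)))
  expect_identical(spike_slab_logprior(z, delta, 0, c(1, 1, 1), cfg1), -Inf)
  expect_error(spike_slab_logprior(z, delta, 0.5, c(1, 1, 1), cfg), "binary")
})

test_that("horseshoe prior: unit scales recover a standard normal", {
  cfg <- prior_config(selection = "horseshoe")
  z <- c(0.5, -1, 0.2, 0, 1.4)
  delta <- c(0.1, -0.6, 0.3)
  lp <- horseshoe_logprior(z, delta, lambda_d = 1, lambda_h = 1,
                           tau_z = 1, tau_delta = 1, cfg)
  scale_mass <- sum(half_cauchy_logpdf(rep(1, 5), 1)) +
    sum(half_cauchy_logpdf(rep(1, 3), 1)) +
    2 * half_cauchy_logpdf(1, 1)
  expect_equal(lp - scale_mass,
               sum(stats::dnorm(c(z, delta), log = TRUE)))
  expect_error(horseshoe_logprior(z, delta, -1, 1, 1, 1, cfg), "non-negative")
  ## default horseshoe scales are all 1
  expect_equal(c(cfg$xi_lambda, cfg$xi_h, cfg$xi_z, cfg$xi_delta), rep(1, 4))
})

test_that("prior configuration round-trips through YAML; empty file = defaults", {
  path <- withr::local_tempfile(fileext = ".yaml")
  cfg <- prior_config(mmax = 25, w_kappa_prior = 0.25,
                      selection = "horseshoe", hierarchy = FALSE)
  write_prior_config(cfg, path)
  expect_equal(read_prior_config(path), cfg)
  empty <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", empty)
  expect_equal(read_prior_config(empty), default_prior_config())
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("not_a_field: 3", bad)
  expect_error(read_prior_config(bad), "unknown prior fields")
})

test_that("generated sampler code reflects the ablation switches", {
  code <- dct_itp_jags_code(default_prior_config(), "dct")
  expect_match(code, "wk ~ dbern\\(0.5")
  expect_match(code, "sigma_k ~ dt\\(0")
  ## removing the hierarchy: independent N(2, 2^2) rates, no mu_k
  code_nh <- dct_itp_jags_code(prior_config(hierarchy = FALSE), "dct")
  expect_match(code_nh, "k\\[a\\] ~ dnorm\\(2, 0.25\\)")
  expect_false(grepl("mu_k", code_nh))
  expect_match(code_nh, "ztilde\\[a\\] ~ dnorm\\(0, 1\\)")
  ## always-on: indicators fixed at 1
  code_on <- dct_itp_jags_code(prior_config(selection = "always_on"), "dct")
  expect_match(code_on, "wk <- 1")
  ## horseshoe: local/global scales instead of indicators
  code_hs <- dct_itp_jags_code(prior_config(selection = "horseshoe"), "dct")
  expect_match(code_hs, "lam_z\\[a\\]")
  expect_false(grepl("dbern", code_hs))
})
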