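test_that("time-effect fraction matches its closed form and limits", {
  p <- scenario1_params()
  expect_equal(time_effect(1, 0, 0, p), 1)
  ## direct scalar evaluation: (1 - e^-1) / (1 - e^-2)
  expect_equal(time_effect(0.5, 0, 0, p), 0.7310585786300049, tolerance = 1e-12)
  ## a zero rate shift leaves the decentralized fraction unchanged
  tgrid <- seq(0, 1, by = 0.1)
  expect_equal(time_effect(tgrid, 2, 1, p), time_effect(tgrid, 2, 0, p))
  ## removable singularity at r = 0: z = -k gives the linear limit t
  p0 <- model_params(k = 1.5, z = -1.5, phi0 = -2.5, phi1 = -30, phi2 = 5)
  expect_equal(time_effect(tgrid, 0, 1, p0), tgrid)
  expect_error(time_effect(-0.2, 0, 0, p), "standardized time")
})

test_that("time-effect is strictly increasing in t and 1 at the terminal time", {
  set.seed(41)
  for (rep in 1:25) {
    r <- runif(1, -6, 6)
    if (abs(r) < 0.05) next
    p <- model_params(k = r, phi0 = -1, phi1 = -10, phi2 = 3)
    v <- time_effect(seq(0, 1, length.out = 40), 0, 0, p)
    expect_true(all(diff(v) > 0))
    expect_equal(v[40], 1)
  }
})

test_that("Emax dose effect reproduces the trial-application values", {
  p <- scenario1_params()
  expect_equal(dose_effect(0, 0, p), -2.5)
  expect_equal(dose_effect(15, 0, p), -25)
  p3 <- scenario3_params()
  ## decentralized terminal loss is 2 kg smaller than onsite
  expect_equal(dose_effect(15, 1, p3) - dose_effect(15, 0, p3), 2)
  ## a non-positive decentralized ED50 is rejected at construction, so the
  ## Emax denominator stays positive for every non-negative dosage
  expect_error(model_params(k = 2, phi0 = 0, phi1 = -30, phi2 = 1,
                            delta2 = -1.2), "delta2")
  expect_error(dose_effect(-1, 0, p), "non-negative")
})

test_that("mean response is the product of the two components", {
  p <- scenario1_params()
  expect_equal(mean_response(0, 15, 4, 0, p), 0)
  expect_equal(mean_response(1, 15, 4, 0, p), -25)
  expect_equal(mean_response(0.5, 15, 4, 0, p),
               0.7310585786300049 * -25, tolerance = 1e-12)
})

test_that("pooling limit: no shift parameters makes sources indistinguishable", {
  p <- scenario1_params()  # z = 0, deltas = 0, starred SDs = 0
  tgrid <- seq(0.1, 1, by = 0.1)
  expect_equal(mean_response(tgrid, 10, 3, 1, p),
               mean_response(tgrid, 10, 3, 0, p))
  sched <- make_schedule()
  sc_dec <- subject_covariance(sched, 4, 15, p)
  on <- rep(0L, 12)
  sc_on <- subject_covariance(sched, 4, 15, p, t = sched$std_time[-1], I = on)
  expect_equal(sc_dec$sigma, sc_on$sigma)
})

test_that("subject covariance has the stated structure", {
  p <- scenario1_params()
  sc <- subject_covariance(make_schedule(), 4, 15, p)
  ## terminal onsite visit: loading 1, variance sigma_s^2 + sigma_e^2
  expect_equal(sc$loadings[12], 1)
  expect_equal(sc$sigma[12, 12], 36 + 25)
  ## decentralized variance inflation: about 1 SD unit in both components
  p2 <- model_params(k = 2, phi0 = -2.5, phi1 = -30, phi2 = 5,
                     sigma_s = 6, sigma_s_star = sqrt(13),
                     sigma_e = 5, sigma_e_star = sqrt(11), n_arms = 5)
  expect_equal(sqrt(36 + 13), 7)
  expect_equal(sqrt(25 + 11), 6)
  sc2 <- subject_covariance(NULL, 4, 15, p2, t = c(0.5, 1), I = c(1L, 1L))
  a <- sc2$loadings
  expect_equal(diag(sc2$sigma), a^2 * (36 + 13) + (25 + 11))
  ## starred between-subject term loads only across decentralized pairs
  sc3 <- subject_covariance(NULL, 4, 15, p2, t = c(0.5, 1), I = c(0L, 1L))
  expect_equal(sc3$sigma[1, 2], sc3$loadings[1] * sc3$loadings[2] * 36)
  ## zero loading leaves only the within-subject diagonal
  sc4 <- subject_covariance(NULL, 4, 15, p2, t = c(0, 1), I = c(0L, 0L))
  expect_equal(sc4$sigma[1, ], c(25, 0))
})

test_that("subject covariance is positive semi-definite for valid parameters", {
  set.seed(99)
  for (rep in 1:20) {
    p <- model_params(k = runif(1, 0.5, 4), z = runif(1, -0.3, 1),
                      phi0 = -2.5, phi1 = runif(1, -35, -20),
                      phi2 = runif(1, 1, 8),
                      sigma_s = runif(1, 0, 8), sigma_s_star = runif(1, 0, 4),
                      sigma_e = runif(1, 0.5, 6), sigma_e_star = runif(1, 0, 4),
                      n_arms = 5)
    I <- rbinom(8, 1, 0.6)
    sc <- subject_covariance(NULL, 2, 5, p, t = sort(runif(8, 0.05, 1)), I = I)
    expect_true(min(eigen(sc$sigma, symmetric = TRUE,
                          only.values = TRUE)$values) > -1e-10)
  }
})

test_that("log-likelihood: trivial case, quadrature oracle, additivity", {
  p <- scenario1_params()
  ## one visit, unit within-subject SD, outcome at the mean
  p1 <- model_params(k = 2, phi0 = -2.5, phi1 = -30, phi2 = 5,
                     sigma_e = 1, n_arms = 5)
  d1 <- trial_data(data.frame(
    subject_id = "s1", arm = 4L, dose_mg = 15, visit = 12L, day = 231,
    std_time = 1, decentralized = 0L, y = -25))
  expect_equal(itp_log_likelihood(d1, p1), -0.5 * log(2 * pi))

  ## marginal MVN equals 1-D quadrature over the subject random effect
  d3 <- trial_data(data.frame(
    subject_id = "s1", arm = 4L, dose_mg = 15, visit = 1:3,
    day = c(7, 14, 21), std_time = c(7, 14, 21) / 231,
    decentralized = 0L, y = c(-3, -5, -7)))
  cond <- function(s) {
    a <- time_effect(d3$std_time, 4, 0, p)
    mu <- a * dose_effect(15, 0, p)
    vapply(s, function(si)
      prod(stats::dnorm(d3$y, mu + a * si, p$sigma_e)) *
        stats::dnorm(si, 0, p$sigma_s), numeric(1))
  }
  oracle <- log(stats::integrate(cond, -80, 80, rel.tol = 1e-13)$value)
  expect_equal(itp_log_likelihood(d3, p), oracle, tolerance = 1e-8)

  ## duplicating a subject doubles the contribution
  d6 <- d3
  d6$subject_id <- "s2"
  both <- trial_data(rbind(as.data.frame(d3), as.data.frame(d6)))
  expect_equal(itp_log_likelihood(both, p), 2 * itp_log_likelihood(d3, p))

  ## missing outcomes are excluded, not imputed, in the marginal density
  dm <- as.data.frame(d3)
  dm$y[2] <- NA
  d2 <- trial_data(dm[!is.na(dm$y), ])
  expect_equal(itp_log_likelihood(trial_data(dm), p), itp_log_likelihood(d2, p))
})

test_that("log-likelihood with decentralized visits matches 2-D quadrature", {
  p <- scenario3_params()
  dd <- trial_data(data.frame(
    subject_id = "s1", arm = 4L, dose_mg = 15, visit = 1:3,
    day = c(7, 63, 231), std_time = c(7, 63, 231) / 231,
    decentralized = c(1L, 0L, 1L), y = c(-6, -14, -22)))
  a <- vapply(1:3, function(i)
    time_effect(dd$std_time[i], 4, dd$decentralized[i], p), numeric(1))
  mu <- a * dose_effect(15, dd$decentralized, p)
  Ivec <- dd$decentralized
  inner <- function(s, ss) {
    m <- mu + a * (s + Ivec * ss)
    sd <- sqrt(p$sigma_e^2 + Ivec * p$sigma_e_star^2)
    prod(stats::dnorm(dd$y, m, sd)) * stats::dnorm(s, 0, p$sigma_s) *
      stats::dnorm(ss, 0, p$sigma_s_star)
  }
  outer_f <- function(s) vapply(s, function(si)
    stats::integrate(function(ss) vapply(ss, function(x) inner(si, x),
                                         numeric(1)),
                     -40, 40, rel.tol = 1e-11)$value, numeric(1))
  oracle <- log(stats::integrate(outer_f, -60, 60, rel.tol = 1e-11)$value)
  expect_equal(itp_log_likelihood(dd, p), oracle, tolerance = 1e-6)
})
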