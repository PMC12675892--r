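test_that("fits are bit-reproducible and respect the retained-draw contract", {
  tt <- tiny_trial(missing_frac = 0.15)
  f1 <- fit_quietly(tt$data, mcmc = fast_mcmc(7), variant = "dct")
  f2 <- fit_quietly(tt$data, mcmc = fast_mcmc(7), variant = "dct")
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$imputed, f2$imputed)
  expect_equal(nrow(f1$draws), 400)  # n_iter / thin
  expect_true(all(f1$inclusion >= 0 & f1$inclusion <= 1))
  ## imputed draws exist exactly for the missing records
  miss <- tt$data[is.na(tt$data$y), c("subject_id", "visit")]
  got <- f1$imputed_map[order(f1$imputed_map$subject_id, f1$imputed_map$visit), ]
  want <- as.data.frame(miss)[order(miss$subject_id, miss$visit), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("complete data yields no imputation draws", {
  tt <- tiny_trial(missing_frac = 0)
  f <- fit_quietly(tt$data, mcmc = fast_mcmc(3), variant = "dct")
  expect_equal(ncol(f$imputed), 0L)
  expect_equal(nrow(f$imputed_map), 0L)
})

test_that("comparator variants restrict the data as specified", {
  tt <- tiny_trial(missing_frac = 0.1)
  expect_error(fit_itp(tt$data, mcmc = fast_mcmc(1), variant = "t"),
               "all-onsite")
  fo <- fit_quietly(tt$data, mcmc = fast_mcmc(1), variant = "o")
  ## onsite-only: no decentralized parameters in the posterior
  expect_false(any(grepl("^z\\[", colnames(fo$draws))))
  expect_false("sigma_sstar" %in% colnames(fo$draws))
  fm <- fit_quietly(tt$data, mcmc = fast_mcmc(1), variant = "m")
  expect_false(any(grepl("^delta\\[", colnames(fm$draws))))
  ## all-missing subjects are dropped with a warning
  dat <- tt$data
  dat$y[dat$subject_id == dat$subject_id[1]] <- NA
  expect_warning(fit_itp(dat, mcmc = fast_mcmc(1), variant = "m"),
                 "no observed outcomes")
})

test_that("DCT fit on all-onsite data agrees with the traditional fit", {
  spec <- scenario_spec(n_per_arm = 10, doses = c(0, 15))
  sched <- visit_schedule(c(0, 14, 28, 42, 56), rep(FALSE, 4))
  dat <- simulate_outcomes(spec, sched, seed = 13)
  fd <- fit_quietly(dat, mcmc = fast_mcmc(5), variant = "dct")
  ft <- fit_quietly(dat, mcmc = fast_mcmc(6), variant = "t")
  ## pooling limit: overlapping 95% intervals for the maximum effect
  qd <- quantile(fd$draws[, "phi1"], c(0.025, 0.975))
  qt <- quantile(ft$draws[, "phi1"], c(0.025, 0.975))
  expect_true(qd[1] < qt[2] && qt[1] < qd[2])
})

test_that("imputation step matches its closed-form conditional mean", {
  p <- scenario3_params()
  dat <- tiny_trial(missing_frac = 0.3, seed = 4)$data
  s <- c(2, -1); s_star <- c(0.5, 1.5)
  ids <- unique(dat$subject_id)
  s <- stats::setNames(rep_len(s, length(ids)), ids)
  s_star <- stats::setNames(rep_len(s_star, length(ids)), ids)

  ## all variance draws zero: imputations equal the conditional mean
  p0 <- model_params(k = p$k, z = p$z, phi0 = p$phi0, phi1 = p$phi1,
                     phi2 = p$phi2, delta0 = p$delta0, delta1 = p$delta1)
  set.seed(1)
  imp <- impute_missing(p0, s * 0, s_star * 0, dat)
  rows <- dat[is.na(dat$y), ]
  mu <- mapply(function(t, m, d, I) mean_response(t, m, d, I, p0),
               rows$std_time, rows$dose_mg, rows$arm, rows$decentralized)
  expect_equal(imp$y, unname(mu))

  ## Monte-Carlo mean of repeated imputations hits mu + a (s + I s*)
  set.seed(2)
  reps <- replicate(4000, impute_missing(p, s, s_star, dat)$y)
  a <- mapply(function(t, d, I) time_effect(t, d, I, p),
              rows$std_time, rows$arm, rows$decentralized)
  target <- mu + a * (s[as.character(rows$subject_id)] +
                        rows$decentralized * s_star[as.character(rows$subject_id)])
  mc_se <- sqrt(p$sigma_e^2 + rows$decentralized * p$sigma_e_star^2) / sqrt(4000)
  expect_true(all(abs(rowMeans(reps) - target) < 4 * mc_se + 1e-9))

  ## onsite missing visits never receive decentralized noise
  p_on <- model_params(k = 2, phi0 = -2.5, phi1 = -30, phi2 = 5,
                       sigma_e = 0, sigma_e_star = 3, n_arms = 5)
  set.seed(3)
  imp_on <- impute_missing(p_on, s, s_star, dat)
  onsite <- rows$decentralized == 0L
  mu_on <- mapply(function(t, m, d, I) mean_response(t, m, d, I, p_on),
                  rows$std_time, rows$dose_mg, rows$arm, rows$decentralized)
  expect_equal(imp_on$y[onsite],
               unname(mu_on[onsite] + a[onsite] * s[as.character(rows$subject_id)][onsite]))
})

test_that("Geweke diagnostic behaves under null, drift, and degenerate chains", {
  ## i.i.d. chains: roughly nominal rejection at the 5% level
  set.seed(1234)
  p <- replicate(120, geweke_diagnostic(rnorm(800)))
  expect_lt(mean(p < 0.05), 0.15)
  expect_gt(mean(p < 0.5), 0.25)   # p-values are not clumped near 1
  ## a strong linear drift is detected
  expect_lt(geweke_diagnostic(seq(0, 10, length.out = 2000)
                              + rnorm(2000, 0, 0.05)), 0.001)
  ## equal early/late segment means give z = 0, p = 1 (the compared
  ## windows are the first 10% and last 50% of the chain)
  set.seed(5)
  v <- rnorm(1000)
  v[500:1000] <- v[500:1000] - mean(v[500:1000]) + mean(v[1:101])
  expect_equal(unname(geweke_diagnostic(v)), 1)
  expect_warning(pconst <- geweke_diagnostic(rep(2, 100)), "constant")
  expect_equal(unname(pconst), 1)
  expect_error(geweke_diagnostic(rnorm(10)), "too short")
})

test_that("fit export writes draws and a summary", {
  tt <- tiny_trial(missing_frac = 0.1)
  f <- fit_quietly(tt$data, mcmc = fast_mcmc(2), variant = "dct")
  dir <- withr::local_tempdir()
  write_fit(f, dir)
  expect_true(file.exists(file.path(dir, "draws.csv")))
  expect_true(file.exists(file.path(dir, "imputed.csv")))
  sm <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(sm$variant, "dct")
  expect_true(is.numeric(sm$posterior_mean$phi1))
  expect_true(all(c("inclusion", "geweke_p") %in% names(sm)))
})
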