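#' Simulate complete trial outcomes
#'
#' Generates a complete (no missingness) hybrid decentralized trial
#' under a [scenario_spec()]. Each subject is randomized to an arm,
#' draws a between-subject effect `s ~ N(0, sigma_s2)` and a
#' decentralized add-on `s* ~ N(0, sigma_s_star2)` once, and each visit
#' adds within-subject noise `e` (plus `e*` when decentralized). Actual
#' visit days are jittered by a whole number of days drawn uniformly on
#' the visit window, and standardized by the last *scheduled* day, so
#' the terminal visit of a jittered subject may standardize slightly
#' away from 1; the mean model is evaluated at the actual standardized
#' times. The outcome is
#' \deqn{Y = \kappa(t; k_d + I z_d)\,\lambda(m_d, I) + \kappa(t)(s + I
#'   s^*) + e + I e^*,} with \eqn{\lambda} from the scenario's
#' dose-response family.
#'
#' @param spec a [scenario_spec()].
#' @param schedule a [visit_schedule()]; defaults to the scenario's
#'   schema.
#' @param seed integer seed.
#' @return a complete [trial_data()].
#' @export
simulate_outcomes <- function(spec, schedule = make_schedule(spec$schedule_id),
                              seed = 1) {
  stopifnot(inherits(spec, "scenario_spec"),
            inherits(schedule, "visit_schedule"))
  set.seed(seed)
  post <- schedule[schedule$visit >= 1L, , drop = FALSE]
  L <- nrow(post)
  last_day <- attr(schedule, "last_day")
  window <- attr(schedule, "window")
  A <- length(spec$doses)
  n <- spec$n_per_arm
  I <- as.integer(post$decentralized)

  rows <- vector("list", A * n)
  idx <- 0L
  for (a in seq_len(A)) {
    lam <- vapply(c(0L, 1L), function(Iv)
      scenario_lambda(spec, spec$doses[a], Iv), numeric(1))
    for (j in seq_len(n)) {
      idx <- idx + 1L
      sid <- sprintf("a%d_s%02d", a - 1L, j)
      s <- stats::rnorm(1, 0, sqrt(spec$sigma_s2))
      s_star <- stats::rnorm(1, 0, sqrt(spec$sigma_s_star2))
      jitter <- sample(-window:window, L, replace = TRUE)
      day <- post$day + jitter
      t <- day / last_day
      r <- spec$k[a] + I * spec$z[a]
      kp <- .kappa(t, r)
      e <- stats::rnorm(L, 0, sqrt(spec$sigma_e2))
      e_star <- stats::rnorm(L, 0, sqrt(spec$sigma_e_star2))
      y <- kp * lam[I + 1L] + kp * (s + I * s_star) + e + I * e_star
      rows[[idx]] <- data.frame(
        subject_id = sid, arm = a - 1L, dose_mg = spec$doses[a],
        visit = post$visit, day = day, std_time = t,
        decentralized = I, y = y
      )
    }
  }
  trial_data(do.call(rbind, rows))
}

#' Apply dropout and intermittent missingness
#'
#' Walks each subject sequentially through the post-treatment visits and
#' applies the missingness mechanism of a [missingness_config()]:
#' outcome-dependent dropout first (absorbing — once a subject drops
#' out, that visit and all later ones are missing), then, for subjects
#' still active, intermittent missingness (and optionally an extra
#' completely-at-random component). Both Bernoulli draws depend only on
#' the previous visit's generated outcome and the scheduled time, never
#' on the current value, so the mechanism is missing-at-random given the
#' generated history.
#'
#' @param data a complete [trial_data()] (sorted by subject, visit).
#' @param cfg a [missingness_config()].
#' @param schedule the [visit_schedule()] used to generate `data`
#'   (supplies scheduled standardized times).
#' @param seed integer seed.
#' @return the [trial_data()] with missing outcomes set to `NA`;
#'   attribute `dropout` is a data frame with each subject's dropout
#'   visit (`NA` when the subject completed the trial).
#' @export
apply_missingness <- function(data, cfg = missingness_config(),
                              schedule = make_schedule(), seed = 1) {
  data <- as_trial_data(data)
  stopifnot(inherits(cfg, "missingness_config"),
            inherits(schedule, "visit_schedule"))
  set.seed(seed)
  data <- data[order(data$subject_id, data$visit), , drop = FALSE]
  t_sched <- if (cfg$log_time == "days")
    schedule$day[match(data$visit, schedule$visit)]
  else schedule$std_time[match(data$visit, schedule$visit)]
  if (anyNA(t_sched)) stop("data contains visits not in the schedule")

  mixed <- cfg$mechanism == "mixed_mcar_mar_dropout"
  beta0 <- if (mixed) cfg$beta0_mixed else cfg$beta0

  ids <- unique(data$subject_id)
  dropout_visit <- rep(NA_integer_, length(ids))
  names(dropout_visit) <- ids
  y_out <- data$y
  for (g in split(seq_len(nrow(data)), match(data$subject_id, ids))) {
    y_prev <- 0
    dropped <- FALSE
    for (i in g) {
      if (dropped) {
        y_out[i] <- NA_real_
        next
      }
      tl <- t_sched[i]
      p_drop <- if (mixed) cfg$dropout_hazard else
        stats::plogis(cfg$alpha0 + cfg$alpha1 * y_prev + cfg$alpha2 * log(tl))
      if (stats::runif(1) < p_drop) {
        dropped <- TRUE
        dropout_visit[data$subject_id[i]] <- data$visit[i]
        y_out[i] <- NA_real_
        y_prev <- data$y[i]
        next
      }
      Il <- data$decentralized[i]
      p_int <- stats::plogis((beta0 + Il * cfg$delta_beta0) +
                             (cfg$beta1 + Il * cfg$delta_beta1) * y_prev +
                             cfg$beta2 * log(tl))
      miss <- stats::runif(1) < p_int
      if (!miss && cfg$mcar_rate > 0)
        miss <- stats::runif(1) < cfg$mcar_rate
      if (miss) y_out[i] <- NA_real_
      y_prev <- data$y[i]   # the true generated outcome, even if missing
    }
  }
  data$y <- y_out
  attr(data, "dropout") <- data.frame(subject_id = ids,
                                      dropout_visit = unname(dropout_visit))
  data
}

#' Simulate a full trial dataset
#'
#' Convenience wrapper: [simulate_outcomes()] followed by
#' [apply_missingness()] with the scenario's missingness configuration.
#' The outcome and missingness draws use distinct seeds derived from
#' `seed` so the two stages are independent.
#'
#' @inheritParams simulate_outcomes
#' @export
simulate_trial <- function(spec, schedule = make_schedule(spec$schedule_id),
                           seed = 1) {
  complete <- simulate_outcomes(spec, schedule, seed = seed)
  apply_missingness(complete, spec$missingness, schedule,
                    seed = seed + 500000L)
}
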