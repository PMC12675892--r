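## Clinical estimands computed from posterior draws, their summaries,
## and the simulation-study metrics. All estimands target the
## centralized (I = 0) curve, so every model variant is compared against
## the same truth.

.auc_nodes <- function(schedule) schedule$std_time  # includes t0 = 0

.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + y[-1]) / 2)

#' Per-draw estimand values
#'
#' Evaluates one of the four clinical estimands on each retained
#' posterior draw, always on the centralized (I = 0) curve:
#' * `"mu"` — mean response at the final visit, \eqn{\mu_d =
#'   \lambda(m_d)}; defined for any dosage on the continuous Emax curve
#'   (default grid 0..15 mg).
#' * `"dmu"` — placebo-subtracted terminal response \eqn{\mu_d - \mu_0}
#'   (default grid 1..15 mg).
#' * `"auc"` — area under the longitudinal mean curve
#'   \eqn{\mu(t, d) = \kappa(t; k_d)\lambda(m_d)} over the scheduled
#'   standardized times (trapezoidal rule on the schedule nodes,
#'   including \eqn{t_0 = 0}); needs the arm-specific rate draw, so the
#'   grid must consist of randomized arm dosages (default: all arms).
#' * `"dauc"` — \eqn{AUC_d - AUC_0} (default: active arms).
#'
#' @param fit an `itp_fit` from [fit_itp()].
#' @param estimand `"auc"`, `"dauc"`, `"mu"`, or `"dmu"`.
#' @param dose_grid dosages (mg) at which to evaluate; defaults above.
#' @param schedule the [visit_schedule()] supplying the quadrature nodes
#'   for the AUC estimands.
#' @return a draws x doses matrix; columns named by dosage. The node set
#'   used for AUC is recorded in attribute `nodes`.
#' @export
estimand_draws <- function(fit, estimand = c("auc", "dauc", "mu", "dmu"),
                           dose_grid = NULL, schedule = make_schedule()) {
  estimand <- match.arg(estimand)
  stopifnot(inherits(fit, "itp_fit"))
  dr <- fit$draws
  lam <- function(m) dr[, "phi0"] + dr[, "phi1"] * m / (dr[, "phi2"] + m)
  if (estimand %in% c("mu", "dmu")) {
    if (is.null(dose_grid))
      dose_grid <- if (estimand == "mu") 0:15 else 1:15
    out <- vapply(dose_grid, lam, numeric(nrow(dr)))
    if (estimand == "dmu") out <- out - lam(0)
  } else {
    if (is.null(dose_grid)) {
      dose_grid <- fit$arms$dose
      if (estimand == "dauc") dose_grid <- dose_grid[dose_grid > 0]
    }
    nodes <- .auc_nodes(schedule)
    auc_one <- function(m) {
      a <- fit$arms$arm[match(m, fit$arms$dose)]
      if (is.na(a))
        stop("AUC needs a randomized arm dosage; ", m, " mg is not one")
      kd <- dr[, sprintf("k[%d]", a + 1L)]
      lm <- lam(m)
      kp <- vapply(nodes, function(tt) .kappa(rep(tt, nrow(dr)), kd),
                   numeric(nrow(dr)))
      apply(kp * lm, 1, function(v) .trapz(nodes, v))
    }
    out <- vapply(dose_grid, auc_one, numeric(nrow(dr)))
    if (estimand == "dauc") out <- out - auc_one(0)
    attr(out, "nodes") <- nodes
  }
  colnames(out) <- dose_grid
  out
}

#' Posterior summaries of estimand draws
#'
#' Posterior mean and the 2.5% / 97.5% quantiles per dose. Quantiles use
#' R's default linear-interpolation convention (type 7).
#'
#' @param draws a draws x doses matrix from [estimand_draws()].
#' @return a data frame with columns `dose`, `mean`, `lower`, `upper`.
#' @export
summarize_estimands <- function(draws) {
  draws <- as.matrix(draws)
  if (nrow(draws) < 2L) stop("need at least 2 draws to summarize")
  out <- data.frame(
    dose = as.numeric(colnames(draws)),
    mean = colMeans(draws),
    lower = apply(draws, 2, stats::quantile, 0.025),
    upper = apply(draws, 2, stats::quantile, 0.975)
  )
  rownames(out) <- NULL
  stopifnot(all(out$lower <= out$upper))
  out
}

#' True estimand values under a scenario
#'
#' The generating truth for an estimand on the centralized curve:
#' terminal response from the scenario's onsite dose-response family,
#' AUC from the trapezoid of \eqn{\kappa(t; k_d)\lambda(m_d)} over the
#' schedule nodes.
#'
#' @param spec a [scenario_spec()].
#' @param estimand as in [estimand_draws()].
#' @param dose_grid dosages; same defaults as [estimand_draws()].
#' @param schedule a [visit_schedule()].
#' @return named numeric vector of truths, one per dose.
#' @export
true_estimand <- function(spec, estimand = c("auc", "dauc", "mu", "dmu"),
                          dose_grid = NULL, schedule = make_schedule()) {
  estimand <- match.arg(estimand)
  stopifnot(inherits(spec, "scenario_spec"))
  if (estimand %in% c("mu", "dmu")) {
    if (is.null(dose_grid))
      dose_grid <- if (estimand == "mu") 0:15 else 1:15
    out <- scenario_lambda(spec, dose_grid, 0)
    if (estimand == "dmu") out <- out - scenario_lambda(spec, 0, 0)
  } else {
    if (is.null(dose_grid)) {
      dose_grid <- spec$doses
      if (estimand == "dauc") dose_grid <- dose_grid[dose_grid > 0]
    }
    nodes <- .auc_nodes(schedule)
    auc_one <- function(m) {
      a <- match(m, spec$doses)
      if (is.na(a)) stop("AUC truth needs an arm dosage")
      .trapz(nodes, .kappa(nodes, spec$k[a]) * scenario_lambda(spec, m, 0))
    }
    out <- vapply(dose_grid, auc_one, numeric(1))
    if (estimand == "dauc") out <- out - auc_one(0)
  }
  names(out) <- dose_grid
  out
}

#' Simulation-study metrics
#'
#' Aggregates per-replication estimand summaries into the four
#' dose-averaged metrics:
#' \deqn{AB = \frac{1}{|D|}\sum_d \frac{1}{N}\sum_n (\hat\Theta_{d,n} -
#'   \Theta_d), \quad
#'   ARMSE = \frac{1}{|D|}\sum_d \sqrt{\frac{1}{N}\sum_n
#'   (\hat\Theta_{d,n} - \Theta_d)^2},}
#' \deqn{ACP = \frac{1}{|D|}\sum_d \frac{1}{N}\sum_n
#'   1\{\Theta_d \in (\hat\Theta^l_{d,n}, \hat\Theta^u_{d,n})\}, \quad
#'   AL = \frac{1}{|D|}\sum_d \frac{1}{N}\sum_n
#'   (\hat\Theta^u_{d,n} - \hat\Theta^l_{d,n}).}
#'
#' @param results list of per-replication data frames from
#'   [summarize_estimands()] (identical dose grids).
#' @param truths named truth vector as from [true_estimand()].
#' @return a one-row data frame with `AB`, `ARMSE`, `ACP`, `AL`; the
#'   per-dose breakdown is in attribute `per_dose`.
#' @export
simulation_metrics <- function(results, truths) {
  if (!length(results)) stop("no replications supplied")
  doses <- results[[1]]$dose
  for (r in results) {
    if (!identical(r$dose, doses))
      stop("replications use mismatched dose grids")
  }
  if (length(truths) != length(doses))
    stop("'truths' must supply one value per dose")
  est <- vapply(results, function(r) r$mean, numeric(length(doses)))
  lo <- vapply(results, function(r) r$lower, numeric(length(doses)))
  up <- vapply(results, function(r) r$upper, numeric(length(doses)))
  est <- matrix(est, nrow = length(doses))
  lo <- matrix(lo, nrow = length(doses))
  up <- matrix(up, nrow = length(doses))
  err <- est - truths
  per_dose <- data.frame(
    dose = doses,
    bias = rowMeans(err),
    rmse = sqrt(rowMeans(err^2)),
    coverage = rowMeans(lo < truths & truths < up),
    length = rowMeans(up - lo)
  )
  out <- data.frame(AB = mean(per_dose$bias),
                    ARMSE = mean(per_dose$rmse),
                    ACP = mean(per_dose$coverage),
                    AL = mean(per_dose$length))
  attr(out, "per_dose") <- per_dose
  out
}
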