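#' Visit schedules for hybrid decentralized trials
#'
#' A visit schedule lists the scheduled study days (baseline = day 0), the
#' standardized times \eqn{t_l = \mathrm{day}_l / \mathrm{day}_L} (so
#' \eqn{t_0 = 0} and \eqn{t_L = 1}), and a per-visit decentralization
#' indicator (\eqn{I_l = 1} for an offsite/remote measurement, 0 for an
#' onsite visit). The baseline visit is always onsite.
#'
#' @param days integer vector of scheduled days, starting at 0 and strictly
#'   increasing.
#' @param decentralized logical (or 0/1) vector, one entry per
#'   post-baseline visit, or of the same length as `days` with the first
#'   entry `FALSE`.
#' @param window visit tolerance in days: an observation within
#'   \eqn{[\mathrm{day}_l - \epsilon, \mathrm{day}_l + \epsilon]} counts
#'   for visit l, otherwise the visit is missing.
#' @return A `visit_schedule` data frame with columns `visit`, `day`,
#'   `std_time`, `decentralized`, and attributes `window` and `last_day`.
#' @export
visit_schedule <- function(days, decentralized, window = 3) {
  days <- as.numeric(days)
  if (length(days) < 2L)
    stop("a schedule needs a baseline and at least one post-treatment visit")
  if (days[1] != 0)
    stop("the first scheduled day (baseline) must be day 0")
  if (any(diff(days) <= 0))
    stop("scheduled days must be strictly increasing")
  dec <- as.logical(decentralized)
  if (length(dec) == length(days) - 1L) dec <- c(FALSE, dec)
  if (length(dec) != length(days))
    stop("'decentralized' must have one entry per visit (or per post-baseline visit)")
  if (dec[1])
    stop("the baseline visit must be onsite")
  if (window < 0) stop("'window' must be non-negative")
  out <- data.frame(
    visit = seq_along(days) - 1L,
    day = days,
    std_time = days / days[length(days)],
    decentralized = dec
  )
  attr(out, "window") <- window
  attr(out, "last_day") <- days[length(days)]
  class(out) <- c("visit_schedule", "data.frame")
  out
}

#' Built-in visit schemas
#'
#' `default12` is the weight-management trial layout: 12 post-treatment
#' visits over 231 days — visits 1-3 weekly, 4-6 biweekly, 7-12 every four
#' weeks — with onsite measurement at the baseline and at visits 1, 6 and
#' 12, all other visits decentralized, and a visit window of \eqn{\pm}3
#' days. The three sensitivity schemas keep the same cadence idea:
#' `schema8_5dec` has 8 visits of which 5 are decentralized,
#' `schema12_4dec` has the `default12` days with only 4 decentralized
#' visits, and `schema15_9dec` has 15 visits of which 9 are decentralized.
#'
#' @param schema one of `"default12"`, `"schema8_5dec"`, `"schema12_4dec"`,
#'   `"schema15_9dec"`.
#' @return a [visit_schedule()].
#' @examples
#' make_schedule("default12")
#' @export
make_schedule <- function(schema = "default12") {
  valid <- c("default12", "schema8_5dec", "schema12_4dec", "schema15_9dec")
  if (!is.character(schema) || length(schema) != 1L || !(schema %in% valid))
    stop("unknown schema; valid ids: ", paste(valid, collapse = ", "))
  switch(schema,
    default12 = visit_schedule(
      days = c(0, 7, 14, 21, 35, 49, 63, 91, 119, 147, 175, 203, 231),
      decentralized = !(1:12 %in% c(1, 6, 12))
    ),
    schema8_5dec = visit_schedule(
      days = c(0, 7, 14, 28, 42, 70, 98, 126, 154),
      decentralized = !(1:8 %in% c(1, 5, 8))
    ),
    schema12_4dec = visit_schedule(
      days = c(0, 7, 14, 21, 35, 49, 63, 91, 119, 147, 175, 203, 231),
      decentralized = (1:12 %in% c(2, 4, 8, 10))
    ),
    schema15_9dec = visit_schedule(
      days = c(0, 7, 14, 21, 28, 42, 56, 70, 84, 112, 140, 168, 196, 224,
               252, 280),
      decentralized = !(1:15 %in% c(1, 3, 6, 9, 12, 15))  # 9 decentralized
    )
  )
}

#' @export
print.visit_schedule <- function(x, ...) {
  L <- nrow(x) - 1L
  cat(sprintf(
    "Visit schedule: %d post-treatment visits over %d days (window +/- %g days)\n",
    L, attr(x, "last_day"), attr(x, "window")
  ))
  cat(sprintf("  decentralized visits: %s\n",
              paste(x$visit[x$decentralized], collapse = ", ")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
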