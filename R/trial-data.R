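#' Long-format trial data
#'
#' One row per subject-visit with the columns `subject_id`, `arm`
#' (0 = placebo), `dose_mg`, `visit` (post-treatment index 1..L), `day`
#' (actual day, possibly jittered), `std_time` (actual day divided by the
#' last *scheduled* day), `decentralized` (0/1), and `y` (change from
#' baseline in kg; `NA` = missing). The baseline visit is not stored: the
#' change from baseline at \eqn{t_0} is identically zero.
#'
#' @param df a data frame with the columns above.
#' @return a validated `trial_data` data frame.
#' @export
trial_data <- function(df) {
  req <- c("subject_id", "arm", "dose_mg", "visit", "day",
           "std_time", "decentralized", "y")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[req]
  df$arm <- as.integer(df$arm)
  df$visit <- as.integer(df$visit)
  df$decentralized <- as.integer(df$decentralized)
  if (any(duplicated(df[c("subject_id", "visit")])))
    stop("duplicate (subject_id, visit) records")
  if (any(df$visit < 1L))
    stop("only post-treatment visits (visit >= 1) are stored")
  if (any(!df$decentralized %in% c(0L, 1L)))
    stop("'decentralized' must be 0 or 1")
  if (any(df$arm < 0L)) stop("'arm' must be a non-negative index")
  if (any(df$dose_mg < 0)) stop("'dose_mg' must be non-negative")
  bad <- tapply(df$dose_mg, df$arm, function(x) length(unique(x)) > 1L)
  if (any(bad)) stop("an arm must have a single dosage")
  class(df) <- c("trial_data", "data.frame")
  df
}

#' @rdname trial_data
#' @export
as_trial_data <- function(df) {
  if (inherits(df, "trial_data")) df else trial_data(df)
}

#' @export
print.trial_data <- function(x, ...) {
  arms <- unique(x[c("arm", "dose_mg")])
  arms <- arms[order(arms$arm), ]
  cat(sprintf(
    "Trial data: %d subjects, %d arms (%s mg), %d records (%.1f%% missing)\n",
    length(unique(x$subject_id)), nrow(arms),
    paste(arms$dose_mg, collapse = ", "),
    nrow(x), 100 * mean(is.na(x$y))
  ))
  print(utils::head(as.data.frame(x), 8), row.names = FALSE)
  if (nrow(x) > 8) cat("...\n")
  invisible(x)
}

#' Read / write trial data as CSV
#'
#' The on-disk format is a plain CSV with the `trial_data` header; an
#' empty `y` field marks a missing outcome. Numeric fields are written
#' with 17 significant digits so a write/read round-trip reproduces the
#' data exactly.
#'
#' @param path file path.
#' @return `read_trial_csv` returns a [trial_data()]; `write_trial_csv`
#'   returns `path` invisibly.
#' @export
read_trial_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c(
    subject_id = "character", arm = "integer", dose_mg = "numeric",
    visit = "integer", day = "numeric", std_time = "numeric",
    decentralized = "integer", y = "numeric"
  ), na.strings = "")
  out <- tryCatch(trial_data(df), error = function(e) {
    dup <- duplicated(df[c("subject_id", "visit")])
    if (any(dup))
      stop("malformed trial CSV at data line ", which(dup)[1], ": ",
           conditionMessage(e), call. = FALSE)
    stop("malformed trial CSV: ", conditionMessage(e), call. = FALSE)
  })
  out
}

#' @rdname read_trial_csv
#' @param data a [trial_data()].
#' @export
write_trial_csv <- function(data, path) {
  data <- as_trial_data(data)
  out <- data.frame(
    subject_id = as.character(data$subject_id),
    arm = data$arm,
    dose_mg = sprintf("%.17g", data$dose_mg),
    visit = data$visit,
    day = sprintf("%.17g", data$day),
    std_time = sprintf("%.17g", data$std_time),
    decentralized = data$decentralized,
    y = ifelse(is.na(data$y), "", sprintf("%.17g", data$y)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
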