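## Tabular observation files and fit/study reports.

.obs_header <- c("subject_id", "time_d", "sa_fod_per_umol")

#' Read or write plasma observation tables
#'
#' Observations are CSV files with the exact header
#' `subject_id,time_d,sa_fod_per_umol`: one row per plasma sample, time in
#' decimal days and specific activity in fraction of dose per µmol plasma
#' retinol.  Malformed, blank or negative entries are rejected with the
#' offending line number; duplicate (subject, time) pairs are rejected.
#'
#' @param path CSV file path.
#' @return `read_observations()` returns a data frame with columns
#'   `subject_id`, `time`, `sa_p` (the package-internal column names);
#'   `write_observations()` returns `path` invisibly.
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop("observation file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = c("character", "character", "character"),
                         strip.white = TRUE)
  if (!identical(names(raw), .obs_header))
    stop("observation file must have header ",
         paste(.obs_header, collapse = ","), call. = FALSE)
  if (nrow(raw) == 0L)
    return(data.frame(subject_id = character(), time = numeric(),
                      sa_p = numeric(), stringsAsFactors = FALSE))
  line_no <- seq_len(nrow(raw)) + 1L  # header is line 1
  time <- suppressWarnings(as.numeric(raw$time_d))
  sa <- suppressWarnings(as.numeric(raw$sa_fod_per_umol))
  bad <- raw$subject_id == "" | is.na(time) | is.na(sa)
  if (any(bad))
    stop("malformed observation row(s) at line(s) ",
         paste(line_no[bad], collapse = ", "), call. = FALSE)
  neg <- time < 0 | sa < 0
  if (any(neg))
    stop("negative time or specific activity at line(s) ",
         paste(line_no[neg], collapse = ", "), call. = FALSE)
  dup <- duplicated(paste(raw$subject_id, time, sep = "\r"))
  if (any(dup))
    stop("duplicate (subject, time) pair(s) at line(s) ",
         paste(line_no[dup], collapse = ", "), call. = FALSE)
  data.frame(subject_id = raw$subject_id, time = time, sa_p = sa,
             stringsAsFactors = FALSE)
}

#' @rdname read_observations
#' @param observations Data frame with columns `subject_id`, `time`, `sa_p`.
#' @export
write_observations <- function(observations, path) {
  observations <- check_observations(observations)
  df <- data.frame(subject_id = observations$subject_id,
                   time_d = format(observations$time, digits = 17, trim = TRUE),
                   sa_fod_per_umol = format(observations$sa_p, digits = 17,
                                            trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a composite fit report
#'
#' Writes the fitted parameters, fractional standard deviations, objective
#' and convergence status as JSON, and the per-observation weighted
#' residuals as CSV alongside it.
#'
#' @param fit An [rid_fit][fit_composite()].
#' @param path Path of the JSON report; the residual CSV gets the same name
#'   with suffix `_residuals.csv`.
#' @param seed Optional seed to record in the report.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path, seed = NULL) {
  stopifnot(inherits(fit, "rid_fit"))
  report <- list(
    params = unclass(fit$params),
    free = fit$free, fixed = fit$fixed,
    fcv = as.list(fit$fcv),
    converged = fit$converged,
    objective = fit$objective,
    n_obs = fit$n_obs,
    tbs = steady_state(fit$params)$tbs,
    seed = seed
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  res_path <- sub("\\.json$", "", path)
  utils::write.csv(data.frame(weighted_residual = fit$residuals),
                   paste0(res_path, "_residuals.csv"), row.names = FALSE)
  invisible(path)
}
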