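# Label-incorporation dynamics: linear slopes of abundance vs time.

#' Fit a linear slope of abundance versus time
#'
#' Ordinary least squares through all (time, abundance) points pooled across
#' replicates, via [stats::lm()]. Used to estimate the initial rate of label
#' incorporation from a corrected time course.
#'
#' @param time Time points (h), one per observation; at least two distinct
#'   values.
#' @param abundance Relative abundance (fraction or %) per observation.
#' @return A `slope_estimate`: list with `slope` (per h), `intercept`,
#'   `stderr` (standard error of the slope; 0 for a perfect 2-point fit) and
#'   `n` (number of observations).
#' @examples
#' fit_slope(c(0, 24), c(0, 46.7))$slope  # 1.95 %/h
#' @export
fit_slope <- function(time, abundance) {
  if (length(time) != length(abundance)) {
    stop("time and abundance must have equal length", call. = FALSE)
  }
  keep <- is.finite(time) & is.finite(abundance)
  time <- time[keep]
  abundance <- abundance[keep]
  if (length(unique(time)) < 2L) {
    stop("at least two distinct time points are required", call. = FALSE)
  }
  fit <- stats::lm(abundance ~ time)
  cf <- stats::coef(fit)
  # a perfect (noise-free) fit makes summary.lm warn; stderr is then 0
  se <- tryCatch(
    suppressWarnings(summary(fit)$coefficients["time", "Std. Error"]),
    error = function(e) NA_real_)
  if (!is.finite(se)) se <- 0
  structure(list(slope = unname(cf["time"]), intercept = unname(cf[1L]),
                 stderr = se, n = length(time)),
            class = "slope_estimate")
}

#' @export
print.slope_estimate <- function(x, ...) {
  cat(sprintf("<slope> %.4g +/- %.2g per h (intercept %.4g, n = %d)\n",
              x$slope, x$stderr, x$intercept, x$n))
  invisible(x)
}

#' Slopes for every isotopologue of a time course table
#'
#' @param timecourse data.frame with a `time` column and one column per
#'   isotopologue (typically the `fractions` table of a
#'   [correct_isotopologues()] result, times 100 for %).
#' @param per_replicate If `TRUE`, fit each replicate separately (replicates
#'   identified by the `sample` column) and average the slopes; default is a
#'   single pooled fit.
#' @return data.frame with columns `label`, `slope`, `stderr`, `n`.
#' @export
fit_slopes <- function(timecourse, per_replicate = FALSE) {
  df <- as.data.frame(timecourse, check.names = FALSE)
  if (!"time" %in% names(df)) {
    stop("timecourse must have a 'time' column", call. = FALSE)
  }
  canon <- canonical_column_labels(names(df))
  cols <- which(!is.na(canon))
  if (length(cols) == 0L) stop("no isotopologue columns found", call. = FALSE)
  rows <- lapply(cols, function(ci) {
    if (per_replicate && "sample" %in% names(df)) {
      fits <- lapply(split(df, df$sample), function(d) {
        fit_slope(d$time, d[[ci]])
      })
      slopes <- vapply(fits, `[[`, 0, "slope")
      data.frame(label = canon[ci], slope = mean(slopes),
                 stderr = stats::sd(slopes) / sqrt(length(slopes)),
                 n = nrow(df), stringsAsFactors = FALSE)
    } else {
      est <- fit_slope(df$time, df[[ci]])
      data.frame(label = canon[ci], slope = est$slope, stderr = est$stderr,
                 n = est$n, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relative change between uncorrected and corrected slopes
#'
#' `(corrected - uncorrected) / |uncorrected|`; e.g. 1.3 to 1.9 %/h is a
#' +0.46 (46%) change.
#'
#' @param uncorrected,corrected `slope_estimate`s or bare slopes.
#' @return Relative change as a fraction.
#' @export
slope_change <- function(uncorrected, corrected) {
  u <- if (inherits(uncorrected, "slope_estimate")) uncorrected$slope else uncorrected
  cc <- if (inherits(corrected, "slope_estimate")) corrected$slope else corrected
  if (!is.finite(u) || u == 0) {
    stop("uncorrected slope must be nonzero", call. = FALSE)
  }
  (cc - u) / abs(u)
}
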