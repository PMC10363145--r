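#' @keywords internal
"_PACKAGE"

## Internal helpers shared across the pipeline stages.

# Timestamped progress/log line to stderr, mirrored to
# options(diracr.log_file = path) when set. Silenced with
# options(diracr.verbose = FALSE); suppressMessages() also works.
dlog <- function(fmt, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  sprintf(fmt, ...))
  log_file <- getOption("diracr.log_file", NULL)
  if (!is.null(log_file)) cat(line, "\n", file = log_file, append = TRUE)
  if (isTRUE(getOption("diracr.verbose", TRUE))) message(line)
  invisible(NULL)
}

# stop() without the call, so error messages read as contract violations.
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Median absolute deviation with a configurable consistency constant
#'
#' Robust scale estimate used by the robust Z-score normalizations. By
#' default the raw median absolute deviation is returned (constant = 1);
#' setting `consistency = TRUE` applies the 1.4826 factor that makes the MAD
#' a consistent estimator of the Gaussian standard deviation. Because every
#' downstream rank statistic is invariant to a positive per-sample scale
#' factor, the choice only affects intermediate tables.
#'
#' @param x Numeric vector; `NA`s are removed.
#' @param consistency Logical; multiply by 1.4826 if `TRUE`.
#' @return The (possibly scaled) median absolute deviation of `x`.
#' @export
robust_mad <- function(x, consistency = FALSE) {
  stats::mad(x, constant = if (isTRUE(consistency)) 1.4826 else 1,
             na.rm = TRUE)
}

# Validate a probability threshold.
check_alpha <- function(alpha, what = "alpha") {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    fail("%s must be a single number in (0, 1), got %s", what,
         paste(format(alpha), collapse = ", "))
  }
  invisible(alpha)
}
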