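#' @title Unit conversion helpers
#' @description Canonical internal time unit is seconds: S-values are defined
#'   per MBq.s, so cumulated activity must be in MBq.s. Half-lives are entered
#'   in days and scan times in hours; both are converted at the boundary.
#' @name units
NULL

SECONDS_PER_DAY <- 86400
SECONDS_PER_HOUR <- 3600

#' Convert days to seconds
#' @param d time in days
#' @return time in seconds
#' @export
days_to_seconds <- function(d) d * SECONDS_PER_DAY

#' Convert hours to seconds
#' @param h time in hours
#' @return time in seconds
#' @export
hours_to_seconds <- function(h) h * SECONDS_PER_HOUR

#' Decay constant (per second) from a half-life in days
#' @param half_life_d half-life in days, strictly positive (may be `Inf`)
#' @return decay constant in s^-1
#' @export
lambda_per_second <- function(half_life_d) {
  stopifnot(is.numeric(half_life_d), all(half_life_d > 0))
  log(2) / days_to_seconds(half_life_d)
}

# internal: scalar positive finite check with a named error
check_positive <- function(x, name, allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 ||
      (!allow_inf && !is.finite(x))) {
    stop(sprintf("invalid parameter: '%s' must be a positive%s number, got %s",
                 name, if (allow_inf) " (possibly infinite)" else " finite",
                 deparse(x)), call. = FALSE)
  }
  invisible(x)
}
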