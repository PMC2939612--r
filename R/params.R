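#' DNL screening parameters
#'
#' Bundle the three tunables of the dynamic noise level algorithm. The
#' defaults are the settings the algorithm ships with: `delta = 0.5` (the
#' relative step used to predict the second-lowest peak from the lowest),
#' `snr_min = 2` (minimum signal-to-noise ratio for a peak to be called
#' signal) and `n_min = 8` (minimum number of signal peaks for a spectrum to
#' be retained).
#'
#' @param delta non-negative scalar; relative increment for the two-peak
#'   prediction \eqn{\hat I_2 = (1+\delta) I_1}. Larger values make the scan
#'   more tolerant of spread among the lowest noise peaks.
#' @param snr_min positive scalar; a scanned peak is signal when its
#'   observed/predicted abundance ratio is strictly greater than `snr_min`.
#' @param n_min non-negative integer; spectra with fewer signal peaks than
#'   `n_min` are filtered.
#' @return An object of class `dnl_params`.
#' @examples
#' dnl_params()
#' dnl_params(snr_min = 3, n_min = 10)
#' @export
dnl_params <- function(delta = 0.5, snr_min = 2, n_min = 8) {
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) || delta < 0)
    stop("'delta' must be a single non-negative number")
  if (!is.numeric(snr_min) || length(snr_min) != 1L || is.na(snr_min) ||
      snr_min <= 0)
    stop("'snr_min' must be a single positive number")
  if (!is.numeric(n_min) || length(n_min) != 1L || is.na(n_min) ||
      n_min < 0 || n_min != round(n_min))
    stop("'n_min' must be a single non-negative integer")
  structure(
    list(delta = as.numeric(delta), snr_min = as.numeric(snr_min),
         n_min = as.integer(n_min)),
    class = "dnl_params"
  )
}

#' @export
print.dnl_params <- function(x, ...) {
  cat("DNL parameters: delta =", x$delta,
      " SNR_min =", x$snr_min,
      " n_min =", x$n_min, "\n")
  invisible(x)
}

as_dnl_params <- function(x) {
  if (inherits(x, "dnl_params")) return(x)
  if (is.list(x) && all(c("delta", "snr_min", "n_min") %in% names(x)))
    return(dnl_params(x$delta, x$snr_min, x$n_min))
  stop("'params' must be created by dnl_params()")
}
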