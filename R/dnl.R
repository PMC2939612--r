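#' Sort peaks by abundance for the DNL scan
#'
#' Drops peaks with non-positive abundance (the SNR ratio requires positive
#' values) and sorts the remainder by abundance, ascending; abundance ties
#' are broken by m/z, ascending, so the scan order is deterministic.
#'
#' @param spectrum an [mgf_spectrum], or a data.frame/list with elements
#'   `mz` and `intensity`.
#' @return A data.frame with columns `mz` and `intensity` in scan order.
#' @export
sort_peaks <- function(spectrum) {
  mz <- spectrum$mz
  intensity <- spectrum$intensity
  keep <- !is.na(intensity) & intensity > 0
  mz <- mz[keep]
  intensity <- intensity[keep]
  o <- order(intensity, mz)
  data.frame(mz = mz[o], intensity = intensity[o])
}

#' Predicted abundance of the second-lowest peak
#'
#' With only one peak established as noise, the regression of the general
#' step is undefined; the second peak's noise abundance is instead predicted
#' as \eqn{\hat I_2 = (1 + \delta) I_1}.
#'
#' @param first_abundance abundance of the lowest peak; must be positive.
#' @param delta non-negative spread constant (default of the algorithm: 0.5).
#' @return The predicted abundance, a positive scalar.
#' @examples
#' predict_second(100, 0.5)  # 150
#' @export
predict_second <- function(first_abundance, delta = 0.5) {
  if (!is.numeric(first_abundance) || length(first_abundance) != 1L ||
      is.na(first_abundance) || first_abundance <= 0)
    stop("'first_abundance' must be a single positive number")
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) || delta < 0)
    stop("'delta' must be a single non-negative number")
  (1 + delta) * first_abundance
}

#' Ordinary least squares fit of the noise model
#'
#' Fits the straight line \eqn{I_i = \alpha i + \beta} to the sorted noise
#' abundances \eqn{I_1, \dots, I_{k-1}} at abscissae \eqn{i = 1, \dots,
#' k-1}, by the closed-form normal equations. This is the per-peak model the
#' scan refits at every step; for two points the line is exact.
#'
#' @param prefix numeric vector of at least two sorted noise abundances.
#' @return An object of class `noise_fit`: list with `slope`, `intercept`
#'   and `n_points`.
#' @examples
#' fit_noise_regression(c(2, 4))      # slope 2, intercept 0
#' fit_noise_regression(c(1, 2, 4))   # slope 1.5, intercept -2/3
#' @export
fit_noise_regression <- function(prefix) {
  prefix <- as.numeric(prefix)
  m <- length(prefix)
  if (m < 2L) stop("'prefix' must contain at least 2 values")
  if (anyNA(prefix)) stop("'prefix' must not contain missing values")
  x <- seq_len(m)
  sx <- m * (m + 1) / 2
  sxx <- m * (m + 1) * (2 * m + 1) / 6
  sy <- sum(prefix)
  sxy <- sum(x * prefix)
  denom <- m * sxx - sx * sx   # > 0 for m >= 2
  slope <- (m * sxy - sx * sy) / denom
  intercept <- (sy - slope * sx) / m
  structure(list(slope = slope, intercept = intercept, n_points = m),
            class = "noise_fit")
}

#' @export
print.noise_fit <- function(x, ...) {
  cat("Noise regression over", x$n_points, "sorted abundances:",
      "slope", format(x$slope), "intercept", format(x$intercept), "\n")
  invisible(x)
}

#' Predicted abundance of the next peak under the noise hypothesis
#'
#' Extrapolates the fitted noise line one step beyond the fitted prefix:
#' \eqn{\hat I_k = \hat\alpha k + \hat\beta} with `k = n_points + 1`.
#'
#' @param fit a `noise_fit` from [fit_noise_regression()].
#' @param k index of the scanned peak; must equal `fit$n_points + 1`.
#' @return The predicted abundance.
#' @export
predict_peak <- function(fit, k) {
  if (!inherits(fit, "noise_fit")) stop("'fit' must be a noise_fit")
  if (k != fit$n_points + 1L)
    stop("'k' must be n_points + 1 = ", fit$n_points + 1L, ", got ", k)
  fit$slope * k + fit$intercept
}

#' Estimated signal-to-noise ratio of a scanned peak
#'
#' The ratio of the observed abundance to the abundance predicted under the
#' hypothesis that the peak is noise.
#'
#' @param observed observed abundance, positive.
#' @param predicted predicted abundance; must be positive (guaranteed for
#'   positive, ascending-sorted input).
#' @return `observed / predicted`.
#' @export
estimate_snr <- function(observed, predicted) {
  if (!is.numeric(predicted) || length(predicted) != 1L || is.na(predicted) ||
      predicted <= 0)
    stop("'predicted' must be a single positive number")
  observed / predicted
}

#' Dynamic noise level scan of one spectrum
#'
#' The DNL algorithm proper. Peaks are sorted by abundance (non-positive
#' abundances dropped); the lowest peak is taken as noise axiomatically. The
#' scan then tests peaks k = 2, 3, ... in order: the expected noise
#' abundance of peak k is predicted from the k-1 peaks already called noise
#' — by [predict_second()] at k = 2, by an ordinary least squares refit of
#' the noise line ([fit_noise_regression()] / [predict_peak()]) at k > 2 —
#' and the peak is called signal as soon as its observed/predicted ratio
#' exceeds `snr_min` strictly. The prediction at that first signal peak is
#' the spectrum's noise level, and every peak whose abundance is greater
#' than or equal to the observed abundance of the first signal peak counts
#' as signal.
#'
#' Spectra with fewer than two positive peaks yield zero signal peaks: with
#' the first peak noise by assumption there is nothing to test.
#'
#' @param spectrum an [mgf_spectrum] (or anything [sort_peaks()] accepts).
#' @param params a [dnl_params()] object.
#' @return An object of class `dnl_scan`: list with
#'   \describe{
#'     \item{identifier}{the spectrum title (or `NA` for bare peak lists).}
#'     \item{peaks}{the sorted peak data.frame used by the scan.}
#'     \item{snr_trace}{estimated SNR for each scanned k (k = 2 up to the
#'       first signal peak, or up to N when none is found).}
#'     \item{first_signal_index}{1-based index, in sorted order, of the
#'       first signal peak; `NA` when all peaks are noise.}
#'     \item{noise_level}{predicted abundance at the first signal peak
#'       (intensity units); `NA` when all peaks are noise.}
#'     \item{signal_count}{number of signal peaks, n.}
#'     \item{n_total}{number of positive-abundance peaks, N.}
#'     \item{params}{the parameters used.}
#'   }
#' @examples
#' sp <- mgf_spectrum(mz = 100 * 1:5, intensity = c(10, 12, 14, 16, 100),
#'                    title = "demo")
#' scan <- dnl_scan(sp)
#' scan                      # 1 signal peak, noise level 18
#' scan$snr_trace            # 0.8, 1, 1, 5.56
#' @export
dnl_scan <- function(spectrum, params = dnl_params()) {
  params <- as_dnl_params(params)
  pk <- sort_peaks(spectrum)
  y <- pk$intensity
  N <- length(y)
  identifier <- if (!is.null(spectrum$title)) spectrum$title else NA_character_

  trace <- numeric(0)
  first <- NA_integer_
  noise_level <- NA_real_
  if (N >= 2L) {
    trace <- numeric(N - 1L)
    found <- FALSE
    for (k in 2:N) {
      pred <- if (k == 2L) predict_second(y[1L], params$delta)
              else predict_peak(fit_noise_regression(y[seq_len(k - 1L)]), k)
      snr <- estimate_snr(y[k], pred)
      trace[k - 1L] <- snr
      if (snr > params$snr_min) {
        first <- k
        noise_level <- pred
        trace <- trace[seq_len(k - 1L)]
        found <- TRUE
        break
      }
    }
    if (!found) trace <- trace[seq_len(N - 1L)]
  }
  signal_count <- if (is.na(first)) 0L else sum(y >= y[first])

  structure(
    list(identifier = identifier,
         peaks = pk,
         snr_trace = trace,
         first_signal_index = first,
         noise_level = noise_level,
         signal_count = as.integer(signal_count),
         n_total = as.integer(N),
         params = params),
    class = "dnl_scan"
  )
}

#' Full SNR trace without early stopping
#'
#' Diagnostic companion of [dnl_scan()]: computes the estimated SNR for
#' every k = 2..N as if the scan never stopped, i.e. treating all lower
#' peaks as noise at each step. Useful for plotting the per-peak SNR of a
#' noise-only spectrum, where the values should hover around 1.
#'
#' @inheritParams dnl_scan
#' @return Numeric vector of length N - 1 (empty for spectra with fewer
#'   than two positive peaks).
#' @export
snr_trace <- function(spectrum, params = dnl_params()) {
  params <- as_dnl_params(params)
  y <- sort_peaks(spectrum)$intensity
  N <- length(y)
  if (N < 2L) return(numeric(0))
  trace <- numeric(N - 1L)
  for (k in 2:N) {
    pred <- if (k == 2L) predict_second(y[1L], params$delta)
            else predict_peak(fit_noise_regression(y[seq_len(k - 1L)]), k)
    trace[k - 1L] <- estimate_snr(y[k], pred)
  }
  trace
}

#' @export
print.dnl_scan <- function(x, ...) {
  id <- if (is.na(x$identifier)) "<unnamed>" else x$identifier
  cat("DNL scan of '", id, "': ", x$n_total, " positive peaks\n", sep = "")
  if (is.na(x$first_signal_index)) {
    cat("  all peaks classified as noise (0 signal peaks)\n")
  } else {
    cat("  first signal peak at sorted index ", x$first_signal_index,
        ", noise level ", format(x$noise_level), "\n",
        "  signal peaks: ", x$signal_count, "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.dnl_scan <- function(object, ...) {
  print(object)
  p <- object$params
  cat("  parameters: delta =", p$delta, " SNR_min =", p$snr_min, "\n")
  if (length(object$snr_trace)) {
    q <- stats::quantile(object$snr_trace, c(0, 0.5, 1))
    cat("  SNR trace over ", length(object$snr_trace), " scanned peaks: ",
        "min ", format(q[[1L]], digits = 3),
        ", median ", format(q[[2L]], digits = 3),
        ", max ", format(q[[3L]], digits = 3), "\n", sep = "")
  }
  invisible(object)
}

#' Plot a DNL scan
#'
#' Two panels: the sorted abundances with the noise level (when found) and
#' the first-signal boundary, and the SNR trace against the `snr_min`
#' threshold.
#'
#' @param x a `dnl_scan`.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.dnl_scan <- function(x, ...) {
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  y <- x$peaks$intensity
  graphics::plot(seq_along(y), y, type = "h", xlab = "sorted peak index",
                 ylab = "abundance", main = x$identifier, ...)
  if (!is.na(x$noise_level)) {
    graphics::abline(h = x$noise_level, lty = 2, col = "red")
    graphics::abline(v = x$first_signal_index - 0.5, lty = 3, col = "blue")
  }
  if (length(x$snr_trace)) {
    graphics::plot(seq_along(x$snr_trace) + 1L, x$snr_trace, type = "b",
                   xlab = "scanned peak index k", ylab = "estimated SNR")
    graphics::abline(h = x$params$snr_min, lty = 2, col = "red")
    graphics::abline(h = 1, lty = 3, col = "grey40")
  }
  invisible(x)
}
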