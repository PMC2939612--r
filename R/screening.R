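#' Retain-or-filter decision for one scanned spectrum
#'
#' A spectrum is retained when its signal-peak count reaches `n_min`;
#' spectra with fewer signal peaks are filtered as poor quality. The
#' boundary is inclusive: exactly `n_min` signal peaks is enough to keep a
#' spectrum.
#'
#' @param scan a [dnl_scan()] result (produced with the same `delta` and
#'   `snr_min` as `params`).
#' @param params a [dnl_params()] object supplying `n_min`.
#' @return A one-row data.frame with columns `identifier`, `retained`,
#'   `signal_count`, `noise_level` and `n_total`.
#' @export
screen_spectrum <- function(scan, params = scan$params) {
  if (!inherits(scan, "dnl_scan")) stop("'scan' must be a dnl_scan")
  params <- as_dnl_params(params)
  data.frame(identifier = scan$identifier,
             retained = scan$signal_count >= params$n_min,
             signal_count = scan$signal_count,
             noise_level = scan$noise_level,
             n_total = scan$n_total,
             stringsAsFactors = FALSE)
}

#' Remove noise peaks from a spectrum
#'
#' Keeps exactly the signal peaks — those with abundance greater than or
#' equal to the observed abundance of the first signal peak — in their
#' original m/z order, preserving the precursor metadata. A scan that found
#' no signal yields a spectrum with zero peaks.
#'
#' @param spectrum the [mgf_spectrum] the scan was derived from.
#' @param scan the matching [dnl_scan()] result.
#' @return An [mgf_spectrum] containing only the signal peaks.
#' @export
denoise_spectrum <- function(spectrum, scan) {
  if (!inherits(scan, "dnl_scan")) stop("'scan' must be a dnl_scan")
  if (is.na(scan$first_signal_index)) {
    keep <- rep(FALSE, length(spectrum$mz))
  } else {
    threshold <- scan$peaks$intensity[scan$first_signal_index]
    keep <- !is.na(spectrum$intensity) & spectrum$intensity >= threshold
  }
  out <- spectrum
  out$mz <- spectrum$mz[keep]
  out$intensity <- spectrum$intensity[keep]
  out
}

#' Screen an MGF dataset
#'
#' Runs the DNL scan over every spectrum of an MGF file (or an already
#' parsed spectrum list), writes retained spectra to one sink and filtered
#' spectra to an optional second sink, and tallies a screening report with
#' the noise-level and signal-count distributions. Malformed MGF blocks are
#' skipped with a warning and counted separately, so a stray block never
#' aborts a batch run.
#'
#' By default the retained spectra are written with their original peak
#' lists — screening selects spectra, it does not alter them. With
#' `denoise = TRUE` the retained output contains only the signal peaks of
#' each spectrum.
#'
#' @param input path to an MGF file, or a list of [mgf_spectrum] objects.
#' @param params a [dnl_params()] object.
#' @param retained_path optional path for the retained-spectra MGF.
#' @param filtered_path optional path for the filtered-spectra MGF.
#' @param denoise logical; write denoised peak lists to the retained sink.
#' @param verbose logical; log each decision with [message()].
#' @return An object of class `dnl_report`: totals, parameters, the
#'   per-spectrum decision table, and the two histograms (noise level in
#'   0.1-wide bins of log10 intensity; signal counts at integer
#'   resolution).
#' @export
screen_dataset <- function(input, params = dnl_params(),
                           retained_path = NULL, filtered_path = NULL,
                           denoise = FALSE, verbose = FALSE) {
  params <- as_dnl_params(params)
  if (is.character(input)) {
    spectra <- read_mgf(input, on_error = "skip")
  } else {
    spectra <- input
    if (inherits(spectra, "mgf_spectrum")) spectra <- list(spectra)
  }
  skipped <- attr(spectra, "skipped")
  if (is.null(skipped)) skipped <- 0L

  ret_con <- if (!is.null(retained_path)) file(retained_path, "wt")
  flt_con <- if (!is.null(filtered_path)) file(filtered_path, "wt")
  on.exit({
    if (!is.null(ret_con)) close(ret_con)
    if (!is.null(flt_con)) close(flt_con)
  })

  n <- length(spectra)
  decisions <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- spectra[[i]]
    scan <- dnl_scan(sp, params)
    dec <- screen_spectrum(scan, params)
    decisions[[i]] <- dec
    if (verbose)
      message(sprintf("%s: %d signal peaks -> %s", dec$identifier,
                      dec$signal_count,
                      if (dec$retained) "retained" else "filtered"))
    if (dec$retained) {
      if (!is.null(ret_con)) {
        out_sp <- if (denoise) denoise_spectrum(sp, scan) else sp
        write_mgf_block(out_sp, ret_con)
      }
    } else if (!is.null(flt_con)) {
      write_mgf_block(sp, flt_con)
    }
  }
  decisions <- if (n) do.call(rbind, decisions) else
    data.frame(identifier = character(), retained = logical(),
               signal_count = integer(), noise_level = numeric(),
               n_total = integer(), stringsAsFactors = FALSE)

  structure(
    list(total_spectra = n,
         retained = sum(decisions$retained),
         filtered = sum(!decisions$retained),
         skipped = skipped,
         params = params,
         decisions = decisions,
         noise_level_histogram =
           log10_histogram(decisions$noise_level[!is.na(decisions$noise_level)]),
         signal_count_histogram = count_histogram(decisions$signal_count)),
    class = "dnl_report"
  )
}

# 0.1-wide bins of log10(intensity) over the observed range
log10_histogram <- function(values, binwidth = 0.1) {
  if (!length(values))
    return(list(breaks = numeric(0), counts = integer(0)))
  lg <- log10(values)
  lo <- floor(min(lg) / binwidth) * binwidth
  hi <- ceiling(max(lg) / binwidth) * binwidth
  if (hi <= lo) hi <- lo + binwidth
  breaks <- seq(lo, hi, by = binwidth)
  h <- graphics::hist(lg, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = FALSE)
  list(breaks = h$breaks, counts = as.integer(h$counts))
}

# integer-resolution bins 0..max(n)
count_histogram <- function(counts) {
  if (!length(counts))
    return(list(breaks = integer(0), counts = integer(0)))
  values <- 0:max(counts)
  list(breaks = values,
       counts = as.integer(tabulate(counts + 1L, nbins = max(counts) + 1L)))
}

#' @export
print.dnl_report <- function(x, ...) {
  cat("DNL screening report\n")
  print(x$params)
  cat("  spectra: ", x$total_spectra, " (",
      x$retained, " retained, ", x$filtered, " filtered",
      if (x$skipped) paste0(", ", x$skipped, " malformed skipped") else "",
      ")\n", sep = "")
  nl <- x$decisions$noise_level
  nl <- nl[!is.na(nl)]
  if (length(nl))
    cat("  noise level: median ", format(stats::median(nl), digits = 4),
        ", range ", format(min(nl), digits = 4), "-",
        format(max(nl), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Plot a screening report
#'
#' Draws the two distributions of the report: noise level on a log10
#' intensity axis and the number of signal peaks per spectrum, with the
#' `n_min` retention threshold marked.
#'
#' @param x a `dnl_report`.
#' @param ... ignored.
#' @return Invisibly, `x`.
#' @export
plot.dnl_report <- function(x, ...) {
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  nh <- x$noise_level_histogram
  if (length(nh$counts))
    graphics::barplot(nh$counts, names.arg = sprintf("%.1f", nh$breaks[-1L]),
                      xlab = "log10 noise level", ylab = "spectra",
                      main = "Noise level distribution")
  sh <- x$signal_count_histogram
  if (length(sh$counts)) {
    graphics::barplot(sh$counts, names.arg = sh$breaks,
                      xlab = "signal peaks", ylab = "spectra",
                      main = "Signal peak count distribution")
    graphics::abline(v = x$params$n_min, lty = 2, col = "red")
  }
  invisible(x)
}

#' Serialize a screening report to JSON
#'
#' @param report a `dnl_report` from [screen_dataset()].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_report <- function(report, path) {
  if (!inherits(report, "dnl_report")) stop("'report' must be a dnl_report")
  jsonlite::write_json(
    list(total_spectra = report$total_spectra,
         retained = report$retained,
         filtered = report$filtered,
         skipped = report$skipped,
         params = unclass(report$params),
         noise_level_histogram = report$noise_level_histogram,
         signal_count_histogram = report$signal_count_histogram),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
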