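#' Construct an MS/MS spectrum
#'
#' A plain container for one tandem mass spectrum: a peak list of
#' (m/z, abundance) pairs plus the precursor metadata carried by an MGF
#' block. Peaks keep the order they were supplied in; sorting by abundance
#' happens inside the scan, never in the container.
#'
#' @param mz numeric vector of product-ion m/z values (Th); all positive.
#' @param intensity numeric vector of peak abundances (arbitrary intensity
#'   units), same length as `mz`. Non-positive abundances are legal here —
#'   real MGF exports occasionally carry them — and are dropped by the scan.
#' @param title spectrum identifier (MGF TITLE); must be non-empty.
#' @param pepmass precursor m/z (Th), or `NA`.
#' @param charge integer vector of precursor charges, signed (e.g. `c(2, 3)`
#'   for "2+ and 3+", `-2` for "2-"); may be empty when unknown.
#' @param index zero-based position of the spectrum in its source file.
#' @return An object of class `mgf_spectrum`.
#' @examples
#' sp <- mgf_spectrum(mz = c(150.1, 300.2, 450.3),
#'                    intensity = c(10, 55, 23), title = "scan_1")
#' sp
#' @export
mgf_spectrum <- function(mz, intensity, title,
                         pepmass = NA_real_, charge = integer(),
                         index = 0L) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop("'mz' and 'intensity' must have the same length")
  if (any(is.na(mz)) || any(mz <= 0))
    stop("all 'mz' values must be positive and non-missing")
  if (!is.character(title) || length(title) != 1L || is.na(title) ||
      !nzchar(title))
    stop("'title' must be a non-empty string")
  structure(
    list(title = title,
         pepmass = as.numeric(pepmass)[1L],
         charge = as.integer(charge),
         mz = mz,
         intensity = intensity,
         index = as.integer(index)),
    class = "mgf_spectrum"
  )
}

#' @export
print.mgf_spectrum <- function(x, ...) {
  cat("MS/MS spectrum '", x$title, "': ", length(x$mz), " peaks", sep = "")
  if (!is.na(x$pepmass)) cat(", precursor m/z ", format(x$pepmass), sep = "")
  if (length(x$charge))
    cat(", charge ", paste(format_charge(x$charge), collapse = " and "),
        sep = "")
  cat("\n")
  if (length(x$mz)) {
    rng <- range(x$intensity)
    cat("  m/z ", format(min(x$mz)), "-", format(max(x$mz)),
        ", abundance ", format(rng[1L]), "-", format(rng[2L]), "\n", sep = "")
  }
  invisible(x)
}

format_charge <- function(z) {
  sprintf("%d%s", abs(z), ifelse(z < 0, "-", "+"))
}
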