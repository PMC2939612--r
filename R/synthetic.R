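#' Simulate a noise-only MS/MS spectrum
#'
#' Draws peak abundances from a Gaussian distribution, mimicking the
#' electrical/chemical noise floor of an ion trap instrument: no peak
#' carries fragment-ion signal, so a correct DNL scan should classify every
#' peak as noise and the SNR trace should hover around 1. Abundances are
#' truncated at a floor of 1 intensity unit so no draw is lost to the
#' scan's positivity filter; m/z values are uniform over `mz_range`, sorted
#' and distinct. The default mean/sd ratio of 10 keeps the sorted
#' abundances close to linear in rank, which is the regime the noise model
#' assumes.
#'
#' @param n_noise number of noise peaks (at least 1).
#' @param noise_mean,noise_sd Gaussian mean and standard deviation of the
#'   abundances (intensity units); `noise_mean >= 5 * noise_sd` is required
#'   so that draws stay positive and the order statistics near-linear.
#' @param mz_range numeric length-2; m/z window (Th) for the peaks.
#' @param seed optional integer seed; identical seeds give identical
#'   spectra.
#' @param title spectrum identifier; a default is derived from the seed.
#' @return An [mgf_spectrum] with an extra element `is_signal`, the
#'   ground-truth mask (here all `FALSE`).
#' @examples
#' sp <- simulate_noise_spectrum(100, seed = 1)
#' dnl_scan(sp)$signal_count  # 0
#' @export
simulate_noise_spectrum <- function(n_noise = 100, noise_mean = 1000,
                                    noise_sd = 100,
                                    mz_range = c(200, 2000), seed = NULL,
                                    title = NULL) {
  check_synth_args(n_noise, noise_mean, noise_sd, mz_range)
  if (!is.null(seed)) set.seed(seed)
  abundance <- pmax(stats::rnorm(n_noise, noise_mean, noise_sd), 1)
  mz <- draw_mz(n_noise, mz_range)
  if (is.null(title))
    title <- sprintf("noise_n%d_seed%s", n_noise,
                     if (is.null(seed)) "NA" else seed)
  sp <- mgf_spectrum(mz = mz, intensity = abundance, title = title,
                     pepmass = stats::runif(1, 400, 1500), charge = 2L)
  sp$is_signal <- rep(FALSE, n_noise)
  sp
}

#' Simulate a peptide-like MS/MS spectrum with planted signal peaks
#'
#' Generates a Gaussian noise floor as in [simulate_noise_spectrum()] and
#' plants `n_signal` signal peaks whose abundances are uniform between
#' `signal_multiplier` and twice `signal_multiplier` times the largest
#' noise abundance. Every signal peak therefore exceeds every noise peak —
#' the separation assumption a good-quality spectrum satisfies — and with
#' the default multiplier of 2.5 the planted peaks clear the default SNR
#' threshold of 2 robustly. Peaks are returned in m/z order with a
#' ground-truth signal mask.
#'
#' @inheritParams simulate_noise_spectrum
#' @param n_signal number of planted signal peaks; 0 delegates to
#'   [simulate_noise_spectrum()].
#' @param signal_multiplier ratio (> 1) of the lowest possible signal
#'   abundance to the largest noise abundance.
#' @return An [mgf_spectrum] with element `is_signal` marking the planted
#'   peaks.
#' @examples
#' sp <- simulate_peptide_spectrum(n_noise = 50, n_signal = 20, seed = 7)
#' dnl_scan(sp)$signal_count  # 20
#' @export
simulate_peptide_spectrum <- function(n_noise = 50, n_signal = 20,
                                      noise_mean = 1000, noise_sd = 100,
                                      signal_multiplier = 2.5,
                                      mz_range = c(200, 2000), seed = NULL,
                                      title = NULL) {
  check_synth_args(n_noise, noise_mean, noise_sd, mz_range)
  if (!is.numeric(n_signal) || length(n_signal) != 1L || is.na(n_signal) ||
      n_signal < 0 || n_signal != round(n_signal))
    stop("'n_signal' must be a single non-negative integer")
  if (n_signal == 0)
    return(simulate_noise_spectrum(n_noise, noise_mean, noise_sd, mz_range,
                                   seed, title))
  if (!is.numeric(signal_multiplier) || length(signal_multiplier) != 1L ||
      is.na(signal_multiplier) || signal_multiplier <= 1)
    stop("'signal_multiplier' must be a single number > 1")
  if (!is.null(seed)) set.seed(seed)
  noise <- pmax(stats::rnorm(n_noise, noise_mean, noise_sd), 1)
  noise_max <- max(noise)
  signal <- stats::runif(n_signal, noise_max * signal_multiplier,
                         noise_max * 2 * signal_multiplier)
  n <- n_noise + n_signal
  mz <- draw_mz(n, mz_range)
  abundance <- c(noise, signal)
  is_signal <- c(rep(FALSE, n_noise), rep(TRUE, n_signal))
  # pair abundances with m/z at random, then store in m/z order
  perm <- sample.int(n)
  o <- order(mz)
  if (is.null(title))
    title <- sprintf("peptide_n%d_s%d_seed%s", n_noise, n_signal,
                     if (is.null(seed)) "NA" else seed)
  sp <- mgf_spectrum(mz = mz[o], intensity = abundance[perm][o],
                     title = title,
                     pepmass = stats::runif(1, 400, 1500), charge = 2L)
  sp$is_signal <- is_signal[perm][o]
  sp
}

#' Simulate a labelled MGF dataset for screening evaluation
#'
#' Writes an MGF file of `n_good` peptide-like spectra (planted signal
#' peaks, labelled `TP`) and `n_bad` noise-only spectra (labelled
#' `unidentified`) together with the matching label TSV, so the whole
#' screen-then-evaluate pipeline can be exercised without instrument data.
#' Each spectrum gets its own seed derived from `seed`, and identical
#' master seeds give byte-identical output files.
#'
#' @param n_good,n_bad numbers of good (planted-signal) and bad
#'   (noise-only) spectra; together at least 2.
#' @param mgf_path,labels_path output paths.
#' @param n_noise,n_signal,noise_mean,noise_sd,signal_multiplier,mz_range
#'   generator settings, as in [simulate_peptide_spectrum()]; `n_signal`
#'   applies to good spectra only.
#' @param seed master seed.
#' @return Invisibly, a list with the two paths and the counts.
#' @export
simulate_labelled_dataset <- function(n_good, n_bad, mgf_path, labels_path,
                                      n_noise = 50, n_signal = 20,
                                      noise_mean = 1000, noise_sd = 100,
                                      signal_multiplier = 2.5,
                                      mz_range = c(200, 2000), seed = 1) {
  if (n_good + n_bad < 2) stop("need at least 2 spectra in total")
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_good + n_bad)
  spectra <- vector("list", n_good + n_bad)
  ids <- character(n_good + n_bad)
  cats <- character(n_good + n_bad)
  for (i in seq_len(n_good)) {
    id <- sprintf("good_%04d", i)
    spectra[[i]] <- simulate_peptide_spectrum(
      n_noise = n_noise, n_signal = n_signal, noise_mean = noise_mean,
      noise_sd = noise_sd, signal_multiplier = signal_multiplier,
      mz_range = mz_range, seed = seeds[i], title = id)
    ids[i] <- id
    cats[i] <- "TP"
  }
  for (j in seq_len(n_bad)) {
    i <- n_good + j
    id <- sprintf("bad_%04d", j)
    spectra[[i]] <- simulate_noise_spectrum(
      n_noise = n_noise, noise_mean = noise_mean, noise_sd = noise_sd,
      mz_range = mz_range, seed = seeds[i], title = id)
    ids[i] <- id
    cats[i] <- "unidentified"
  }
  write_mgf(spectra, mgf_path)
  writeLines(c("# identifier\tcategory", paste(ids, cats, sep = "\t")),
             labels_path)
  invisible(list(mgf = mgf_path, labels = labels_path,
                 n_good = n_good, n_bad = n_bad))
}

check_synth_args <- function(n_noise, noise_mean, noise_sd, mz_range) {
  if (!is.numeric(n_noise) || length(n_noise) != 1L || is.na(n_noise) ||
      n_noise < 1 || n_noise != round(n_noise))
    stop("'n_noise' must be a single integer >= 1")
  if (!is.numeric(noise_mean) || noise_mean <= 0 ||
      !is.numeric(noise_sd) || noise_sd <= 0)
    stop("'noise_mean' and 'noise_sd' must be positive")
  if (noise_mean < 5 * noise_sd)
    stop("'noise_mean' must be at least 5 * 'noise_sd' to keep abundances ",
         "positive and the sorted noise near-linear")
  if (!is.numeric(mz_range) || length(mz_range) != 2L ||
      mz_range[1L] <= 0 || mz_range[2L] <= mz_range[1L])
    stop("'mz_range' must be an increasing positive pair")
}

# sorted, distinct m/z draws
draw_mz <- function(n, mz_range) {
  mz <- sort(stats::runif(n, mz_range[1L], mz_range[2L]))
  while (anyDuplicated(mz)) {
    dup <- duplicated(mz)
    mz[dup] <- stats::runif(sum(dup), mz_range[1L], mz_range[2L])
    mz <- sort(mz)
  }
  mz
}
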