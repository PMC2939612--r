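# dnlscreen

Quality screening of peptide tandem mass spectra (MS/MS) by **dynamic noise
level (DNL)** estimation.

Shotgun proteomics runs on ion trap instruments produce large numbers of
MS/MS scans that contain nothing but electrical and chemical noise.
Searching them against a protein database wastes compute and inflates the
pool of false-positive peptide matches. Because the noise floor varies by
orders of magnitude from scan to scan, a single global intensity cutoff
cannot separate signal from noise; the noise level has to be estimated per
spectrum. `dnlscreen` does that, filters the spectra that carry too little
signal, and ships the evaluation machinery (sensitivity/specificity, ROC
curves over the filtering threshold) and seeded synthetic-spectrum
generators used to validate it.

## The algorithm

For a spectrum with peak abundances sorted in increasing order
*I*₁ ≤ *I*₂ ≤ … ≤ *I*ₙ, two assumptions are made: in a good-quality
spectrum the signal peaks are all more abundant than the noise peaks, and
every spectrum contains at least one noise peak. The lowest peak is taken
to be noise, and peaks *k* = 2, 3, … are scanned in order:

* **k = 2:** the expected noise abundance is *Î*₂ = (1 + δ) *I*₁, with
  δ = 0.5 by default.
* **k > 2:** an ordinary least squares line *I*ᵢ = α i + β is fitted to
  the *k* − 1 peaks already called noise, and extrapolated one step:
  *Î*ₖ = α̂ k + β̂.
* The estimated signal-to-noise ratio is SNR = *I*ₖ / *Î*ₖ. The first peak
  with SNR > SNR_min (default 2) is the **first signal peak**; *Î*ₖ at that
  peak is the spectrum's **noise level**, and every peak with abundance ≥
  *I*ₖ counts as signal. If no peak exceeds the threshold the whole
  spectrum is noise.

A spectrum is retained when its signal-peak count *n* reaches *n*_min
(default 8); otherwise it is filtered before the database search.

## Worked example

```r
library(dnlscreen)

sp <- mgf_spectrum(mz = c(150.1, 250.2, 350.3, 450.4, 550.5),
                   intensity = c(12, 10, 100, 16, 14), title = "scan_42")
scan <- dnl_scan(sp)
scan
#> DNL scan of 'scan_42': 5 positive peaks
#>   first signal peak at sorted index 5, noise level 18
#>   signal peaks: 1
round(scan$snr_trace, 3)
#> [1] 0.800 1.000 1.000 5.556
```

The sorted abundances are 10, 12, 14, 16, 100. The second peak's SNR is
12 / (1.5 × 10) = 0.8; the next two peaks sit exactly on the fitted noise
line (SNR 1); at the fifth peak the line through 10, 12, 14, 16 predicts
18, so SNR = 100/18 ≈ 5.56 > 2 — that peak is signal, the noise level is
18, and the spectrum has 1 signal peak (filtered at the default
*n*_min = 8).

Batch screening and evaluation on a simulated labelled dataset:

```r
mgf <- tempfile(fileext = ".mgf"); tsv <- tempfile(fileext = ".tsv")
simulate_labelled_dataset(100, 100, mgf, tsv, seed = 13)
rpt <- screen_dataset(mgf)
rpt
#> DNL screening report
#> DNL parameters: delta = 0.5  SNR_min = 2  n_min = 8
#>   spectra: 200 (100 retained, 100 filtered)
#>   noise level: median 1164, range 1093-1218
lab <- read_labels(tsv)
evaluate_screening(rpt$decisions, lab)
#> sensitivity (bad spectra filtered): 1.0000
#> specificity (TP spectra kept):      1.0000
roc_over_nmin(rpt$decisions, lab)
#> ROC over n_min sweep (22 thresholds), AUC = 1.0000
```

All 100 noise-only spectra are filtered and all 100 planted-signal spectra
kept; the ROC sweep over *n*_min separates the classes perfectly, as the
generator constructs them to be separable.

## Command line

A thin CLI wraps the same functions (installed under
`system.file("exec", "dnlscreen", package = "dnlscreen")`):

```sh
dnlscreen filter   in.mgf --out retained.mgf --rejected filtered.mgf --report report.json
dnlscreen evaluate in.mgf --labels labels.tsv --out eval.json
dnlscreen simulate --good 100 --bad 100 --seed 13 --out-mgf sim.mgf --out-labels sim.tsv
```

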