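---
title: "Dynamic noise level screening: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic noise level screening: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnlscreen)
```

## The problem

Ion trap shotgun proteomics acquisitions trigger MS/MS scans on anything
that looks like a precursor, so a large fraction of the recorded spectra
contain only electrical and chemical noise. The noise floor differs by
orders of magnitude between scans — it depends on the precursor intensity,
the fill time, the chromatographic background — so no fixed intensity
cutoff can separate signal from noise across a run. Screening therefore
has to estimate a noise level *per spectrum* and judge spectrum quality
from how many peaks rise above it.

## The model

Let the positive peak abundances of one spectrum, sorted increasingly, be
$I_1 \le I_2 \le \dots \le I_N$. Two assumptions define the method:

1. in a good-quality spectrum, every signal peak is more abundant than
   every noise peak, so the sorted sequence is a block of noise followed
   by a block of signal;
2. at least one noise peak is present, so $I_1$ is noise.

Under assumption 1, sorted *noise* abundances of an ion trap spectrum grow
roughly linearly with rank — empirically, Gaussian-like abundance
distributions with a mean well above the spread have near-linear central
order statistics. The scan exploits this: at step $k$ the $k-1$ peaks
already accepted as noise define a prediction of what $I_k$ should be *if
it were noise*,

$$\hat I_2 = (1+\delta)\,I_1, \qquad
  \hat I_k = \hat\alpha k + \hat\beta \quad (k > 2),$$

where $(\hat\alpha, \hat\beta)$ is the ordinary least squares fit of
$I_i = \alpha i + \beta$ over $i = 1,\dots,k-1$, refitted at every step.
The estimated signal-to-noise ratio of peak $k$ is
$\mathrm{SNR} = I_k / \hat I_k$. The scan stops at the first $k$ with
$\mathrm{SNR} > \mathrm{SNR}_{\min}$ (strict inequality): that peak is the
first signal peak, $\hat I_k$ there is reported as the spectrum's noise
level, and every peak with abundance $\ge I_k$ (observed, not predicted —
ties included) counts as signal. A spectrum whose signal-peak count $n$
falls below $n_{\min}$ is filtered; $n = n_{\min}$ exactly is retained.

For a pure-noise spectrum the predictions track the observations and the
SNR trace hovers around 1:

```{r noise-demo}
sp <- simulate_noise_spectrum(100, seed = 1)
scan <- dnl_scan(sp)
scan
median(snr_trace(sp))
```

## Parameters

* `delta` (unitless, default 0.5): relative step used to predict the
  second peak from the first, needed because a one-point "fit" is
  undefined. It matters only for spectra whose second peak is already
  signal; for typical spectra with many noise peaks its influence
  vanishes, which is why a fixed intermediate value is used rather than a
  tuned one.
* `snr_min` (unitless ratio, default 2): the minimum
  observed-to-predicted abundance ratio for a peak to be called signal.
  Lower values make filtering more aggressive for weak spectra, higher
  values more conservative; discrimination is robust over roughly 1.5–3.
* `n_min` (peaks, default 8): the minimum number of signal peaks for a
  spectrum to be retained. This is the ROC sweep variable of
  `roc_over_nmin()`; 8 is a sensible operating point for tryptic peptides,
  whose informative fragment ladders rarely produce fewer signal peaks.

## Numerical choices and edge cases

* **Sorting** is by abundance ascending with ties broken by m/z ascending
  (stable), so the scan order — and hence the output — is deterministic
  across platforms.
* **Non-positive abundances** are dropped before scanning: the SNR ratio
  needs positive values, and real MGF exports occasionally carry
  zero-intensity peaks. The reader keeps them (it stays faithful to the
  file); only the scan discards them.
* **OLS** is solved in closed form via the normal equations with exact
  integer abscissa sums; for ascending positive data the slope is
  non-negative and the one-step extrapolation
  $\hat I_k \ge \bar I > 0$, so the SNR denominator can never be zero or
  negative. The fit is recomputed over the full prefix at each step so it
  always equals the full-prefix least squares solution.
* **Spectra with fewer than two positive peaks** are defined to have zero
  signal peaks: the first peak is noise by assumption and there is nothing
  to test.
* **Ties at the first-signal boundary** all count as signal, per the
  greater-than-or-equal membership rule.
* **ROC/AUC**: the discriminant is an integer count, so the ROC is a
  finite sweep of $n_{\min}$ from 0 (nothing filtered) to one past the
  largest observed count (everything filtered). The AUC is the trapezoid
  over the sweep-ordered points; vertical segments contribute no area, so
  this equals the exact step-curve area and the rank statistic
  $P(n_{\text{good}} > n_{\text{bad}}) + \tfrac12 P(\text{tie})$, which is
  what `pROC` computes and what the test suite cross-checks against.
  Sensitivity is the fraction of bad spectra (decoy hits plus unidentified)
  correctly filtered; specificity is one minus the fraction of
  true-positive spectra falsely filtered; either is reported as `NA` when
  its class is empty rather than being forced to a value.

## The synthetic generator

`simulate_noise_spectrum()` draws abundances from a Gaussian (default mean
1000, sd 100 intensity units, floor at 1 so no draw is lost to the
positivity filter) with uniform distinct m/z in 200–2000 Th. The mean/sd
ratio of 10 keeps the central order statistics near-linear — the regime
the noise model assumes and the regime ion trap noise occupies; the
specific mean is arbitrary since the classification is scale-invariant
(only the reported noise level scales). `simulate_peptide_spectrum()`
plants `n_signal` peaks uniformly between 2.5× and 5× the largest noise
abundance, so the separation assumption holds by construction and planted
peaks clear `snr_min = 2` with margin. `simulate_labelled_dataset()`
writes matched MGF + label TSV files with per-spectrum seeds derived from
one master seed, byte-identical per seed.

What the generator deliberately does **not** emulate: fragment-ion physics
(b/y ladders, isotope envelopes, charge states), heteroscedastic or
multimodal noise, and — most importantly — spectra that violate the
separation assumption, such as weak peptide spectra whose lowest signal
peaks are interleaved with the noise. Passing tests on synthetic data
therefore demonstrate that the implementation performs the scan correctly
and recovers planted structure, not that real ion trap data are this
cleanly separable; on real data the published operating characteristics
are markedly less than perfect, and the evaluation module exists precisely
to measure that against search-engine labels.

## Design choices

* "Greater than the threshold" is implemented as strict inequality
  (`SNR > snr_min`), the literal reading of the scan rule.
* Signal membership uses the *observed* abundance of the first signal
  peak as the cutoff; the noise level (the *predicted* abundance there) is
  reported separately. The two differ by the factor SNR at the boundary.
* Batch screening writes retained spectra with their original peak lists
  by default; denoised output (signal peaks only, original m/z order) is
  opt-in, since screening is about selecting spectra, and downstream
  search engines are usually given the unmodified peaks.
* Malformed MGF blocks are skipped and counted in batch mode rather than
  aborting the run — merged multi-experiment MGF files in practice contain
  stray blocks — while the plain reader errors loudly, naming the line.
* The report histograms bin the noise level in 0.1-wide bins of
  log10(intensity) (noise levels span orders of magnitude) and the signal
  count at integer resolution; spectra with no detected signal have no
  noise level and are excluded from the first histogram.
* The charge stratification of the evaluation comes from the label table,
  not from MGF `CHARGE` lines: the relevant classes reflect how spectra
  were *searched*, which the MGF alone cannot reconstruct. Charge is
  otherwise never used by the screen — the algorithm intentionally applies
  one parameter set to all spectra.
* `read_mgf()` parses eagerly and returns a list; the screening loop still
  writes its sinks one spectrum at a time. For desk-scale files (tens of
  thousands of spectra) memory is not a concern, and an R-idiomatic list
  beats a hand-rolled lazy iterator for inspectability.
* The label join uses MGF titles as identifiers, synthesizing
  `index=<position>` when a block lacks a `TITLE`, so joins remain
  possible for any input.

## Problem sizes used in the checks

The bundled tests run entirely on generated data: the noise-classification
check uses 200 simulated spectra of 100 peaks; the regression
cross-validation uses 1000 random prefixes of length 2–12 against a
brute-force grid minimizer; the labelled-dataset recovery uses 100 good
plus 100 bad spectra of 50–70 peaks. These sizes exercise every code path
while keeping the whole suite under half a minute.

## Known limitations

* The separation assumption is structural: a spectrum whose signal peaks
  interleave with its noise peaks will have its noise level overestimated
  and its signal count underestimated. The method screens; it does not
  identify.
* The linear noise model is a local approximation of the sorted-abundance
  curve; heavy-tailed noise (sporadic high spikes) can trigger the SNR
  threshold early and inflate the signal count.
* One parameter set applies to all spectra; charge-specific thresholds
  are deliberately unsupported.
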