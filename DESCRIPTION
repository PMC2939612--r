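Package: dnlscreen
Title: Dynamic Noise Level Screening of Tandem Mass Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quality screening of peptide tandem mass spectra (MS/MS) by
    dynamic noise level (DNL) estimation. For each spectrum the peak
    abundances are sorted and scanned from lowest to highest; an incremental
    linear regression over the sorted noise abundances predicts the next
    peak, and the first peak whose observed/predicted signal-to-noise ratio
    exceeds a threshold marks the noise level. Spectra with too few signal
    peaks are filtered before database searching. Includes Mascot Generic
    Format (MGF) input/output, batch screening with JSON reports, optional
    per-spectrum denoising, ROC-based evaluation against search-result
    labels, and seeded synthetic-spectrum generators for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
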