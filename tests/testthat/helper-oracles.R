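# Independent oracles and fixture builders shared across test files.

# Quick spectrum from a bare abundance vector; m/z defaults keep sort order
# deterministic without introducing abundance ties.
toy_spectrum <- function(intensity, mz = 100 + 10 * seq_along(intensity),
                         title = "toy") {
  mgf_spectrum(mz = mz, intensity = intensity, title = title)
}

# Brute-force least squares by coarse-to-fine 2-D grid refinement.
# Independent of the closed-form implementation: it only evaluates the
# residual sum of squares on a grid. The line is parametrized as
# y = s * (x - mean(x)) + c so the two grid axes are orthogonal in the RSS
# metric and the refinement cannot get trapped in a diagonal valley; the
# conventional intercept is recovered at the end.
grid_ols <- function(y, iters = 16L) {
  x <- seq_along(y)
  xc <- x - mean(x)
  scale <- max(abs(y), 1)
  s0 <- 0
  c0 <- 0
  half <- 2 * scale
  for (it in seq_len(iters)) {
    s <- seq(s0 - half, s0 + half, length.out = 21L)
    cc <- seq(c0 - half, c0 + half, length.out = 21L)
    g <- expand.grid(s = s, c = cc)
    pred <- outer(xc, g$s) +
      matrix(g$c, nrow = length(x), ncol = nrow(g), byrow = TRUE)
    rss <- colSums((pred - y)^2)
    best <- which.min(rss)
    s0 <- g$s[best]
    c0 <- g$c[best]
    half <- half / 5
  }
  list(slope = s0, intercept = c0 - s0 * mean(x))
}

# Write an MGF literal (vector of lines) to a temp file.
write_mgf_text <- function(lines, eol = "\n") {
  path <- tempfile(fileext = ".mgf")
  con <- file(path, "wb")
  writeChar(paste0(paste(lines, collapse = eol), eol), con,
            eos = NULL)
  close(con)
  path
}

decisions_frame <- function(identifier, signal_count,
                            retained = rep(TRUE, length(identifier))) {
  data.frame(identifier = identifier, retained = retained,
             signal_count = signal_count, stringsAsFactors = FALSE)
}

labels_frame <- function(identifier, category,
                         charge_class = rep(NA_character_,
                                            length(identifier))) {
  data.frame(identifier = identifier, category = category,
             charge_class = charge_class, stringsAsFactors = FALSE)
}
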