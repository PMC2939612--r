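#' Read spectra from a Mascot Generic Format (MGF) file
#'
#' Parses every `BEGIN IONS`/`END IONS` block into an [mgf_spectrum].
#' `TITLE`, `PEPMASS` (first number) and `CHARGE` are interpreted; other
#' header lines are ignored. Peak lines must contain at least two
#' whitespace-separated numbers, of which the first two are used. Windows
#' and Unix line endings and trailing blank lines are both accepted. A block
#' without a `TITLE` gets the synthetic identifier `index=<position>` so
#' that label joins stay possible.
#'
#' @param path path to an MGF file.
#' @param on_error `"stop"` (default) raises an error naming the offending
#'   line for malformed blocks; `"skip"` drops the malformed block with a
#'   warning and continues at the next `BEGIN IONS` (batch-mode behaviour).
#' @return A list of [mgf_spectrum] objects, in file order, with an
#'   attribute `skipped` giving the number of malformed blocks dropped
#'   (always 0 under `on_error = "stop"`). An empty file yields an empty
#'   list.
#' @seealso [write_mgf()], [screen_dataset()]
#' @export
read_mgf <- function(path, on_error = c("stop", "skip")) {
  on_error <- match.arg(on_error)
  if (!file.exists(path)) stop("MGF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)

  spectra <- list()
  skipped <- 0L
  n <- length(lines)
  i <- 1L
  idx <- 0L

  bad <- function(lineno, msg) {
    full <- sprintf("malformed MGF block at line %d: %s", lineno, msg)
    if (on_error == "stop") stop(full, call. = FALSE)
    warning(full, call. = FALSE)
  }

  while (i <= n) {
    line <- trimws(lines[[i]])
    if (!nzchar(line)) { i <- i + 1L; next }
    if (identical(line, "END IONS")) {
      bad(i, "END IONS without matching BEGIN IONS")
      skipped <- skipped + 1L
      i <- i + 1L
      next
    }
    if (!identical(line, "BEGIN IONS")) {
      # stray content between blocks is ignored (comments, CHARGE defaults)
      i <- i + 1L
      next
    }
    block_start <- i
    i <- i + 1L
    title <- NA_character_
    pepmass <- NA_real_
    charge <- integer()
    mz <- numeric()
    intensity <- numeric()
    ok <- TRUE
    closed <- FALSE
    while (i <= n) {
      line <- trimws(lines[[i]])
      if (identical(line, "END IONS")) { closed <- TRUE; i <- i + 1L; break }
      if (identical(line, "BEGIN IONS")) break
      if (!nzchar(line)) { i <- i + 1L; next }
      if (grepl("^[A-Za-z][A-Za-z0-9_]*=", line)) {
        eq <- regexpr("=", line, fixed = TRUE)
        key <- toupper(substr(line, 1L, eq - 1L))
        val <- trimws(substr(line, eq + 1L, nchar(line)))
        if (key == "TITLE") {
          title <- val
        } else if (key == "PEPMASS") {
          num <- suppressWarnings(as.numeric(strsplit(val, "[[:space:]]+")[[1L]][1L]))
          pepmass <- num
        } else if (key == "CHARGE") {
          charge <- parse_charge(val)
        }
        i <- i + 1L
        next
      }
      fields <- strsplit(line, "[[:space:]]+")[[1L]]
      vals <- suppressWarnings(as.numeric(fields))
      if (length(vals) < 2L || anyNA(vals[1:2])) {
        bad(i, sprintf("unparseable peak line '%s'", line))
        ok <- FALSE
        # skim forward to the end of this block
        while (i <= n && !identical(trimws(lines[[i]]), "END IONS") &&
               !identical(trimws(lines[[i]]), "BEGIN IONS"))
          i <- i + 1L
        if (i <= n && identical(trimws(lines[[i]]), "END IONS")) {
          closed <- TRUE
          i <- i + 1L
        }
        break
      }
      mz <- c(mz, vals[1L])
      intensity <- c(intensity, vals[2L])
      i <- i + 1L
    }
    if (!closed && ok) {
      bad(block_start, "BEGIN IONS without matching END IONS")
      ok <- FALSE
    }
    if (ok) {
      if (is.na(title) || !nzchar(title)) title <- sprintf("index=%d", idx)
      spectra[[length(spectra) + 1L]] <-
        mgf_spectrum(mz = mz, intensity = intensity, title = title,
                     pepmass = pepmass, charge = charge, index = idx)
    } else {
      skipped <- skipped + 1L
    }
    idx <- idx + 1L
  }
  attr(spectra, "skipped") <- skipped
  spectra
}

# "2+", "2+ and 3+", "2+,3+", "3-", bare "2" all accepted
parse_charge <- function(val) {
  m <- regmatches(val, gregexpr("[0-9]+[+-]?", val))[[1L]]
  if (!length(m)) return(integer())
  sign <- ifelse(grepl("-$", m), -1L, 1L)
  as.integer(sub("[+-]$", "", m)) * sign
}

#' Write spectra to an MGF file
#'
#' The inverse of [read_mgf()]: m/z and abundance values are rendered with
#' nine significant digits so that a write/read round trip reproduces the
#' peak list to well within 1e-6 relative. Output is deterministic: the same
#' spectra always produce byte-identical files.
#'
#' @param spectra a list of [mgf_spectrum] objects (or a single spectrum).
#' @param path output path.
#' @return Invisibly, the number of spectra written.
#' @export
write_mgf <- function(spectra, path) {
  if (inherits(spectra, "mgf_spectrum")) spectra <- list(spectra)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (sp in spectra) write_mgf_block(sp, con)
  invisible(length(spectra))
}

write_mgf_block <- function(sp, con) {
  out <- c("BEGIN IONS", paste0("TITLE=", sp$title))
  if (!is.na(sp$pepmass))
    out <- c(out, paste0("PEPMASS=", sprintf("%.9g", sp$pepmass)))
  if (length(sp$charge))
    out <- c(out, paste0("CHARGE=",
                         paste(format_charge(sp$charge), collapse = " and ")))
  if (length(sp$mz))
    out <- c(out, sprintf("%.9g %.9g", sp$mz, sp$intensity))
  out <- c(out, "END IONS", "")
  writeLines(out, con)
  invisible(NULL)
}

#' Read a label table for screening evaluation
#'
#' Reads the tab-separated table that assigns each spectrum identifier to a
#' database-search outcome: `TP` (true-positive match), `FP` (decoy match)
#' or `unidentified` (no significant match). An optional third column gives
#' the precursor-charge class, `single` or `multi`, used to stratify ROC
#' curves. Category and charge-class tokens are case-insensitive; lines
#' starting with `#` are skipped.
#'
#' @param path path to a TSV file with columns identifier, category and
#'   optionally charge_class; no header required.
#' @return A data.frame with columns `identifier`, `category` and
#'   `charge_class` (`NA` where absent).
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  keep <- nzchar(trimws(lines)) & !grepl("^#", lines)
  ids <- character(); cats <- character(); chg <- character()
  for (ln in which(keep)) {
    fields <- strsplit(lines[[ln]], "\t", fixed = TRUE)[[1L]]
    fields <- trimws(fields)
    if (length(fields) < 2L)
      stop("label line ", ln, " has fewer than 2 tab-separated fields")
    cat_raw <- tolower(fields[[2L]])
    category <- switch(cat_raw,
                       tp = "TP", fp = "FP", unidentified = "unidentified",
                       stop("unknown category '", fields[[2L]],
                            "' on label line ", ln))
    cc <- NA_character_
    if (length(fields) >= 3L && nzchar(fields[[3L]])) {
      cc_raw <- tolower(fields[[3L]])
      if (!cc_raw %in% c("single", "multi"))
        stop("unknown charge class '", fields[[3L]], "' on label line ", ln)
      cc <- cc_raw
    }
    ids <- c(ids, fields[[1L]])
    cats <- c(cats, category)
    chg <- c(chg, cc)
  }
  if (anyDuplicated(ids))
    stop("duplicate identifier(s) in label table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  data.frame(identifier = ids, category = cats, charge_class = chg,
             stringsAsFactors = FALSE)
}
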