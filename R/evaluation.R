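#' Sensitivity and specificity of a screening run
#'
#' Scores screening decisions against database-search labels. Spectra
#' labelled `FP` or `unidentified` are the "bad" class the screen should
#' remove; spectra labelled `TP` are the "good" class it should keep.
#' Sensitivity is the fraction of bad spectra correctly filtered;
#' specificity is one minus the fraction of TP spectra falsely filtered.
#' Either is `NA` when its class is empty.
#'
#' @param decisions data.frame with columns `identifier` and `retained`
#'   (e.g. the `decisions` element of a [screen_dataset()] report).
#' @param labels label table from [read_labels()] (columns `identifier`,
#'   `category`).
#' @return An object of class `dnl_eval`: the category-by-outcome count
#'   table, `sensitivity` and `specificity`.
#' @export
evaluate_screening <- function(decisions, labels) {
  joined <- join_labels(decisions, labels)
  filtered <- !joined$retained
  category <- factor(joined$category,
                     levels = c("TP", "FP", "unidentified"))
  counts <- table(category = category,
                  outcome = factor(ifelse(filtered, "filtered", "retained"),
                                   levels = c("filtered", "retained")))
  bad <- category %in% c("FP", "unidentified")
  good <- category == "TP"
  sensitivity <- if (any(bad)) sum(filtered & bad) / sum(bad) else NA_real_
  specificity <- if (any(good)) 1 - sum(filtered & good) / sum(good)
                 else NA_real_
  structure(list(counts = counts, sensitivity = sensitivity,
                 specificity = specificity),
            class = "dnl_eval")
}

join_labels <- function(decisions, labels) {
  stopifnot(is.data.frame(decisions),
            all(c("identifier", "retained") %in% names(decisions)))
  idx <- match(decisions$identifier, labels$identifier)
  if (anyNA(idx))
    stop("decisions without a label: ",
         paste(utils::head(decisions$identifier[is.na(idx)], 10L),
               collapse = ", "))
  extra <- setdiff(labels$identifier, decisions$identifier)
  if (length(extra))
    warning(length(extra), " labelled spectra absent from decisions ",
            "were ignored")
  cbind(decisions,
        category = labels$category[idx],
        charge_class = labels$charge_class[idx],
        stringsAsFactors = FALSE)
}

#' @export
print.dnl_eval <- function(x, ...) {
  cat("Screening evaluation\n")
  print(x$counts)
  cat("sensitivity (bad spectra filtered): ",
      if (is.na(x$sensitivity)) "undefined" else
        sprintf("%.4f", x$sensitivity), "\n", sep = "")
  cat("specificity (TP spectra kept):      ",
      if (is.na(x$specificity)) "undefined" else
        sprintf("%.4f", x$specificity), "\n", sep = "")
  invisible(x)
}

#' ROC curve over the signal-count threshold
#'
#' Sweeps the retention threshold `n_min` from 0 (nothing filtered) to one
#' beyond the largest observed signal count (everything filtered) and
#' records, at each setting, the sensitivity against one minus the
#' specificity. Because the discriminant is the integer signal count, the
#' curve is a finite threshold sweep, and the area under it is computed by
#' the trapezoid rule over the sweep-ordered points (vertical segments
#' contribute nothing, so the result is the exact step-curve area).
#'
#' @param decisions data.frame with columns `identifier` and
#'   `signal_count`.
#' @param labels label table from [read_labels()].
#' @param charge_class optional `"single"` or `"multi"`: restrict the
#'   evaluation to spectra of that precursor-charge class (requires the
#'   label table's `charge_class` column).
#' @param sweep_max optional upper end of the `n_min` sweep; defaults to
#'   `max(signal_count) + 1`.
#' @return An object of class `dnl_roc`: data.frame `points` with columns
#'   `n_min`, `fpr` (1 - specificity) and `sensitivity`, plus `auc`.
#' @export
roc_over_nmin <- function(decisions, labels, charge_class = NULL,
                          sweep_max = NULL) {
  stopifnot(is.data.frame(decisions),
            all(c("identifier", "signal_count") %in% names(decisions)))
  if (!is.null(charge_class)) {
    charge_class <- match.arg(charge_class, c("single", "multi"))
    labels <- labels[!is.na(labels$charge_class) &
                       labels$charge_class == charge_class, , drop = FALSE]
    decisions <- decisions[decisions$identifier %in% labels$identifier, ,
                           drop = FALSE]
  }
  decisions$retained <- TRUE  # placeholder for the join; sweep sets it
  joined <- join_labels(decisions, labels)
  bad <- joined$category %in% c("FP", "unidentified")
  good <- joined$category == "TP"
  if (!any(bad) || !any(good))
    stop("ROC analysis needs at least one TP and one FP/unidentified ",
         "spectrum", if (!is.null(charge_class))
           paste0(" in charge class '", charge_class, "'"))
  n <- joined$signal_count
  if (is.null(sweep_max)) sweep_max <- max(n) + 1L
  thresholds <- 0:sweep_max
  sens <- fpr <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    filtered <- n < thresholds[i]
    sens[i] <- sum(filtered & bad) / sum(bad)
    fpr[i] <- sum(filtered & good) / sum(good)
  }
  points <- data.frame(n_min = thresholds, fpr = fpr, sensitivity = sens)
  auc <- trapezoid_auc(fpr, sens)
  structure(list(points = points, auc = auc), class = "dnl_roc")
}

# trapezoid over sweep-ordered (x, y); x and y are monotone non-decreasing
trapezoid_auc <- function(x, y) {
  if (length(x) < 2L) return(NA_real_)
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

#' @export
print.dnl_roc <- function(x, ...) {
  cat("ROC over n_min sweep (", nrow(x$points), " thresholds), AUC = ",
      sprintf("%.4f", x$auc), "\n", sep = "")
  invisible(x)
}

#' Plot a ROC curve
#'
#' @param x a `dnl_roc`.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.dnl_roc <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$sensitivity, type = "b",
                 xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("AUC = %.4f", x$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Filtered and retained fractions per label category
#'
#' Tallies, for each search-result category (TP, FP, unidentified), how
#' many spectra the screen filtered and retained and the corresponding
#' fractions. Fractions are `NA` for categories with no spectra.
#'
#' @inheritParams evaluate_screening
#' @return data.frame with one row per category: `n`, `filtered`,
#'   `retained`, `fraction_filtered`, `fraction_retained`.
#' @export
category_tally <- function(decisions, labels) {
  joined <- join_labels(decisions, labels)
  cats <- c("TP", "FP", "unidentified")
  out <- lapply(cats, function(cc) {
    sel <- joined$category == cc
    n <- sum(sel)
    nf <- sum(sel & !joined$retained)
    data.frame(category = cc, n = n, filtered = nf, retained = n - nf,
               fraction_filtered = if (n) nf / n else NA_real_,
               fraction_retained = if (n) (n - nf) / n else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
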