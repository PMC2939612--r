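test_that("evaluate_screening computes the two ratios from the counts", {
  # 100 bad of which 80 filtered; 50 TP of which 2 filtered
  ids <- c(sprintf("bad_%03d", 1:100), sprintf("tp_%03d", 1:50))
  retained <- c(rep(FALSE, 80), rep(TRUE, 20), rep(FALSE, 2), rep(TRUE, 48))
  dec <- decisions_frame(ids, signal_count = rep(0L, 150),
                         retained = retained)
  lab <- labels_frame(ids, c(rep("unidentified", 50), rep("FP", 50),
                             rep("TP", 50)))
  ev <- evaluate_screening(dec, lab)
  expect_equal(ev$sensitivity, 0.80)
  expect_equal(ev$specificity, 0.96)
  expect_identical(sum(ev$counts), 150L)
  expect_identical(unname(ev$counts["TP", "filtered"]), 2L)
})

test_that("empty denominators give absent ratios", {
  dec <- decisions_frame(c("a", "b"), c(10L, 12L), retained = c(TRUE, TRUE))
  ev <- evaluate_screening(dec, labels_frame(c("a", "b"), c("TP", "TP")))
  expect_equal(ev$specificity, 1)
  expect_true(is.na(ev$sensitivity))

  dec2 <- decisions_frame(sprintf("x%d", 1:10), rep(0L, 10),
                          retained = rep(FALSE, 10))
  ev2 <- evaluate_screening(dec2, labels_frame(sprintf("x%d", 1:10),
                                               rep("unidentified", 10)))
  expect_equal(ev2$sensitivity, 1)
  expect_true(is.na(ev2$specificity))
})

test_that("label joins are validated", {
  dec <- decisions_frame(c("a", "b"), c(1L, 2L))
  expect_error(evaluate_screening(dec, labels_frame("a", "TP")), "b")
  expect_warning(
    evaluate_screening(decisions_frame("a", 1L, retained = FALSE),
                       labels_frame(c("a", "zzz"), c("TP", "FP"))),
    "ignored")
})

test_that("roc_over_nmin reproduces the enumerated toy sweep", {
  # bad signal counts {1, 3}, good {2, 4}; AUC by rank statistic = 0.75
  dec <- decisions_frame(c("b1", "b2", "g1", "g2"), c(1L, 3L, 2L, 4L))
  lab <- labels_frame(c("b1", "b2", "g1", "g2"),
                      c("unidentified", "FP", "TP", "TP"))
  roc <- roc_over_nmin(dec, lab)
  expect_identical(roc$points$n_min, 0:5)
  expect_equal(roc$points$sensitivity, c(0, 0, 0.5, 0.5, 1, 1))
  expect_equal(roc$points$fpr, c(0, 0, 0, 0.5, 0.5, 1))
  expect_equal(roc$auc, 0.75)

  # endpoints: nothing filtered at n_min = 0, everything beyond the max
  expect_equal(unlist(roc$points[1L, c("fpr", "sensitivity")]),
               c(fpr = 0, sensitivity = 0))
  expect_equal(unlist(roc$points[nrow(roc$points),
                                 c("fpr", "sensitivity")]),
               c(fpr = 1, sensitivity = 1))
})

test_that("the trapezoid AUC agrees with pROC on random data", {
  skip_if_not_installed("pROC")
  set.seed(99)
  for (rep in 1:5) {
    n_bad <- sample(10:40, 1L)
    n_good <- sample(10:40, 1L)
    bad_n <- rpois(n_bad, 4)
    good_n <- rpois(n_good, 9)
    dec <- decisions_frame(sprintf("s%03d", seq_len(n_bad + n_good)),
                           as.integer(c(bad_n, good_n)))
    lab <- labels_frame(dec$identifier,
                        c(rep("unidentified", n_bad), rep("TP", n_good)))
    roc <- roc_over_nmin(dec, lab)
    ref <- suppressMessages(
      pROC::auc(pROC::roc(controls = bad_n, cases = good_n,
                          direction = "<", quiet = TRUE)))
    expect_equal(roc$auc, as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("ROC curves are monotone with AUC in [0, 1]", {
  set.seed(7)
  for (rep in 1:6) {
    n <- 40L
    counts <- as.integer(rpois(n, 6))
    cats <- sample(c("TP", "FP", "unidentified"), n, replace = TRUE,
                   prob = c(0.4, 0.2, 0.4))
    # guarantee both classes occur
    cats[1L] <- "TP"; cats[2L] <- "unidentified"
    dec <- decisions_frame(sprintf("s%03d", 1:n), counts)
    roc <- roc_over_nmin(dec, labels_frame(dec$identifier, cats))
    expect_true(all(diff(roc$points$sensitivity) >= 0))
    expect_true(all(diff(roc$points$fpr) >= 0))
    expect_gte(roc$auc, 0)
    expect_lte(roc$auc, 1)
  }
})

test_that("perfect separation gives AUC 1; uninformative labels give ~0.5", {
  dec <- decisions_frame(sprintf("s%02d", 1:20),
                         as.integer(c(1:10, 21:30)))
  lab <- labels_frame(dec$identifier,
                      c(rep("unidentified", 10), rep("TP", 10)))
  expect_equal(roc_over_nmin(dec, lab)$auc, 1)

  set.seed(123)
  counts <- as.integer(rpois(2000, 8))
  cats <- sample(c("TP", "unidentified"), 2000, replace = TRUE)
  dec2 <- decisions_frame(sprintf("s%04d", 1:2000), counts)
  auc <- roc_over_nmin(dec2, labels_frame(dec2$identifier, cats))$auc
  expect_lt(abs(auc - 0.5), 0.05)
})

test_that("evaluate at a sweep threshold equals the matching ROC point", {
  set.seed(31)
  counts <- as.integer(rpois(60, 7))
  cats <- c(rep("TP", 30), rep("unidentified", 30))
  ids <- sprintf("s%03d", 1:60)
  lab <- labels_frame(ids, cats)
  roc <- roc_over_nmin(decisions_frame(ids, counts), lab)
  for (nm in c(0L, 3L, 8L, 12L)) {
    dec <- decisions_frame(ids, counts, retained = counts >= nm)
    ev <- evaluate_screening(dec, lab)
    pt <- roc$points[roc$points$n_min == nm, ]
    expect_equal(ev$sensitivity, pt$sensitivity)
    expect_equal(1 - ev$specificity, pt$fpr)
  }
})

test_that("charge-class stratification restricts the ROC to the subset", {
  ids <- sprintf("s%02d", 1:40)
  counts <- as.integer(c(rpois(20, 3), rpois(20, 10)))
  cats <- rep(c("unidentified", "TP"), each = 20)
  charge <- rep(c("single", "multi"), times = 20)
  lab <- labels_frame(ids, cats, charge)
  dec <- decisions_frame(ids, counts)
  roc_single <- roc_over_nmin(dec, lab, charge_class = "single")
  sub <- charge == "single"
  ref <- roc_over_nmin(decisions_frame(ids[sub], counts[sub]),
                       labels_frame(ids[sub], cats[sub]))
  expect_equal(roc_single$auc, ref$auc)

  only_tp <- labels_frame(ids[cats == "TP"], cats[cats == "TP"])
  expect_error(roc_over_nmin(decisions_frame(ids[cats == "TP"],
                                             counts[cats == "TP"]),
                             only_tp),
               "at least one")
})

test_that("category_tally reports per-category filtered fractions", {
  ids <- c(sprintf("u%d", 1:4), sprintf("t%d", 1:2))
  dec <- decisions_frame(ids, rep(0L, 6),
                         retained = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  lab <- labels_frame(ids, c(rep("unidentified", 4), rep("TP", 2)))
  tal <- category_tally(dec, lab)
  expect_equal(tal$fraction_filtered[tal$category == "unidentified"], 0.75)
  expect_true(is.na(tal$fraction_filtered[tal$category == "FP"]))
  expect_equal(tal$fraction_retained[tal$category == "TP"], 1)
  expect_identical(sum(tal$n), 6L)
})

test_that("category_tally matches ground truth on a synthetic dataset", {
  mgf <- tempfile(fileext = ".mgf")
  tsv <- tempfile(fileext = ".tsv")
  simulate_labelled_dataset(15, 15, mgf, tsv, seed = 21)
  rpt <- screen_dataset(mgf)
  lab <- read_labels(tsv)
  tal <- category_tally(rpt$decisions, lab)
  # direct count, bypassing category_tally
  joined_filtered <- !rpt$decisions$retained[
    match(lab$identifier, rpt$decisions$identifier)]
  for (cc in c("TP", "unidentified")) {
    expect_equal(tal$filtered[tal$category == cc],
                 sum(joined_filtered[lab$category == cc]))
  }
})
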