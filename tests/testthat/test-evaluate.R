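test_that("histopathologic categories map to the fixed benign/premalignant classes", {
  expect_equal(map_histopathology_to_class("hyperplastic polyp"), "benign")
  expect_equal(map_histopathology_to_class("regular mucosa"), "benign")
  expect_equal(map_histopathology_to_class("lipomatous polyp"), "benign")
  expect_equal(map_histopathology_to_class("adenocarcinoma"), "premalignant")
  expect_equal(
    map_histopathology_to_class(c("tubular adenoma", "tubulovillous adenoma",
                                  "villous adenoma", "serrated adenoma")),
    rep("premalignant", 4))
  # case and whitespace are normalised before lookup
  expect_equal(map_histopathology_to_class("Tubular Adenoma "), "premalignant")
  expect_equal(map_histopathology_to_class("  HYPERPLASTIC  POLYP"), "benign")
  expect_error(map_histopathology_to_class("fibroma"), "accepted values")
})

test_that("maximum 3D diameter matches hand-computable geometries", {
  m <- array(0L, dim = c(7, 7, 7))
  m[4, 4, 4] <- 1L
  expect_equal(max_3d_diameter(m), 0)
  m[5, 4, 4] <- 1L
  expect_equal(max_3d_diameter(m, c(1, 1, 1)), 1)
  expect_equal(max_3d_diameter(m, c(2, 1, 1)), 2)
  cube <- array(0L, dim = c(7, 7, 7))
  cube[3:5, 3:5, 3:5] <- 1L
  expect_equal(max_3d_diameter(cube), sqrt(12), tolerance = 1e-12)
  expect_error(max_3d_diameter(array(0L, dim = c(3, 3, 3))), "empty")
})

test_that("boundary-voxel diameter equals the all-pairs computation on random masks", {
  set.seed(42)
  for (i in 1:100) {
    m <- random_mask()
    sp <- runif(3, 0.5, 2)
    expect_equal(max_3d_diameter(m, sp), oracle_diameter(m, sp),
                 tolerance = 1e-12)
  }
})

test_that("size strata use half-up integer rounding of the diameter", {
  expect_equal(as.character(size_stratum(c(5.4, 5.5, 9.4, 9.6, 0, 12))),
               c("<=5mm", "6-9mm", "6-9mm", ">=10mm", "<=5mm", ">=10mm"))
  expect_error(size_stratum(-1), "non-negative")
  # every diameter falls in exactly one stratum
  d <- runif(50, 0, 20)
  expect_false(anyNA(size_stratum(d)))
})

test_that("roc_auc is the Mann-Whitney statistic with ties counted half", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 10), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.5, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
  set.seed(7)
  for (i in 1:100) {
    n <- sample(4:200, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- round(runif(n), sample(1:3, 1))  # coarse scores force ties
    expect_equal(roc_auc(s, y), oracle_auc(s, y), tolerance = 1e-12)
  }
})

test_that("threshold selection maximises specificity at the sensitivity floor", {
  s <- c(0.1, 0.2, 0.6, 0.9); y <- c(0, 0, 1, 1)
  thr <- select_threshold(s, y, 0.8)
  cm <- confusion_metrics(s, y, thr)
  expect_equal(cm$fraction, c(1, 1))  # perfectly separated
  # target sensitivity 1 captures every positive
  expect_lte(select_threshold(s, y, 1), 0.6)
  set.seed(11)
  for (i in 1:60) {
    n <- sample(6:100, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- round(runif(n), 2)
    thr <- select_threshold(s, y, 0.8)
    expect_equal(thr, oracle_threshold(s, y, 0.8))
  }
})

test_that("confusion metrics report half-up whole percents with exact counts", {
  # sensitivity 63/79 -> 80%, specificity 27/39 -> 69%
  s <- c(rep(1, 63), rep(0, 16), rep(0, 27), rep(1, 12))
  y <- c(rep(1, 79), rep(0, 39))
  cm <- confusion_metrics(s, y, 0.5)
  expect_equal(cm$numerator, c(63, 27))
  expect_equal(cm$denominator, c(79, 39))
  expect_equal(cm$percent, c(80, 69))
  # 17/39 -> 44%
  s2 <- c(rep(1, 63), rep(0, 16), rep(0, 17), rep(1, 22))
  expect_equal(confusion_metrics(s2, y, 0.5)$percent[2], 44)
})

test_that("per-category accuracy counts reconcile with the overall count", {
  set.seed(3)
  cats <- sample(c("hyperplastic polyp", "tubular adenoma",
                   "tubulovillous adenoma", "regular mucosa"), 60,
                 replace = TRUE)
  rec <- tibble::tibble(histopathologic_category = cats)
  truth <- map_histopathology_to_class(cats)
  pred <- ifelse(runif(60) < 0.7, truth,
                 ifelse(truth == "benign", "premalignant", "benign"))
  acc <- category_accuracy(pred, rec)
  expect_equal(sum(acc$correct), sum(pred == truth))
  expect_equal(sum(acc$total), 60)
  # empty categories report 0/0 with no percentage
  empty <- acc[acc$category == "villous adenoma", ]
  expect_equal(empty$total, 0)
  expect_true(is.na(empty$percent))
})

test_that("worked example: 23 of 26 tubulovillous adenomas is 88%", {
  rec <- tibble::tibble(
    histopathologic_category = rep("tubulovillous adenoma", 26))
  pred <- c(rep("premalignant", 23), rep("benign", 3))
  acc <- category_accuracy(pred, rec)
  row <- acc[acc$category == "tubulovillous adenoma", ]
  expect_equal(c(row$correct, row$total, row$percent), c(23, 26, 88))
})

test_that("cohort summary reproduces printed-style counts and subtotals", {
  counts <- c("regular mucosa" = 3, "hyperplastic polyp" = 78,
              "lipomatous polyp" = 2, "tubular adenoma" = 57,
              "tubulovillous adenoma" = 16, "villous adenoma" = 8,
              "serrated adenoma" = 4, "adenocarcinoma" = 1)
  manifest <- tibble::tibble(
    histopathologic_category = rep(names(counts), counts))
  tab <- summarize_cohort(manifest)
  expect_equal(sum(tab$n), 169)
  expect_equal(unname(attr(tab, "class_totals")["premalignant"]), 86)
  expect_equal(unname(attr(tab, "class_totals")["benign"]), 83)
  expect_equal(tab$percent[tab$category == "hyperplastic polyp"], 46)
  expect_equal(tab$percent[tab$category == "tubular adenoma"], 34)
})

test_that("evaluate_scores assembles a self-consistent report", {
  set.seed(5)
  n <- 80
  cats <- sample(names(polypcnn:::histopathology_classes)[c(2, 4, 5)], n,
                 replace = TRUE)
  labels <- map_histopathology_to_class(cats) == "premalignant"
  scores <- pmin(pmax(labels * 0.4 + runif(n, 0, 0.6), 0), 1)
  manifest <- tibble::tibble(
    polyp_id = sprintf("P%03d_L1", seq_len(n)),
    position = "supine",
    histopathologic_category = cats,
    diameter_mm = runif(n, 3, 14))
  rep <- evaluate_scores(scores, manifest)
  expect_s3_class(rep, "polyp_eval")
  expect_equal(rep$auc, roc_auc(scores, as.integer(labels)))
  expect_equal(sum(rep$confusion$denominator), n)
  expect_equal(sum(rep$subgroup_aucs$n), n)
  expect_equal(sum(rep$category_accuracy$total), n)
  td <- tidy(rep)
  expect_true(all(c("auc", "sensitivity", "specificity") %in% td$metric))
  gl <- glance(rep)
  expect_equal(gl$n, n)
  expect_s3_class(autoplot(rep), "ggplot")
})
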