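histopathology_classes <- c(
  "regular mucosa" = "benign",
  "hyperplastic polyp" = "benign",
  "lipomatous polyp" = "benign",
  "tubular adenoma" = "premalignant",
  "tubulovillous adenoma" = "premalignant",
  "villous adenoma" = "premalignant",
  "serrated adenoma" = "premalignant",
  "adenocarcinoma" = "premalignant")

#' Map a histopathologic category to the benign/premalignant class
#'
#' Regular mucosa, hyperplastic and lipomatous polyps are benign; tubular,
#' tubulovillous, villous and serrated adenomas and adenocarcinomas are
#' premalignant. Categories are normalised for case and surrounding
#' whitespace before lookup.
#'
#' @param category Character vector of histopathologic categories.
#' @return Character vector of `"benign"` / `"premalignant"`.
#' @export
map_histopathology_to_class <- function(category) {
  key <- gsub("\\s+", " ", trimws(tolower(category)))
  # accept the bare "lipomatous" wording as well
  key[key == "lipomatous"] <- "lipomatous polyp"
  out <- histopathology_classes[key]
  if (anyNA(out))
    abort(paste0("unknown histopathologic category: ",
                 paste(unique(category[is.na(out)]), collapse = ", "),
                 "; accepted values: ",
                 paste(names(histopathology_classes), collapse = ", ")))
  unname(out)
}

#' Maximum 3D diameter of a segmentation mask
#'
#' The maximum Euclidean distance in mm between any two mask-voxel centres.
#' Computed on the mask's boundary voxels, which yields the same value as
#' the all-pairs computation since extremal points lie on the boundary.
#'
#' @param mask Binary 3D array.
#' @param spacing_mm Voxel spacing triple in mm.
#' @return Diameter in mm (0 for a single voxel).
#' @export
max_3d_diameter <- function(mask, spacing_mm = c(1, 1, 1)) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) abort("mask is empty: diameter is undefined")
  if (nrow(idx) == 1) return(0)
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 3)
  d <- dim(mask)
  on_boundary <- function(ix) {
    out <- rep(FALSE, nrow(ix))
    for (a in 1:3) for (s in c(-1L, 1L)) {
      nb <- ix
      nb[, a] <- nb[, a] + s
      edge <- nb[, a] < 1 | nb[, a] > d[a]
      inner <- !edge
      free <- edge
      free[inner] <- mask[nb[inner, , drop = FALSE]] == 0
      out <- out | free
    }
    out
  }
  b <- idx[on_boundary(idx), , drop = FALSE]
  pts <- sweep(b - 1, 2, spacing_mm, "*")
  max(stats::dist(pts))
}

#' Polyp size stratum from the maximum 3D diameter
#'
#' The diameter is rounded to the nearest integer millimetre (half up) and
#' binned into the `<=5`, `6-9` and `>=10` mm strata.
#'
#' @param diameter_mm Non-negative diameters in mm.
#' @return Factor with levels `"<=5mm"`, `"6-9mm"`, `">=10mm"`.
#' @export
size_stratum <- function(diameter_mm) {
  if (any(diameter_mm < 0)) abort("diameters must be non-negative")
  r <- round_half_up(diameter_mm)
  factor(ifelse(r <= 5, "<=5mm", ifelse(r <= 9, "6-9mm", ">=10mm")),
         levels = c("<=5mm", "6-9mm", ">=10mm"))
}

#' Area under the ROC curve
#'
#' The Mann-Whitney two-sample statistic (ties counted half), identical to
#' trapezoidal integration of the empirical ROC curve.
#'
#' @param scores Numeric scores (higher = more premalignant).
#' @param labels Binary labels (1 = premalignant).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("AUC undefined: both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Candidate thresholds: midpoints between adjacent distinct scores plus
# sentinels below the minimum (classify all positive) and above the maximum.
threshold_candidates <- function(scores) {
  s <- sort(unique(scores))
  c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, s[length(s)] + 1)
}

#' Select a classification threshold at a fixed sensitivity
#'
#' Among candidate thresholds (midpoints between adjacent distinct scores
#' plus sentinels), returns the one that maximises specificity subject to
#' sensitivity >= `target_sensitivity`, breaking ties toward the larger
#' threshold. The prediction rule is `score >= threshold` implies
#' premalignant. If only the classify-all-positive sentinel attains the
#' target, it is returned with a warning.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (1 = premalignant).
#' @param target_sensitivity Sensitivity floor in (0, 1]; default 0.80.
#' @return The selected threshold.
#' @export
select_threshold <- function(scores, labels, target_sensitivity = 0.80) {
  labels <- as.integer(labels)
  if (!any(labels == 1) || !any(labels == 0))
    abort("both classes must be present")
  if (target_sensitivity <= 0 || target_sensitivity > 1)
    abort("`target_sensitivity` must lie in (0, 1]")
  cand <- threshold_candidates(scores)
  P <- sum(labels == 1); N <- sum(labels == 0)
  sens <- vapply(cand, function(t) sum(scores >= t & labels == 1) / P,
                 numeric(1))
  spec <- vapply(cand, function(t) sum(scores < t & labels == 0) / N,
                 numeric(1))
  ok <- sens >= target_sensitivity
  if (sum(ok) == 1 && which(ok) == 1L)
    warn("only the classify-all-positive threshold attains the target sensitivity")
  best_spec <- max(spec[ok])
  max(cand[ok & spec == best_spec])   # ties break toward the larger threshold
}

#' Sensitivity and specificity at a threshold
#'
#' Counts with the rule `score >= threshold` implies premalignant.
#' Whole-percent values are rounded half-up from the exact fractions.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (1 = premalignant).
#' @param threshold Classification threshold.
#' @return A tibble with one row per metric: numerator, denominator,
#'   fraction and whole percent.
#' @export
confusion_metrics <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  if (!any(labels == 1) || !any(labels == 0))
    abort("both classes must be present")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); P <- sum(labels == 1)
  tn <- sum(pred == 0 & labels == 0); N <- sum(labels == 0)
  tibble(metric = c("sensitivity", "specificity"),
         numerator = c(tp, tn), denominator = c(P, N),
         fraction = c(tp / P, tn / N),
         percent = percent_half_up(c(tp, tn), c(P, N)))
}

#' Per-category prediction accuracy
#'
#' A record is correct when its predicted class equals the class its
#' histopathologic category maps to. Categories with no records are
#' reported as 0/0 without a percentage.
#'
#' @param predicted Character vector of predicted classes
#'   (`"benign"`/`"premalignant"`), aligned with `records`.
#' @param records Tibble with a `histopathologic_category` column.
#' @return A tibble: category, class, correct, total, percent.
#' @export
category_accuracy <- function(predicted, records) {
  stopifnot(length(predicted) == nrow(records))
  truth <- map_histopathology_to_class(records$histopathologic_category)
  cat_norm <- gsub("\\s+", " ", trimws(tolower(records$histopathologic_category)))
  all_cats <- names(histopathology_classes)
  out <- lapply(all_cats, function(cc) {
    sel <- cat_norm == cc
    tibble(category = cc, class = unname(histopathology_classes[cc]),
           correct = sum(sel & predicted == truth), total = sum(sel))
  })
  out <- dplyr::bind_rows(out)
  out$percent <- percent_half_up(out$correct, out$total)
  out
}

#' Cohort composition table by histopathologic category
#'
#' Per-category segmentation counts with whole-percent shares of the column
#' total (half-up) and the benign/premalignant subtotals implied by the
#' class mapping.
#'
#' @param manifest Tibble with one row per segmentation and a
#'   `histopathologic_category` column.
#' @return A tibble: category, class, n, total, percent; class subtotals
#'   are attached as the `class_totals` attribute.
#' @export
summarize_cohort <- function(manifest) {
  cat_norm <- gsub("\\s+", " ", trimws(tolower(manifest$histopathologic_category)))
  total <- nrow(manifest)
  out <- dplyr::bind_rows(lapply(names(histopathology_classes), function(cc)
    tibble(category = cc, class = unname(histopathology_classes[cc]),
           n = sum(cat_norm == cc), total = total)))
  out$percent <- percent_half_up(out$n, out$total)
  cls <- map_histopathology_to_class(manifest$histopathologic_category)
  attr(out, "class_totals") <- c(benign = sum(cls == "benign"),
                                 premalignant = sum(cls == "premalignant"))
  out
}

#' Evaluate an ensemble on a test cohort
#'
#' Scores every segmentation, computes the ROC-AUC, selects (or applies) a
#' classification threshold at the target sensitivity, and assembles the
#' standard report: sensitivity and specificity with integer
#' numerators/denominators, per-size-stratum AUCs (strata derived from the
#' mask-based maximum 3D diameters in the manifest), and per-category
#' accuracy.
#'
#' @param ensemble A trained `polyp_ensemble`.
#' @param dataset A `model_dataset` for the test cohort (50^3 grid or
#'   centre-croppable).
#' @param target_sensitivity Sensitivity floor for threshold selection.
#' @param threshold `NULL` to select the threshold on these scores (the
#'   replication mode), or a fixed numeric threshold fitted elsewhere.
#' @return A `polyp_eval` object.
#' @export
evaluate_ensemble <- function(ensemble, dataset, target_sensitivity = 0.80,
                              threshold = NULL) {
  stopifnot(inherits(ensemble, "polyp_ensemble"),
            inherits(dataset, "model_dataset"))
  dataset <- dataset_centre_crop(dataset)
  scores <- predict(ensemble, dataset)
  evaluate_scores(scores, dataset$manifest,
                  target_sensitivity = target_sensitivity,
                  threshold = threshold, variant = ensemble$variant)
}

#' Evaluate a score vector against a manifest
#'
#' The score-level core of [evaluate_ensemble()], usable with scores read
#' back from a CSV.
#'
#' @param scores Numeric scores aligned with `manifest` rows.
#' @param manifest Segmentation manifest with `histopathologic_category`
#'   and `diameter_mm` columns.
#' @param target_sensitivity Sensitivity floor for threshold selection.
#' @param threshold Optional fixed threshold; selected from the scores when
#'   `NULL`.
#' @param variant Variant label recorded in the report.
#' @return A `polyp_eval` object.
#' @export
evaluate_scores <- function(scores, manifest, target_sensitivity = 0.80,
                            threshold = NULL, variant = NA_character_) {
  labels <- as.integer(
    map_histopathology_to_class(manifest$histopathologic_category) ==
      "premalignant")
  auc <- roc_auc(scores, labels)
  threshold_source <- if (is.null(threshold)) "evaluation" else "fixed"
  if (is.null(threshold))
    threshold <- select_threshold(scores, labels, target_sensitivity)
  conf <- confusion_metrics(scores, labels, threshold)
  strata <- size_stratum(manifest$diameter_mm)
  sub <- vapply(levels(strata), function(s) {
    sel <- strata == s
    if (length(unique(labels[sel])) < 2) return(NA_real_)
    roc_auc(scores[sel], labels[sel])
  }, numeric(1))
  n_sub <- vapply(levels(strata), function(s) sum(strata == s), integer(1))
  predicted <- ifelse(scores >= threshold, "premalignant", "benign")
  score_tbl <- tibble(
    id = paste0(manifest$polyp_id, "_", manifest$position),
    score = scores, label = labels, predicted = predicted,
    stratum = strata,
    histopathologic_category = manifest$histopathologic_category,
    diameter_mm = manifest$diameter_mm)
  structure(
    list(variant = variant, auc = auc, threshold = threshold,
         threshold_source = threshold_source,
         target_sensitivity = target_sensitivity,
         confusion = conf,
         subgroup_aucs = tibble(stratum = names(sub), auc = unname(sub),
                                n = unname(n_sub)),
         category_accuracy = category_accuracy(predicted, manifest),
         scores = score_tbl),
    class = "polyp_eval")
}

#' @export
print.polyp_eval <- function(x, ...) {
  cat(sprintf("<polyp_eval> %s: AUC %.3f, threshold %.3f (%s)\n",
              x$variant, x$auc, x$threshold, x$threshold_source))
  s <- x$confusion
  for (i in 1:2)
    cat(sprintf("  %s: %d%% (%d of %d)\n", s$metric[i], s$percent[i],
                s$numerator[i], s$denominator[i]))
  sub <- x$subgroup_aucs
  cat("  subgroup AUC:",
      paste(sprintf("%s %.2f (n=%d)", sub$stratum,
                    sub$auc, sub$n), collapse = ", "), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an evaluation report into one row per metric
#'
#' @param x A `polyp_eval`.
#' @param ... Unused.
#' @return A tibble with columns metric, estimate, numerator, denominator.
#' @export
tidy.polyp_eval <- function(x, ...) {
  dplyr::bind_rows(
    tibble(metric = "auc", estimate = x$auc,
           numerator = NA_real_, denominator = NA_real_),
    tibble(metric = "threshold", estimate = x$threshold,
           numerator = NA_real_, denominator = NA_real_),
    tibble(metric = x$confusion$metric, estimate = x$confusion$fraction,
           numerator = as.numeric(x$confusion$numerator),
           denominator = as.numeric(x$confusion$denominator)),
    tibble(metric = paste0("auc_", x$subgroup_aucs$stratum),
           estimate = x$subgroup_aucs$auc,
           numerator = NA_real_,
           denominator = as.numeric(x$subgroup_aucs$n)))
}

#' One-row summary of an evaluation report
#'
#' @param x A `polyp_eval`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.polyp_eval <- function(x, ...) {
  tibble(variant = x$variant, n = nrow(x$scores),
         n_premalignant = sum(x$scores$label == 1),
         n_benign = sum(x$scores$label == 0),
         auc = x$auc, threshold = x$threshold,
         sensitivity = x$confusion$fraction[1],
         specificity = x$confusion$fraction[2])
}

#' ROC curve for an evaluation report
#'
#' @param object A `polyp_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.polyp_eval <- function(object, ...) {
  s <- object$scores
  thr <- sort(unique(c(-Inf, s$score, Inf)), decreasing = TRUE)
  pts <- dplyr::bind_rows(lapply(thr, function(t) {
    tibble(fpr = mean(s$score[s$label == 0] >= t),
           tpr = mean(s$score[s$label == 1] >= t))
  }))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8, colour = "#2166ac") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "sensitivity",
      title = sprintf("%s: AUC %.2f", object$variant, object$auc)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
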