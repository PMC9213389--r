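#' Trilinear upsampling of a cubic grid
#'
#' Resamples a cubic array to side `out` with half-voxel-centre alignment
#' (the convention that maps cell centres to cell centres, as used for
#' class-activation maps).
#'
#' @param arr Cubic 3D array.
#' @param out Output side length.
#' @return A `out^3` array.
#' @export
upsample_trilinear <- function(arr, out) {
  n <- dim(arr)[1]
  stopifnot(length(dim(arr)) == 3, all(dim(arr) == n))
  s <- (seq_len(out) - 0.5) * n / out - 0.5
  i0 <- pmin(pmax(floor(s), 0), n - 1)
  fr <- pmin(pmax(s - i0, 0), 1)
  i1 <- pmin(i0 + 1, n - 1)
  i0 <- i0 + 1; i1 <- i1 + 1              # to 1-based indices
  res <- array(0, dim = c(out, out, out))
  wx <- list(1 - fr, fr); ix <- list(i0, i1)
  for (cx in 1:2) for (cy in 1:2) for (cz in 1:2) {
    w <- outer(outer(wx[[cx]], wx[[cy]]), wx[[cz]])
    res <- res + w * arr[ix[[cx]], ix[[cy]], ix[[cz]], drop = FALSE]
  }
  res
}

# Grad-CAM++ channel weighting for a linear-in-features class score.
#
# `A` is the final-stage feature tensor (d, d, d, K); `grad` the per-voxel
# gradient of the pre-logistic class score with respect to A (same shape;
# here spatially constant per channel because the head is global average
# pooling followed by a dense unit, but the formula is kept general). The
# exponential class-score factor in the original weighting cancels under
# the final max-normalisation and is omitted.
gradcampp_map <- function(A, grad) {
  K <- dim(A)[4]
  g2 <- grad^2
  g3 <- grad^3
  sumA <- apply(A, 4, sum)
  denom <- 2 * g2 + sweep(g3, 4, sumA, "*")
  alpha <- ifelse(abs(denom) > 1e-12, g2 / denom, 0)
  wplus <- apply(alpha * pmax(grad, 0), 4, sum)
  L <- array(0, dim = dim(A)[1:3])
  for (k in seq_len(K)) L <- L + wplus[k] * A[, , , k]
  pmax(L, 0)
}

# Heatmap for one member network on a single 50^3 input.
member_heatmap <- function(net, x) {
  out <- cpp_forward(net$weights, x, return_features = TRUE)
  A <- array(out$features, dim = dim(out$features)[1:4])
  d3 <- dim(A)[1]
  # d(logit)/dA_k is w_k / n_locations: GAP feeds a single dense unit
  gvec <- as.numeric(net$weights$Wd) / d3^3
  grad <- array(rep(gvec, each = d3^3), dim = dim(A))
  L <- gradcampp_map(A, grad)
  up <- upsample_trilinear(L, dim(x)[1])
  m <- max(up)
  list(map = if (m > 0) up / m else up, score = out$scores[1])
}

#' Grad-CAM++ volumetric class activation
#'
#' Computes the Grad-CAM++ class-activation volume at the final
#' convolutional stage (the third residual add, 7^3 x 64 features):
#' channel weights from the alpha-weighted rectified gradients of the
#' pre-logistic class score, a rectified weighted feature sum, trilinear
#' upsampling to the input grid, and normalisation by the volume maximum
#' (an all-zero map stays all-zero, so activations always lie in `[0, 1]`).
#' For an ensemble the member maps are averaged and re-normalised.
#'
#' @param object A trained `member_network` or `polyp_ensemble`.
#' @param input A single `model_input` (or `(50,50,50,C)` array).
#' @param input_id Optional identifier stored in the result.
#' @return A `heatmap_result`: list with `activation` (array in `[0, 1]`
#'   congruent with the input grid), `score`, `source_layer`, `input_id`.
#' @export
gradcampp <- function(object, input, input_id = NULL) {
  x <- as_input_batch(input)
  if (dim(x)[5] != 1) abort("gradcampp() explains one input at a time")
  if (inherits(object, "member_network")) {
    if (!object$trained)
      warn("network is untrained: the activation map is defined but meaningless")
    hm <- member_heatmap(object, x)
    act <- hm$map; score <- hm$score
  } else if (inherits(object, "polyp_ensemble")) {
    if (length(object$members) == 0) abort("ensemble has no members")
    if (!object$members[[1]]$trained)
      warn("ensemble is untrained: the activation map is defined but meaningless")
    maps <- lapply(object$members, member_heatmap, x = x)
    act <- Reduce(`+`, lapply(maps, `[[`, "map")) / length(maps)
    m <- max(act)
    if (m > 0) act <- act / m
    score <- mean(vapply(maps, `[[`, numeric(1), "score"))
  } else {
    abort("`object` must be a member_network or polyp_ensemble")
  }
  structure(list(activation = act, score = score, source_layer = "add3",
                 input_id = input_id),
            class = "heatmap_result")
}

#' @export
print.heatmap_result <- function(x, ...) {
  cat(sprintf(
    "<heatmap_result> %s grid, score %.3f, activation range [%.2f, %.2f]\n",
    paste(dim(x$activation), collapse = "x"), x$score,
    min(x$activation), max(x$activation)))
  invisible(x)
}

#' Fraction of mask voxels at or above an activation threshold
#'
#' The attention statistic: the fraction of voxels inside the polyp
#' segmentation mask whose class activation meets or exceeds `threshold`
#' (inclusive).
#'
#' @param heatmap A `heatmap_result` or an activation array.
#' @param mask Binary mask array congruent with the activation grid.
#' @param threshold Activation threshold (default 0.25).
#' @return Fraction in `[0, 1]`.
#' @export
mask_coverage <- function(heatmap, mask, threshold = 0.25) {
  act <- if (inherits(heatmap, "heatmap_result")) heatmap$activation
         else heatmap
  if (!identical(dim(act), dim(mask)[1:3]))
    abort("heatmap and mask grids are not congruent")
  inside <- mask != 0
  if (!any(inside)) abort("mask is empty: coverage is undefined")
  mean(act[inside] >= threshold)
}

#' Mean Grad-CAM++ mask coverage over a cohort
#'
#' Computes the per-segmentation mask coverage for every record and the
#' unweighted mean. Masks serve only as evaluation references here, so the
#' ensemble must be the image-only (noSEG) variant. Records without a mask
#' are listed and excluded with a warning.
#'
#' @param ensemble A trained noSEG `polyp_ensemble`.
#' @param cohort A `polyp_cohort` (or manifest with mask paths).
#' @param threshold Activation threshold (default 0.25).
#' @return A `coverage_result`: list with `mean_coverage` and the
#'   `per_record` tibble (id, score, coverage).
#' @export
cohort_coverage <- function(ensemble, cohort, threshold = 0.25) {
  stopifnot(inherits(ensemble, "polyp_ensemble"))
  if (ensemble$variant != "noSEG")
    abort("mask coverage is defined for the image-only (noSEG) variant")
  in_memory <- inherits(cohort, "polyp_cohort") && !is.null(cohort$volumes)
  manifest <- if (inherits(cohort, "polyp_cohort")) cohort$manifest else cohort
  ids <- paste0(manifest$polyp_id, "_", manifest$position)
  has_mask <- if (in_memory) ids %in% names(cohort$masks)
              else !is.na(manifest$mask_path) & nzchar(manifest$mask_path)
  if (any(!has_mask)) {
    warn(paste0("excluding records without masks: ",
                paste(ids[!has_mask], collapse = ", ")))
  }
  keep <- which(has_mask)
  rows <- lapply(keep, function(i) {
    if (in_memory) {
      v <- cohort$volumes[[ids[i]]]
      m <- cohort$masks[[ids[i]]]
    } else {
      v <- read_volume(manifest$volume_path[i])$values
      m <- read_volume(manifest$mask_path[i])$values
    }
    if (dim(v)[1] > 50) {
      ctr <- centre_voxel(dim(v)[1])
      v <- crop_subvolume(v, ctr, 50)
      m <- crop_subvolume(m, ctr, 50)
    }
    hm <- gradcampp(ensemble, model_input(v), input_id = ids[i])
    tibble(id = ids[i], score = hm$score,
           coverage = mask_coverage(hm, m, threshold))
  })
  per_record <- dplyr::bind_rows(rows)
  structure(list(mean_coverage = mean(per_record$coverage),
                 per_record = per_record, threshold = threshold),
            class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf(
    "<coverage_result> %d segmentations, mean coverage %.1f%% at threshold %.2f\n",
    nrow(x$per_record), 100 * x$mean_coverage, x$threshold))
  invisible(x)
}

# An equal-volume background reference region: the mask translated along x
# by its bounding-box width plus a margin (falling back to -x), staying
# inside the grid and disjoint from the polyp.
background_region <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  w <- max(idx[, 1]) - min(idx[, 1]) + 3
  d <- dim(mask)
  for (shift in c(w, -w)) {
    sx <- idx[, 1] + shift
    if (all(sx >= 1 & sx <= d[1])) {
      bg <- array(0L, dim = d)
      bg[cbind(sx, idx[, 2], idx[, 3])] <- 1L
      if (!any(bg & mask)) return(bg)
    }
  }
  abort("could not place a disjoint background region")
}
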