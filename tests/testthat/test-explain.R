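# Member whose weights are all zero: every feature map is zero.
zero_member <- function(channels = 1) {
  net <- build_member(network_config(channels), seed = 1)
  net$weights <- lapply(net$weights, function(w) w * 0)
  net
}

small_input <- function(seed = 1) {
  set.seed(seed)
  model_input(array(runif(50^3, -1000, 200), dim = c(50, 50, 50)))
}

test_that("all-zero features yield an all-zero heatmap", {
  hm <- suppressWarnings(gradcampp(zero_member(), small_input()))
  expect_equal(max(abs(hm$activation)), 0)
  expect_warning(gradcampp(zero_member(), small_input()), "untrained")
})

test_that("heatmaps are max-normalised to [0, 1] on the input grid", {
  net <- build_member(network_config(1), seed = 3)
  net$trained <- TRUE   # silence the untrained warning; weights are random
  hm <- gradcampp(net, small_input(2))
  expect_equal(dim(hm$activation), c(50, 50, 50))
  expect_gte(min(hm$activation), 0)
  expect_lte(max(hm$activation), 1)
  expect_true(max(hm$activation) %in% c(0, 1))
  expect_equal(hm$source_layer, "add3")
})

test_that("a single positive feature channel produces a map constant on its support", {
  # toy head: the class score is the spatial mean of channel 2, so the
  # Grad-CAM++ map is proportional to that channel's (rectified) activation
  A <- array(0, dim = c(7, 7, 7, 64))
  block <- list(2:4, 3:5, 2:3)
  A[block[[1]], block[[2]], block[[3]], 2] <- 1
  A[, , , 7] <- runif(343)  # a channel the score does not depend on
  w <- rep(0, 64); w[2] <- 1
  grad <- array(rep(w / 343, each = 343), dim = dim(A))
  L <- polypcnn:::gradcampp_map(A, grad)
  on_support <- L[block[[1]], block[[2]], block[[3]]]
  expect_equal(length(unique(round(as.numeric(on_support), 12))), 1)
  expect_gt(on_support[1], 0)
  expect_equal(sum(L[, , , drop = FALSE][A[, , , 2] == 0]), 0)
})

test_that("trilinear upsampling preserves constants and value range", {
  expect_equal(upsample_trilinear(array(3, c(7, 7, 7)), 50),
               array(3, c(50, 50, 50)))
  set.seed(1)
  a <- array(runif(343), dim = c(7, 7, 7))
  up <- upsample_trilinear(a, 50)
  expect_gte(min(up), min(a) - 1e-12)
  expect_lte(max(up), max(a) + 1e-12)
})

test_that("mask coverage counts threshold-inclusive fractions", {
  act <- array(0, dim = c(4, 4, 4))
  mask <- array(0L, dim = c(4, 4, 4))
  mask[1:4, 1, 1] <- 1L
  act[1:4, 1, 1] <- c(0.30, 0.25, 0.20, 0.10)
  expect_equal(mask_coverage(act, mask, 0.25), 0.5)
  act[1:4, 1, 1] <- 1
  expect_equal(mask_coverage(act, mask, 0.25), 1)
  expect_error(mask_coverage(act, array(0L, dim = c(4, 4, 4))), "empty")
  expect_error(mask_coverage(act, mask[1:2, 1:2, 1:2, drop = FALSE]),
               "congruent")
})

test_that("mask coverage matches a voxel-loop oracle and is monotone in the threshold", {
  set.seed(8)
  act <- array(runif(12^3), dim = c(12, 12, 12))
  for (i in 1:20) {
    mask <- random_mask()
    thr <- runif(1)
    expect_equal(mask_coverage(act, mask, thr),
                 oracle_coverage(act, mask, thr))
  }
  mask <- random_mask()
  cov <- vapply(seq(0, 1, by = 0.1), function(t) mask_coverage(act, mask, t),
                numeric(1))
  expect_true(all(diff(cov) <= 0))
})

test_that("cohort coverage averages per-record coverages", {
  coh <- generate_cohort(n_patients = 2, seed = 4, size = 50)
  net <- build_member(network_config(1), seed = 2)
  net$trained <- TRUE
  ens <- structure(list(variant = "noSEG", members = list(net),
                        member_seeds = NULL, params = NULL,
                        config = net$config, base_seed = 1L),
                   class = "polyp_ensemble")
  cov <- cohort_coverage(ens, coh)
  expect_s3_class(cov$per_record, "tbl_df")
  expect_equal(cov$mean_coverage, mean(cov$per_record$coverage))
  # a single record's mean equals that record's coverage
  coh1 <- coh
  coh1$manifest <- coh1$manifest[1, ]
  cov1 <- cohort_coverage(ens, coh1)
  expect_equal(cov1$mean_coverage, cov1$per_record$coverage[1])
  # masks are evaluation references: the SEG variant is refused
  ens_seg <- ens; ens_seg$variant <- "SEG"
  expect_error(cohort_coverage(ens_seg, coh), "noSEG")
})

test_that("ensemble heatmaps average member maps and stay in [0, 1]", {
  n1 <- build_member(network_config(1), seed = 5); n1$trained <- TRUE
  n2 <- build_member(network_config(1), seed = 6); n2$trained <- TRUE
  ens <- structure(list(variant = "noSEG", members = list(n1, n2),
                        member_seeds = NULL, params = NULL,
                        config = n1$config, base_seed = 1L),
                   class = "polyp_ensemble")
  x <- small_input(9)
  hm <- gradcampp(ens, x)
  m1 <- gradcampp(n1, x)$activation
  m2 <- gradcampp(n2, x)$activation
  avg <- (m1 + m2) / 2
  expected <- if (max(avg) > 0) avg / max(avg) else avg
  expect_equal(hm$activation, expected, tolerance = 1e-12)
})

test_that("heatmap overlays render as three orthogonal panels", {
  net <- build_member(network_config(1), seed = 7)
  net$trained <- TRUE
  v <- array(runif(50^3, -1000, 100), dim = c(50, 50, 50))
  hm <- gradcampp(net, model_input(v))
  p <- plot_heatmap_overlay(v, hm)
  expect_s3_class(p, "ggplot")
})
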