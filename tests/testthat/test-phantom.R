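test_that("phantom generation is bit-identical under a fixed seed", {
  spec <- phantom_spec("premalignant", diameter_mm = 8)
  g1 <- generate_polyp_volume(spec, seed = 7)
  g2 <- generate_polyp_volume(spec, seed = 7)
  expect_identical(g1$volume, g2$volume)
  expect_identical(g1$mask, g2$mask)
  # a different noise seed with the same shape seed changes HU values only
  g3 <- generate_polyp_volume(spec, seed = 8, shape_seed = 7)
  expect_identical(g3$mask, g1$mask)
  expect_false(identical(g3$volume, g1$volume))
})

test_that("mask diameter tracks the requested diameter", {
  for (cls in c("benign", "premalignant")) {
    spec <- phantom_spec(cls, diameter_mm = 8)
    for (s in 1:5) {
      g <- generate_polyp_volume(spec, seed = s)
      expect_gte(g$record$diameter_mm, 6.4)
      expect_lte(g$record$diameter_mm, 9.6)
    }
  }
})

test_that("oversized polyps are rejected with a sizing error", {
  expect_error(
    generate_polyp_volume(phantom_spec("benign", diameter_mm = 48), seed = 1),
    "does not fit")
})

test_that("phantoms have air lumen, tissue wall, and a wall-attached mask", {
  g <- generate_polyp_volume(phantom_spec("premalignant", 10), seed = 3)
  v <- g$volume; m <- g$mask
  expect_equal(dim(v), c(50, 50, 50))
  # top of the volume is lumen air, bottom is soft tissue
  expect_lt(mean(v[, , 50]), -850)
  expect_gt(mean(v[, , 1]), -150)
  expect_gt(mean(v[m == 1]), -150)
  # mask never touches the grid boundary
  expect_equal(sum(m[c(1, 50), , ]) + sum(m[, c(1, 50), ]) +
                 sum(m[, , c(1, 50)]), 0)
  # every mask voxel is 6-connected to the wall region (tissue outside the
  # mask, recovered from the HU field)
  wall <- array(0L, dim = dim(m))
  wall[v > -400 & m == 0L] <- 1L
  expect_true(mask_connected_to_wall(m, wall))
})

test_that("separability 0 makes the two classes statistically indistinguishable", {
  n <- 30
  mean_hu <- function(cls, seeds)
    vapply(seeds, function(s) {
      g <- generate_polyp_volume(
        phantom_spec(cls, 8, separability = 0), seed = s)
      mean(g$volume[g$mask == 1])
    }, numeric(1))
  a <- mean_hu("benign", 1:n)
  b <- mean_hu("premalignant", 101:(100 + n))
  # permutation test on the difference in means
  obs <- abs(mean(a) - mean(b))
  pool <- c(a, b)
  set.seed(99)
  perm <- replicate(400, {
    ix <- sample(2 * n, n)
    abs(mean(pool[ix]) - mean(pool[-ix]))
  })
  p <- (1 + sum(perm >= obs)) / 401
  expect_gt(p, 0.01)
})

test_that("the class signal scales with separability", {
  # handcrafted feature: HU standard deviation inside the mask
  feat <- function(cls, sep, seeds)
    vapply(seeds, function(s) {
      g <- generate_polyp_volume(phantom_spec(cls, 8, separability = sep),
                                 seed = s)
      stats::sd(g$volume[g$mask == 1])
    }, numeric(1))
  n <- 50
  f_b1 <- feat("benign", 1, 1:n)
  f_p1 <- feat("premalignant", 1, 201:(200 + n))
  auc1 <- roc_auc(c(f_b1, f_p1), rep(0:1, each = n))
  expect_gte(auc1, 0.9)
  f_b0 <- feat("benign", 0, 401:(400 + n))
  f_p0 <- feat("premalignant", 0, 601:(600 + n))
  auc0 <- roc_auc(c(f_b0, f_p0), rep(0:1, each = n))
  expect_gte(auc0, 0.35)
  expect_lte(auc0, 0.65)
})

test_that("cohorts pair supine and prone renderings of each polyp", {
  coh <- generate_cohort(n_patients = 10, class_prevalence = 0.5, seed = 1)
  m <- coh$manifest
  n_polyps <- length(unique(m$polyp_id))
  expect_equal(nrow(m), 2 * n_polyps)
  expect_true(all(table(m$polyp_id) == 2))
  expect_false(anyDuplicated(m[c("patient_id", "polyp_id", "position")]) > 0)
  # class labels match the histopathology mapping
  expect_equal(map_histopathology_to_class(m$histopathologic_category),
               m$class_label)
  # per-class polyp counts match the prevalence within rounding
  per_polyp <- m[!duplicated(m$polyp_id), ]
  expect_equal(sum(per_polyp$class_label == "premalignant"),
               round(0.5 * n_polyps))
  # supine and prone share the lesion shape, hence the diameter
  d <- tapply(m$diameter_mm, m$polyp_id, function(x) diff(range(x)))
  expect_true(all(d < 1e-9))
})

test_that("cohort generation is deterministic and honours the size mix", {
  c1 <- generate_cohort(n_patients = 6, seed = 5, size_mix = c(0, 1, 0))
  c2 <- generate_cohort(n_patients = 6, seed = 5, size_mix = c(0, 1, 0))
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$volumes, c2$volumes)
  # every mask's rounded diameter falls in the 6-9 mm stratum
  expect_true(all(size_stratum(c1$manifest$diameter_mm) == "6-9mm"))
  expect_error(generate_cohort(5, size_mix = c(0.5, 0.5, 0.5)), "size_mix")
})

test_that("cohorts written to disk round-trip through the manifest", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(n_patients = 3, seed = 2, dir = dir, size = 50)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  m <- read.csv(file.path(dir, "manifest.csv"))
  expect_true(all(file.exists(m$volume_path)))
  expect_true(all(file.exists(m$mask_path)))
  v <- read_volume(m$volume_path[1])
  expect_equal(dim(v$values), c(50, 50, 50))
  msk <- read_volume(m$mask_path[1])$values
  expect_equal(max_3d_diameter(msk, v$spacing_mm[1:3]), m$diameter_mm[1],
               tolerance = 1e-5)
})
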