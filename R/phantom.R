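#' Specification of a synthetic colorectal polyp phantom
#'
#' Describes one simulated polyp embedded at an air--soft-tissue interface in
#' a CT-colonography-like subvolume. The two classes mimic the qualitative
#' morphological contrast between lesion types: benign polyps are smooth and
#' homogeneous, premalignant polyps are lobulated and textured. The
#' `separability` parameter scales the class-conditional differences in
#' surface lobulation and intra-polyp texture; at `separability = 0` the two
#' classes are generated from identical distributions, at `1` they are
#' clearly distinct.
#'
#' @param polyp_class `"benign"` or `"premalignant"`.
#' @param diameter_mm Target maximum 3D diameter of the polyp in mm.
#' @param separability Real in `[0, 1]` scaling the class-conditional
#'   differences in `lobulation` and `texture_sd`.
#' @param lobulation Surface-perturbation amplitude as a fraction of the
#'   polyp radius. Defaults to 0.08 for benign polyps and
#'   `0.08 + 0.32 * separability` for premalignant ones.
#' @param texture_sd Standard deviation (HU) of the intra-polyp
#'   heterogeneity field. Defaults to 5 HU for benign polyps and
#'   `5 + 75 * separability` for premalignant ones, so that separability 1
#'   is an unambiguous contrast for both handcrafted features and
#'   desk-scale CNN training.
#' @param wall_offset_mm Signed distance (mm) of the colonic wall surface
#'   (the polyp base) from the subvolume centre along z.
#' @param voxel_spacing_mm Triple of positive voxel spacings in mm.
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(polyp_class = c("benign", "premalignant"),
                         diameter_mm = 8,
                         separability = 1,
                         lobulation = NULL,
                         texture_sd = NULL,
                         wall_offset_mm = 0,
                         voxel_spacing_mm = c(1, 1, 1)) {
  polyp_class <- match.arg(polyp_class)
  if (!is.numeric(diameter_mm) || length(diameter_mm) != 1 || diameter_mm <= 0)
    abort("`diameter_mm` must be a positive scalar")
  if (!is.numeric(separability) || separability < 0 || separability > 1)
    abort("`separability` must lie in [0, 1]")
  if (length(voxel_spacing_mm) == 1)
    voxel_spacing_mm <- rep(voxel_spacing_mm, 3)
  if (any(voxel_spacing_mm <= 0))
    abort("voxel spacings must be strictly positive")
  premal <- polyp_class == "premalignant"
  if (is.null(lobulation))
    lobulation <- 0.08 + if (premal) 0.42 * separability else 0
  if (is.null(texture_sd))
    texture_sd <- 5 + if (premal) 75 * separability else 0
  if (lobulation < 0 || texture_sd < 0)
    abort("`lobulation` and `texture_sd` must be non-negative")
  structure(
    list(polyp_class = polyp_class, diameter_mm = diameter_mm,
         separability = separability, lobulation = lobulation,
         texture_sd = texture_sd, wall_offset_mm = wall_offset_mm,
         voxel_spacing_mm = as.numeric(voxel_spacing_mm)),
    class = "phantom_spec")
}

# Bump-perturbation shape parameters for one polyp (shared between the
# supine and prone renderings of that polyp): broad lobes plus fine surface
# bumps, so that large amplitudes read as spiculated rather than merely
# ellipsoidal.
draw_shape_params <- function(n_broad = 12, n_fine = 24) {
  n_bumps <- n_broad + n_fine
  d <- matrix(rnorm(n_bumps * 3), ncol = 3)
  d <- d / sqrt(rowSums(d^2))
  list(dirs = d,
       sigma = c(runif(n_broad, 0.25, 0.6), runif(n_fine, 0.08, 0.2)),
       amp = runif(n_bumps, -1, 1))
}

# Evaluate the raw angular perturbation field at unit directions U (n x 3).
bump_field <- function(U, shape) {
  ct <- U %*% t(shape$dirs)
  ct[ct > 1] <- 1; ct[ct < -1] <- -1
  theta <- acos(ct)
  rowSums(sweep(exp(-sweep(theta^2, 2, 2 * shape$sigma^2, "/")), 2,
                shape$amp, "*"))
}

# Normalised radius multiplier rho(dir) with max antipodal mean radius 1, so
# the realised maximum 3D diameter tracks the requested diameter closely.
make_radius_fun <- function(shape, lobulation) {
  V <- matrix(rnorm(1500), ncol = 3)
  V <- V / sqrt(rowSums(V^2))
  a <- (2 + lobulation * (bump_field(V, shape) + bump_field(-V, shape))) / 2
  scale <- max(a, 1e-6)
  function(U) pmax(1 + lobulation * bump_field(U, shape), 0.05) / scale
}

# 90-degree rotations about the z axis (preserves the wall-below geometry).
rotate_z90 <- function(arr, k) {
  k <- k %% 4
  for (i in seq_len(k)) {
    n <- dim(arr)[1]
    arr <- aperm(arr[, n:1, , drop = FALSE], c(2, 1, 3))
  }
  arr
}

#' Generate one synthetic CT polyp subvolume with its segmentation mask
#'
#' Renders a cubic HU grid containing an air lumen (about -1000 HU), a
#' soft-tissue wall (about 40 HU), and one polyp protruding from the wall
#' into the lumen. The polyp is a star-convex body around a centre on the
#' wall surface whose radius is modulated by smooth angular bumps
#' (amplitude `lobulation * radius`); premalignant phantoms additionally
#' carry a correlated intra-polyp texture field. Identical `(spec, seed,
#' shape_seed)` inputs reproduce bit-identical outputs.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed for the acquisition noise (voxel noise and
#'   texture field).
#' @param size Cubic grid side in voxels (50 canonical; 60 yields a context
#'   volume for random-crop augmentation).
#' @param shape_seed Integer seed for the polyp shape; defaults to `seed`.
#'   Two renderings with equal `shape_seed` but different `seed` share the
#'   lesion geometry with independent noise, emulating supine/prone
#'   acquisitions of one polyp.
#' @param rotation_k Number of 90-degree rotations about z applied to the
#'   rendered volume and mask.
#'
#' @return A list with `volume` (HU array, `size^3`), `mask` (0/1 integer
#'   array), and `record` (one-row tibble with the measured mask diameter).
#' @export
generate_polyp_volume <- function(spec, seed, size = 50, shape_seed = seed,
                                  rotation_k = 0) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- spec$voxel_spacing_mm
  R <- spec$diameter_mm / 2
  # worst-case polyp extent must stay clear of the grid boundary
  max_r_vox <- R * (1 + spec$lobulation) / min(sp) + 2
  if (max_r_vox >= size / 2)
    abort(sprintf(
      "polyp diameter %.1f mm does not fit a %d^3 grid at spacing %.2f mm",
      spec$diameter_mm, size, min(sp)))

  # geometry (bumps and radius normalisation) depends only on shape_seed
  rho <- with_seed(shape_seed,
                   make_radius_fun(draw_shape_params(), spec$lobulation))

  with_seed(seed, {
    n <- size
    ax <- (seq_len(n) - 1) * sp[1]
    ay <- (seq_len(n) - 1) * sp[2]
    az <- (seq_len(n) - 1) * sp[3]
    centre <- c(ax[n] / 2, ay[n] / 2, az[n] / 2)
    z_wall <- centre[3] - spec$wall_offset_mm

    # polyp mask within a bounding box around the centre
    mask <- array(0L, dim = c(n, n, n))
    rmax <- R * (1 + spec$lobulation) + max(sp)
    ix <- which(abs(ax - centre[1]) <= rmax)
    iy <- which(abs(ay - centre[2]) <= rmax)
    iz <- which(abs(az - (z_wall)) <= rmax)
    g <- expand.grid(x = ix, y = iy, z = iz)
    dx <- ax[g$x] - centre[1]
    dy <- ay[g$y] - centre[2]
    dz <- az[g$z] - z_wall
    r <- sqrt(dx^2 + dy^2 + dz^2)
    inside <- r < 1e-9
    nz <- !inside
    if (any(nz)) {
      U <- cbind(dx[nz], dy[nz], dz[nz]) / r[nz]
      inside[nz] <- r[nz] <= R * rho(U) + 0.3 * min(sp)
    }
    mask[cbind(g$x, g$y, g$z)[inside, , drop = FALSE]] <- 1L

    # HU field: lumen air, tissue wall, polyp = wall tissue + texture
    vol <- array(-1000 + rnorm(n^3, 0, 30), dim = c(n, n, n))
    wall <- outer(rep(TRUE, n * n), az <= z_wall)
    dim(wall) <- c(n, n, n)
    tissue <- wall | (mask == 1L)
    vol[tissue] <- 40 + rnorm(sum(tissue), 0, 20)
    if (spec$texture_sd > 0) {
      # heterogeneity field: mostly coarse patchy lumps (correlation length
      # of several mm, the "mottled" appearance of heterogeneous adenomas)
      # with a smaller voxel-scale component
      coarse <- array(rnorm(6^3), dim = c(6, 6, 6))
      field <- upsample_trilinear(coarse, n)
      field <- field / stats::sd(field)
      fine <- array(rnorm(n^3), dim = c(n, n, n))
      mix <- sqrt(0.8) * field + sqrt(0.2) * fine
      # positively skewed lumps: heterogeneous adenomatous tissue carries
      # bright components (enhancing/calcified nests), so the field has a
      # texture-proportional bright-patch component rather than being
      # sign-symmetric
      skew <- 0.6 * mix + 0.8 * pmax(mix, 0)
      vol[mask == 1L] <- vol[mask == 1L] + spec$texture_sd * skew[mask == 1L]
    }

    if (rotation_k %% 4 != 0) {
      vol <- rotate_z90(vol, rotation_k)
      mask <- rotate_z90(mask, rotation_k)
    }

    diam <- max_3d_diameter(mask, sp)
    record <- tibble(
      polyp_class = spec$polyp_class,
      diameter_target_mm = spec$diameter_mm,
      diameter_mm = diam,
      lobulation = spec$lobulation,
      texture_sd = spec$texture_sd,
      separability = spec$separability,
      seed = as.integer(seed),
      shape_seed = as.integer(shape_seed))
    list(volume = vol, mask = mask, record = record)
  })
}

# Histopathologic category frequencies used when sampling cohort labels,
# loosely following the screening-population mix of the two classes.
category_weights <- list(
  benign = c("regular mucosa" = 3, "hyperplastic polyp" = 78,
             "lipomatous polyp" = 2),
  premalignant = c("tubular adenoma" = 57, "tubulovillous adenoma" = 16,
                   "villous adenoma" = 8, "serrated adenoma" = 4,
                   "adenocarcinoma" = 1))

#' Generate a synthetic polyp cohort with a segmentation-level manifest
#'
#' Simulates `n_patients` patients, each carrying one or more polyps; every
#' polyp is rendered in supine and prone positions that share the lesion
#' shape but have independently re-simulated noise, and the prone rendering
#' is additionally rotated by a random multiple of 90 degrees. Class labels
#' are assigned to match `class_prevalence` up to integer rounding, and each
#' polyp receives a histopathologic category drawn within its class.
#'
#' @param n_patients Number of simulated patients (>= 1).
#' @param class_prevalence Fraction of polyps that are premalignant.
#' @param size_mix Pooled fractions (summing to 1) of polyps in the three
#'   maximum 3D diameter strata `<=5`, `6-9` and `>=10` mm. The class
#'   conditional mixes deviate from this pooled mix in proportion to
#'   `separability`, mirroring the size-class association of screening
#'   cohorts (premalignant polyps skew large); at separability 0 both
#'   classes share the pooled mix exactly.
#' @param separability Class separability passed to [phantom_spec()].
#' @param seed Integer seed; all cohort randomness derives from it.
#' @param dir Output directory. When given, volumes and masks are written as
#'   NIfTI files and the manifest as `manifest.csv`; when `NULL` the cohort
#'   is kept in memory.
#' @param size Grid side in voxels (default 60, a context grid supporting
#'   random-crop augmentation; use 50 for fixed-grid cohorts).
#' @param voxel_spacing_mm Isotropic voxel spacing in mm.
#' @param polyps_per_patient Mean additional polyps per patient beyond the
#'   first (Poisson).
#'
#' @return An object of class `polyp_cohort`: a list with the `manifest`
#'   tibble and, for in-memory cohorts, named lists `volumes` and `masks`.
#' @export
generate_cohort <- function(n_patients, class_prevalence = 0.5,
                            size_mix = c(0.15, 0.40, 0.45),
                            separability = 1, seed = 1, dir = NULL,
                            size = 60, voxel_spacing_mm = 1,
                            polyps_per_patient = 0.3) {
  if (n_patients < 1) abort("`n_patients` must be >= 1")
  if (length(size_mix) != 3 || any(size_mix < 0) ||
      abs(sum(size_mix) - 1) > 1e-8)
    abort("`size_mix` must be three non-negative fractions summing to 1")
  if (class_prevalence <= 0 || class_prevalence >= 1)
    abort("`class_prevalence` must lie in (0, 1)")
  write_files <- !is.null(dir)
  if (write_files) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    if (!dir.exists(dir)) abort(sprintf("cannot create directory '%s'", dir))
  }

  # Class-conditional size strata: screening cohorts skew premalignant
  # polyps large and benign polyps small-to-medium. The deviations from the
  # pooled mix are scaled by `separability` so that at 0 the two classes
  # share one size distribution exactly.
  tilt_mix <- list(benign = c(0.36, 0.49, -0.53),
                   premalignant = c(-0.35, -0.47, 0.51))
  class_mix <- lapply(tilt_mix, function(r) {
    m <- size_mix * pmax(1 + separability * r, 0)
    m / sum(m)
  })

  plan <- with_seed(seed, {
    n_pol <- 1L + rpois(n_patients, polyps_per_patient)
    total <- sum(n_pol)
    n_pre <- round(class_prevalence * total)
    cls <- rep("benign", total)
    cls[sample.int(total, n_pre)] <- "premalignant"
    stratum <- vapply(cls, function(cl)
      sample.int(3, 1, prob = class_mix[[cl]]), integer(1))
    lo <- c(3.8, 6.6, 10.2)[stratum]
    hi <- c(5.3, 8.8, 13.5)[stratum]
    diam <- runif(total, lo, hi)
    cat_of <- vapply(cls, function(cl) {
      w <- category_weights[[cl]]
      sample(names(w), 1, prob = w)
    }, character(1))
    tibble(
      patient = rep(seq_len(n_patients), n_pol),
      lesion = unlist(lapply(n_pol, seq_len)),
      class_label = cls,
      category = cat_of,
      diameter = diam,
      shape_seed = sample.int(2147483646L, total),
      seed_supine = sample.int(2147483646L, total),
      seed_prone = sample.int(2147483646L, total),
      rot_prone = sample.int(4, total, replace = TRUE) - 1L)
  })

  sp <- rep(voxel_spacing_mm, 3)
  rows <- list()
  volumes <- list()
  masks <- list()
  for (i in seq_len(nrow(plan))) {
    p <- plan[i, ]
    spec <- phantom_spec(p$class_label, diameter_mm = p$diameter,
                         separability = separability,
                         voxel_spacing_mm = sp)
    polyp_id <- sprintf("P%03d_L%d", p$patient, p$lesion)
    for (pos in c("supine", "prone")) {
      nseed <- if (pos == "supine") p$seed_supine else p$seed_prone
      rot <- if (pos == "supine") 0L else p$rot_prone
      g <- generate_polyp_volume(spec, seed = nseed, size = size,
                                 shape_seed = p$shape_seed, rotation_k = rot)
      seg_id <- paste0(polyp_id, "_", pos)
      vpath <- mpath <- NA_character_
      if (write_files) {
        vpath <- file.path(dir, paste0(seg_id, ".nii.gz"))
        mpath <- file.path(dir, paste0(seg_id, "_mask.nii.gz"))
        write_volume(g$volume, sp, vpath)
        write_volume(g$mask, sp, mpath, datatype = "uint8")
      } else {
        volumes[[seg_id]] <- g$volume
        masks[[seg_id]] <- g$mask
      }
      rows[[seg_id]] <- tibble(
        patient_id = sprintf("P%03d", p$patient),
        polyp_id = polyp_id,
        position = pos,
        histopathologic_category = p$category,
        class_label = p$class_label,
        volume_path = vpath,
        mask_path = mpath,
        diameter_mm = g$record$diameter_mm,
        seed = as.integer(nseed))
    }
  }
  manifest <- dplyr::bind_rows(rows)
  stopifnot(!anyDuplicated(manifest[c("patient_id", "polyp_id", "position")]))
  if (write_files)
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  structure(
    list(manifest = manifest,
         volumes = if (!write_files) volumes,
         masks = if (!write_files) masks,
         size = size, spacing = sp, separability = separability,
         seed = as.integer(seed), dir = if (write_files) dir),
    class = "polyp_cohort")
}

#' @export
print.polyp_cohort <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "<polyp_cohort> %d segmentations, %d polyps, %d patients (%d^3 grid)\n",
    nrow(m), length(unique(m$polyp_id)), length(unique(m$patient_id)),
    x$size))
  cat(sprintf("  premalignant: %d | benign: %d | separability: %.2f\n",
              sum(m$class_label == "premalignant"),
              sum(m$class_label == "benign"), x$separability))
  invisible(x)
}
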