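#' Write a volume or mask as a NIfTI file
#'
#' @param values Numeric or integer 3D array.
#' @param spacing_mm Voxel spacing triple in mm, recorded in the header.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI datatype; masks should use `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(values, spacing_mm, path, datatype = "auto") {
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- spacing_mm
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a NIfTI volume
#'
#' @param path File path.
#' @return A list with `values` (plain array) and `spacing_mm`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(values = array(as.numeric(img), dim = dim(img)),
       spacing_mm = RNifti::pixdim(img))
}

#' Crop a cubic window from a volume
#'
#' Extracts the half-open window `[centre - size/2, centre + size/2)` along
#' each axis, with `centre` given as a 0-based voxel coordinate. No
#' resampling or padding is performed; a window that exceeds the volume
#' bounds is an error.
#'
#' @param volume 3D array (or 4D array with trailing channel axis).
#' @param centre 0-based voxel coordinate triple of the window centre.
#' @param size Window side in voxels (default 50).
#' @return The cropped array.
#' @export
crop_subvolume <- function(volume, centre, size = 50) {
  d <- dim(volume)[1:3]
  half <- size %/% 2
  lo <- centre - half            # 0-based inclusive start
  hi <- lo + size - 1            # 0-based inclusive end
  if (any(lo < 0) || any(hi > d - 1))
    abort(sprintf(
      "crop window [%s]..[%s] exceeds volume bounds %s (no implicit padding)",
      paste(lo, collapse = ","), paste(hi, collapse = ","),
      paste(d, collapse = "x")))
  idx <- Map(function(l, s) seq.int(l + 1, l + s), lo, list(size, size, size))
  if (length(dim(volume)) == 4)
    volume[idx[[1]], idx[[2]], idx[[3]], , drop = FALSE]
  else
    volume[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# centre voxel (0-based) used for centre crops of a cubic grid
centre_voxel <- function(d) rep(d %/% 2, 3)

#' Normalize HU intensities to the unit interval
#'
#' Clips to the `[-1000, 400]` HU window (air through contrast-free soft
#' tissue) and maps it affinely to `[0, 1]`.
#'
#' @param x Numeric array of HU values.
#' @param lo,hi Clip window bounds in HU.
#' @return Array of the same shape with values in `[0, 1]`.
#' @export
normalize_intensity <- function(x, lo = -1000, hi = 400) {
  if (any(!is.finite(x))) abort("volume contains non-finite voxels")
  x <- pmin(pmax(x, lo), hi)
  (x - lo) / (hi - lo)
}

#' Random train-validation split over segmentation ids
#'
#' Draws a uniformly random partition of `ids` with `round(fraction * N)`
#' training units, deterministic given `seed`. When `groups` is supplied
#' (e.g. patient ids), whole groups are assigned to one side so that
#' correlated segmentations never straddle the split.
#'
#' @param ids Character or integer vector of unit ids (>= 5).
#' @param fraction Training fraction in (0, 1); default 0.8.
#' @param seed Integer seed.
#' @param groups Optional grouping vector aligned with `ids`.
#' @return A `train_val_split` list with `train_ids`, `val_ids`.
#' @export
make_split <- function(ids, fraction = 0.8, seed = 1, groups = NULL) {
  if (fraction <= 0 || fraction >= 1) abort("`fraction` must lie in (0, 1)")
  if (length(ids) < 5) abort("need at least 5 ids to split")
  if (anyDuplicated(ids)) abort("`ids` must be unique")
  if (is.null(groups)) {
    n_train <- round(fraction * length(ids))
    train <- with_seed(seed, sample(ids, n_train))
  } else {
    stopifnot(length(groups) == length(ids))
    gu <- unique(groups)
    n_g <- round(fraction * length(gu))
    g_train <- with_seed(seed, sample(gu, n_g))
    train <- ids[groups %in% g_train]
  }
  structure(list(train_ids = train,
                 val_ids = setdiff(ids, train),
                 fraction = fraction, seed = as.integer(seed)),
            class = "train_val_split")
}

#' Assemble a single model input
#'
#' Stacks a normalized image channel and, for the two-channel (SEG) variant,
#' a binary mask channel into one `(D, D, D, C)` array. Intensity
#' normalization is applied exactly once; re-normalization of an already
#' normalized input is refused.
#'
#' @param image Cubic HU array, or an already normalized array with
#'   `normalized = TRUE`.
#' @param mask Optional binary mask array of the same grid.
#' @param normalized Set to `TRUE` when `image` is already in `[0, 1]`.
#' @return A `model_input` array of shape `(D, D, D, C)`.
#' @export
model_input <- function(image, mask = NULL, normalized = FALSE) {
  d <- dim(image)
  stopifnot(length(d) == 3, d[1] == d[2], d[2] == d[3])
  img <- if (normalized) {
    if (min(image) < 0 || max(image) > 1)
      abort("`normalized = TRUE` but image values fall outside [0, 1]")
    image
  } else normalize_intensity(image)
  ch <- if (is.null(mask)) list(img) else {
    stopifnot(identical(dim(mask)[1:3], d))
    list(img, (mask != 0) + 0)
  }
  x <- array(unlist(ch, use.names = FALSE), dim = c(d, length(ch)))
  structure(x, class = c("model_input", "array"), normalized = TRUE)
}

#' Training-time geometric augmentation
#'
#' Applies, in order: a random `size^3` crop from the context grid, an
#' independent flip along each axis (probability 0.5 each), and a rotation
#' by a random multiple of 90 degrees in a random axis pair. All channels
#' (image and mask) undergo identical geometric transforms; intensities are
#' untouched. Validation data must never pass through this function -- it is
#' centre-cropped instead.
#'
#' @param input A `model_input` (or `(D, D, D, C)` array) with `D >= size`.
#' @param seed Integer seed; identical seeds reproduce identical outputs.
#' @param size Output side length (default 50).
#' @return A `model_input` of shape `(size, size, size, C)`.
#' @export
augment <- function(input, seed, size = 50) {
  x <- unclass(input)
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  if (dim(x)[1] < size)
    abort(sprintf("context grid %d^3 is smaller than the %d^3 crop",
                  dim(x)[1], size))
  out <- cpp_augment(x, as.integer(seed), as.integer(size))
  structure(out, class = c("model_input", "array"),
            normalized = attr(input, "normalized"))
}

#' Build the model input tensor for a cohort
#'
#' Loads (or takes from memory) every segmentation in a cohort manifest,
#' normalizes the image channel, optionally stacks the segmentation mask as
#' a second channel (SEG variant), and returns the stacked `(D, D, D, C, N)`
#' tensor with labels. The noSEG variant never touches mask data.
#'
#' @param cohort A `polyp_cohort` or a manifest tibble with `volume_path`
#'   (and `mask_path` for SEG) columns.
#' @param variant `"noSEG"` (image only) or `"SEG"` (image + mask).
#' @param crop `"none"` to keep the stored grid (context cohorts stay at
#'   their generation size) or `"centre"` for a deterministic 50^3 crop.
#' @return A `model_dataset` list: `x`, `y` (1 = premalignant), `ids`,
#'   `manifest`, `variant`.
#' @export
build_model_inputs <- function(cohort, variant = c("noSEG", "SEG"),
                               crop = c("none", "centre")) {
  variant <- match.arg(variant)
  crop <- match.arg(crop)
  in_memory <- inherits(cohort, "polyp_cohort") && !is.null(cohort$volumes)
  manifest <- if (inherits(cohort, "polyp_cohort")) cohort$manifest else cohort
  ids <- paste0(manifest$polyp_id, "_", manifest$position)
  get_vol <- function(i) {
    if (in_memory) cohort$volumes[[ids[i]]]
    else read_volume(manifest$volume_path[i])$values
  }
  get_mask <- function(i) {
    if (in_memory) cohort$masks[[ids[i]]]
    else read_volume(manifest$mask_path[i])$values
  }
  xs <- lapply(seq_len(nrow(manifest)), function(i) {
    v <- get_vol(i)
    m <- if (variant == "SEG") get_mask(i) else NULL
    xi <- unclass(model_input(v, m))
    if (crop == "centre" && dim(xi)[1] > 50)
      xi <- crop_subvolume(xi, centre_voxel(dim(xi)[1]), 50)
    xi
  })
  d <- dim(xs[[1]])
  x <- array(unlist(xs, use.names = FALSE), dim = c(d, length(xs)))
  structure(
    list(x = x,
         y = as.integer(manifest$class_label == "premalignant"),
         ids = ids, manifest = manifest, variant = variant),
    class = "model_dataset")
}

# Subset a model_dataset by segmentation ids (order follows `ids`).
dataset_subset <- function(dataset, ids) {
  ix <- match(ids, dataset$ids)
  if (anyNA(ix)) abort("unknown segmentation ids in split")
  structure(
    list(x = dataset$x[, , , , ix, drop = FALSE],
         y = dataset$y[ix], ids = dataset$ids[ix],
         manifest = dataset$manifest[ix, ], variant = dataset$variant),
    class = "model_dataset")
}

# Deterministic centre crop of a whole dataset tensor to 50^3.
dataset_centre_crop <- function(dataset, size = 50) {
  d <- dim(dataset$x)[1]
  if (d == size) return(dataset)
  off <- (d - size) %/% 2
  dataset$x <- dataset$x[off + seq_len(size), off + seq_len(size),
                         off + seq_len(size), , , drop = FALSE]
  dataset
}
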