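#' Training hyperparameters
#'
#' Defaults are the reference training configuration: plain stochastic
#' gradient descent at learning rate 0.01, binary cross-entropy loss,
#' batch size 8, early stopping when the validation AUC has not strictly
#' improved for 64 consecutive epochs (weights restored from the best
#' epoch). `momentum` defaults to 0 and may be raised for small-scale runs.
#'
#' @param optimizer `"sgd"` (the reference optimiser) or `"adam"`. The
#'   architecture has no normalisation layers, which leaves plain SGD on a
#'   long ill-conditioned plateau at small sample sizes; the adaptive
#'   option is used by the desk profile to converge in few epochs.
#' @param learning_rate Learning rate (0.01 is the reference SGD value;
#'   around 1e-3 suits the adaptive optimiser).
#' @param momentum SGD momentum coefficient (0 disables).
#' @param batch_size Mini-batch size.
#' @param patience_epochs Early-stopping patience on validation AUC.
#' @param max_epochs Hard cap on training epochs.
#' @param dropout_rate Dropout on the pooled feature vector.
#' @param augment Apply random-crop/flip/rotation augmentation to training
#'   inputs (validation inputs are always centre-cropped, never augmented).
#' @param clip_norm Global L2 bound on the batch-mean gradient (0 disables).
#'   The 1-filter shortcut convolutions receive gradients summed across all
#'   block channels, which makes unclipped SGD with momentum prone to
#'   divergence; clipping stabilises the accelerated small-scale profile.
#' @param weight_decay Decoupled L2 shrinkage coefficient on convolution and
#'   dense weights (0 disables). Discourages per-sample memorisation, which
#'   otherwise outruns generalisable feature learning on small cohorts.
#' @param center_init Apply data-dependent bias centering before training:
#'   each convolution bias is set so the layer's pre-activation is
#'   zero-mean over a reference batch of training inputs. Without
#'   normalisation layers, rectified activations otherwise accumulate
#'   means that dwarf the between-sample signal and stall SGD on a long
#'   plateau.
#' @param loss,monitor Recorded for provenance; only binary cross-entropy
#'   and validation-AUC monitoring are implemented.
#' @return A `training_params` list.
#' @export
training_params <- function(optimizer = c("sgd", "adam"),
                            learning_rate = 0.01, momentum = 0,
                            batch_size = 8, patience_epochs = 64,
                            max_epochs = 1000, dropout_rate = 0.5,
                            augment = TRUE, clip_norm = 0,
                            weight_decay = 0, center_init = TRUE,
                            loss = "binary_crossentropy",
                            monitor = "val_auc") {
  optimizer <- match.arg(optimizer)
  stopifnot(learning_rate >= 0, momentum >= 0, momentum < 1,
            batch_size >= 1, patience_epochs >= 1, max_epochs >= 1,
            dropout_rate >= 0, dropout_rate < 1, clip_norm >= 0)
  if (!identical(loss, "binary_crossentropy"))
    abort("only the binary cross-entropy loss is implemented")
  if (!identical(monitor, "val_auc"))
    abort("only validation-AUC monitoring is implemented")
  structure(list(optimizer = optimizer,
                 learning_rate = learning_rate, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 patience_epochs = as.integer(patience_epochs),
                 max_epochs = as.integer(max_epochs),
                 dropout_rate = dropout_rate, augment = augment,
                 clip_norm = clip_norm, weight_decay = weight_decay,
                 center_init = center_init,
                 loss = loss, monitor = monitor),
            class = "training_params")
}

#' Train one member network
#'
#' Runs SGD with per-epoch validation-AUC monitoring. Training halts when
#' the validation AUC has not strictly exceeded its running maximum for
#' `patience_epochs` consecutive epochs (or at `max_epochs`), and the
#' weights from the best-validation-AUC epoch are restored. The returned
#' history records every epoch's training loss and validation AUC.
#'
#' @param net An untrained (or trained) `member_network`.
#' @param dataset A `model_dataset` whose grid is 50^3 or a larger context
#'   grid (training inputs are randomly cropped, validation inputs
#'   centre-cropped).
#' @param split A [make_split()] partition of `dataset$ids`.
#' @param params A [training_params()].
#' @param seed Seed for shuffling, augmentation and dropout.
#' @return The trained `member_network` with `history`, `best_epoch` and
#'   recorded seeds.
#' @export
train_member <- function(net, dataset, split, params = training_params(),
                         seed = 1) {
  stopifnot(inherits(net, "member_network"),
            inherits(dataset, "model_dataset"),
            inherits(split, "train_val_split"),
            inherits(params, "training_params"))
  tr <- dataset_subset(dataset, split$train_ids)
  va <- dataset_centre_crop(dataset_subset(dataset, split$val_ids))
  if (length(unique(va$y)) < 2)
    abort("validation set contains a single class: AUC is undefined")
  if (length(unique(tr$y)) < 2)
    abort("training set contains a single class")
  p <- unclass(params)
  p$dropout_rate <- net$config$dropout_rate
  if (isTRUE(params$center_init)) {
    # deterministic reference batch for bias centering: the first training
    # samples of this member's split, centre-cropped
    ref <- dataset_centre_crop(
      dataset_subset(dataset, head(split$train_ids, 16)))
    net$weights <- cpp_center_init(net$weights, ref$x)
  }
  fit <- cpp_train_member(net$weights, tr$x, tr$y, va$x, va$y, p,
                          as.integer(seed))
  net$weights <- fit$weights
  net$trained <- TRUE
  net$history <- tibble(epoch = seq_along(fit$train_loss),
                        train_loss = fit$train_loss,
                        val_auc = fit$val_auc,
                        grad_norm = fit$grad_norm)
  net$best_epoch <- fit$best_epoch
  net$best_val_auc <- fit$best_val_auc
  net$stopped_early <- fit$stopped_early
  net$seeds$split <- split$seed
  net$seeds$train <- as.integer(seed)
  net
}

#' Train a deep ensemble of member networks
#'
#' Trains `n_members` member CNNs, each on its own random 80-20
#' train-validation split of the segmentations (split seed `base_seed + i`
#' for member `i`) with an independent weight-initialisation seed. Members
#' are trained independently, so results are invariant to training order
#' given the per-member seeds. The ensemble prediction is the unweighted
#' arithmetic mean of the member scores.
#'
#' @param dataset A `model_dataset` built with the matching `variant`.
#' @param variant `"noSEG"` (1-channel) or `"SEG"` (2-channel).
#' @param n_members Number of member networks (reference configuration: 50).
#' @param base_seed Base seed from which all member seeds derive.
#' @param params A [training_params()].
#' @param split_fraction Training fraction of each member split.
#' @param group_splits Split at patient level instead of segmentation level.
#' @param progress Print a line per trained member.
#' @return A `polyp_ensemble` object.
#' @export
train_ensemble <- function(dataset, variant = c("noSEG", "SEG"),
                           n_members = 50, base_seed = 1,
                           params = training_params(),
                           split_fraction = 0.8, group_splits = FALSE,
                           progress = FALSE) {
  variant <- match.arg(variant)
  if (n_members < 1) abort("`n_members` must be >= 1")
  stopifnot(inherits(dataset, "model_dataset"))
  if (!identical(dataset$variant, variant))
    abort(sprintf("dataset was built for variant %s, not %s",
                  dataset$variant, variant))
  in_ch <- if (variant == "SEG") 2L else 1L
  if (dim(dataset$x)[4] != in_ch)
    abort(sprintf("%s expects %d-channel inputs, got %d",
                  variant, in_ch, dim(dataset$x)[4]))
  config <- network_config(in_channels = in_ch,
                           dropout_rate = params$dropout_rate)
  groups <- if (group_splits) dataset$manifest$patient_id
  members <- vector("list", n_members)
  seeds <- tibble(member = seq_len(n_members),
                  split_seed = base_seed + seq_len(n_members),
                  init_seed = child_seed(base_seed, seq_len(n_members), 1L),
                  train_seed = child_seed(base_seed, seq_len(n_members), 2L))
  for (i in seq_len(n_members)) {
    split <- make_split(dataset$ids, fraction = split_fraction,
                        seed = seeds$split_seed[i], groups = groups)
    net <- build_member(config, seed = seeds$init_seed[i])
    members[[i]] <- train_member(net, dataset, split, params,
                                 seed = seeds$train_seed[i])
    if (progress)
      message(sprintf("member %d/%d: %d epochs, best val AUC %.3f",
                      i, n_members, nrow(members[[i]]$history),
                      members[[i]]$best_val_auc))
  }
  structure(list(variant = variant, members = members,
                 member_seeds = seeds, params = params, config = config,
                 base_seed = as.integer(base_seed)),
            class = "polyp_ensemble")
}

#' Member-wise scores for a batch of inputs
#'
#' @param ensemble A `polyp_ensemble`.
#' @param input Inputs accepted by [forward()].
#' @return A numeric matrix (inputs x members).
#' @export
member_scores <- function(ensemble, input) {
  stopifnot(inherits(ensemble, "polyp_ensemble"))
  n <- dim(as_input_batch(input))[5]
  ms <- vapply(ensemble$members, function(m) forward(m, input), numeric(n))
  matrix(ms, nrow = n)
}

#' Ensemble prediction
#'
#' The ensemble score is the unweighted arithmetic mean of the member
#' scores, and therefore lies within the member score range.
#'
#' @param object A `polyp_ensemble`.
#' @param newdata Inputs accepted by [forward()].
#' @param type `"score"` for the mean, `"members"` for the score matrix.
#' @param ... Unused.
#' @return Numeric vector of ensemble scores, or the member score matrix.
#' @export
predict.polyp_ensemble <- function(object, newdata,
                                   type = c("score", "members"), ...) {
  type <- match.arg(type)
  if (length(object$members) == 0) abort("ensemble has no members")
  ms <- member_scores(object, newdata)
  if (type == "members") return(ms)
  rowMeans(ms)
}

#' @export
print.polyp_ensemble <- function(x, ...) {
  cat(sprintf("<polyp_ensemble> %s, %d members (base seed %d)\n",
              x$variant, length(x$members), x$base_seed))
  if (length(x$members) && x$members[[1]]$trained) {
    aucs <- vapply(x$members, function(m) m$best_val_auc, numeric(1))
    cat(sprintf("  member validation AUC: median %.3f, range %.3f-%.3f\n",
                stats::median(aucs), min(aucs), max(aucs)))
  }
  invisible(x)
}

#' Persist an ensemble to a directory
#'
#' Writes one checkpoint per member plus a JSON manifest recording the
#' variant, seeds and training parameters.
#'
#' @param ensemble A `polyp_ensemble`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
save_ensemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(ensemble$members))
    saveRDS(ensemble$members[[i]],
            file.path(dir, sprintf("member_%03d.rds", i)))
  meta <- list(variant = ensemble$variant,
               n_members = length(ensemble$members),
               base_seed = ensemble$base_seed,
               member_seeds = ensemble$member_seeds,
               params = unclass(ensemble$params),
               in_channels = ensemble$config$in_channels)
  jsonlite::write_json(meta, file.path(dir, "ensemble.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Load an ensemble saved by [save_ensemble()]
#'
#' @param dir Ensemble directory.
#' @return A `polyp_ensemble`.
#' @export
load_ensemble <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "ensemble.json"),
                              simplifyVector = TRUE)
  members <- lapply(seq_len(meta$n_members), function(i)
    readRDS(file.path(dir, sprintf("member_%03d.rds", i))))
  params <- do.call(training_params, meta$params[
    setdiff(names(meta$params), character())])
  structure(list(variant = meta$variant, members = members,
                 member_seeds = as_tibble(meta$member_seeds),
                 params = params,
                 config = network_config(in_channels = meta$in_channels),
                 base_seed = meta$base_seed),
            class = "polyp_ensemble")
}
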