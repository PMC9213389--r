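# Fixed-score member: all-zero weights except the output bias, so the
# forward pass returns sigmoid(bias) for every input.
fixed_member <- function(score, channels = 1) {
  net <- build_member(network_config(channels), seed = 1)
  net$weights <- lapply(net$weights, function(w) w * 0)
  net$weights$bd <- stats::qlogis(score)
  net$trained <- TRUE
  net
}

manual_ensemble <- function(members, variant = "noSEG") {
  structure(list(variant = variant, members = members, member_seeds = NULL,
                 params = training_params(), config = members[[1]]$config,
                 base_seed = 1L),
            class = "polyp_ensemble")
}

# Small synthetic two-class dataset with constant-intensity classes; the
# within-class jitter keeps validation scores untied.
toy_dataset <- function(n = 16, seed = 1, d = 50) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  x <- array(0, dim = c(d, d, d, 1, n))
  for (i in seq_len(n))
    x[, , , 1, i] <- (if (y[i] == 1) 0.72 else 0.30) + rnorm(1, 0, 0.02) +
      array(rnorm(d^3, 0, 0.01), dim = c(d, d, d))
  x <- pmin(pmax(x, 0), 1)
  structure(list(x = x, y = y, ids = sprintf("t%02d", seq_len(n)),
                 manifest = tibble::tibble(id = sprintf("t%02d", seq_len(n))),
                 variant = "noSEG"),
            class = "model_dataset")
}

test_that("ensemble prediction is the arithmetic mean of member scores", {
  ens <- manual_ensemble(list(fixed_member(0.2), fixed_member(0.4),
                              fixed_member(0.6)))
  x <- array(runif(50^3), dim = c(50, 50, 50, 1, 1))
  expect_equal(predict(ens, x), 0.4, tolerance = 1e-6)
  ms <- predict(ens, x, type = "members")
  expect_equal(predict(ens, x), mean(ms), tolerance = 1e-15)
  # identical members collapse to the single-member score
  ens1 <- manual_ensemble(list(fixed_member(0.3), fixed_member(0.3)))
  expect_equal(predict(ens1, x), forward(fixed_member(0.3), x),
               tolerance = 1e-15)
  # the ensemble score lies within the member score range
  set.seed(2)
  nets <- lapply(1:3, function(s) build_member(network_config(1), seed = s))
  ens3 <- manual_ensemble(nets)
  sc <- predict(ens3, x)
  msc <- predict(ens3, x, type = "members")
  expect_gte(sc, min(msc))
  expect_lte(sc, max(msc))
  empty <- manual_ensemble(list(fixed_member(0.5)))
  empty$members <- list()
  expect_error(predict(empty, x), "no members")
})

test_that("training refuses degenerate splits before starting", {
  ds <- toy_dataset(12)
  net <- build_member(network_config(1), seed = 1)
  # validation ids drawn from one class only
  split <- structure(list(train_ids = ds$ids[1:8],
                          val_ids = ds$ids[c(9, 11)],  # both label 0
                          fraction = 0.8, seed = 1L),
                     class = "train_val_split")
  expect_error(train_member(net, ds, split, training_params(), 1),
               "single class")
})

test_that("early stopping counts strictly-improving validation AUC epochs", {
  ds <- toy_dataset(12, seed = 3)
  split <- make_split(ds$ids, 2 / 3, seed = 1)
  net <- build_member(network_config(1), seed = 2)
  # zero learning rate freezes the network: epoch 1 sets the best AUC and
  # no later epoch improves it, so patience 2 stops after exactly 3 epochs
  p <- training_params(learning_rate = 0, patience_epochs = 2,
                       max_epochs = 50, augment = FALSE)
  fit <- train_member(net, ds, split, p, seed = 5)
  expect_equal(nrow(fit$history), 3)
  expect_equal(fit$best_epoch, 1)
  expect_true(fit$stopped_early)
  expect_equal(fit$history$val_auc[1], max(fit$history$val_auc))
})

test_that("restored weights reproduce the best epoch's validation AUC", {
  ds <- toy_dataset(15, seed = 4)
  split <- make_split(ds$ids, 0.8, seed = 2)
  net <- build_member(network_config(1), seed = 3)
  p <- training_params(learning_rate = 0.005, clip_norm = 5,
                       patience_epochs = 8, max_epochs = 8,
                       augment = FALSE, center_init = FALSE)
  fit <- train_member(net, ds, split, p, seed = 6)
  expect_equal(fit$best_val_auc, max(fit$history$val_auc))
  expect_equal(fit$history$val_auc[fit$best_epoch], fit$best_val_auc)
  # recompute the validation AUC from the restored weights
  va <- polypcnn:::dataset_subset(ds, split$val_ids)
  sc <- forward(fit, va$x)
  expect_equal(roc_auc(sc, va$y), fit$best_val_auc, tolerance = 1e-12)
})

test_that("separable toy classes are learned within a few epochs", {
  ds <- toy_dataset(16, seed = 5)
  split <- make_split(ds$ids, 0.75, seed = 3)
  net <- build_member(network_config(1), seed = 4)
  p <- training_params(learning_rate = 0.005, clip_norm = 5,
                       patience_epochs = 8, max_epochs = 8,
                       augment = FALSE, center_init = FALSE)
  fit <- train_member(net, ds, split, p, seed = 7)
  expect_lt(min(fit$history$train_loss[-1]), fit$history$train_loss[1])
})

test_that("ensembles train reproducibly and order-invariantly", {
  ds <- toy_dataset(14, seed = 6)
  p <- training_params(patience_epochs = 3, max_epochs = 3, augment = FALSE,
                       center_init = FALSE)
  e1 <- train_ensemble(ds, "noSEG", n_members = 2, base_seed = 6, params = p)
  e2 <- train_ensemble(ds, "noSEG", n_members = 2, base_seed = 6, params = p)
  x <- ds$x[, , , , 1:4, drop = FALSE]
  expect_identical(predict(e1, x), predict(e2, x))
  expect_identical(e1$members[[1]]$weights, e2$members[[1]]$weights)
  # member seeds are recorded
  expect_equal(e1$member_seeds$split_seed, c(7, 8))
  expect_error(train_ensemble(ds, "noSEG", n_members = 0, base_seed = 1),
               ">= 1")
  expect_error(train_ensemble(ds, "SEG", n_members = 1, base_seed = 1),
               "variant")
})

test_that("ensembles round-trip through save/load", {
  ds <- toy_dataset(12, seed = 8)
  p <- training_params(patience_epochs = 2, max_epochs = 2, augment = FALSE,
                       center_init = FALSE)
  ens <- train_ensemble(ds, "noSEG", n_members = 2, base_seed = 10, params = p)
  dir <- withr::local_tempdir()
  save_ensemble(ens, dir)
  expect_true(file.exists(file.path(dir, "ensemble.json")))
  expect_length(list.files(dir, pattern = "member_.*rds"), 2)
  ens2 <- load_ensemble(dir)
  x <- ds$x[, , , , 1:3, drop = FALSE]
  expect_identical(predict(ens, x), predict(ens2, x))
  expect_equal(ens2$variant, "noSEG")
})
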