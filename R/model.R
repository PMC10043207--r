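#' CNN architecture specification
#'
#' The multi-label outcome classifier: `n_conv` convolutional blocks (32
#' filters of 3x3 with same padding, ReLU, 2x2 max-pooling) followed by
#' three linear layers (2048, 128 and 3 units), with ReLU activations
#' between them, dropout at rate 0.8 after the first linear activation
#' and a per-class sigmoid output. With the default 128 x 128 single
#' channel input the flattened convolutional output is 8 x 8 x 32 = 2048,
#' matching the first linear width.
#'
#' @param input_size input image side in pixels.
#' @param n_conv number of conv blocks.
#' @param filters filters per conv layer.
#' @param linear_widths output widths of the linear layers; the last entry
#'   is the number of classes (3 strategies).
#' @param dropout dropout rate after the first linear activation.
#' @return A `model_spec` list.
#' @export
model_spec <- function(input_size = 128, n_conv = 4, filters = 32,
                       linear_widths = c(2048, 128, 3), dropout = 0.8) {
  stopifnot(input_size >= 2^n_conv, length(linear_widths) >= 1,
            dropout >= 0, dropout < 1)
  structure(list(input_size = as.integer(input_size),
                 n_conv = as.integer(n_conv), filters = as.integer(filters),
                 linear_widths = as.integer(linear_widths),
                 dropout = dropout),
            class = "model_spec")
}

#' Training configuration
#'
#' @param epochs training epochs.
#' @param lr ADAM learning rate.
#' @param batch_size minibatch size.
#' @param seed RNG seed controlling initialisation, shuffling and dropout;
#'   training is reproducible from it (single-threaded BLAS assumed).
#' @export
train_config <- function(epochs = 100, lr = 1e-4, batch_size = 16,
                         seed = 1L) {
  stopifnot(epochs >= 1)
  list(epochs = as.integer(epochs), lr = lr,
       batch_size = as.integer(batch_size), seed = as.integer(seed))
}

#' Encode a tissue disk as a CNN input image
#'
#' Background and PV openings map to 0, healthy tissue to 0.5 and
#' fibrotic tissue to 1.0; the grid is resampled to the model input size
#' with nearest-neighbour interpolation. Note the lesion masks are *not*
#' part of the encoding: the network never sees them.
#'
#' @param disk a `tissue_disk`.
#' @param input_size target side length in pixels.
#' @return `input_size` x `input_size` numeric matrix.
#' @export
disk_to_image <- function(disk, input_size = 128) {
  lab <- disk$label_grid
  img <- matrix(0, nrow(lab), ncol(lab))
  img[lab == LBL_HEALTHY] <- 0.5
  img[lab == LBL_FIBROTIC] <- 1.0
  if (nrow(lab) != input_size) {
    idx <- pmin(nrow(lab), pmax(1L, round(seq(1, nrow(lab),
                                              length.out = input_size))))
    img <- img[idx, idx]
  }
  img
}

#' Stack a cohort of disks into a CNN input array
#'
#' @param disks list of `tissue_disk`s.
#' @param input_size image side in pixels.
#' @return H x W x N array of encoded images (see [disk_to_image()]).
#' @export
cohort_images <- function(disks, input_size) {
  arr <- array(0, dim = c(input_size, input_size, length(disks)))
  for (i in seq_along(disks)) arr[, , i] <- disk_to_image(disks[[i]], input_size)
  arr
}

#' Multi-label mean-squared-error loss
#'
#' The training loss for one sample: `sum((yscore - y)^2) / N` with `N`
#' the number of classes.
#'
#' @param yscore predicted class scores in \[0,1\].
#' @param y ground-truth labels (0/1).
#' @export
mse_multilabel <- function(yscore, y) {
  if (length(yscore) != length(y)) stop("length mismatch")
  sum((yscore - y)^2) / length(y)
}

#' Train one fold
#'
#' Trains the CNN on `train_idx`, evaluates the validation loss after
#' every epoch and returns the checkpoint with the lowest validation loss
#' (the model-selection rule), together with the per-epoch loss log.
#'
#' @param images H x W x N array (see [cohort_images()]).
#' @param labels N x 3 numeric 0/1 matrix, columns (PVI, FIBRO, ROTOR).
#' @param train_idx,val_idx disjoint 1-based index vectors.
#' @param spec [model_spec()].
#' @param config [train_config()].
#' @return An `af_cnn` object: `weights`, `spec`, `log` (tibble of epoch,
#'   train_loss, val_loss), `best_epoch`.
#' @export
train_fold <- function(images, labels, train_idx, val_idx, spec, config) {
  stopifnot(length(train_idx) > 0, length(val_idx) > 0,
            !anyDuplicated(c(train_idx, val_idx)))
  conf <- c(unclass(spec), config)
  fit <- cnn_train_cpp(images, labels, as.integer(train_idx),
                       as.integer(val_idx), conf)
  structure(list(weights = fit$weights, spec = spec, config = config,
                 log = tibble::tibble(epoch = seq_along(fit$train_loss),
                                      train_loss = fit$train_loss,
                                      val_loss = fit$val_loss),
                 best_epoch = fit$best_epoch,
                 best_val_loss = fit$best_val_loss),
            class = "af_cnn")
}

#' Predict strategy-success scores
#'
#' @param object an `af_cnn`.
#' @param images H x W x N array or a single H x W matrix.
#' @param ... unused.
#' @return N x 3 matrix of sigmoid scores.
#' @export
predict.af_cnn <- function(object, images, ...) {
  if (is.matrix(images))
    images <- array(images, dim = c(dim(images), 1))
  conf <- c(unclass(object$spec), object$config)
  cnn_predict_cpp(object$weights, conf, images)
}

#' Area under the ROC curve
#'
#' Rank-based AUC (equivalent to the probability that a random positive
#' scores above a random negative, ties counted half).
#'
#' @param scores continuous scores.
#' @param labels 0/1 labels.
#' @return AUC in \[0,1\], or NA (with a warning) if only one class is
#'   present.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Per-class evaluation metrics
#'
#' AUC from the continuous scores; recall, precision and F1 from scores
#' thresholded at `threshold`. When the model predicts no positives at
#' all, precision is reported as 1.0 (the zero-prediction convention) and
#' recall/F1 are 0.
#'
#' @param scores N x K score matrix.
#' @param labels N x K 0/1 matrix.
#' @param threshold classification threshold.
#' @param class_names optional column names.
#' @return A tibble with one row per class: auc, recall, precision, f1.
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5,
                            class_names = c("PVI", "FIBRO", "ROTOR")) {
  stopifnot(identical(dim(scores), dim(labels)))
  rows <- lapply(seq_len(ncol(scores)), function(k) {
    y <- as.integer(labels[, k]); s <- scores[, k]
    pred <- as.integer(s >= threshold)
    tp <- sum(pred == 1 & y == 1)
    recall <- if (sum(y == 1) == 0) NA_real_ else tp / sum(y == 1)
    precision <- if (sum(pred == 1) == 0) 1.0 else tp / sum(pred == 1)
    f1 <- if (is.na(recall) || recall + precision == 0) 0
      else 2 * recall * precision / (recall + precision)
    auc <- suppressWarnings(auc_score(s, y))
    tibble::tibble(class = class_names[k], auc = auc, recall = recall,
                   precision = precision, f1 = f1)
  })
  do.call(rbind, rows)
}

#' Hold-out + k-fold split
#'
#' Splits disk ids into a hold-out test set and `n_folds` cross-validation
#' folds of the remainder, reproducibly from `seed`.
#'
#' @param ids character vector of disk ids.
#' @param n_holdout hold-out size.
#' @param n_folds number of CV folds.
#' @param seed RNG seed.
#' @return A `dataset_split`: `holdout_ids`, `cv_fold` (named integer
#'   vector over the remaining ids).
#' @export
make_split <- function(ids, n_holdout = 50, n_folds = 5, seed = 1) {
  stopifnot(n_holdout < length(ids))
  withr::with_seed(seed, {
    holdout <- sample(ids, n_holdout)
    rest <- setdiff(ids, holdout)
    fold <- sample(rep(seq_len(n_folds), length.out = length(rest)))
  })
  structure(list(holdout_ids = holdout,
                 cv_fold = setNames(fold, rest)),
            class = "dataset_split")
}

#' Cross-validated training and hold-out evaluation
#'
#' Trains one model per fold (that fold held out as the validation set
#' used for checkpoint selection, the others as training data), evaluates
#' every fold's selected checkpoint on the fixed hold-out set, and
#' reports per-class metrics as mean +/- sd across folds. The best fold
#' is the one with the highest mean hold-out AUC.
#'
#' @param images H x W x N array, in the order of `ids`.
#' @param labels N x 3 matrix, same order.
#' @param ids disk ids (length N).
#' @param split a `dataset_split` over `ids`.
#' @param spec,config model and training settings.
#' @return List: `report` (per-fold per-class tibble), `summary`
#'   (mean +/- sd per class), `best_fold`, `best_model`.
#' @export
cross_validate <- function(images, labels, ids, split, spec, config) {
  hold_idx <- match(split$holdout_ids, ids)
  folds <- sort(unique(split$cv_fold))
  reports <- list(); models <- list()
  for (f in folds) {
    val_ids <- names(split$cv_fold)[split$cv_fold == f]
    train_ids <- names(split$cv_fold)[split$cv_fold != f]
    cfg <- config
    cfg$seed <- config$seed + f
    m <- train_fold(images, labels, match(train_ids, ids),
                    match(val_ids, ids), spec, cfg)
    sc <- predict(m, images[, , hold_idx, drop = FALSE])
    rep_f <- evaluate_scores(sc, labels[hold_idx, , drop = FALSE])
    rep_f$fold <- f
    reports[[f]] <- rep_f
    models[[f]] <- m
  }
  report <- do.call(rbind, reports)
  agg <- lapply(split(report, report$class), function(d)
    tibble::tibble(class = d$class[1],
                   auc_mean = mean(d$auc), auc_sd = sd(d$auc),
                   recall_mean = mean(d$recall), recall_sd = sd(d$recall),
                   precision_mean = mean(d$precision),
                   precision_sd = sd(d$precision),
                   f1_mean = mean(d$f1), f1_sd = sd(d$f1)))
  fold_auc <- vapply(split(report, report$fold),
                     function(d) mean(d$auc, na.rm = TRUE), 0)
  best_fold <- as.integer(names(which.max(fold_auc)))
  list(report = report, summary = do.call(rbind, agg),
       best_fold = best_fold, best_model = models[[best_fold]],
       models = models)
}
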