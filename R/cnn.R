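#' Layered CNN architecture for activation t-map classification
#'
#' Builds the layer schedule of the image classifier at one of four depths.
#' Counting every declared layer (input, softmax and the classification
#' output included), the schedule is: input; two blocks of
#' (conv, relu, cross-channel LRN, maxpool); `k - 2` blocks of
#' (conv, relu, maxpool); dropout; fully-connected(2); softmax;
#' classification output — so a depth of `3k + 7` layers with
#' `k in {3, 4, 5, 6}` conv blocks for depths 16/19/22/25. Filter counts
#' double per block from `base_filters`, capped at `max_filters`. The first
#' convolution is 7x7 stride 2 (pad 3); later ones 3x3 stride 1 (pad 1);
#' pooling is 2x2 stride 2.
#'
#' @param depth Total layer count, one of 16, 19, 22, 25.
#' @param input_size Input image side length (square RGB input).
#' @param n_classes Number of output classes.
#' @param base_filters Filters in the first conv block.
#' @param max_filters Cap on filters per block.
#' @param dropout Dropout probability before the fully-connected layer.
#' @param lrn_window,lrn_alpha,lrn_beta,lrn_k Cross-channel normalization
#'   hyperparameters.
#' @return An object of class `cnn_architecture`.
#' @examples
#' arch <- cnn_architecture(22)
#' length(arch$layers)  # 22
#' @export
cnn_architecture <- function(depth, input_size = 227, n_classes = 2,
                             base_filters = 8, max_filters = 128,
                             dropout = 0.5, lrn_window = 5, lrn_alpha = 1e-4,
                             lrn_beta = 0.75, lrn_k = 2) {
  supported <- c(16L, 19L, 22L, 25L)
  if (!depth %in% supported)
    stop("unsupported depth ", depth, "; supported depths: ",
         paste(supported, collapse = ", "), call. = FALSE)
  k <- (depth - 7L) %/% 3L
  layers <- list(list(type = "input", size = c(input_size, input_size, 3L)))
  size <- input_size
  filters <- base_filters
  for (blk in seq_len(k)) {
    if (blk == 1L) {
      conv <- list(type = "conv", kernel = 7L, stride = 2L, pad = 3L,
                   filters = as.integer(filters))
      size <- (size + 2 * 3 - 7) %/% 2 + 1
    } else {
      conv <- list(type = "conv", kernel = 3L, stride = 1L, pad = 1L,
                   filters = as.integer(filters))
    }
    layers <- c(layers, list(conv, list(type = "relu")))
    if (blk <= 2L)
      layers <- c(layers, list(list(type = "lrn", window = as.integer(lrn_window),
                                    alpha = lrn_alpha, beta = lrn_beta,
                                    k = lrn_k)))
    layers <- c(layers, list(list(type = "maxpool", size = 2L, stride = 2L)))
    size <- (size - 2) %/% 2 + 1
    if (size < 1)
      stop("spatial size collapses below 1 pixel; increase `input_size`",
           call. = FALSE)
    filters <- min(filters * 2, max_filters)
  }
  layers <- c(layers,
              list(list(type = "dropout", p = dropout),
                   list(type = "fc", units = as.integer(n_classes)),
                   list(type = "softmax"),
                   list(type = "output", classes = as.integer(n_classes))))
  stopifnot(length(layers) == depth)
  structure(list(depth = as.integer(depth), k = k, layers = layers,
                 input_size = as.integer(input_size),
                 n_classes = as.integer(n_classes),
                 final_spatial = as.integer(size)),
            class = "cnn_architecture")
}

#' Propagated feature-map shapes of an architecture
#'
#' @param arch A `cnn_architecture`.
#' @return data.frame of layer type and output height/width/channels.
#' @export
architecture_shapes <- function(arch) {
  h <- w <- arch$input_size; c <- 3L
  rows <- lapply(arch$layers, function(L) {
    if (L$type == "conv") {
      h <<- (h + 2 * L$pad - L$kernel) %/% L$stride + 1
      w <<- (w + 2 * L$pad - L$kernel) %/% L$stride + 1
      c <<- L$filters
    } else if (L$type == "maxpool") {
      h <<- (h - L$size) %/% L$stride + 1
      w <<- (w - L$size) %/% L$stride + 1
    } else if (L$type == "fc") {
      h <<- 1L; w <<- 1L; c <<- L$units
    }
    data.frame(type = L$type, height = h, width = w, channels = c)
  })
  do.call(rbind, rows)
}

#' @export
print.cnn_architecture <- function(x, ...) {
  cat(sprintf("cnn_architecture: %d layers (%d conv blocks), input %dx%dx3, final spatial %dx%d\n",
              x$depth, x$k, x$input_size, x$input_size,
              x$final_spatial, x$final_spatial))
  invisible(x)
}

#' Training configuration (SGD with momentum)
#'
#' Defaults follow the standard recipe for this classifier: 100 epochs,
#' learning rate 0.01, momentum 0.9, SGDM solver, 70:30 stratified split.
#'
#' @param epochs Training epochs (>= 0).
#' @param learn_rate Initial learning rate.
#' @param momentum Momentum coefficient in `[0, 1)`.
#' @param batch_size Mini-batch size.
#' @param split Training fraction of the 70:30 split.
#' @param seed Integer seed.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 100, learn_rate = 0.01, momentum = 0.9,
                         batch_size = 32, split = 0.7, seed = 1) {
  if (epochs < 0) stop("`epochs` must be >= 0", call. = FALSE)
  if (learn_rate <= 0) stop("`learn_rate` must be > 0", call. = FALSE)
  if (momentum < 0 || momentum >= 1)
    stop("`momentum` must be in [0, 1)", call. = FALSE)
  structure(list(epochs = as.integer(epochs), learn_rate = learn_rate,
                 momentum = momentum, batch_size = as.integer(batch_size),
                 split = split, seed = as.integer(seed)),
            class = "train_config")
}

init_weights <- function(arch) {
  shapes <- architecture_shapes(arch)
  weights <- list()
  h <- arch$input_size; c_in <- 3L
  for (i in seq_along(arch$layers)) {
    L <- arch$layers[[i]]
    if (L$type == "conv") {
      fan_in <- L$kernel^2 * c_in
      weights[[length(weights) + 1L]] <- list(
        W = matrix(stats::rnorm(fan_in * L$filters, 0, sqrt(2 / fan_in)),
                   fan_in, L$filters),
        b = rep(0, L$filters))
      c_in <- L$filters
    } else if (L$type == "fc") {
      sp <- shapes[i - 2L, ]   # shape before dropout/fc
      fan_in <- sp$height * sp$width * sp$channels
      weights[[length(weights) + 1L]] <- list(
        W = matrix(stats::rnorm(fan_in * L$units, 0, sqrt(2 / fan_in)),
                   fan_in, L$units),
        b = rep(0, L$units))
    }
  }
  weights
}

#' Stratified 70:30 split of an image dataset
#'
#' Random stratified split: per class, `round(ratio * n_class)` images go to
#' training and the rest to validation. Optionally grouped by subject (whole
#' subjects assigned to one side) as the leakage-safe alternative; the
#' default pools trials before splitting.
#'
#' @param ds An `image_dataset`.
#' @param ratio Training fraction.
#' @param seed Integer seed.
#' @param group_by_subject Keep each subject's images on one side.
#' @return List with `train`, `validation` (both `image_dataset`s) and the
#'   index vectors `train_idx`, `val_idx`.
#' @export
split_dataset <- function(ds, ratio = 0.7, seed = 1,
                          group_by_subject = FALSE) {
  labs <- ds$labels
  if (ratio < 1 && any(table(labs) < 2))
    stop("each class needs at least 2 images to split", call. = FALSE)
  set.seed(seed)
  train_idx <- integer(0)
  if (group_by_subject) {
    subj <- unique(ds$meta$subject)
    n_tr <- round_half_up(ratio * length(subj), 0)
    keep <- sample(subj, n_tr)
    train_idx <- which(ds$meta$subject %in% keep)
  } else {
    for (cl in levels(labs)) {
      idx <- which(labs == cl)
      n_tr <- round_half_up(ratio * length(idx), 0)
      train_idx <- c(train_idx, sample(idx, n_tr))
    }
  }
  train_idx <- sort(train_idx)
  val_idx <- setdiff(seq_along(labs), train_idx)
  list(train = subset_dataset(ds, train_idx),
       validation = subset_dataset(ds, val_idx),
       train_idx = train_idx, val_idx = val_idx)
}

#' Train the CNN classifier
#'
#' Mini-batch stochastic gradient descent with momentum on the softmax
#' cross-entropy, recording per-epoch training accuracy and loss. All
#' randomness (weight initialization, epoch shuffling, dropout) is drawn
#' from R's RNG, so a fixed `config$seed` reproduces the run on one thread.
#'
#' @param arch A `cnn_architecture`.
#' @param train_set An `image_dataset`.
#' @param config A `train_config`.
#' @return An object of class `cnn_model`: `arch`, `weights`, `curves`
#'   (data.frame epoch/loss/accuracy), `classes`.
#' @export
train_cnn <- function(arch, train_set, config = train_config()) {
  stopifnot(inherits(arch, "cnn_architecture"),
            inherits(train_set, "image_dataset"))
  n <- dim(train_set$images)[4]
  if (config$epochs > 0 && n == 0)
    stop("training set is empty", call. = FALSE)
  if (nlevels(train_set$labels) != arch$n_classes)
    stop("architecture output classes do not match label cardinality",
         call. = FALSE)
  set.seed(config$seed)
  weights <- init_weights(arch)
  # zero-center inputs on the training-set mean image (stored in the model)
  input_mean <- if (n > 0) rowMeans(train_set$images, dims = 3) else
    array(0, dim(train_set$images)[1:3])
  curves <- data.frame(epoch = integer(0), loss = numeric(0),
                       accuracy = numeric(0))
  if (config$epochs > 0) {
    y <- as.integer(train_set$labels) - 1L
    fit <- cnn_train_cpp(train_set$images, y, arch$layers, weights,
                         as.numeric(input_mean), config$epochs,
                         config$learn_rate, config$momentum,
                         config$batch_size)
    weights <- fit$weights
    curves <- data.frame(epoch = seq_len(config$epochs), loss = fit$loss,
                         accuracy = fit$accuracy)
  }
  structure(list(arch = arch, weights = weights, curves = curves,
                 input_mean = input_mean,
                 classes = levels(train_set$labels), config = config),
            class = "cnn_model")
}

#' Predict labels and class scores
#'
#' @param model A `cnn_model`.
#' @param images `image_dataset` or H x W x 3 (x N) array matching the
#'   architecture input.
#' @return List with `labels` (factor) and `scores` (N x 2 matrix of softmax
#'   probabilities; columns named by class, rows sum to 1).
#' @export
predict_cnn <- function(model, images) {
  if (inherits(images, "image_dataset")) images <- images$images
  d <- dim(images)
  if (length(d) == 3L) {
    images <- array(images, c(d, 1L))
    d <- dim(images)
  }
  if (length(d) != 4L || d[1] != model$arch$input_size ||
      d[2] != model$arch$input_size || d[3] != 3L)
    stop(sprintf("images must be %d x %d x 3 (x N)", model$arch$input_size,
                 model$arch$input_size), call. = FALSE)
  mu <- model$input_mean
  if (is.null(mu)) mu <- numeric(0)
  scores <- cnn_predict_cpp(images, model$arch$layers, model$weights,
                            as.numeric(mu))
  colnames(scores) <- model$classes
  labels <- factor(model$classes[max.col(scores, ties.method = "first")],
                   levels = model$classes)
  list(labels = labels, scores = scores)
}

#' @export
predict.cnn_model <- function(object, newdata, ...) predict_cnn(object, newdata)

#' @export
print.cnn_model <- function(x, ...) {
  trained <- nrow(x$curves) > 0
  cat(sprintf("cnn_model: depth %d, %s (%d epochs)%s\n",
              x$arch$depth, if (trained) "trained" else "untrained",
              nrow(x$curves),
              if (trained) sprintf(", final train accuracy %.3f",
                                   utils::tail(x$curves$accuracy, 1)) else ""))
  invisible(x)
}

#' Save/load a trained model (weights + JSON architecture sidecar)
#'
#' Weights go to R's native serialization; the architecture and classes are
#' written next to it as human-readable JSON.
#'
#' @param model A `cnn_model`.
#' @param path Checkpoint path (e.g. `model.rds`).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(list(depth = model$arch$depth,
                            input_size = model$arch$input_size,
                            classes = model$classes,
                            layers = model$arch$layers),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)

#' Write training curves as CSV
#' @param model A `cnn_model`.
#' @param path CSV path.
#' @export
write_curves_csv <- function(model, path) {
  utils::write.csv(model$curves, path, row.names = FALSE)
  invisible(path)
}
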