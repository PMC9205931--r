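# Convolutional classifier: configuration, training, inference, grid
# search, and checkpointing.

#' Model architecture configuration
#'
#' Describes the convolutional classifier: one to three convolutional
#' layers (4-16 filters each; the first kernel has a 7 x 4 extent, spanning
#' 7 positions and the full base axis, so the base dimension is collapsed
#' after the first layer), one to three dense layers, dropout and
#' leaky-ReLU on all but the output layer, and a softmax output over the
#' species classes. The default architecture — one conv layer of 4 filters
#' followed by three dense layers of 128 neurons — is the smallest
#' configuration that reliably captures the structure of short (~60 bp)
#' barcode amplicons.
#'
#' @param conv_layers List of conv layer specs, each a list with
#'   `n_filters` (4-16) and optionally `kernel_extent` (positions, default
#'   7) and `depthwise_separable` (accepted for forward compatibility;
#'   standard convolutions are computed).
#' @param dense_layers Integer vector (1-3 entries) of dense layer widths.
#' @param dropout_rate Dropout probability on dense hidden layers during
#'   training (default 0.2).
#' @param leaky_slope Negative-part slope of the leaky-ReLU (default 0.01).
#' @param input_width Model input width in positions (default 150).
#' @param n_classes Number of species classes (>= 2).
#' @return An object of class `model_config`.
#' @export
model_config <- function(conv_layers = list(list(n_filters = 4L)),
                         dense_layers = c(128L, 128L, 128L),
                         dropout_rate = 0.2, leaky_slope = 0.01,
                         input_width = 150L, n_classes = 2L) {
  if (!is.list(conv_layers) || length(conv_layers) < 1L || length(conv_layers) > 3L)
    stop("conv_layers must be a list of 1 to 3 layer specs")
  conv_layers <- lapply(conv_layers, function(cl) {
    cl <- as.list(cl)
    if (is.null(cl$n_filters)) stop("each conv layer needs n_filters")
    if (cl$n_filters < 4L || cl$n_filters > 16L)
      stop("n_filters must be in 4..16")
    if (is.null(cl$kernel_extent)) cl$kernel_extent <- 7L
    if (cl$kernel_extent < 1L) stop("kernel_extent must be >= 1")
    if (is.null(cl$depthwise_separable)) cl$depthwise_separable <- FALSE
    cl[c("n_filters", "kernel_extent", "depthwise_separable")]
  })
  if (length(dense_layers) < 1L || length(dense_layers) > 3L)
    stop("dense_layers must have 1 to 3 entries")
  if (any(dense_layers < 1L)) stop("dense layer widths must be positive")
  stopifnot(dropout_rate >= 0, dropout_rate < 1, leaky_slope > 0,
            input_width >= 1)
  if (n_classes < 2L) stop("n_classes must be >= 2")
  structure(list(
    conv_layers = conv_layers,
    dense_layers = as.integer(dense_layers),
    dropout_rate = dropout_rate, leaky_slope = leaky_slope,
    input_width = as.integer(input_width), n_classes = as.integer(n_classes)
  ), class = "model_config")
}

#' Build an (untrained) convolutional classifier
#'
#' Initializes the network weights (He initialization, deterministic given
#' `seed`) for the given architecture and species label index.
#'
#' @param config A [model_config()]; its `n_classes` must match the label
#'   index.
#' @param label_index Named integer vector (species -> 0-based class), as
#'   in `reference_db$label_index`.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `cnn_classifier`.
#' @export
build_classifier <- function(config, label_index, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  if (length(label_index) != config$n_classes)
    stop(sprintf("label_index has %d species but config$n_classes = %d",
                 length(label_index), config$n_classes))
  layers <- .with_seed(seed, .nn_init(config))
  structure(list(
    config = config, layers = layers,
    label_index = label_index[order(label_index)],
    training_meta = list(trained = FALSE, init_seed = seed)
  ), class = "cnn_classifier")
}

#' @export
print.cnn_classifier <- function(x, ...) {
  cf <- x$config
  cat(sprintf(
    "cnn_classifier: %d conv layer(s) [%s filters], dense [%s], %d classes, %s parameters%s\n",
    length(cf$conv_layers),
    paste(vapply(cf$conv_layers, `[[`, numeric(1), "n_filters"), collapse = ","),
    paste(cf$dense_layers, collapse = ","), cf$n_classes,
    format(n_parameters(x), big.mark = ","),
    if (isTRUE(x$training_meta$trained)) " (trained)" else " (untrained)"))
  invisible(x)
}

#' Number of trainable parameters of a classifier
#' @param classifier A `cnn_classifier`.
#' @return Numeric parameter count.
#' @export
n_parameters <- function(classifier) .nn_n_params(classifier$layers)

#' Train a convolutional classifier
#'
#' Minimizes categorical cross-entropy with Adam over freshly augmented
#' batches: at every epoch the (optionally class-balanced) reference
#' records are re-augmented under `aug`, shuffled, and consumed in
#' minibatches. Deterministic given `seed` (which drives balancing,
#' augmentation, shuffling and dropout).
#'
#' @param classifier A `cnn_classifier` from [build_classifier()].
#' @param train_db A [reference_db()] whose label index matches the
#'   classifier.
#' @param aug An [augment_config()] (its `target_width` must equal the
#'   model input width).
#' @param epochs Training epochs (default 50); `epochs = 0` returns the
#'   classifier unchanged apart from metadata.
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param batch_size Minibatch size (default 32).
#' @param seed Integer seed.
#' @param balance Balance classes by oversampling before training
#'   (default TRUE).
#' @param verbose Print per-epoch loss every 10 epochs.
#' @return The fitted `cnn_classifier` with `training_meta` recording
#'   epochs, learning rate, seed, augmentation config and final loss.
#' @export
train_classifier <- function(classifier, train_db, aug = augment_config(),
                             epochs = 50L, learning_rate = 1e-3,
                             batch_size = 32L, seed = 1L,
                             balance = TRUE, verbose = FALSE) {
  stopifnot(inherits(classifier, "cnn_classifier"),
            inherits(train_db, "reference_db"),
            inherits(aug, "augment_config"))
  if (!nrow(train_db$records)) stop("empty training database")
  if (length(train_db$label_index) != classifier$config$n_classes)
    stop("training database label index does not match config$n_classes")
  if (!identical(names(train_db$label_index), names(classifier$label_index)))
    stop("training database species do not match the classifier's label index")
  if (aug$target_width != classifier$config$input_width)
    stop("aug$target_width must equal the model input width")
  config <- classifier$config
  layers <- classifier$layers
  meta <- list(trained = epochs > 0L, epochs = as.integer(epochs),
               learning_rate = learning_rate, batch_size = as.integer(batch_size),
               seed = as.integer(seed), augment = unclass(aug),
               init_seed = classifier$training_meta$init_seed)
  if (epochs > 0L) {
    .with_seed(seed, {
      db <- if (balance) balance_oversample(train_db, seed = seed) else train_db
      state <- .adam_init(layers)
      final_loss <- NA_real_
      for (ep in seq_len(epochs)) {
        batch <- make_epoch_batch(db, aug)
        n <- length(batch$labels)
        ord <- sample.int(n)
        losses <- numeric(0)
        for (start in seq(1L, n, by = batch_size)) {
          take <- ord[start:min(start + batch_size - 1L, n)]
          X <- batch$inputs[, take, drop = FALSE]
          y <- batch$labels[take]
          fw <- .nn_forward(layers, X, config, train = TRUE)
          loss <- .nn_loss(fw$probs, y)
          if (!is.finite(loss))
            stop(sprintf("non-finite loss at epoch %d (learning rate too high?)", ep))
          losses <- c(losses, loss)
          grads <- .nn_backward(layers, fw$cache, fw$probs, y, config)
          upd <- .adam_step(layers, grads, state, learning_rate)
          layers <- upd$layers
          state <- upd$state
        }
        final_loss <- mean(losses)
        if (verbose && (ep %% 10L == 0L || ep == 1L))
          message(sprintf("epoch %3d  loss %.4f", ep, final_loss))
      }
      meta$final_loss <- final_loss
    })
  }
  classifier$layers <- layers
  classifier$training_meta <- meta
  classifier
}

#' Class probabilities for a set of sequences
#'
#' Encodes the sequences (shaped to the model input width) and runs the
#' forward pass in chunks. Reads containing non-IUPAC characters are
#' skipped: their rows are all-`NA` and they are flagged in the `invalid`
#' attribute.
#'
#' @param classifier A `cnn_classifier`.
#' @param seqs Character vector of IUPAC DNA sequences.
#' @param chunk_size Sequences encoded per forward pass (default 4096).
#' @return An `N x C` matrix of class probabilities (columns named by
#'   species, in class-index order); each valid row sums to 1. Attribute
#'   `invalid`: logical vector flagging skipped reads.
#' @export
predict_proba <- function(classifier, seqs, chunk_size = 4096L) {
  stopifnot(inherits(classifier, "cnn_classifier"))
  n <- length(seqs)
  C <- classifier$config$n_classes
  out <- matrix(NA_real_, n, C, dimnames = list(NULL, names(classifier$label_index)))
  ok <- .valid_iupac(seqs) & nzchar(seqs)
  idx_ok <- which(ok)
  for (start in seq_len(ceiling(length(idx_ok) / chunk_size))) {
    take <- idx_ok[((start - 1L) * chunk_size + 1L):min(start * chunk_size, length(idx_ok))]
    X <- .encode_batch(seqs[take], classifier$config$input_width)
    fw <- .nn_forward(classifier$layers, X, classifier$config, train = FALSE)
    out[take, ] <- t(fw$probs)
  }
  attr(out, "invalid") <- !ok
  out
}

#' Architecture grid search
#'
#' Trains every candidate configuration under identical conditions (same
#' augmentation, epochs, learning rate and seed) and ranks them by
#' hold-out accuracy at threshold 0; ties are broken toward fewer
#' parameters.
#'
#' @param configs List of [model_config()] objects (>= 1).
#' @param train_db,holdout_db Training and hold-out [reference_db()]s over
#'   the same label universe.
#' @param aug An [augment_config()] used for training.
#' @param epochs,learning_rate,batch_size,seed Passed to
#'   [train_classifier()].
#' @return List with `best_config`, `best_classifier`, and `report` (a
#'   data.frame with one row per candidate: architecture summary,
#'   parameter count, hold-out accuracy).
#' @export
grid_search <- function(configs, train_db, holdout_db, aug = augment_config(),
                        epochs = 50L, learning_rate = 1e-3,
                        batch_size = 32L, seed = 1L) {
  if (!length(configs)) stop("need at least one candidate configuration")
  ex <- .expand_records(holdout_db)
  rows <- lapply(seq_along(configs), function(i) {
    cf <- configs[[i]]
    clf <- build_classifier(cf, train_db$label_index, seed = seed)
    clf <- train_classifier(clf, train_db, aug, epochs = epochs,
                            learning_rate = learning_rate,
                            batch_size = batch_size, seed = seed)
    probs <- predict_proba(clf, ex$sequence)
    pred <- max.col(probs, ties.method = "first") - 1L
    acc <- mean(pred == ex$class)
    list(clf = clf, row = data.frame(
      config_id = i,
      conv = paste(vapply(cf$conv_layers, `[[`, numeric(1), "n_filters"),
                   collapse = "x"),
      dense = paste(cf$dense_layers, collapse = "x"),
      n_parameters = n_parameters(clf),
      holdout_accuracy = acc))
  })
  report <- do.call(rbind, lapply(rows, `[[`, "row"))
  best <- order(-report$holdout_accuracy, report$n_parameters)[1]
  list(best_config = configs[[best]], best_classifier = rows[[best]]$clf,
       report = report)
}

#' Save / load a classifier checkpoint
#'
#' A checkpoint is a directory with `config.json` (architecture),
#' `label_index.json` (species classes), `meta.json` (training metadata)
#' and `weights.rds` (fitted parameters at full precision). A reloaded
#' classifier reproduces [predict_proba()] bit-identically.
#'
#' @param classifier A `cnn_classifier`.
#' @param dir Checkpoint directory (created if needed).
#' @return `save_classifier`: `dir` invisibly; `load_classifier`: the
#'   classifier.
#' @export
save_classifier <- function(classifier, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(classifier$config),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  write_label_index(classifier$label_index, file.path(dir, "label_index.json"))
  jsonlite::write_json(c(list(format_version = 1L), classifier$training_meta),
                       file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(classifier$layers, file.path(dir, "weights.rds"))
  invisible(dir)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  config <- model_config(
    conv_layers = lapply(seq_len(nrow(cfg$conv_layers)), function(i)
      as.list(cfg$conv_layers[i, ])),
    dense_layers = cfg$dense_layers, dropout_rate = cfg$dropout_rate,
    leaky_slope = cfg$leaky_slope, input_width = cfg$input_width,
    n_classes = cfg$n_classes)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  structure(list(
    config = config,
    layers = readRDS(file.path(dir, "weights.rds")),
    label_index = read_label_index(file.path(dir, "label_index.json")),
    training_meta = meta[setdiff(names(meta), "format_version")]
  ), class = "cnn_classifier")
}
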