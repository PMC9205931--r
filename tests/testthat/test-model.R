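test_that("model configuration enforces the architecture ranges", {
  expect_error(model_config(conv_layers = list()), "1 to 3")
  expect_error(model_config(conv_layers = rep(list(list(n_filters = 4)), 4)),
               "1 to 3")
  expect_error(model_config(conv_layers = list(list(n_filters = 2))), "4..16")
  expect_error(model_config(conv_layers = list(list(n_filters = 32))), "4..16")
  expect_error(model_config(dense_layers = integer(0)), "1 to 3")
  expect_error(model_config(dense_layers = c(8, 8, 8, 8)), "1 to 3")
  expect_error(model_config(n_classes = 1), "n_classes")
  expect_error(build_classifier(model_config(n_classes = 3),
                                c(a = 0L, b = 1L)), "n_classes")
})

test_that("the reported optimal architectures build, with softmax outputs over C classes", {
  # split-sampling optimum: 1 conv x 4 filters (7x4), 3 dense x 128, 156 classes
  idx156 <- stats::setNames(0:155, sprintf("sp%03d", 1:156))
  cfg <- model_config(conv_layers = list(list(n_filters = 4)),
                      dense_layers = c(128, 128, 128), n_classes = 156)
  clf <- build_classifier(cfg, idx156, seed = 1)
  p <- predict_proba(clf, c("ACGTACGT", strrep("N", 150)))
  expect_equal(dim(p), c(2, 156))
  expect_equal(rowSums(p), c(1, 1), tolerance = 1e-6)
  expect_true(all(p >= 0))

  # full-database optimum: 1 conv x 4 filters, 2 dense x 384, 368 classes
  idx368 <- stats::setNames(0:367, sprintf("sp%03d", 1:368))
  cfg2 <- model_config(conv_layers = list(list(n_filters = 4)),
                       dense_layers = c(384, 384), n_classes = 368)
  clf2 <- build_classifier(cfg2, idx368, seed = 1)
  expect_equal(ncol(predict_proba(clf2, "ACGT")), 368)
})

test_that("backpropagation gradients match finite differences on a small multi-layer net", {
  cfg <- model_config(conv_layers = list(list(n_filters = 4),
                                         list(n_filters = 5)),
                      dense_layers = c(7), dropout_rate = 0,
                      input_width = 25, n_classes = 3)
  set.seed(20)
  layers <- ednacnn:::.nn_init(cfg)
  X <- ednacnn:::.encode_batch(
    c(strrep("ACGTW", 5), strrep("GGTCA", 5), strrep("TTNAC", 5)), 25)
  y <- c(0L, 2L, 1L)
  fw <- ednacnn:::.nn_forward(layers, X, cfg, train = FALSE)
  grads <- ednacnn:::.nn_backward(layers, fw$cache, fw$probs, y, cfg)
  loss_at <- function(layers) {
    f <- ednacnn:::.nn_forward(layers, X, cfg, train = FALSE)
    ednacnn:::.nn_loss(f$probs, y)
  }
  eps <- 1e-5
  for (li in seq_along(layers)) {
    for (p in c("W", "b")) {
      theta <- layers[[li]][[p]]
      for (k in sample(seq_along(theta), min(6, length(theta)))) {
        up <- layers; up[[li]][[p]][k] <- theta[k] + eps
        dn <- layers; dn[[li]][[p]][k] <- theta[k] - eps
        num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
        expect_equal(grads[[li]][[p]][k], num, tolerance = 1e-4)
      }
    }
  }
})

test_that("training separates a small synthetic species set and is seed-deterministic", {
  db <- tiny_sep_db(3, len = 40, seqs_per_species = 2)
  cfg <- model_config(conv_layers = list(list(n_filters = 4)),
                      dense_layers = c(32), input_width = 60,
                      n_classes = n_classes(db))
  aug <- augment_config(sub_rate = 0.02, max_insertions = 1,
                        max_deletions = 1, target_width = 60)
  clf <- build_classifier(cfg, db$label_index, seed = 2)
  fit1 <- train_classifier(clf, db, aug, epochs = 25, seed = 3)
  fit2 <- train_classifier(clf, db, aug, epochs = 25, seed = 3)
  ex <- ednacnn:::.expand_records(db)
  p1 <- predict_proba(fit1, ex$sequence)
  expect_identical(p1, predict_proba(fit2, ex$sequence))
  pred <- max.col(p1, ties.method = "first") - 1L
  expect_gte(mean(pred == ex$class), 0.95)
  expect_true(fit1$training_meta$trained)
  expect_equal(fit1$training_meta$epochs, 25L)
})

test_that("zero-epoch training returns the initialized weights unchanged", {
  db <- toy_db()
  cfg <- model_config(input_width = 20, dense_layers = 8,
                      n_classes = n_classes(db))
  clf <- build_classifier(cfg, db$label_index, seed = 4)
  aug <- augment_config(target_width = 20)
  fit <- train_classifier(clf, db, aug, epochs = 0, seed = 1)
  expect_identical(fit$layers, clf$layers)
  expect_false(fit$training_meta$trained)
})

test_that("training rejects mismatched inputs", {
  db <- toy_db()
  cfg <- model_config(input_width = 20, n_classes = 5)
  idx5 <- stats::setNames(0:4, letters[1:5])
  clf <- build_classifier(cfg, idx5, seed = 1)
  expect_error(train_classifier(clf, db, augment_config(target_width = 20)),
               "label index")
  cfg3 <- model_config(input_width = 30, n_classes = n_classes(db))
  clf3 <- build_classifier(cfg3, db$label_index, seed = 1)
  expect_error(train_classifier(clf3, db, augment_config(target_width = 20)),
               "target_width")
})

test_that("prediction flags invalid reads, is deterministic, and duplicates agree", {
  db <- tiny_sep_db(3)
  cfg <- model_config(input_width = 50, dense_layers = 16,
                      n_classes = n_classes(db))
  clf <- build_classifier(cfg, db$label_index, seed = 5)
  s <- db$records$sequence[1]
  p <- predict_proba(clf, c(s, "AXGT!", s))
  expect_true(all(is.na(p[2, ])))
  expect_equal(attr(p, "invalid"), c(FALSE, TRUE, FALSE))
  expect_identical(p[1, ], p[3, ])
})

test_that("checkpoints reload to bit-identical predictions", {
  db <- tiny_sep_db(3)
  cfg <- model_config(input_width = 50, dense_layers = 16,
                      n_classes = n_classes(db))
  clf <- train_classifier(build_classifier(cfg, db$label_index, seed = 6),
                          db, augment_config(target_width = 50),
                          epochs = 3, seed = 7)
  dir <- withr::local_tempdir()
  save_classifier(clf, dir)
  back <- load_classifier(dir)
  expect_equal(back$config, clf$config)
  expect_identical(back$label_index, clf$label_index)
  seqs <- db$records$sequence
  expect_identical(predict_proba(back, seqs), predict_proba(clf, seqs))
})

test_that("grid search ranks by hold-out accuracy and breaks ties toward fewer parameters", {
  db <- tiny_sep_db(3, seqs_per_species = 3)
  sp <- split_train_holdout(db, seed = 8)
  aug <- augment_config(sub_rate = 0.02, max_insertions = 0,
                        max_deletions = 0, target_width = 50)
  mk <- function(dense) model_config(dense_layers = dense, input_width = 50,
                                     n_classes = n_classes(db))
  gs <- grid_search(list(mk(c(16)), mk(c(16, 16))), sp$train, sp$holdout,
                    aug, epochs = 20, seed = 9)
  expect_equal(nrow(gs$report), 2)
  expect_true(all(c("n_parameters", "holdout_accuracy") %in% names(gs$report)))
  # with equal accuracy the smaller net must win; otherwise the more accurate
  best_row <- gs$report[order(-gs$report$holdout_accuracy,
                              gs$report$n_parameters)[1], ]
  expect_equal(n_parameters(gs$best_classifier), best_row$n_parameters)
  # single-candidate search returns that candidate
  gs1 <- grid_search(list(mk(16)), sp$train, sp$holdout, aug,
                     epochs = 1, seed = 1)
  expect_equal(gs1$best_config, mk(16))
  expect_equal(nrow(gs1$report), 1)
})
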