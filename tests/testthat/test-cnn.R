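test_that("architecture depth equals the declared layer count for all depths", {
  for (depth in c(16, 19, 22, 25)) {
    arch <- cnn_architecture(depth)
    expect_length(arch$layers, depth)
    expect_equal(arch$k, (depth - 7) / 3)
    expect_equal(arch$layers[[1]]$type, "input")
    expect_equal(arch$layers[[depth]]$type, "output")
    expect_gte(arch$final_spatial, 1)                  # 227-pixel input
    shp <- architecture_shapes(arch)
    expect_equal(shp$channels[nrow(shp)], 2)
    # shape-propagation oracle: spatial size after pools stays positive
    expect_true(all(shp$height >= 1 & shp$width >= 1))
  }
  expect_equal(cnn_architecture(22)$k, 5)
})

test_that("unsupported depths are rejected with the supported list", {
  expect_error(cnn_architecture(17), "16, 19, 22, 25")
  expect_error(cnn_architecture(10), "unsupported")
})

test_that("first two blocks carry LRN and the schedule ends with the classifier stack", {
  arch <- cnn_architecture(22)
  types <- vapply(arch$layers, `[[`, character(1), "type")
  expect_equal(sum(types == "lrn"), 2)
  expect_equal(sum(types == "conv"), 5)
  expect_equal(sum(types == "maxpool"), 5)
  expect_equal(tail(types, 4), c("dropout", "fc", "softmax", "output"))
  # filter widths double from the base and are capped
  filt <- vapply(Filter(function(l) l$type == "conv", arch$layers),
                 `[[`, integer(1), "filters")
  expect_equal(filt, pmin(8 * 2^(0:4), 128))
})

test_that("stratified split reproduces the 70:30 counts", {
  ds <- toy_image_dataset(n_per_class = 20, size = 32, seed = 1)
  sp <- split_dataset(ds, 0.7, seed = 2)
  expect_equal(as.vector(table(sp$train$labels)), c(14, 14))
  expect_equal(as.vector(table(sp$validation$labels)), c(6, 6))
  expect_length(intersect(sp$train_idx, sp$val_idx), 0)
  expect_setequal(c(sp$train_idx, sp$val_idx), seq_along(ds$labels))
  # different seeds: different index sets, identical per-class counts
  sp2 <- split_dataset(ds, 0.7, seed = 3)
  expect_false(identical(sp$train_idx, sp2$train_idx))
  expect_equal(table(sp2$train$labels), table(sp$train$labels))
})

test_that("a 100:0 ratio puts everything in training", {
  ds <- toy_image_dataset(n_per_class = 5, size = 32)
  sp <- split_dataset(ds, 1.0, seed = 1)
  expect_equal(dim(sp$train$images)[4], 10)
  expect_equal(dim(sp$validation$images)[4], 0)
})

test_that("subject-grouped splitting keeps subjects on one side", {
  ds <- toy_image_dataset(n_per_class = 16, size = 32)
  sp <- split_dataset(ds, 0.7, seed = 5, group_by_subject = TRUE)
  shared <- intersect(unique(sp$train$meta$subject),
                      unique(sp$validation$meta$subject))
  expect_length(shared, 0)
})

test_that("an untrained model predicts at chance on balanced data", {
  ds <- toy_image_dataset(n_per_class = 30, size = 44, seed = 4)
  arch <- cnn_architecture(16, input_size = 44, base_filters = 4)
  m <- train_cnn(arch, ds, train_config(epochs = 0, seed = 9))
  expect_equal(nrow(m$curves), 0)
  pr <- predict_cnn(m, ds)
  acc <- mean(pr$labels == ds$labels)
  # binomial 99% interval around 0.5 for n = 60
  expect_gte(acc, qbinom(0.005, 60, 0.5) / 60)
  expect_lte(acc, qbinom(0.995, 60, 0.5) / 60)
})

test_that("softmax scores sum to one and batch prediction equals one-by-one", {
  ds <- toy_image_dataset(n_per_class = 6, size = 44, seed = 2)
  arch <- cnn_architecture(16, input_size = 44, base_filters = 4)
  m <- train_cnn(arch, ds, train_config(epochs = 2, batch_size = 4, seed = 3))
  pr <- predict_cnn(m, ds)
  expect_equal(rowSums(pr$scores), rep(1, 12), tolerance = 1e-6)
  for (i in c(1, 7, 12)) {
    single <- predict_cnn(m, ds$images[, , , i])
    expect_equal(as.numeric(single$scores), as.numeric(pr$scores[i, ]),
                 tolerance = 1e-10)
  }
  expect_error(predict_cnn(m, array(0, c(10, 10, 3, 1))), "images must be")
})

test_that("the toy separable set is learned and loss decreases", {
  ds <- toy_image_dataset(n_per_class = 30, size = 44, seed = 6)
  sp <- split_dataset(ds, 0.7, seed = 1)
  arch <- cnn_architecture(16, input_size = 44, base_filters = 4)
  m <- train_cnn(arch, sp$train, train_config(epochs = 15, seed = 2))
  pr <- predict_cnn(m, sp$validation)
  expect_gte(mean(pr$labels == sp$validation$labels), 0.9)
  # loss is non-increasing over epoch-averaged windows of 5
  win <- tapply(m$curves$loss, rep(1:3, each = 5), mean)
  expect_true(all(diff(win) < 0))
})

test_that("training is reproducible for a fixed seed", {
  ds <- toy_image_dataset(n_per_class = 8, size = 44, seed = 3)
  arch <- cnn_architecture(16, input_size = 44, base_filters = 4)
  m1 <- train_cnn(arch, ds, train_config(epochs = 3, seed = 11))
  m2 <- train_cnn(arch, ds, train_config(epochs = 3, seed = 11))
  expect_equal(m1$curves$loss, m2$curves$loss, tolerance = 1e-6)
  expect_equal(m1$weights[[1]]$W, m2$weights[[1]]$W, tolerance = 1e-6)
  m3 <- train_cnn(arch, ds, train_config(epochs = 3, seed = 12))
  expect_false(isTRUE(all.equal(m1$curves$loss, m3$curves$loss)))
})

test_that("models round-trip through the checkpoint format", {
  ds <- toy_image_dataset(n_per_class = 4, size = 44, seed = 5)
  arch <- cnn_architecture(16, input_size = 44, base_filters = 4)
  m <- train_cnn(arch, ds, train_config(epochs = 1, seed = 1))
  f <- tempfile(fileext = ".rds")
  save_model(m, f)
  expect_true(file.exists(paste0(f, ".json")))
  m2 <- load_model(f)
  pr1 <- predict_cnn(m, ds); pr2 <- predict_cnn(m2, ds)
  expect_identical(pr1$scores, pr2$scores)
  unlink(c(f, paste0(f, ".json")))
})
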