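test_that("architecture audit: blocks, widths, pooling schedule, dropout", {
  spec <- cnn_spec()
  expect_equal(spec$conv_widths, c(8L, 16L, 32L, 64L))
  expect_equal(spec$pool_windows, c(2L, 3L, 2L, 3L))
  expect_equal(spec$fc_units, 128L)
  expect_equal(spec$n_classes, 2L)
  expect_equal(spec$dropout, 0.4)
  # ceil-mode pooling: 32 -> 16 -> 6 -> 3 -> 1 per axis
  expect_equal(sapply(spec$shapes, `[`, 1), c(32L, 16L, 6L, 3L, 1L))
  p <- build_cnn(small_spec(), seed = 1)
  expect_equal(dim(p$conv1_w)[5], 8)
  expect_equal(dim(p$conv4_w)[4:5], c(32, 64))
  expect_length(p$fc2_b, 2)
  # dropout is active before both fully connected layers during training
  x <- array(rnorm(12^3 * 2), c(12, 12, 12, 1, 2))
  l1 <- fedalz:::with_seed(5, fedalz:::cnn_forward(p, x, TRUE, 0.4)$logits)
  l2 <- fedalz:::with_seed(5, fedalz:::cnn_forward(p, x, TRUE, 0)$logits)
  expect_false(isTRUE(all.equal(l1, l2)))
})

test_that("compiled convolution matches a direct-summation oracle", {
  set.seed(2)
  D <- 4; Cin <- 2; Cout <- 3; K <- 3; pad <- 1; B <- 2
  x <- array(rnorm(D^3 * Cin * B), c(D, D, D, Cin, B))
  w <- array(rnorm(K^3 * Cin * Cout) * 0.3, c(K, K, K, Cin, Cout))
  b <- rnorm(Cout)
  out <- fedalz:::.conv3d_forward(x, w, b, pad)
  oracle <- array(0, dim(out))
  for (s in 1:B) for (co in 1:Cout) for (zo in 1:D) for (yo in 1:D) for (xo in 1:D) {
    acc <- b[co]
    for (ci in 1:Cin) for (kz in 1:K) for (ky in 1:K) for (kx in 1:K) {
      zi <- zo - pad + kz - 1; yi <- yo - pad + ky - 1; xi <- xo - pad + kx - 1
      if (zi >= 1 && zi <= D && yi >= 1 && yi <= D && xi >= 1 && xi <= D) {
        acc <- acc + x[zi, yi, xi, ci, s] * w[kz, ky, kx, ci, co]
      }
    }
    oracle[zo, yo, xo, co, s] <- acc
  }
  expect_lt(max(abs(out - oracle)), 1e-5)   # single-precision kernel
  g <- array(rnorm(length(out)), dim(out))
  bw <- fedalz:::.conv3d_backward(x, w, g, pad)
  dW_num <- array(0, dim(w))
  for (ci in 1:Cin) for (co in 1:Cout) for (kz in 1:K) for (ky in 1:K) for (kx in 1:K) {
    acc <- 0
    for (s in 1:B) for (zo in 1:D) for (yo in 1:D) for (xo in 1:D) {
      zi <- zo - pad + kz - 1; yi <- yo - pad + ky - 1; xi <- xo - pad + kx - 1
      if (zi >= 1 && zi <= D && yi >= 1 && yi <= D && xi >= 1 && xi <= D) {
        acc <- acc + x[zi, yi, xi, ci, s] * g[zo, yo, xo, co, s]
      }
    }
    dW_num[kz, ky, kx, ci, co] <- acc
  }
  expect_lt(max(abs(bw$dw - dW_num)), 1e-5)
  expect_lt(max(abs(bw$db - sapply(1:Cout, function(co) sum(g[, , , co, ])))), 1e-5)
})

test_that("parameter count matches a closed-form per-layer oracle", {
  spec <- cnn_spec(c(36, 36, 36))
  p <- build_cnn(spec, seed = 2)
  widths <- c(1, 8, 16, 32, 64)
  k <- 3
  n_conv <- sum(k^3 * widths[1:4] * widths[2:5] + widths[2:5])  # weights + biases
  n_bn <- sum(4 * widths[2:5])          # gamma, beta, running mean, running var
  # 36 -> 18 -> 6 -> 3 -> 1, so the flattened head sees 1*1*1*64 features
  n_fc <- 64 * 128 + 128 + 128 * 2 + 2
  expect_equal(length(flatten_params(p)), n_conv + n_bn + n_fc)
})

test_that("too-small inputs fail with a shape error; builds are deterministic", {
  expect_error(cnn_spec(c(2, 2, 2), kernel = 3, pad = 0), "stage shapes")
  p1 <- build_cnn(small_spec(), seed = 9)
  p2 <- build_cnn(small_spec(), seed = 9)
  expect_identical(flatten_params(p1), flatten_params(p2))
  expect_false(identical(flatten_params(build_cnn(small_spec(), seed = 10)),
                         flatten_params(p1)))
})

test_that("flatten/unflatten is an exact round trip for any parameter state", {
  p <- build_cnn(small_spec(), seed = 3)
  v <- flatten_params(p)
  perturbed <- unflatten_params(v * 1.7 - 0.3, p)
  expect_identical(flatten_params(unflatten_params(flatten_params(perturbed),
                                                   perturbed)),
                   flatten_params(perturbed))
  expect_equal(dim(perturbed$conv2_w), dim(p$conv2_w))
  expect_error(unflatten_params(v[-1], p))
})

test_that("training: zero-epoch identity, determinism, loss recording", {
  co <- small_cohort()
  d <- build_dataset(co, co$records$subject_id[1:16])
  p <- build_cnn(small_spec(), seed = 4)
  p0 <- local_train(p, d, train_config(epochs = 0, seed = 1))
  expect_identical(flatten_params(p0), flatten_params(p))
  pa <- local_train(p, d, train_config(epochs = 2, seed = 21))
  pb <- local_train(p, d, train_config(epochs = 2, seed = 21))
  expect_identical(flatten_params(pa), flatten_params(pb))
  expect_length(attr(pa, "loss"), 2)
  empty_data <- structure(
    list(x = d$x[, , , 0, drop = FALSE], y = d$y[0], subject_id = character(0)),
    class = "fedalz_dataset")
  expect_error(local_train(p, empty_data, train_config(epochs = 1)), "empty")
})

test_that("easily separable volumes are learned to perfect training accuracy", {
  co <- separable_cohort(n = 40)
  d <- build_dataset(co, co$records$subject_id)
  p <- local_train(build_cnn(small_spec(), seed = 5), d,
                   train_config(epochs = 20, seed = 9))
  m <- evaluate_model(p, d)
  expect_equal(m$balanced_accuracy, 1.0)
})

test_that("weight decay shrinks weights relative to an identical run without it", {
  co <- small_cohort()
  d <- build_dataset(co, co$records$subject_id[1:16])
  p <- build_cnn(small_spec(), seed = 6)
  wd <- local_train(p, d, train_config(epochs = 3, seed = 11, weight_decay = 1e-4))
  nowd <- local_train(p, d, train_config(epochs = 3, seed = 11, weight_decay = 0))
  expect_lt(sum(flatten_params(wd)^2), sum(flatten_params(nowd)^2))
})

test_that("balanced accuracy follows the confusion matrix", {
  # hand-counted: 8/10 AD correct, 6/10 CN correct -> (0.8 + 0.6) / 2 = 0.7
  truth <- factor(rep(c("AD", "CN"), each = 10), levels = c("AD", "CN"))
  pred <- truth
  pred[c(1, 2, 11, 12, 13, 14)] <- rev(levels(truth))[as.integer(truth[c(1, 2, 11, 12, 13, 14)])]
  m <- fedalz:::metrics_from_predictions(pred, truth)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.6)
  expect_equal(m$balanced_accuracy, 0.7)
  # perfect predictions
  expect_equal(fedalz:::metrics_from_predictions(truth, truth)$balanced_accuracy, 1)
})

test_that("a constant classifier scores balanced accuracy 0.5", {
  co <- small_cohort()
  d <- build_dataset(co, mixed_ids(co, 12))
  p <- build_cnn(small_spec(), seed = 7)
  p$fc2_w[] <- 0
  p$fc2_b <- c(10, -10)    # always predicts AD
  m <- evaluate_model(p, d)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 0)
  expect_equal(m$balanced_accuracy, 0.5)
})

test_that("evaluation is invariant to sample order and flags single-class data", {
  co <- small_cohort()
  ids <- mixed_ids(co, 10)
  d <- build_dataset(co, ids)
  p <- build_cnn(small_spec(), seed = 8)
  m1 <- evaluate_model(p, d)
  m2 <- evaluate_model(p, build_dataset(co, rev(ids)))
  expect_equal(m1$balanced_accuracy, m2$balanced_accuracy)
  ad_only <- build_dataset(co, co$records$subject_id[co$records$diagnosis == "AD"][1:4])
  ms <- evaluate_model(p, ad_only)
  expect_true(ms$single_class)
  expect_true(is.na(ms$balanced_accuracy))
  expect_false(is.na(ms$sensitivity))
})
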