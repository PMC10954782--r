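#' 3D CNN architecture specification
#'
#' Four convolutional blocks (convolution, batch normalization, ReLU,
#' ceil-mode max-pooling) with 8, 16, 32 and 64 feature maps and pooling
#' windows 2, 3, 2 and 3, followed by two fully connected layers of 128 and 2
#' units with dropout 0.4 applied before each. Pooling uses ceil mode (partial
#' trailing windows are kept), so the default 32-voxel axes survive the
#' (2, 3, 2, 3) schedule as 16, 6, 3, 1.
#'
#' @param input_shape Voxel grid of the input volumes (length 3).
#' @param conv_widths Feature maps per convolutional block.
#' @param pool_windows Max-pooling window (= stride) per block.
#' @param fc_units Width of the hidden fully connected layer.
#' @param n_classes Output units (AD, CN).
#' @param dropout Dropout probability before each fully connected layer.
#' @param kernel,pad Convolution kernel size and zero padding (kernel 3,
#'   padding 1 keeps spatial size).
#' @return A `fedalz_cnn_spec`, including the per-stage spatial `shapes`.
#' @export
cnn_spec <- function(input_shape = c(32, 32, 32), conv_widths = c(8, 16, 32, 64),
                     pool_windows = c(2, 3, 2, 3), fc_units = 128, n_classes = 2,
                     dropout = 0.4, kernel = 3, pad = 1) {
  stopifnot(length(conv_widths) == 4, length(pool_windows) == 4,
            dropout >= 0, dropout < 1, kernel >= 1, pad >= 0)
  shapes <- list(as.integer(input_shape))
  d <- as.integer(input_shape)
  for (b in 1:4) {
    conv_d <- d + 2L * pad - kernel + 1L
    if (any(conv_d < 1)) {
      stop("input too small for the convolution/pooling schedule; stage shapes: ",
           paste(vapply(shapes, paste, "", collapse = "x"), collapse = " -> "),
           " -> conv", b, " would be ", paste(conv_d, collapse = "x"))
    }
    d <- as.integer(ceiling(conv_d / pool_windows[b]))
    shapes[[b + 1]] <- d
  }
  structure(list(input_shape = as.integer(input_shape),
                 conv_widths = as.integer(conv_widths),
                 pool_windows = as.integer(pool_windows),
                 fc_units = as.integer(fc_units),
                 n_classes = as.integer(n_classes),
                 dropout = dropout, kernel = as.integer(kernel),
                 pad = as.integer(pad), shapes = shapes,
                 flat_features = prod(d) * conv_widths[4]),
            class = "fedalz_cnn_spec")
}

#' Initialize the model parameters
#'
#' Parameters are held as an ordered named list of arrays — convolution
#' weights/biases, batch-norm scale/shift and running mean/variance per block,
#' then the two dense layers — with a canonical flattening contract
#' ([flatten_params()] / [unflatten_params()]). Running batch-norm statistics
#' are part of the parameter state (they travel with the model during
#' federated aggregation) but are not touched by the optimizer. Weights use
#' He-normal initialization; the same seed reproduces the parameters exactly.
#'
#' @param spec A [cnn_spec()].
#' @param seed Integer seed.
#' @return A `fedalz_params` named list with attributes `spec` and `trainable`.
#' @export
build_cnn <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "fedalz_cnn_spec"))
  k <- spec$kernel
  widths <- c(1L, spec$conv_widths)
  params <- list()
  trainable <- logical(0)
  with_seed(seed, {
    for (b in 1:4) {
      cin <- widths[b]; cout <- widths[b + 1]
      fan_in <- k^3 * cin
      params[[paste0("conv", b, "_w")]] <-
        array(rnorm(k^3 * cin * cout, 0, sqrt(2 / fan_in)), c(k, k, k, cin, cout))
      params[[paste0("conv", b, "_b")]] <- numeric(cout)
      params[[paste0("bn", b, "_gamma")]] <- rep(1, cout)
      params[[paste0("bn", b, "_beta")]] <- numeric(cout)
      params[[paste0("bn", b, "_mean")]] <- numeric(cout)
      params[[paste0("bn", b, "_var")]] <- rep(1, cout)
      trainable <- c(trainable, setNames(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
        paste0(c("conv", "conv", "bn", "bn", "bn", "bn"), b, "_",
               c("w", "b", "gamma", "beta", "mean", "var"))))
    }
    fin <- spec$flat_features
    params$fc1_w <- matrix(rnorm(fin * spec$fc_units, 0, sqrt(2 / fin)),
                           fin, spec$fc_units)
    params$fc1_b <- numeric(spec$fc_units)
    params$fc2_w <- matrix(rnorm(spec$fc_units * spec$n_classes, 0,
                                 sqrt(2 / spec$fc_units)),
                           spec$fc_units, spec$n_classes)
    params$fc2_b <- numeric(spec$n_classes)
    trainable <- c(trainable, fc1_w = TRUE, fc1_b = TRUE,
                   fc2_w = TRUE, fc2_b = TRUE)
  })
  structure(params, spec = spec, trainable = trainable,
            class = "fedalz_params")
}

#' Flatten model parameters to a single vector and back
#'
#' The canonical order is the list order of [build_cnn()], each array in
#' column-major order. `unflatten_params(flatten_params(p), p)` restores `p`
#' exactly for any parameter state.
#'
#' @param params A `fedalz_params`.
#' @return `flatten_params`: a numeric vector; `unflatten_params`: a
#'   `fedalz_params` with the template's shapes and attributes.
#' @export
flatten_params <- function(params) {
  unlist(lapply(params, as.numeric), use.names = FALSE)
}

#' @rdname flatten_params
#' @param vec Numeric vector of length `length(flatten_params(template))`.
#' @param template A `fedalz_params` supplying shapes and attributes.
#' @export
unflatten_params <- function(vec, template) {
  lens <- vapply(template, length, 0L)
  stopifnot(length(vec) == sum(lens))
  out <- template
  at <- 0L
  for (i in seq_along(template)) {
    piece <- vec[(at + 1L):(at + lens[i])]
    dm <- dim(template[[i]])
    out[[i]] <- if (is.null(dm)) piece else array(piece, dm)
    at <- at + lens[i]
  }
  out
}

#' Training configuration
#'
#' @param learning_rate,weight_decay Adam learning rate and coupled L2
#'   weight-decay coefficient (both default 1e-4).
#' @param batch_size Mini-batch size (default 4: at desk scale, more optimizer
#'   steps per data pass converge faster on a single CPU at the fixed
#'   learning rate).
#' @param epochs Number of passes over the data.
#' @param seed Integer seed for shuffling, dropout and any initialization.
#' @param class_weights If `TRUE`, inverse-frequency class weights in the
#'   cross-entropy (the study cohort is 166 AD vs 452 CN).
#' @param dropout Optional override of the architecture's dropout (e.g. 0 for
#'   the deliberately overfit membership-inference targets).
#' @return A `fedalz_train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, weight_decay = 1e-4,
                         batch_size = 4, epochs = 1, seed = 1,
                         class_weights = TRUE, dropout = NULL) {
  stopifnot(learning_rate > 0, weight_decay >= 0, batch_size >= 1, epochs >= 0)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = batch_size, epochs = epochs, seed = seed,
                 class_weights = class_weights, dropout = dropout),
            class = "fedalz_train_config")
}

# inverse-frequency class weights over the present classes
class_weight_vec <- function(y, use_weights) {
  k <- nlevels(y)
  cnt <- tabulate(y, k)
  w <- rep(1, k)
  if (use_weights) {
    present <- cnt > 0
    w[present] <- sum(cnt) / (sum(present) * cnt[present])
    w[!present] <- 0
  }
  w
}

#' Train the CNN on labeled volumes
#'
#' Mini-batch Adam with weighted cross-entropy. Each epoch reshuffles under a
#' sub-seed derived from `cfg$seed` and the epoch index, so a training run is
#' bitwise reproducible and a run of `n` epochs equals `n` successive
#' one-epoch calls re-seeded by continuing epoch indices (via `epoch_offset`).
#' Optimizer state never travels with the exchanged model, but a client may
#' keep its own state between rounds: pass the previous call's `"opt_state"`
#' attribute as `opt_state` to continue the same Adam run.
#'
#' @param params A `fedalz_params` starting state.
#' @param data A `fedalz_dataset` (non-empty; a single-class dataset is
#'   allowed, as in the diagnosis non-IID scenarios).
#' @param cfg A [train_config()].
#' @param epoch_offset Added to the epoch index in the sub-seed derivation
#'   (used by the federated loop so round `r` continues the epoch numbering).
#' @param opt_state Optional Adam state from a previous call (moment vectors
#'   and step count); `NULL` starts fresh.
#' @return Updated `fedalz_params` with attributes `loss` (per-epoch mean
#'   weighted training loss) and `opt_state` (the Adam state after the call).
#' @export
local_train <- function(params, data, cfg, epoch_offset = 0, opt_state = NULL) {
  stopifnot(inherits(data, "fedalz_dataset"))
  n <- length(data$y)
  if (n == 0) stop("empty training data")
  if (cfg$epochs == 0) {
    attr(params, "loss") <- numeric(0)
    attr(params, "opt_state") <- opt_state
    return(params)
  }
  spec <- attr(params, "spec")
  drop_p <- if (is.null(cfg$dropout)) spec$dropout else cfg$dropout
  class_w <- class_weight_vec(data$y, cfg$class_weights)
  y_int <- as.integer(data$y)
  theta <- flatten_params(params)
  trainable_mask <- rep(attr(params, "trainable"),
                        vapply(params, length, 0L))
  st <- if (is.null(opt_state)) adam_init(length(theta)) else opt_state
  stopifnot(length(st$m) == length(theta))
  losses <- numeric(cfg$epochs)
  d <- dim(data$x)
  for (e in seq_len(cfg$epochs)) {
    with_seed(derive_seed(cfg$seed, "epoch", e + epoch_offset), {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      tot_loss <- 0
      for (bt in batches) {
        xb <- array(data$x[, , , bt, drop = FALSE], c(d[1:3], 1L, length(bt)))
        fwd <- cnn_forward(params, xb, training = TRUE, drop_p = drop_p)
        params <- fwd$params          # running BN statistics updated
        ls <- ce_loss(fwd$logits, y_int[bt], class_w)
        tot_loss <- tot_loss + ls$loss * length(bt)
        g <- cnn_backward(params, fwd, ls$dlogits)
        gflat <- unlist(lapply(names(params), function(nm) {
          if (is.null(g[[nm]])) numeric(length(params[[nm]])) else as.numeric(g[[nm]])
        }), use.names = FALSE)
        theta <- flatten_params(params)
        gflat <- gflat + cfg$weight_decay * theta * trainable_mask
        upd <- adam_step(st, theta, gflat, cfg$learning_rate)
        st <- upd$state
        theta <- ifelse(trainable_mask, upd$theta, theta)
        params <- unflatten_params(theta, params)
      }
      losses[e] <- tot_loss / n
    })
  }
  attr(params, "loss") <- losses
  attr(params, "opt_state") <- st
  params
}

#' Class posterior probabilities for a dataset
#'
#' Inference mode: dropout off, batch-norm running statistics. Rows whose
#' logits are not finite (which can happen when "parameters" are an
#' adversarially reconstructed random vector) fall back to the uninformative
#' posterior (0.5, 0.5).
#'
#' @param params A `fedalz_params`.
#' @param data A `fedalz_dataset`.
#' @param batch_size Inference batch size.
#' @return Matrix `n x n_classes` of posteriors (columns AD, CN).
#' @export
predict_posteriors <- function(params, data, batch_size = 16) {
  n <- length(data$y)
  stopifnot(n >= 1)
  d <- dim(data$x)
  spec <- attr(params, "spec")
  out <- matrix(NA_real_, n, spec$n_classes)
  for (start in seq(1, n, by = batch_size)) {
    bt <- start:min(start + batch_size - 1, n)
    xb <- array(data$x[, , , bt, drop = FALSE], c(d[1:3], 1L, length(bt)))
    fwd <- cnn_forward(params, xb, training = FALSE, drop_p = 0)
    lg <- fwd$logits
    bad <- !is.finite(rowSums(lg))
    lg[bad, ] <- 0
    out[bt, ] <- softmax_rows(lg)
  }
  colnames(out) <- levels(data$y)
  out
}

#' Balanced-accuracy evaluation
#'
#' Sensitivity is the AD recall, specificity the CN recall, and balanced
#' accuracy their mean. If the data contain a single class, the missing recall
#' and the balanced accuracy are `NA` and the record is flagged
#' (`single_class = TRUE`); the present class's recall is still returned.
#'
#' @param params A `fedalz_params`.
#' @param data A `fedalz_dataset` with at least one sample.
#' @return A `fedalz_metrics`: list with `sensitivity`, `specificity`,
#'   `balanced_accuracy`, `n` and `single_class`.
#' @export
evaluate_model <- function(params, data) {
  post <- predict_posteriors(params, data)
  pred <- factor(levels(data$y)[max.col(post, ties.method = "first")],
                 levels = levels(data$y))
  metrics_from_predictions(pred, data$y)
}

# confusion-matrix metrics shared with the attack evaluation
metrics_from_predictions <- function(pred, truth) {
  lv <- levels(truth)
  stopifnot(length(lv) == 2)
  rec <- vapply(lv, function(cl) {
    n_cl <- sum(truth == cl)
    if (n_cl == 0) NA_real_ else sum(pred == cl & truth == cl) / n_cl
  }, 0)
  single <- anyNA(rec)
  structure(list(sensitivity = rec[[1]], specificity = rec[[2]],
                 balanced_accuracy = if (single) NA_real_ else mean(rec),
                 n = length(truth), single_class = single),
            class = "fedalz_metrics")
}

#' @export
print.fedalz_metrics <- function(x, ...) {
  cat(sprintf("<fedalz_metrics> balanced accuracy %.3f (sens %.3f, spec %.3f, n=%d)\n",
              x$balanced_accuracy, x$sensitivity, x$specificity, x$n))
  invisible(x)
}
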