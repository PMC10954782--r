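#' Federated-learning session configuration
#'
#' @param rounds Number of federated rounds (each round: broadcast, local
#'   training, aggregation, validation).
#' @param local_epochs Local epochs per client per round.
#' @param train A [train_config()] for the local updates (its `epochs` field
#'   is overridden by `local_epochs`).
#' @param aggregator `"fedavg"` (plaintext weighted averaging) or `"secagg"`
#'   (secure aggregation of the weighted sum; requires at least three
#'   clients).
#' @param weighting `"by_size"` (weights proportional to client sample
#'   counts, the classic FedAvg rule) or `"uniform"`.
#' @param secagg A [secagg_config()] (used when `aggregator = "secagg"`).
#' @return A `fedalz_fl_config`.
#' @export
fl_config <- function(rounds = 10, local_epochs = 1, train = train_config(),
                      aggregator = c("fedavg", "secagg"),
                      weighting = c("by_size", "uniform"),
                      secagg = secagg_config()) {
  aggregator <- match.arg(aggregator)
  weighting <- match.arg(weighting)
  stopifnot(rounds >= 1, local_epochs >= 0)
  structure(list(rounds = as.integer(rounds),
                 local_epochs = as.integer(local_epochs), train = train,
                 aggregator = aggregator, weighting = weighting,
                 secagg = secagg),
            class = "fedalz_fl_config")
}

#' FedAvg parameter aggregation
#'
#' Coordinate-wise weighted mean of client models, with weights proportional
#' to the client sample counts (`by_size`, the classic rule) or uniform. All
#' parameter tensors — including the batch-norm running statistics — are
#' averaged alike, since the protocol exchanges the model state wholesale.
#'
#' @param updates List of `fedalz_params`, one per client.
#' @param n_samples Integer vector of client sample counts.
#' @param weighting `"by_size"` or `"uniform"`.
#' @return The aggregated `fedalz_params`.
#' @export
fedavg_aggregate <- function(updates, n_samples = rep(1L, length(updates)),
                             weighting = c("by_size", "uniform")) {
  weighting <- match.arg(weighting)
  stopifnot(length(updates) >= 1, length(n_samples) == length(updates))
  ref <- updates[[1]]
  for (u in updates[-1]) {
    if (!identical(names(u), names(ref))) {
      stop("parameter name mismatch between client updates")
    }
    for (nm in names(ref)) {
      if (!identical(dim(u[[nm]]), dim(ref[[nm]])) ||
          length(u[[nm]]) != length(ref[[nm]])) {
        stop("shape mismatch in tensor: ", nm)
      }
    }
  }
  w <- if (weighting == "by_size") n_samples / sum(n_samples) else
    rep(1 / length(updates), length(updates))
  out <- ref
  for (nm in names(ref)) {
    acc <- w[1] * ref[[nm]]
    if (length(updates) > 1) {
      for (i in 2:length(updates)) acc <- acc + w[i] * updates[[i]][[nm]]
    }
    out[[nm]] <- acc
  }
  attr(out, "loss") <- NULL
  attr(out, "opt_state") <- NULL   # optimizer state never leaves a client
  out
}

#' Run a federated training session
#'
#' One session executes `cfg$rounds` rounds of the five-phase protocol:
#' client initialization from the broadcast global model, local training for
#' `cfg$local_epochs` epochs, reporting of local models, (secure) weighted
#' averaging into the new global model, and redistribution. After each round
#' the global model is scored on the validation set; the round model with the
#' highest validation balanced accuracy (earliest round on ties) is returned.
#'
#' @param partitions Client partitions from [partition_cohort()].
#' @param cohort The `fedalz_cohort` the partitions refer to.
#' @param cfg A [fl_config()].
#' @param val_data Validation `fedalz_dataset` held by the server for model
#'   selection.
#' @param seed Session master seed; expands to per-round, per-client sub-seeds.
#' @return List with `best_params`, `best_round`, and `log` (data.frame with
#'   one row per round: validation metrics, mean client loss, and for secure
#'   aggregation the maximum coordinate-wise deviation from the plaintext
#'   average, a simulation-only diagnostic).
#' @export
run_session <- function(partitions, cohort, cfg, val_data, seed = 1) {
  stopifnot(inherits(cfg, "fedalz_fl_config"), length(partitions) >= 1,
            length(val_data$y) >= 1)
  if (cfg$aggregator == "secagg" && length(partitions) < cfg$secagg$min_clients) {
    stop("secure aggregation requires at least ", cfg$secagg$min_clients,
         " clients")
  }
  for (p in partitions) {
    if (length(p$subject_ids) == 0) {
      stop("client ", p$client_id, " has no data")
    }
  }
  client_data <- lapply(partitions, function(p) build_dataset(cohort, p$subject_ids))
  n_i <- vapply(client_data, function(d) length(d$y), 0L)
  spec <- cnn_spec(input_shape = cohort$grid$shape)
  global <- build_cnn(spec, derive_seed(seed, "init"))
  log <- data.frame()
  best <- NULL; best_ba <- -Inf; best_round <- NA_integer_
  # clients keep their local optimizer state across rounds (it never leaves
  # the client and is not part of the exchanged model)
  opt_states <- vector("list", length(client_data))
  for (r in seq_len(cfg$rounds)) {
    updates <- vector("list", length(client_data))
    losses <- numeric(length(client_data))
    for (i in seq_along(client_data)) {
      tc <- cfg$train
      tc$epochs <- cfg$local_epochs
      tc$seed <- derive_seed(seed, "train", r, i)
      updates[[i]] <- local_train(global, client_data[[i]], tc,
                                  opt_state = opt_states[[i]])
      opt_states[[i]] <- attr(updates[[i]], "opt_state")
      losses[i] <- mean(attr(updates[[i]], "loss"))
    }
    residual <- NA_real_
    if (cfg$aggregator == "secagg") {
      global <- secure_fedavg(updates, n_i, cfg$secagg,
                              seed = derive_seed(seed, "secagg", r),
                              weighting = cfg$weighting)
      plain <- fedavg_aggregate(updates, n_i, cfg$weighting)
      residual <- max(abs(flatten_params(global) - flatten_params(plain)))
    } else {
      global <- fedavg_aggregate(updates, n_i, cfg$weighting)
    }
    m <- evaluate_model(global, val_data)
    log <- rbind(log, data.frame(round = r, mean_client_loss = mean(losses),
                                 val_balanced_accuracy = m$balanced_accuracy,
                                 secagg_residual = residual))
    if (!is.na(m$balanced_accuracy) && m$balanced_accuracy > best_ba) {
      best_ba <- m$balanced_accuracy; best <- global; best_round <- r
    }
  }
  if (is.null(best)) { best <- global; best_round <- cfg$rounds }
  list(best_params = best, best_round = best_round, log = log,
       final_params = global, client_updates = updates, n_samples = n_i)
}

#' Centralized (pooled-data) training baseline
#'
#' Follows the same schedule as a federated session with a single client
#' holding all development data: `cfg$rounds` blocks of `cfg$local_epochs`
#' epochs, validation-based selection after each block. With matched seeds a
#' one-client FedAvg session produces bitwise identical parameters.
#'
#' @param dev_data Pooled development `fedalz_dataset`.
#' @param cfg A [fl_config()] (its aggregator is ignored).
#' @param val_data Validation `fedalz_dataset`.
#' @param seed Master seed (same derivation scheme as [run_session()]).
#' @param spec Optional [cnn_spec()]; defaults to the data's grid.
#' @return List with `best_params`, `best_round`, `log`, `final_params`.
#' @export
run_centralized <- function(dev_data, cfg, val_data, seed = 1, spec = NULL) {
  stopifnot(inherits(cfg, "fedalz_fl_config"), length(val_data$y) >= 1)
  if (is.null(spec)) spec <- cnn_spec(input_shape = dim(dev_data$x)[1:3])
  params <- build_cnn(spec, derive_seed(seed, "init"))
  log <- data.frame()
  best <- NULL; best_ba <- -Inf; best_round <- NA_integer_
  opt_state <- NULL
  for (r in seq_len(cfg$rounds)) {
    tc <- cfg$train
    tc$epochs <- cfg$local_epochs
    tc$seed <- derive_seed(seed, "train", r, 1)
    params <- local_train(params, dev_data, tc, opt_state = opt_state)
    opt_state <- attr(params, "opt_state")
    m <- evaluate_model(params, val_data)
    log <- rbind(log, data.frame(round = r,
                                 mean_client_loss = mean(attr(params, "loss")),
                                 val_balanced_accuracy = m$balanced_accuracy,
                                 secagg_residual = NA_real_))
    if (!is.na(m$balanced_accuracy) && m$balanced_accuracy > best_ba) {
      best_ba <- m$balanced_accuracy; best <- params; best_round <- r
    }
  }
  if (is.null(best)) { best <- params; best_round <- cfg$rounds }
  list(best_params = best, best_round = best_round, log = log,
       final_params = params)
}
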