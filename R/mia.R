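#' Shadow-model training for the membership-inference attack
#'
#' The shadow model is a replica of the target: same architecture and
#' training hyperparameters, trained on an auxiliary dataset that is disjoint
#' (by subject id) from the target's training data.
#'
#' @param spec A [cnn_spec()] (the target's architecture).
#' @param shadow_train A non-empty `fedalz_dataset` for the shadow model.
#' @param cfg A [train_config()] matching the target's training.
#' @param target_train_ids Subject ids of the target's training set; overlap
#'   with the shadow data is an error.
#' @param seed Initialization seed for the shadow model.
#' @return Trained `fedalz_params`.
#' @export
train_shadow <- function(spec, shadow_train, cfg, target_train_ids,
                         seed = 1) {
  if (length(shadow_train$y) == 0) stop("empty shadow training data")
  overlap <- intersect(shadow_train$subject_id, target_train_ids)
  if (length(overlap)) {
    stop("shadow training data overlaps the target's training set: ",
         paste(head(overlap, 3), collapse = ", "))
  }
  local_train(build_cnn(spec, derive_seed(seed, "shadow")), shadow_train, cfg)
}

# attack features from a model's outputs on a dataset:
# posteriors sorted descending, true-class one-hot, per-sample CE loss
attack_features <- function(params, data) {
  p <- predict_posteriors(params, data)
  ps <- t(apply(p, 1, sort, decreasing = TRUE))
  y <- as.integer(data$y)
  onehot <- matrix(0, nrow(p), ncol(p))
  onehot[cbind(seq_len(nrow(p)), y)] <- 1
  loss <- -log(pmax(p[cbind(seq_len(nrow(p)), y)], 1e-12))
  f <- cbind(ps, onehot, loss)
  colnames(f) <- c(paste0("post", seq_len(ncol(p))),
                   paste0("class", seq_len(ncol(p))), "loss")
  f
}

#' Build the attack training set from a shadow model
#'
#' Feeds the shadow model its own training samples (members) and disjoint
#' held-out samples (non-members); each output becomes one attack example.
#'
#' @param shadow Trained shadow `fedalz_params`.
#' @param members The shadow model's training `fedalz_dataset`.
#' @param nonmembers A held-out `fedalz_dataset` disjoint from it.
#' @return A list with feature matrix `x` and factor `y`
#'   (member/nonmember).
#' @export
build_attack_set <- function(shadow, members, nonmembers) {
  if (length(members$y) == 0 || length(nonmembers$y) == 0) {
    stop("need non-empty member and non-member sets")
  }
  x <- rbind(attack_features(shadow, members),
             attack_features(shadow, nonmembers))
  y <- factor(rep(c("member", "nonmember"),
                  c(length(members$y), length(nonmembers$y))),
              levels = c("member", "nonmember"))
  list(x = x, y = y)
}

#' Train the attack model
#'
#' A ridge-regularized logistic regression on the attack features (sorted
#' posteriors, true-class indicator, sample loss). With two diagnosis classes
#' the per-class attack models of the shadow-model framework collapse into a
#' single model with the class indicator as a feature.
#'
#' @param examples Output of [build_attack_set()].
#' @param lambda Ridge penalty.
#' @return A `fedalz_attack` classifier.
#' @export
train_attack <- function(examples, lambda = 1e-2) {
  if (nlevels(droplevels(examples$y)) < 2) {
    stop("attack training needs both member and non-member examples")
  }
  # drop constant columns (glmnet standardization would divide by zero)
  keep <- apply(examples$x, 2, function(col) stats::sd(col) > 0)
  if (!any(keep)) stop("all attack features are constant")
  fit <- glmnet::glmnet(examples$x[, keep, drop = FALSE],
                        examples$y == "member",
                        family = "binomial", alpha = 0, lambda = lambda,
                        standardize = TRUE)
  structure(list(fit = fit, keep = keep), class = "fedalz_attack")
}

# attack-model membership decision for a feature matrix
attack_predict <- function(attack, x) {
  p <- predict(attack$fit, x[, attack$keep, drop = FALSE], type = "response")
  factor(ifelse(p[, 1] > 0.5, "member", "nonmember"),
         levels = c("member", "nonmember"))
}

#' Evaluate the attack against a target model
#'
#' Member metric = sensitivity (recall on training samples), non-member
#' metric = specificity (recall on held-out samples); balanced accuracy is
#' their mean.
#'
#' @param attack A `fedalz_attack`.
#' @param target Target `fedalz_params` (the attacked checkpoint).
#' @param target_members `fedalz_dataset` of samples in the target's training
#'   data.
#' @param target_nonmembers `fedalz_dataset` of samples not in it.
#' @return A `fedalz_metrics` (sensitivity/specificity/balanced accuracy
#'   over membership).
#' @export
evaluate_attack <- function(attack, target, target_members, target_nonmembers) {
  if (length(target_members$y) == 0 || length(target_nonmembers$y) == 0) {
    stop("need non-empty member and non-member sets")
  }
  x <- rbind(attack_features(target, target_members),
             attack_features(target, target_nonmembers))
  truth <- factor(rep(c("member", "nonmember"),
                      c(length(target_members$y), length(target_nonmembers$y))),
                  levels = c("member", "nonmember"))
  metrics_from_predictions(attack_predict(attack, x), truth)
}

#' Attack the secure-aggregation view of one client
#'
#' The honest-but-curious server targeting client `i` observes only that
#' client's masked partial sum ([adversary_view()]). The adversary proceeds
#' as if the decoded vector were the client's model parameters; since the
#' view is uniform on the field and independent of the client's data, the
#' resulting membership decisions carry no signal and the attack's balanced
#' accuracy is statistically indistinguishable from chance.
#'
#' @param attack A `fedalz_attack`.
#' @param view A `fedalz_fpvec` from [adversary_view()].
#' @param template A `fedalz_params` supplying the parameter shapes (the
#'   model architecture is public).
#' @param target_members,target_nonmembers Datasets as in
#'   [evaluate_attack()].
#' @return A `fedalz_metrics`.
#' @export
attack_secagg_view <- function(attack, view, template, target_members,
                               target_nonmembers) {
  if (length(target_members$y) == 0 || length(target_nonmembers$y) == 0) {
    stop("need non-empty member and non-member sets")
  }
  stopifnot(inherits(view, "fedalz_fpvec"))
  pseudo <- unflatten_params(fp_decode(view), template)
  evaluate_attack(attack, pseudo, target_members, target_nonmembers)
}
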