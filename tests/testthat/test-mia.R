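# overfit-mode training configuration used to make membership visible
overfit_cfg <- function(epochs, seed) {
  train_config(epochs = epochs, seed = seed, weight_decay = 0,
               class_weights = FALSE, dropout = 0)
}

test_that("shadow training enforces disjointness from the target", {
  co <- small_cohort()
  ids <- co$records$subject_id
  shadow_data <- build_dataset(co, ids[1:8])
  expect_error(train_shadow(small_spec(), shadow_data, overfit_cfg(1, 1),
                            target_train_ids = ids[5:12]),
               "overlaps")
  empty <- structure(list(x = shadow_data$x[, , , 0, drop = FALSE],
                          y = shadow_data$y[0], subject_id = character(0)),
                     class = "fedalz_dataset")
  expect_error(train_shadow(small_spec(), empty, overfit_cfg(1, 1), ids[1]),
               "empty")
})

test_that("attack examples carry valid posterior features and labels", {
  co <- small_cohort()
  ids <- co$records$subject_id
  shadow <- build_cnn(small_spec(), seed = 3)   # untrained model suffices here
  members <- build_dataset(co, ids[1:6])
  nonmembers <- build_dataset(co, ids[7:10])
  ex <- build_attack_set(shadow, members, nonmembers)
  expect_equal(nrow(ex$x), 10)
  expect_equal(as.vector(table(ex$y)), c(6, 4))
  expect_equal(rowSums(ex$x[, c("post1", "post2")]), rep(1, 10), tolerance = 1e-6)
  expect_true(all(ex$x[, "post1"] >= ex$x[, "post2"]))
  expect_error(build_attack_set(shadow, members,
                                structure(list(x = members$x[, , , 0, drop = FALSE],
                                               y = members$y[0],
                                               subject_id = character(0)),
                                          class = "fedalz_dataset")),
               "non-empty")
})

test_that("an overfit shadow model separates members from non-members", {
  co <- small_cohort()
  cfg <- overfit_cfg(25, seed = 5)
  member_ids <- mixed_ids(co, 16)
  nonmember_ids <- mixed_ids(co, 16, offset = 8)
  shadow <- train_shadow(small_spec(), build_dataset(co, member_ids), cfg,
                         target_train_ids = mixed_ids(co, 16, offset = 16),
                         seed = 5)
  members <- build_dataset(co, member_ids)
  nonmembers <- build_dataset(co, nonmember_ids)
  ex <- build_attack_set(shadow, members, nonmembers)
  mean_conf <- tapply(ex$x[, "post1"], ex$y, mean)
  expect_gt(mean_conf[["member"]], mean_conf[["nonmember"]])
})

test_that("the attack classifier fits separable features and not noise", {
  set.seed(31)
  n <- 250
  # perfectly separated synthetic features
  x <- cbind(post1 = c(runif(n, 0.9, 1), runif(n, 0.5, 0.6)),
             post2 = c(runif(n, 0, 0.1), runif(n, 0.4, 0.5)),
             class1 = rbinom(2 * n, 1, 0.5), class2 = 0,
             loss = c(runif(n, 0, 0.1), runif(n, 1, 2)))
  y <- factor(rep(c("member", "nonmember"), each = n),
              levels = c("member", "nonmember"))
  at <- train_attack(list(x = x, y = y))
  pred <- fedalz:::attack_predict(at, x)
  expect_equal(mean(pred == y), 1.0)
  # label-shuffled features: held-out balanced accuracy near chance
  y_shuf <- sample(y)
  idx <- sample(2 * n, n)
  at0 <- train_attack(list(x = x[idx, ], y = y_shuf[idx]))
  pred0 <- fedalz:::attack_predict(at0, x[-idx, ])
  m0 <- fedalz:::metrics_from_predictions(pred0, y_shuf[-idx])
  expect_lt(abs(m0$balanced_accuracy - 0.5), 0.15)
  # determinism
  at2 <- train_attack(list(x = x, y = y))
  expect_identical(fedalz:::attack_predict(at2, x), pred)
  expect_error(train_attack(list(x = x, y = factor(rep("member", 2 * n),
                                                   levels = levels(y)))),
               "both")
})

test_that("attack evaluation reports membership sensitivity/specificity", {
  co <- small_cohort()
  cfg <- overfit_cfg(25, seed = 6)
  target_ids <- mixed_ids(co, 16)
  shadow_ids <- mixed_ids(co, 16, offset = 8)
  aux_ids <- mixed_ids(co, 12, offset = 16)
  eval_nonmember_ids <- mixed_ids(co, 4, offset = 22)
  target <- local_train(build_cnn(small_spec(), seed = 7),
                        build_dataset(co, target_ids), cfg)
  shadow <- train_shadow(small_spec(), build_dataset(co, shadow_ids), cfg,
                         target_train_ids = target_ids, seed = 8)
  ex <- build_attack_set(shadow, build_dataset(co, shadow_ids),
                         build_dataset(co, aux_ids))
  at <- train_attack(ex)
  m <- evaluate_attack(at, target, build_dataset(co, target_ids),
                       build_dataset(co, eval_nonmember_ids))
  expect_s3_class(m, "fedalz_metrics")
  expect_true(m$balanced_accuracy >= 0 && m$balanced_accuracy <= 1)
  expect_error(evaluate_attack(at, target, build_dataset(co, target_ids),
                               structure(list(x = ex$x[0, ], y = factor(NULL),
                                              subject_id = character(0)),
                                         class = "fedalz_dataset")),
               "non-empty")
})

test_that("the secure-aggregation view feeds the attack nothing usable", {
  co <- small_cohort()
  ids <- co$records$subject_id
  spec <- small_spec()
  updates <- lapply(1:3, function(i) build_cnn(spec, seed = 20 + i))
  cfg <- secagg_config()
  w <- rep(1 / 3, 3)
  enc <- lapply(1:3, function(i) fp_encode(w[i] * flatten_params(updates[[i]]), cfg))
  tr <- secure_exchange(enc, cfg, seed = 4)
  shadow <- build_cnn(spec, seed = 9)
  ex <- build_attack_set(shadow, build_dataset(co, mixed_ids(co, 8)),
                         build_dataset(co, mixed_ids(co, 8, offset = 4)))
  at <- train_attack(ex)
  m <- attack_secagg_view(at, adversary_view(tr, 2), updates[[1]],
                          build_dataset(co, mixed_ids(co, 8)),
                          build_dataset(co, mixed_ids(co, 8, offset = 4)))
  expect_s3_class(m, "fedalz_metrics")
  expect_error(attack_secagg_view(at, adversary_view(tr, 2), updates[[1]],
                                  build_dataset(co, mixed_ids(co, 8)),
                                  structure(list(x = NULL, y = factor(NULL),
                                                 subject_id = character(0)),
                                            class = "fedalz_dataset")),
               "non-empty")
})
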