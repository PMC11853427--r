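test_that("the asymmetric loss reduces to cross-entropy without focusing", {
  cfg <- asl_config(gamma_pos = 0, gamma_neg = 0, margin = 0)
  grid <- expand.grid(p = seq(0.02, 0.98, by = 0.04), y = c(0, 1))
  ours <- asl_loss(grid$p, grid$y, cfg, reduce = FALSE)
  bce <- ifelse(grid$y == 1, -log(grid$p), -log(1 - grid$p))
  expect_equal(ours, bce, tolerance = 1e-9)
})

test_that("asymmetric loss worked examples hold", {
  expect_equal(asl_loss(0.5, 1, asl_config(gamma_pos = 0)), -log(0.5),
               tolerance = 1e-12)
  # the probability margin zeroes easy negatives
  expect_equal(asl_loss(0.03, 0, asl_config(margin = 0.05)), 0)
  # a perfect positive costs nothing in the limit
  expect_lt(asl_loss(1 - 1e-7, 1, asl_config()), 1e-6)
  expect_gte(asl_loss(0.9, 0, asl_config()), 0)
})

test_that("asymmetric loss is monotone in the predicted probability", {
  cfg <- asl_config(gamma_pos = 2, gamma_neg = 4, margin = 0.05)
  p <- seq(0.01, 0.99, by = 0.01)
  lpos <- asl_loss(p, rep(1, length(p)), cfg, reduce = FALSE)
  expect_true(all(diff(lpos) <= 1e-12))
  lneg <- asl_loss(p, rep(0, length(p)), cfg, reduce = FALSE)
  expect_true(all(diff(lneg) >= -1e-12))
})

test_that("the loss gradient matches finite differences on a grid", {
  cfg <- asl_config(gamma_pos = 1, gamma_neg = 4, margin = 0.05)
  for (y in c(0, 1)) for (p in c(0.04, 0.3, 0.7, 0.96)) {
    num <- (asl_loss(p + 1e-6, y, cfg) - asl_loss(p - 1e-6, y, cfg)) / 2e-6
    expect_equal(rgtsite:::asl_grad(p, y, cfg), num, tolerance = 1e-4)
  }
})

test_that("train/validation splits partition chains reproducibly", {
  ids <- sprintf("C%02d", 1:20)
  sp <- split_train_val(ids, fraction = 0.10, seed = 7)
  expect_length(sp$val, 2L)
  expect_length(sp$train, 18L)
  expect_setequal(c(sp$train, sp$val), ids)
  expect_length(intersect(sp$train, sp$val), 0L)
  expect_identical(sp, split_train_val(ids, fraction = 0.10, seed = 7))
  expect_false(identical(sp, split_train_val(ids, fraction = 0.10, seed = 8)))
  expect_error(split_train_val("one", 0.1, 1), "at least 2")
  # tiny sets still hold out at least one chain
  expect_length(split_train_val(c("a", "b", "c"), 0.1, 1)$val, 1L)
})

make_tiny_training_set <- function(n_chains = 4, n = 16) {
  prov <- stub_embedding_provider(seed = 5, dim = 12)
  bundles <- lapply(seq_len(n_chains), function(c) {
    chain <- generate_chain(n, seed = 100 + c)
    pk <- suppressWarnings(plant_pocket(chain, seed = 200 + c, radius = 5))
    featurize_chain(chain, pk$labels, prov)
  })
  names(bundles) <- sprintf("T%d", seq_len(n_chains))
  bundles
}

test_that("early stopping fires after exactly patience non-improving epochs", {
  bundles <- make_tiny_training_set()
  cfg <- train_config(max_epochs = 50L, patience = 10L, seed = 1L)
  ck <- train(bundles, cfg, tiny_config(),
              .val_loss_override = function(epoch, loss) epoch)
  expect_equal(nrow(ck$log), 11L)   # epoch 1 improves; 10 more, then stop
  expect_equal(ck$best_epoch, 1L)
})

test_that("training on all-negative labels drives probabilities down", {
  bundles <- make_tiny_training_set()
  for (i in seq_along(bundles)) bundles[[i]]$labels[] <- 0L
  cfg <- train_config(learning_rate = 1e-3, max_epochs = 6L, patience = 20L,
                      seed = 2L)
  ck <- train(bundles, cfg, tiny_config())
  # the prior-initialized head starts at the loss optimum for this
  # degenerate signal, so the loss can only stay put or improve
  expect_lte(tail(ck$log$train_loss, 1), ck$log$train_loss[1] + 1e-12)
  pr <- predict_chain(bundles[[1]], ck)
  expect_true(all(pr$probabilities < 0.5))
  expect_true(all(pr$labels == 0L))
})

test_that("a tiny model overfits a single chain to perfect training F1", {
  # three copies of one chain: train, step, and validate on the same
  # structure, so the best-validation checkpoint is the converged model
  one <- make_tiny_training_set(n_chains = 1, n = 20)[[1]]
  bundles <- list(T1 = one, T2 = one, T3 = one)
  cfg <- train_config(learning_rate = 3e-3, weight_decay = 0,
                      max_epochs = 300L, patience = 300L, seed = 3L)
  mcfg <- rgt_config(d = 32, heads = 4, k_pe = 4, n_blocks = 1,
                     use_local = FALSE, global_dim = 12, dropout = 0.1,
                     d_ff = 32, classifier_dims = c(16L, 8L, 1L))
  ck <- train(bundles, cfg, mcfg)
  pr <- predict_chain(one, ck)
  m <- metrics(confusion(one$labels, pr$labels))
  expect_equal(m$F1, 100)
})

test_that("training runs are reproducible for a fixed seed", {
  bundles <- make_tiny_training_set()
  cfg <- train_config(max_epochs = 2L, seed = 11L)
  ck1 <- train(bundles, cfg, tiny_config())
  ck2 <- train(bundles, cfg, tiny_config())
  expect_identical(ck1$log$train_loss, ck2$log$train_loss)
  expect_identical(ck1$log$val_loss, ck2$log$val_loss)
})

test_that("prediction applies the stored scaling and thresholds inclusively", {
  bundles <- make_tiny_training_set()
  cfg <- train_config(max_epochs = 2L, seed = 12L)
  ck <- train(bundles, cfg, tiny_config())
  pr <- predict_chain(bundles[[1]], ck)
  expect_length(pr$probabilities, chain_length <- 16L)
  # probability exactly at the threshold is called positive
  thr <- pr$probabilities[3]
  pr2 <- predict_chain(bundles[[1]], ck, threshold = thr)
  expect_equal(pr2$labels[3], 1L)
  # an unreachable threshold yields all negatives
  expect_true(all(predict_chain(bundles[[1]], ck, threshold = 1.1)$labels == 0L))
  # repeated calls are identical
  expect_identical(pr, predict_chain(bundles[[1]], ck))
})

test_that("checkpoints round-trip through disk", {
  bundles <- make_tiny_training_set()
  ck <- train(bundles, train_config(max_epochs = 1L, seed = 13L), tiny_config())
  path <- tempfile(fileext = ".rds")
  save_checkpoint(ck, path)
  ck2 <- load_checkpoint(path)
  expect_identical(ck2$model$params$A0, ck$model$params$A0)
  log_path <- tempfile(fileext = ".tsv")
  write_training_log(ck, log_path)
  logged <- read.delim(log_path)
  expect_equal(names(logged), c("epoch", "train_loss", "val_loss",
                                "val_F1", "val_MCC"))
})
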