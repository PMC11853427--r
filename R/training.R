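#' Asymmetric loss configuration
#'
#' Separate focusing exponents for the positive and negative terms and a
#' probability margin that zeroes the loss on easy negatives — suited to the
#' ~1:20 positive:negative imbalance of binding-site data. Defaults follow
#' the recommended asymmetric setting (`gamma_pos = 0`, `gamma_neg = 4`,
#' `margin = 0.05`).
#'
#' @param gamma_pos,gamma_neg Focusing exponents (>= 0).
#' @param margin Probability margin in `[0, 1)`.
#' @export
asl_config <- function(gamma_pos = 0, gamma_neg = 4, margin = 0.05) {
  stopifnot(gamma_pos >= 0, gamma_neg >= 0, margin >= 0, margin < 1)
  list(gamma_pos = gamma_pos, gamma_neg = gamma_neg, margin = margin)
}

#' Asymmetric loss for binary per-residue classification
#'
#' For a positive residue: `(1 - p)^gamma_pos * (-log p)`. For a negative
#' residue, with the shifted probability `p_m = max(p - margin, 0)`:
#' `p_m^gamma_neg * (-log(1 - p_m))`. With both exponents 0 and margin 0 this
#' is binary cross-entropy. Probabilities are clamped to
#' `[1e-7, 1 - 1e-7]`.
#'
#' @param p Predicted probabilities.
#' @param y 0/1 labels.
#' @param cfg An [asl_config()].
#' @param reduce Return the mean over residues (default) or the per-residue
#'   vector.
#' @return Non-negative scalar (or vector).
#' @export
asl_loss <- function(p, y, cfg = asl_config(), reduce = TRUE) {
  stopifnot(length(p) == length(y), all(y %in% c(0, 1)))
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  pm <- pmax(p - cfg$margin, 0)
  lpos <- (1 - p)^cfg$gamma_pos * (-log(p))
  lneg <- ifelse(pm > 0, pm^cfg$gamma_neg * (-log(1 - pm)), 0)
  l <- ifelse(y == 1, lpos, lneg)
  if (reduce) mean(l) else l
}

# gradient of the mean asymmetric loss w.r.t. p
asl_grad <- function(p, y, cfg = asl_config()) {
  n <- length(p)
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  pm <- pmax(p - cfg$margin, 0)
  gp <- cfg$gamma_pos; gn <- cfg$gamma_neg
  dpos <- if (gp == 0) -1 / p else
    gp * (1 - p)^(gp - 1) * log(p) - (1 - p)^gp / p
  dneg <- ifelse(pm > 0,
                 (if (gn == 0) 1 / (1 - pm) else
                    gn * pm^(gn - 1) * (-log(1 - pm)) + pm^gn / (1 - pm)),
                 0)
  ifelse(y == 1, dpos, dneg) / n
}

#' Training configuration
#'
#' Defaults follow the published training protocol: Adam with learning rate
#' 1e-4, weight decay 5e-5, epsilon 1e-7, betas (0.9, 0.999); one chain per
#' optimization step; dropout 0.3; 10% of training chains held out for
#' validation; early stop after 10 epochs without validation-loss
#' improvement.
#'
#' @param learning_rate,weight_decay,eps,betas Adam hyperparameters.
#' @param dropout Dropout rate.
#' @param patience Early-stopping patience in epochs.
#' @param val_fraction Fraction of chains used for validation.
#' @param max_epochs Epoch cap.
#' @param seed Integer seed fixing the split, init, and all training noise.
#' @param asl An [asl_config()].
#' @param lr_decay Multiplier applied to the learning rate when the
#'   validation loss has not improved for `lr_patience` epochs
#'   (reduce-on-plateau); 1 disables the schedule.
#' @param lr_patience Plateau length, in epochs, before a decay step.
#' @param min_lr Learning-rate floor for the schedule.
#' @export
train_config <- function(learning_rate = 1e-4, weight_decay = 5e-5,
                         eps = 1e-7, betas = c(0.9, 0.999), dropout = 0.3,
                         patience = 10L, val_fraction = 0.10,
                         max_epochs = 200L, seed = 1L, asl = asl_config(),
                         lr_decay = 1, lr_patience = 15L, min_lr = 1e-4) {
  stopifnot(learning_rate > 0, val_fraction > 0, val_fraction < 1,
            patience >= 1, lr_decay > 0, lr_decay <= 1)
  list(learning_rate = learning_rate, weight_decay = weight_decay, eps = eps,
       betas = betas, dropout = dropout, patience = as.integer(patience),
       val_fraction = val_fraction, max_epochs = as.integer(max_epochs),
       seed = as.integer(seed), asl = asl, lr_decay = lr_decay,
       lr_patience = as.integer(lr_patience), min_lr = min_lr)
}

#' Split chain ids into training and validation sets
#'
#' @param chain_ids Vector of ids (length >= 2).
#' @param fraction Validation fraction; the validation set has
#'   `max(1, round(fraction * n))` chains.
#' @param seed Integer seed.
#' @return List with `train` and `val` id vectors (disjoint, exhaustive).
#' @export
split_train_val <- function(chain_ids, fraction = 0.10, seed = 1L) {
  n <- length(chain_ids)
  if (n < 2L) stop("need at least 2 chains to split")
  set.seed(seed)
  n_val <- max(1L, round(fraction * n))
  val <- sort(sample(n, n_val))
  list(train = chain_ids[-val], val = chain_ids[val])
}

# --- Adam optimizer over nested parameter/gradient lists --------------------

adam_state_new <- function() new.env(parent = emptyenv())

adam_step <- function(params, grads, state, cfg, path = "") {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    key <- paste0(path, "/", nm)
    if (is.list(g)) {
      params[[nm]] <- adam_step(params[[nm]], g, state, cfg, key)
    } else {
      p <- params[[nm]]
      mkey <- paste0(key, ".m"); vkey <- paste0(key, ".v"); tkey <- paste0(key, ".t")
      if (is.null(state[[mkey]])) {
        state[[mkey]] <- p * 0; state[[vkey]] <- p * 0; state[[tkey]] <- 0L
      }
      t <- state[[tkey]] + 1L
      state[[tkey]] <- t
      # decay weight matrices only; biases and normalization parameters are
      # exempt (standard decoupled-decay practice)
      wd <- if (is.matrix(p)) cfg$weight_decay else 0
      params[[nm]] <- adam_update_cpp(p, g, state[[mkey]], state[[vkey]], t,
                                      cfg$learning_rate, cfg$betas[1],
                                      cfg$betas[2], cfg$eps, wd)
    }
  }
  params
}

# deep copy is implicit for R lists; snapshot is just assignment
# one evaluation pass: mean loss plus pooled metrics over the chains
eval_val_set <- function(bundles, model, asl, threshold = 0.5) {
  losses <- numeric(length(bundles))
  counts <- vector("list", length(bundles))
  for (i in seq_along(bundles)) {
    b <- bundles[[i]]
    out <- rgt_forward(b, model, training = FALSE)
    losses[i] <- asl_loss(out$p, b$labels, asl)
    counts[[i]] <- confusion(b$labels, as.integer(out$p >= threshold))
  }
  list(loss = mean(losses), metrics = metrics(pool_counts(counts)))
}

#' Train the residual graph transformer
#'
#' One chain per optimization step, Adam with the configured
#' hyperparameters, validation split by chain, early stopping on validation
#' loss, and best-validation checkpointing. Feature scaling statistics are
#' computed on the training split and stored in the checkpoint.
#'
#' @param bundles Named list of `feature_bundle`s (all with labels).
#' @param cfg A [train_config()].
#' @param model_config An [rgt_config()].
#' @param verbose Print per-epoch progress.
#' @param .val_loss_override Internal testing hook: function(epoch, loss)
#'   replacing the measured validation loss (used to exercise the stopping
#'   rule deterministically).
#' @return Checkpoint list: best `model`, `scaling`, per-epoch `log`
#'   data frame, `best_epoch`, `config` echo.
#' @export
train <- function(bundles, cfg = train_config(), model_config = rgt_config(),
                  verbose = FALSE, .val_loss_override = NULL) {
  if (length(bundles) < 2L) stop("need at least 2 chains to train")
  ids <- names(bundles)
  if (is.null(ids)) ids <- as.character(seq_along(bundles))
  sp <- split_train_val(ids, cfg$val_fraction, cfg$seed)
  scaling <- compute_feature_scaling(bundles[sp$train])
  scaled <- lapply(bundles, function(b) {
    b <- apply_feature_scaling(b, scaling)
    # positional encodings depend only on the graph: compute once per chain
    b$pe <- laplacian_pe(b$graph, model_config$k_pe)$vectors
    b
  })
  model <- rgt_init(model_config, seed = cfg$seed)
  state <- adam_state_new()
  set.seed(cfg$seed + 1L)
  best <- Inf; best_params <- model$params; best_epoch <- 0L; wait <- 0L
  opt_cfg <- cfg; lr_wait <- 0L
  log_rows <- vector("list", cfg$max_epochs)
  for (epoch in seq_len(cfg$max_epochs)) {
    order_ <- sample(sp$train)
    tr_losses <- numeric(length(order_))
    for (i in seq_along(order_)) {
      b <- scaled[[order_[i]]]
      out <- rgt_forward(b, model, training = TRUE, keep_cache = TRUE)
      loss <- asl_loss(out$p, b$labels, cfg$asl)
      if (!is.finite(loss))
        stop(sprintf("training diverged: non-finite loss at epoch %d chain %s",
                     epoch, order_[i]))
      tr_losses[i] <- loss
      dp <- asl_grad(out$p, b$labels, cfg$asl)
      grads <- rgt_backward(dp, out$cache, model)
      model$params <- adam_step(model$params, grads, state, opt_cfg)
    }
    ev <- eval_val_set(scaled[sp$val], model, cfg$asl)
    val_loss <- ev$loss
    if (!is.null(.val_loss_override)) val_loss <- .val_loss_override(epoch, val_loss)
    vm <- ev$metrics
    log_rows[[epoch]] <- data.frame(
      epoch = epoch, train_loss = mean(tr_losses), val_loss = val_loss,
      val_F1 = vm$F1, val_MCC = ifelse(is.na(vm$MCC), NA_real_, vm$MCC))
    if (verbose)
      message(sprintf("epoch %3d train %.5f val %.5f F1 %.2f", epoch,
                      mean(tr_losses), val_loss, vm$F1))
    if (val_loss < best - 1e-12) {
      best <- val_loss; best_params <- model$params
      best_epoch <- epoch; wait <- 0L; lr_wait <- 0L
    } else {
      wait <- wait + 1L
      lr_wait <- lr_wait + 1L
      if (wait >= cfg$patience) break
      if (cfg$lr_decay < 1 && lr_wait >= cfg$lr_patience &&
          opt_cfg$learning_rate > cfg$min_lr) {
        opt_cfg$learning_rate <- max(opt_cfg$learning_rate * cfg$lr_decay,
                                     cfg$min_lr)
        lr_wait <- 0L
        if (verbose)
          message(sprintf("epoch %3d: learning rate -> %g", epoch,
                          opt_cfg$learning_rate))
      }
    }
  }
  model$params <- best_params
  list(format_version = "rgtsite-checkpoint-1",
       model = model, scaling = scaling,
       log = do.call(rbind, Filter(Negate(is.null), log_rows)),
       best_epoch = best_epoch,
       config = list(train = cfg, model = model$config,
                     split = sp))
}

#' Save / load a model checkpoint
#' @param checkpoint Output of [train()].
#' @param path File path.
#' @export
save_checkpoint <- function(checkpoint, path) {
  saveRDS(checkpoint, path, version = 2)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format_version, "rgtsite-checkpoint-1"))
    stop("unrecognized checkpoint format")
  ck
}

#' Write the per-epoch training log as TSV
#' @param checkpoint Output of [train()].
#' @param path Output path.
#' @export
write_training_log <- function(checkpoint, path) {
  write.table(checkpoint$log, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Predict binding probabilities and labels for one chain
#'
#' Applies the checkpoint's stored feature scaling, runs a deterministic
#' evaluation-mode forward pass, and thresholds (probability >= threshold
#' is positive).
#'
#' @param bundle An unscaled `feature_bundle`.
#' @param checkpoint Output of [train()].
#' @param threshold Classification threshold (default 0.5).
#' @return List with `probabilities` and 0/1 `labels`.
#' @export
predict_chain <- function(bundle, checkpoint, threshold = 0.5) {
  b <- apply_feature_scaling(bundle, checkpoint$scaling)
  cfg <- checkpoint$model$config
  if (cfg$use_global && (is.null(b$global) || ncol(b$global) != cfg$global_dim))
    stop("global block: bundle embeddings do not match model config")
  out <- rgt_forward(b, checkpoint$model, training = FALSE)
  list(probabilities = out$p, labels = as.integer(out$p >= threshold))
}
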