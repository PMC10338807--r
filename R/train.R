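## Two-stage optimisation: stage 1 (default epochs 1-40, lr 0.01) trains
## the FDID module only — the DR branches receive neither forward passes
## nor gradients; stage 2 (epochs 41-80, lr 0.0001) trains FDID and DR
## jointly, the DR loss gradient flowing through the fused probabilities
## back into the heads and backbone. SGD with momentum, batch size 8,
## Xavier initialisation.

#' Xavier-initialise all learnable parameters of a model (or sub-tree)
#'
#' Convolution and FC weights are Glorot-uniform, biases zero, batch-norm
#' scales 1 / shifts 0, running statistics reset. Reproducible per seed.
#'
#' @param model an `msnet_model`, backbone, or any layer tree.
#' @param seed integer RNG seed.
#' @return The initialised object.
#' @export
init_weights <- function(model, seed = 1L) {
  force(model)  # the constructor may touch the RNG; force before seeding
  set.seed(seed)
  if (inherits(model, "msnet_model")) {
    model$backbone <- tree_map_layers(model$backbone, xavier_fill)
    model$heads <- tree_map_layers(model$heads, xavier_fill)
    model$dr <- tree_map_layers(model$dr, xavier_fill)
    model
  } else {
    tree_map_layers(model, xavier_fill)
  }
}

#' Training configuration
#'
#' Defaults are the published full-run schedule: 80 epochs, FDID-only for
#' the first 40 at lr 0.01, then joint training at lr 0.0001, SGD
#' momentum 0.9, batch size 8.
#'
#' @param stage1_epochs last epoch of the FDID-only stage.
#' @param total_epochs total epochs (> `stage1_epochs`).
#' @param lr_stage1,lr_stage2 learning rates of the two stages.
#' @param batch_size minibatch size.
#' @param momentum SGD momentum.
#' @param epsilon,epsilon_panel collaborative-loss weights
#'   (see [msnet_loss_config()]).
#' @param semantic_weight weight of the semantic loss term.
#' @param augment an [msnet_augment_config()], or `NULL` to disable.
#' @param lr_decay per-epoch multiplicative decay of the learning rate
#'   within each stage (1 = the published constant-rate schedule).
#' @param rebalance_key class-balancing label (`"individual"`,
#'   `"panel"`), or `NULL` to disable rebalancing.
#' @param select_head head used for best-checkpoint selection
#'   (`"panel"` or `"individual"`; the refined head once stage 2 starts).
#' @param seed RNG seed covering shuffling, augmentation and dropout.
#' @return Configuration list.
#' @export
msnet_train_config <- function(stage1_epochs = 40L, total_epochs = 80L,
                               lr_stage1 = 0.01, lr_stage2 = 0.0001,
                               lr_decay = 1, batch_size = 8L,
                               momentum = 0.9,
                               epsilon = 0.6, epsilon_panel = 0.6,
                               semantic_weight = 1,
                               augment = msnet_augment_config(),
                               rebalance_key = "individual",
                               select_head = "panel", seed = 1L) {
  if (stage1_epochs >= total_epochs)
    stopf("stage1_epochs must be smaller than total_epochs")
  if (lr_stage1 <= 0 || lr_stage2 <= 0)
    stopf("learning rates must be positive")
  list(stage1_epochs = as.integer(stage1_epochs),
       total_epochs = as.integer(total_epochs),
       lr_stage1 = lr_stage1, lr_stage2 = lr_stage2, lr_decay = lr_decay,
       batch_size = as.integer(batch_size), momentum = momentum,
       epsilon = epsilon, epsilon_panel = epsilon_panel,
       semantic_weight = semantic_weight, augment = augment,
       rebalance_key = rebalance_key, select_head = select_head,
       seed = as.integer(seed))
}

#' Stage and learning rate for an epoch
#'
#' Epochs up to `stage1_epochs` are `fdid_only` at `lr_stage1` (DR frozen
#' and its loss excluded); later epochs are `joint` at `lr_stage2`.
#'
#' @param epoch epoch number in `1..total_epochs`.
#' @param cfg an [msnet_train_config()].
#' @return List with `stage` and `lr`.
#' @export
stage_of <- function(epoch, cfg = msnet_train_config()) {
  if (epoch < 1L || epoch > cfg$total_epochs)
    stopf("epoch %s outside 1..%d", epoch, cfg$total_epochs)
  decay <- cfg$lr_decay %||% 1
  if (epoch <= cfg$stage1_epochs)
    list(stage = "fdid_only",
         lr = cfg$lr_stage1 * decay^(epoch - 1L))
  else
    list(stage = "joint",
         lr = cfg$lr_stage2 * decay^(epoch - cfg$stage1_epochs - 1L))
}

## Assemble a batch of samples into the (s,s,s,2,B) input plus label
## matrices/vectors. Augmentation is drawn here (training only).
assemble_batch <- function(samples, cfg = NULL, augment = FALSE) {
  B <- length(samples)
  s <- dim(samples[[1]]$cube)[1]
  x <- array(0, c(s, s, s, 2L, B))
  y0 <- y1 <- integer(B)
  sem <- matrix(0L, 8L, B)
  for (i in seq_len(B)) {
    sm <- samples[[i]]
    pair <- roi_pair(sm$cube, sm$mask)
    if (augment && !is.null(cfg$augment))
      pair <- augment_pair(pair, cfg$augment)
    x[, , , 1L, i] <- pair$nodule
    x[, , , 2L, i] <- pair$mask
    y0[i] <- sm$individual
    y1[i] <- sm$panel
    sem[, i] <- as.integer(sm$semantic[SEMANTIC_FEATURES])
  }
  list(x = x, individual = y0, panel = y1, semantic = sem)
}

## Soft-target matrix (2 x B) for a batch of label pairs.
soft_targets <- function(ya, yb, epsilon) {
  vapply(seq_along(ya), function(i) soften(ya[i], yb[i], epsilon),
         numeric(2))
}

## Per-batch loss terms and logit gradients (mean reduction over batch).
batch_losses <- function(fw, batch, cfg, joint) {
  B <- length(batch$individual)
  q_ind <- soft_targets(batch$individual, batch$panel, cfg$epsilon)
  q_pan <- soft_targets(batch$panel, batch$individual, cfg$epsilon_panel)
  ce <- function(p, q) -mean(colSums(q * log(pmax(p, PROB_FLOOR))))
  g_heads <- list()
  terms <- c(individual = ce(fw$head_probs$individual, q_ind),
             panel = ce(fw$head_probs$panel, q_pan))
  g_heads$individual <- (fw$head_probs$individual - q_ind) / B
  g_heads$panel <- (fw$head_probs$panel - q_pan) / B
  sem_total <- 0
  for (j in seq_along(SEMANTIC_FEATURES)) {
    nm <- SEMANTIC_FEATURES[j]
    q <- rbind(1 - batch$semantic[j, ], batch$semantic[j, ])
    sem_total <- sem_total + ce(fw$head_probs[[nm]], q)
    g_heads[[nm]] <- cfg$semantic_weight *
      (fw$head_probs[[nm]] - q) / (8 * B)
  }
  terms["semantic"] <- cfg$semantic_weight * sem_total / 8
  g_dr <- NULL
  if (joint) {
    terms["dr_individual"] <- ce(fw$dr_probs$individual, q_ind)
    terms["dr_panel"] <- ce(fw$dr_probs$panel, q_pan)
    g_dr <- list(individual = (fw$dr_probs$individual - q_ind) / B,
                 panel = (fw$dr_probs$panel - q_pan) / B)
  }
  list(terms = terms, total = sum(terms), g_heads = g_heads, g_dr = g_dr)
}

#' Batched prediction on a list of samples
#'
#' @param model trained `msnet_model`.
#' @param samples list of samples (elements `cube`, `mask`).
#' @param batch_size forward-pass batch size.
#' @param run_dr also evaluate the DR branches.
#' @param flip_average average the predictions over the eight axis-flip
#'   variants of each case (deterministic test-time augmentation; flips
#'   are exact symmetries of the training distribution).
#' @return List of N x 2 probability matrices, one per head
#'   (`individual`, `panel`, the eight semantic features, and with DR
#'   `dr_individual`, `dr_panel`).
#' @export
msnet_predict_batch <- function(model, samples, batch_size = 8L,
                                run_dr = TRUE, flip_average = FALSE) {
  flips <- if (flip_average) expand.grid(f1 = c(FALSE, TRUE),
                                         f2 = c(FALSE, TRUE),
                                         f3 = c(FALSE, TRUE))
  else data.frame(f1 = FALSE, f2 = FALSE, f3 = FALSE)
  acc <- NULL
  for (v in seq_len(nrow(flips))) {
    sv <- if (all(!unlist(flips[v, ]))) samples else lapply(samples,
      function(s) {
        d <- dim(s$cube)
        ix <- lapply(1:3, function(a)
          if (flips[v, a]) rev(seq_len(d[a])) else seq_len(d[a]))
        s$cube <- s$cube[ix[[1]], ix[[2]], ix[[3]]]
        s$mask <- s$mask[ix[[1]], ix[[2]], ix[[3]]]
        s
      })
    out <- list()
    add <- function(nm, m) out[[nm]] <<- rbind(out[[nm]], t(m))
    for (at in seq(1L, length(sv), by = batch_size)) {
      ix <- at:min(at + batch_size - 1L, length(sv))
      b <- assemble_batch(sv[ix])
      fw <- net_fw(model, b$x, training = FALSE, keep = FALSE,
                   run_dr = run_dr)
      for (nm in HEAD_NAMES) add(nm, fw$head_probs[[nm]])
      if (run_dr) {
        add("dr_individual", fw$dr_probs$individual)
        add("dr_panel", fw$dr_probs$panel)
      }
    }
    acc <- if (is.null(acc)) out else
      setNames(lapply(names(out), function(nm) acc[[nm]] + out[[nm]]),
               names(out))
  }
  lapply(acc, function(m) m / nrow(flips))
}

## Accuracy of a head's argmax predictions against integer labels.
head_accuracy <- function(probs, labels) {
  keep <- !is.na(labels)
  if (!any(keep)) return(NA_real_)
  mean((probs[keep, 2] > probs[keep, 1]) == (labels[keep] == 1L))
}

#' Train MS-Net with the two-stage schedule
#'
#' Runs the configured schedule over the training samples, logging every
#' loss term and validation accuracy per epoch and checkpointing the model
#' with the best validation accuracy on the selection head (refined head
#' once the joint stage has begun). Samples whose panel label is the
#' excluded sentinel must be filtered out beforehand.
#'
#' @param model an initialised `msnet_model`.
#' @param train_samples,val_samples sample lists (see
#'   [build_phantom_set()] for the sample fields).
#' @param cfg an [msnet_train_config()].
#' @param verbose print one line per epoch.
#' @return List with `model` (final), `best_model`, `best_accuracy`, and
#'   `log` (one row per epoch).
#' @export
train_run <- function(model, train_samples, val_samples = list(),
                      cfg = msnet_train_config(), verbose = FALSE) {
  if (!length(train_samples)) stopf("train_run: empty training set")
  if (any(vapply(train_samples, function(s) is.na(s$panel), logical(1))))
    stopf("train_run: excluded panel labels present; filter upstream")
  set.seed(cfg$seed)
  vel <- NULL
  log_rows <- list()
  best <- list(model = model, acc = -Inf)
  for (epoch in seq_len(cfg$total_epochs)) {
    st <- stage_of(epoch, cfg)
    joint <- st$stage == "joint"
    data_e <- if (!is.null(cfg$rebalance_key))
      rebalance(train_samples, cfg$rebalance_key) else train_samples
    data_e <- data_e[sample.int(length(data_e))]
    epoch_terms <- NULL
    n_batches <- 0L
    for (at in seq(1L, length(data_e), by = cfg$batch_size)) {
      ix <- at:min(at + cfg$batch_size - 1L, length(data_e))
      batch <- assemble_batch(data_e[ix], cfg,
                              augment = !is.null(cfg$augment))
      fw <- net_fw(model, batch$x, training = TRUE, keep = TRUE,
                   run_dr = joint)
      model <- fw$model
      bl <- batch_losses(fw, batch, cfg, joint)
      bw <- net_bw(model, fw, bl$g_heads, bl$g_dr)
      upd <- sgd_step(model, bw$grads, vel, st$lr, cfg$momentum)
      model <- upd$node
      vel <- upd$vel
      epoch_terms <- if (is.null(epoch_terms)) bl$terms else {
        common <- union(names(epoch_terms), names(bl$terms))
        e <- setNames(numeric(length(common)), common)
        e[names(epoch_terms)] <- epoch_terms
        e[names(bl$terms)] <- e[names(bl$terms)] + bl$terms
        e
      }
      n_batches <- n_batches + 1L
    }
    epoch_terms <- epoch_terms / n_batches
    val_acc <- c(individual = NA_real_, panel = NA_real_)
    if (length(val_samples)) {
      pr <- msnet_predict_batch(model, val_samples, cfg$batch_size,
                                run_dr = joint)
      y0 <- vapply(val_samples, function(s) as.integer(s$individual),
                   integer(1))
      y1 <- vapply(val_samples, function(s) as.integer(s$panel),
                   integer(1))
      use <- if (joint) c("dr_individual", "dr_panel") else
        c("individual", "panel")
      val_acc <- c(individual = head_accuracy(pr[[use[1]]], y0),
                   panel = head_accuracy(pr[[use[2]]], y1))
      sel <- val_acc[[cfg$select_head]]
      if (!is.na(sel) && sel >= best$acc && joint) {
        best <- list(model = model, acc = sel)
      }
    }
    log_rows[[epoch]] <- data.frame(
      epoch = epoch, stage = st$stage, lr = st$lr,
      loss_total = sum(epoch_terms), t(epoch_terms),
      val_acc_individual = val_acc[["individual"]],
      val_acc_panel = val_acc[["panel"]])
    if (verbose)
      message(sprintf(
        "epoch %3d [%s] loss %.4f val acc ind %.3f panel %.3f",
        epoch, st$stage, sum(epoch_terms),
        val_acc[["individual"]], val_acc[["panel"]]))
  }
  log <- do.call(rbind, lapply(log_rows, function(r) {
    miss <- setdiff(names(log_rows[[length(log_rows)]]), names(r))
    for (m in miss) r[[m]] <- NA_real_
    r[names(log_rows[[length(log_rows)]])]
  }))
  if (!is.finite(best$acc)) best <- list(model = model, acc = NA_real_)
  list(model = model, best_model = best$model, best_accuracy = best$acc,
       log = log)
}

#' Desk-scale training profile
#'
#' The configuration used by the package's CPU-scale learning checks: a
#' one-block-per-stage quarter-width backbone on 32^3 cubes, 32-wide
#' heads and DR branches, and a 10-epoch two-stage schedule (5 FDID-only
#' epochs at lr 0.01, then joint at 0.003, decay 0.85/epoch, momentum
#' 0.5, batch 8, malignant rebalancing, no augmentation). The published
#' full-run settings remain the defaults of [msnet_train_config()]; this
#' profile exists because ~100 gradient steps need a shallower network
#' and a gentler, decaying schedule to converge.
#'
#' @param seed RNG seed used for initialisation and training.
#' @return List with `config` (backbone), `head_hidden`, `dr_hidden`,
#'   `train` (an [msnet_train_config()]).
#' @export
msnet_micro_profile <- function(seed = 1L) {
  list(config = msnet_reduced_config(blocks = c(1L, 1L, 1L, 1L)),
       head_hidden = 32L, dr_hidden = 32L,
       train = msnet_train_config(stage1_epochs = 5L, total_epochs = 10L,
                                  lr_stage1 = 0.01, lr_stage2 = 0.003,
                                  lr_decay = 0.85, momentum = 0.5,
                                  batch_size = 8L, augment = NULL,
                                  rebalance_key = "individual",
                                  seed = seed))
}

#' Build an MS-Net model from the micro profile
#'
#' @param profile output of [msnet_micro_profile()].
#' @param seed initialisation seed.
#' @return An initialised `msnet_model`.
#' @export
msnet_micro_model <- function(profile = msnet_micro_profile(), seed = 1L) {
  msnet_model(profile$config, head_hidden = profile$head_hidden,
              dr_hidden = profile$dr_hidden, seed = seed)
}
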