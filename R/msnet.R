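## MS-Net assembly. FDID = shared backbone + 10 parallel prediction heads
## (8 semantic features, individual diagnosis, panel diagnosis), each head
## FC(F->H) -> BN -> ReLU -> Dropout(0.5) -> FC(H->2) -> Softmax. DR fuses
## the ten 2-d predictions (20 values, canonical order) and refines the two
## diagnoses through two parallel FC -> BN -> ReLU -> FC -> Softmax
## branches. Probability index 1 = benign, 2 = malignant throughout.

HEAD_NAMES <- c(SEMANTIC_FEATURES, "individual", "panel")
FUSION_DIM <- 20L

build_head <- function(in_dim, hidden) {
  list(layer_fc(in_dim, hidden), layer_bn(hidden), layer_relu(),
       layer_dropout(0.5), layer_fc(hidden, 2L))
}

build_dr_branch <- function(hidden) {
  list(layer_fc(FUSION_DIM, hidden), layer_bn(hidden), layer_relu(),
       layer_fc(hidden, 2L))
}

#' Construct an MS-Net model
#'
#' Builds backbone, the ten FDID heads and the two DR branches; weights are
#' Xavier-initialised when `seed` is given, otherwise zero until
#' [init_weights()].
#'
#' @param config backbone configuration ([msnet_default_config()] or
#'   [msnet_reduced_config()]).
#' @param head_hidden hidden width of each prediction head (published
#'   value 256; the reduced profile uses less).
#' @param dr_hidden hidden width of each DR branch (default 32).
#' @param seed optional integer; when given the model is initialised
#'   reproducibly.
#' @return An `msnet_model` object.
#' @export
msnet_model <- function(config = msnet_default_config(), head_hidden = 256L,
                        dr_hidden = 32L, seed = NULL) {
  heads <- setNames(lapply(HEAD_NAMES, function(nm)
    build_head(config$feature_dim, head_hidden)), HEAD_NAMES)
  model <- structure(
    list(backbone = build_backbone(config),
         heads = heads,
         dr = list(individual = build_dr_branch(dr_hidden),
                   panel = build_dr_branch(dr_hidden)),
         config = config,
         head_hidden = as.integer(head_hidden),
         dr_hidden = as.integer(dr_hidden)),
    class = "msnet_model")
  if (!is.null(seed)) model <- init_weights(model, seed)
  model
}

#' @export
print.msnet_model <- function(x, ...) {
  cat("MS-Net model\n")
  cat("  backbone input:", x$config$input_side, "^3 x",
      x$config$input_channels, "channels; shared feature:",
      x$config$feature_dim, "d\n")
  cat("  heads: 10 (8 semantic + individual + panel), hidden",
      x$head_hidden, "\n")
  cat("  DR branches: 2, hidden", x$dr_hidden, "\n")
  cat("  learnable parameters:", count_params(x[c("backbone", "heads",
                                                  "dr")]), "\n")
  invisible(x)
}

check_cube_pair <- function(nodule_cube, mask_cube, side) {
  if (!identical(dim(nodule_cube), dim(mask_cube)))
    stopf("nodule and mask cubes must have identical dims")
  d <- dim(nodule_cube)
  if (length(d) != 3L || !all(d == side))
    stopf("expected %d^3 cubes, got %s", side, paste(d, collapse = "x"))
  if (!is_binary_array(mask_cube)) stopf("mask cube must be binary")
}

stack_input <- function(nodule_cube, mask_cube) {
  s <- dim(nodule_cube)[1]
  array(c(as.numeric(nodule_cube), as.numeric(mask_cube)), c(s, s, s, 2L, 1L))
}

## ---- full internal forward / backward (batched) --------------------------

net_fw <- function(model, x, training = FALSE, keep = training,
                   run_dr = TRUE) {
  bbr <- backbone_fw(model$backbone, x, training, keep)
  model$backbone <- bbr$bb
  shared <- bbr$feat
  head_logits <- head_probs <- head_caches <- setNames(
    vector("list", length(HEAD_NAMES)), HEAD_NAMES)
  for (nm in HEAD_NAMES) {
    r <- seq_forward(model$heads[[nm]], shared, training, keep)
    model$heads[[nm]] <- r$layers
    head_logits[[nm]] <- r$y
    head_probs[[nm]] <- softmax_cols(r$y)
    head_caches[[nm]] <- r$caches
  }
  fusion <- do.call(rbind, head_probs[HEAD_NAMES])  # 20 x N
  dr_logits <- dr_probs <- dr_caches <- NULL
  if (run_dr) {
    dr_logits <- dr_probs <- dr_caches <- setNames(vector("list", 2L),
                                                   names(model$dr))
    for (nm in names(model$dr)) {
      r <- seq_forward(model$dr[[nm]], fusion, training, keep)
      model$dr[[nm]] <- r$layers
      dr_logits[[nm]] <- r$y
      dr_probs[[nm]] <- softmax_cols(r$y)
      dr_caches[[nm]] <- r$caches
    }
  }
  list(shared = shared, head_logits = head_logits, head_probs = head_probs,
       fusion = fusion, dr_logits = dr_logits, dr_probs = dr_probs,
       caches = if (keep) list(backbone = bbr$caches, heads = head_caches,
                               dr = dr_caches),
       model = model)
}

## Backprop. g_head_logits: named list of (2 x N) gradients at head logits
## (from the head losses). g_dr_logits: named list of gradients at DR
## logits, or NULL in stage 1 (DR then receives no gradient and the DR
## gradient route into the heads is absent).
net_bw <- function(model, fw, g_head_logits, g_dr_logits = NULL) {
  n_heads <- length(HEAD_NAMES)
  dr_grads <- NULL
  if (!is.null(g_dr_logits)) {
    gfusion <- matrix(0, FUSION_DIM, ncol(fw$fusion))
    dr_grads <- setNames(vector("list", 2L), names(model$dr))
    for (nm in names(model$dr)) {
      r <- seq_backward(model$dr[[nm]], fw$caches$dr[[nm]],
                        g_dr_logits[[nm]])
      dr_grads[[nm]] <- r$grads
      gfusion <- gfusion + r$gx
    }
    ## route the fusion gradient through each head's softmax
    for (i in seq_len(n_heads)) {
      nm <- HEAD_NAMES[i]
      gp <- gfusion[(2L * i - 1L):(2L * i), , drop = FALSE]
      p <- fw$head_probs[[nm]]
      gz <- p * (gp - matrix(colSums(gp * p), 2L, ncol(p), byrow = TRUE))
      g_head_logits[[nm]] <- g_head_logits[[nm]] + gz
    }
  }
  gshared <- matrix(0, nrow(fw$shared), ncol(fw$shared))
  head_grads <- setNames(vector("list", n_heads), HEAD_NAMES)
  for (nm in HEAD_NAMES) {
    r <- seq_backward(model$heads[[nm]], fw$caches$heads[[nm]],
                      g_head_logits[[nm]])
    head_grads[[nm]] <- r$grads
    gshared <- gshared + r$gx
  }
  bb <- backbone_bw(model$backbone, fw$caches$backbone, gshared)
  list(grads = list(backbone = bb$grads, heads = head_grads, dr = dr_grads))
}

## ---- public single-case operations ---------------------------------------

#' Run one prediction head
#'
#' @param head one element of `model$heads` (an FC-BN-ReLU-Dropout-FC
#'   stack).
#' @param shared shared feature vector (length = the head's input width).
#' @param training apply dropout (`TRUE`) or run deterministically.
#' @return Length-2 probability vector summing to 1.
#' @export
head_forward <- function(head, shared, training = FALSE) {
  if (length(shared) != head[[1]]$cfg$in_dim)
    stopf("head_forward: expected input of length %d", head[[1]]$cfg$in_dim)
  r <- seq_forward(head, matrix(shared, ncol = 1L), training, keep = FALSE)
  drop(softmax_cols(r$y))
}

#' FDID forward pass for one case
#'
#' Concatenates the nodule and (reader-specific) mask cubes into a
#' 2-channel input, runs the shared backbone once, and evaluates the ten
#' parallel heads. No head sees another head's output.
#'
#' @param model an [msnet_model()].
#' @param nodule_cube,mask_cube cubic arrays of the configured side; mask
#'   strictly binary.
#' @return `msnet_fdid_output`: list with `semantic` (named list of eight
#'   2-d probability vectors), `individual`, `panel`.
#' @export
fdid_forward <- function(model, nodule_cube, mask_cube) {
  check_cube_pair(nodule_cube, mask_cube, model$config$input_side)
  fw <- net_fw(model, stack_input(nodule_cube, mask_cube),
               training = FALSE, keep = FALSE, run_dr = FALSE)
  structure(list(
    semantic = setNames(lapply(SEMANTIC_FEATURES,
                               function(nm) drop(fw$head_probs[[nm]])),
                        SEMANTIC_FEATURES),
    individual = drop(fw$head_probs$individual),
    panel = drop(fw$head_probs$panel)), class = "msnet_fdid_output")
}

#' Fuse the ten FDID predictions into the DR input
#'
#' Concatenation order is part of the contract: the eight semantic
#' probability pairs in canonical feature order ([semantic_features()]),
#' then the individual, then the panel diagnosis.
#'
#' @param out an `msnet_fdid_output`.
#' @return Numeric vector of length 20.
#' @export
fuse_predictions <- function(out) {
  unlist(c(out$semantic[SEMANTIC_FEATURES],
           list(out$individual, out$panel)), use.names = FALSE)
}

#' Diagnosis-refinement forward pass
#'
#' @param model an [msnet_model()].
#' @param fusion length-20 fusion vector from [fuse_predictions()].
#' @return `msnet_dr_output`: list with `individual_refined` and
#'   `panel_refined` 2-d probability vectors (index 1 = benign).
#' @export
dr_forward <- function(model, fusion) {
  if (length(fusion) != FUSION_DIM)
    stopf("dr_forward: expected a length-%d fusion vector", FUSION_DIM)
  x <- matrix(fusion, ncol = 1L)
  out <- lapply(model$dr, function(branch)
    drop(softmax_cols(seq_forward(branch, x, FALSE, FALSE)$y)))
  structure(list(individual_refined = out$individual,
                 panel_refined = out$panel), class = "msnet_dr_output")
}

#' Full MS-Net forward pass for one case
#'
#' @inheritParams fdid_forward
#' @return List with elements `fdid` and `dr`.
#' @export
msnet_forward <- function(model, nodule_cube, mask_cube) {
  fdid <- fdid_forward(model, nodule_cube, mask_cube)
  dr <- dr_forward(model, fuse_predictions(fdid))
  list(fdid = fdid, dr = dr)
}

#' Serialise predictions for one case as JSON-ready list
#'
#' @param fdid,dr outputs of [fdid_forward()] / [dr_forward()].
#' @return Nested list matching the documented per-case JSON schema.
#' @export
prediction_record <- function(fdid, dr) {
  list(semantic = fdid$semantic, individual = fdid$individual,
       panel = fdid$panel, refined_individual = dr$individual_refined,
       refined_panel = dr$panel_refined)
}

## ---- checkpointing -------------------------------------------------------

#' Save / load a model checkpoint
#'
#' The checkpoint is an RDS of the full model plus a JSON architecture
#' descriptor alongside it (same path with extension `.json`).
#'
#' @param model an `msnet_model`.
#' @param path checkpoint file path.
#' @return `msnet_load` returns the model; `msnet_save` the path,
#'   invisibly.
#' @export
msnet_save <- function(model, path) {
  saveRDS(model, path)
  desc <- list(package = "msnet3d",
               feature_dim = model$config$feature_dim,
               input_side = model$config$input_side,
               head_hidden = model$head_hidden, dr_hidden = model$dr_hidden,
               n_parameters = count_params(model[c("backbone", "heads",
                                                   "dr")]),
               stages = lapply(model$config$stages, function(s)
                 list(reduce = s$reduce, expand = s$expand,
                      blocks = s$blocks,
                      branches = lapply(s$branches, unlist))))
  jsonlite::write_json(desc, paste0(sub("\\.rds$", "", path), ".json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname msnet_save
#' @export
msnet_load <- function(path) readRDS(path)

#' Construct a standalone prediction head
#'
#' One FDID prediction branch (FC in->hidden, BN, ReLU, Dropout 0.5,
#' FC hidden->2) outside a full model, Xavier-initialised when `seed` is
#' given. Useful for head-level experiments; run it with
#' [head_forward()].
#'
#' @param in_dim input (shared feature) width; published value 1024.
#' @param hidden hidden width; published value 256.
#' @param seed optional initialisation seed.
#' @return A list of layers accepted by [head_forward()].
#' @export
prediction_head <- function(in_dim = 1024L, hidden = 256L, seed = NULL) {
  h <- build_head(in_dim, hidden)
  if (!is.null(seed)) {
    set.seed(seed)
    h <- tree_map_layers(h, xavier_fill)
  }
  h
}
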