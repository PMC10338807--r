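## Collaborative loss: cross-entropy against a softened target that mixes
## the current reader's (individual) label with the panel label,
## q' = (1 - eps) * onehot(y0) + eps * onehot(y1), eps in [0,1] (default
## 0.6). With agreeing labels q' stays one-hot ([1,0]); with y0 benign and
## y1 malignant at the default it becomes [0.4, 0.6]. Classes are coded
## 0 = benign, 1 = malignant; vector index 1 is the benign probability.

PROB_FLOOR <- 1e-12

onehot2 <- function(y) {
  if (!y %in% c(0L, 1L)) stopf("class label must be 0 (benign) or 1")
  if (y == 0L) c(1, 0) else c(0, 1)
}

check_epsilon <- function(epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || is.na(epsilon) ||
      epsilon < 0 || epsilon > 1)
    stopf("epsilon must be a single number in [0, 1]")
}

#' Soften a diagnosis label pair
#'
#' Mixes the one-hot encodings of the individual label `y0` and the panel
#' label `y1` into the soft target `(1 - epsilon) * onehot(y0) +
#' epsilon * onehot(y1)`.
#'
#' @param y0 individual label, 0 (benign) or 1 (malignant).
#' @param y1 panel label, 0 or 1.
#' @param epsilon mixing weight of the panel label, in \[0, 1\]; default 0.6.
#' @return Numeric length-2 probability vector (benign, malignant).
#' @examples
#' soften(0, 0, 0.6)  # agreement: c(1, 0)
#' soften(0, 1, 0.6)  # disagreement: c(0.4, 0.6)
#' @export
soften <- function(y0, y1, epsilon = 0.6) {
  check_epsilon(epsilon)
  (1 - epsilon) * onehot2(as.integer(y0)) + epsilon * onehot2(as.integer(y1))
}

check_simplex <- function(p, tol = 1e-6) {
  if (length(p) != 2L || any(!is.finite(p)) || any(p < -tol) ||
      abs(sum(p) - 1) > tol)
    stopf("prediction must be a 2-d probability vector (sum 1 within %g)",
          tol)
}

cross_entropy2 <- function(q, p) -sum(q * log(pmax(p, PROB_FLOOR)))

#' Collaborative loss for one prediction
#'
#' Cross-entropy of the prediction `p` against the softened target built
#' from the individual and panel labels; equal to
#' `(1 - epsilon) * H(onehot(y0), p) + epsilon * H(onehot(y1), p)`.
#' Natural logarithm; probabilities are floored at 1e-12 before the log.
#'
#' @inheritParams soften
#' @param p length-2 predicted probability vector.
#' @return Non-negative scalar loss.
#' @export
collaborative_loss <- function(p, y0, y1, epsilon = 0.6) {
  check_simplex(p)
  cross_entropy2(soften(y0, y1, epsilon), p)
}

#' Mean cross-entropy over the eight semantic heads
#'
#' Plain (unsoftened) cross-entropy against one-hot binary targets,
#' averaged over heads. Softening applies only to the two diagnosis heads.
#'
#' @param predictions list of eight length-2 probability vectors, or a
#'   2 x 8 matrix of column probabilities.
#' @param labels integer vector of eight binary labels (0/1).
#' @return Scalar loss (0 for perfectly confident correct predictions).
#' @export
semantic_loss <- function(predictions, labels) {
  if (is.matrix(predictions))
    predictions <- lapply(seq_len(ncol(predictions)),
                          function(j) predictions[, j])
  if (length(predictions) != 8L || length(labels) != 8L)
    stopf("semantic_loss: expected 8 predictions and 8 labels")
  mean(vapply(seq_len(8L), function(i) {
    check_simplex(predictions[[i]])
    cross_entropy2(onehot2(as.integer(labels[i])), predictions[[i]])
  }, numeric(1)))
}

#' Loss configuration
#'
#' @param epsilon panel-label weight in the individual head's soft target.
#' @param epsilon_panel individual-label weight in the panel head's soft
#'   target (the symmetric counterpart; same default).
#' @param semantic_weight multiplier on the semantic-head loss term.
#' @param stage `"fdid_only"` (stage 1: no refinement-head terms) or
#'   `"joint"`.
#' @return Loss configuration list.
#' @export
msnet_loss_config <- function(epsilon = 0.6, epsilon_panel = 0.6,
                              semantic_weight = 1,
                              stage = c("fdid_only", "joint")) {
  check_epsilon(epsilon)
  check_epsilon(epsilon_panel)
  list(epsilon = epsilon, epsilon_panel = epsilon_panel,
       semantic_weight = semantic_weight, stage = match.arg(stage))
}

#' Total training objective for one case
#'
#' Stage `fdid_only`: collaborative loss on the two initial diagnosis heads
#' (the panel head uses the symmetric soft target, individual opinion as
#' reference) plus the semantic-head loss. Stage `joint` adds the same two
#' collaborative terms on the refined heads. All terms equally weighted by
#' default.
#'
#' @param fdid an FDID output (see [fdid_forward()]).
#' @param dr a DR output ([dr_forward()]) or `NULL` in stage 1.
#' @param labels list with elements `individual` (0/1), `panel` (0/1; the
#'   excluded sentinel `NA` is a contract violation here — excluded cases
#'   are filtered upstream), and `semantic` (8 binary values in canonical
#'   feature order).
#' @param cfg a [msnet_loss_config()].
#' @return Scalar loss.
#' @export
total_loss <- function(fdid, dr = NULL, labels, cfg = msnet_loss_config()) {
  y0 <- labels$individual
  y1 <- labels$panel
  if (is.null(y1) || is.na(y1))
    stopf("total_loss: excluded panel label reached the loss; filter upstream")
  sem <- labels$semantic[SEMANTIC_FEATURES]
  total <- collaborative_loss(fdid$individual, y0, y1, cfg$epsilon) +
    collaborative_loss(fdid$panel, y1, y0, cfg$epsilon_panel) +
    cfg$semantic_weight *
      semantic_loss(fdid$semantic[SEMANTIC_FEATURES], sem)
  if (cfg$stage == "joint") {
    if (is.null(dr)) stopf("total_loss: joint stage requires a DR output")
    total <- total +
      collaborative_loss(dr$individual_refined, y0, y1, cfg$epsilon) +
      collaborative_loss(dr$panel_refined, y1, y0, cfg$epsilon_panel)
  }
  total
}
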