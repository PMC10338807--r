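## Evaluation: confusion counts (malignant = positive), the five headline
## metrics, nodule-level cross-validation designs, and per-nodule
## aggregation of panel-head predictions across readers.

#' Confusion counts for binary benign/malignant predictions
#'
#' @param predicted,truth equal-length vectors of classes (0 = benign,
#'   1 = malignant).
#' @return List with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stopf("confusion: length mismatch (%d vs %d)", length(predicted),
          length(truth))
  p <- as.integer(predicted); t <- as.integer(truth)
  if (any(!p %in% 0:1) || any(!t %in% 0:1))
    stopf("confusion: classes must be 0 (benign) or 1 (malignant)")
  list(tp = sum(p == 1L & t == 1L), fp = sum(p == 1L & t == 0L),
       tn = sum(p == 0L & t == 0L), fn = sum(p == 0L & t == 1L))
}

#' Accuracy, sensitivity, specificity, precision and F1
#'
#' Ratios with zero denominators are returned as `NA` with a warning.
#'
#' @param c confusion counts from [confusion()].
#' @return Named numeric vector of the five metrics (fractions in
#'   \[0, 1\]).
#' @export
metrics <- function(c) {
  n <- c$tp + c$fp + c$tn + c$fn
  if (n == 0L) stopf("metrics: no cases")
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator)", what),
              call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  sens <- ratio(c$tp, c$tp + c$fn, "sensitivity")
  spec <- ratio(c$tn, c$tn + c$fp, "specificity")
  prec <- ratio(c$tp, c$tp + c$fp, "precision")
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) {
    NA_real_
  } else {
    2 * prec * sens / (prec + sens)
  }
  c(accuracy = (c$tp + c$tn) / n, sensitivity = sens, specificity = spec,
    precision = prec, f1 = f1)
}

## Stratified assignment of nodules to k groups (balanced within class).
stratified_assign <- function(labels, k) {
  assign <- integer(length(labels))
  for (cl in unique(labels)) {
    ix <- which(labels == cl)
    ix <- ix[sample.int(length(ix))]
    assign[ix] <- rep(seq_len(k), length.out = length(ix))
  }
  assign
}

#' Cross-validation fold assignments at the nodule level
#'
#' `panel_5fold`: five label-stratified folds of nodules (the panel-label
#' design). `individual_4subset`: four equal label-stratified subsets with
#' the four role rotations train/train/validation/test. All annotations of
#' one nodule stay together, so reader-level cases never straddle
#' train/test.
#'
#' @param cases data frame with columns `nodule_id` and `label` (one row
#'   per case; repeated `nodule_id`s allowed for per-annotation cases).
#' @param scheme `"panel_5fold"` or `"individual_4subset"`.
#' @param seed RNG seed for the stratified shuffle.
#' @return For the panel scheme, an integer fold vector (per case). For
#'   the individual scheme, a list with `subset` (per case) and
#'   `rotations` (list of 4 role assignments, each naming the test,
#'   validation and training subsets).
#' @export
make_folds <- function(cases, scheme = c("panel_5fold",
                                         "individual_4subset"),
                       seed = 1L) {
  scheme <- match.arg(scheme)
  k <- if (scheme == "panel_5fold") 5L else 4L
  nod <- unique(cases$nodule_id)
  if (length(nod) < k)
    stopf("make_folds: %d nodules is fewer than %d folds", length(nod), k)
  nod_label <- vapply(nod, function(id)
    as.integer(cases$label[match(id, cases$nodule_id)]), integer(1))
  set.seed(seed)
  nod_assign <- stratified_assign(nod_label, k)
  per_case <- nod_assign[match(cases$nodule_id, nod)]
  if (scheme == "panel_5fold") return(per_case)
  rotations <- lapply(seq_len(4L), function(r) {
    test <- r
    val <- r %% 4L + 1L
    list(test = test, validation = val,
         train = setdiff(seq_len(4L), c(test, val)))
  })
  list(subset = per_case, rotations = rotations)
}

#' Aggregate per-annotation panel predictions to the nodule level
#'
#' The nodule's panel probability is the arithmetic mean of the refined
#' panel head's probability vectors over that nodule's annotations; the
#' predicted class is the argmax (threshold 0.5 on the malignant
#' probability).
#'
#' @param probs N x 2 matrix of per-annotation panel probabilities.
#' @param nodule_ids length-N vector of nodule identifiers.
#' @return Data frame with `nodule_id`, `p_benign`, `p_malignant`,
#'   `class`.
#' @export
aggregate_panel_predictions <- function(probs, nodule_ids) {
  if (nrow(probs) != length(nodule_ids))
    stopf("aggregate_panel_predictions: row/id mismatch")
  ids <- unique(nodule_ids)
  agg <- t(vapply(ids, function(id)
    colMeans(probs[nodule_ids == id, , drop = FALSE]), numeric(2)))
  data.frame(nodule_id = ids, p_benign = agg[, 1], p_malignant = agg[, 2],
             class = as.integer(agg[, 2] > agg[, 1]),
             stringsAsFactors = FALSE)
}

#' Mean and standard deviation of per-fold metrics
#'
#' @param fold_metrics list (or matrix) of per-fold metric vectors from
#'   [metrics()].
#' @return Data frame with one row per metric: `mean`, `sd`.
#' @export
summarize_folds <- function(fold_metrics) {
  m <- if (is.list(fold_metrics)) do.call(rbind, fold_metrics) else
    fold_metrics
  data.frame(metric = colnames(m), mean = colMeans(m),
             sd = apply(m, 2L, sd), row.names = NULL)
}
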