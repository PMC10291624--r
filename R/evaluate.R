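# Per-class precision / recall / F1 for semantic segmentation output.

#' Confusion matrix over the four semantic classes
#'
#' Tallies (true, predicted) counts over `SOIL_BASE, STICK, STEMWORK,
#' OTHER_BIO`. Points whose true label is `UNCLASSIFIED` (unlabelable) are
#' excluded from evaluation, as are the (normally nonexistent) points
#' predicted `UNCLASSIFIED`; both are counted in `n_excluded`.
#'
#' @param pred,truth equal-length label vectors (character/factor over the
#'   semantic classes).
#' @return a `plant_confusion` object: 4 x 4 integer matrix
#'   (rows = true, cols = predicted) with attribute `n_excluded`.
#' @export
confusion_matrix <- function(pred, truth) {
  pred <- as.character(pred)
  truth <- as.character(truth)
  if (length(pred) != length(truth)) {
    stop("pred and truth must have equal length")
  }
  bad <- setdiff(unique(c(pred, truth)), SEMANTIC_CLASSES)
  if (length(bad)) stop("unknown semantic class: ", bad[1])
  keep <- truth != "UNCLASSIFIED" & pred != "UNCLASSIFIED"
  m <- table(factor(truth[keep], levels = EVAL_CLASSES),
             factor(pred[keep], levels = EVAL_CLASSES))
  m <- matrix(as.integer(m), 4, 4,
              dimnames = list(true = EVAL_CLASSES, pred = EVAL_CLASSES))
  structure(m, n_excluded = sum(!keep), class = c("plant_confusion",
                                                  class(m)))
}

#' Precision, recall and F1 per class and class-averaged
#'
#' For each class c: `P = TP / (TP + FP)`, `R = TP / (TP + FN)`,
#' `F1 = 2PR / (P + R)`; any zero denominator yields 0 (conservative
#' convention for absent classes). The class average is the unweighted
#' (macro) mean over the four classes.
#'
#' @param cm a `plant_confusion` from [confusion_matrix()].
#' @return a list with `per_class` (data.frame: class, precision, recall,
#'   f1, support) and `macro_f1`.
#' @export
f1_scores <- function(cm) {
  stopifnot(inherits(cm, "plant_confusion"))
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  p <- safe_div(tp, tp + fp)
  r <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * p * r, p + r)
  list(per_class = data.frame(class = EVAL_CLASSES, precision = unname(p),
                              recall = unname(r), f1 = unname(f1),
                              support = unname(rowSums(cm))),
       macro_f1 = mean(f1))
}

#' Evaluate a predicted segmentation against a reference cloud
#'
#' Convenience wrapper: compares the semantic labels of two clouds (or a
#' cloud and a plain label vector) point-for-point.
#'
#' @param pred a `plant_cloud` or label vector with predictions.
#' @param truth a `plant_cloud` or label vector with the reference.
#' @return as [f1_scores()], plus element `confusion`.
#' @export
evaluate_segmentation <- function(pred, truth) {
  pl <- if (inherits(pred, "plant_cloud")) as.character(pred$semantic) else
    pred
  tl <- if (inherits(truth, "plant_cloud")) as.character(truth$semantic) else
    truth
  cm <- confusion_matrix(pl, tl)
  out <- f1_scores(cm)
  out$confusion <- cm
  out
}
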