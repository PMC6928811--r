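#' @include calibration.R
NULL

.evalCore <- function(model, dataset, split = "test", floatAccuracy = NA_real_) {
  sel <- switch(split,
                all = seq_along(dataset@images),
                which(dataset@split == split))
  if (!length(sel)) stop("no images in the requested split", call. = FALSE)
  classNames <- model@classNames
  nC <- length(classNames)
  confusion <- matrix(0L, nC, nC, dimnames = list(truth = classNames,
                                                  prediction = classNames))
  for (i in sel) {
    p <- predictCell(model, dataset@images[[i]])
    pred <- which.max(p)
    truth <- dataset@labels[i] + 1L
    confusion[truth, pred] <- confusion[truth, pred] + 1L
  }
  overall <- 100 * sum(diag(confusion)) / sum(confusion)
  perClass <- 100 * diag(confusion) / pmax(rowSums(confusion), 1L)
  names(perClass) <- classNames
  drop <- if (is.na(floatAccuracy)) NA_real_ else overall - floatAccuracy
  new("EvalReport", overall = overall, perClass = perClass,
      confusion = confusion, accuracyDrop = drop)
}

#' @rdname evaluateModel
#' @param split "test" (default), "train" or "all"
#' @param floatAccuracy optional float reference accuracy (percent); when
#'   given, the report's accuracy drop is `quantized - float` in
#'   percentage points (negative = worse), the usual sign convention
#' @export
setMethod("evaluateModel", "FloatCNN",
  function(model, dataset, split = "test", floatAccuracy = NA_real_, ...) {
    .evalCore(model, dataset, split, floatAccuracy)
  })

#' @rdname evaluateModel
#' @export
setMethod("evaluateModel", "QuantizedModel",
  function(model, dataset, split = "test", floatAccuracy = NA_real_, ...) {
    .evalCore(model, dataset, split, floatAccuracy)
  })

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: overall accuracy %.2f%%", object@overall))
  if (!is.na(object@accuracyDrop))
    cat(sprintf(" (drop vs float: %+.2f pp)", object@accuracyDrop))
  cat("\nPer-class accuracy (%):\n")
  print(round(object@perClass, 2))
  cat("Confusion matrix (rows = truth):\n")
  print(object@confusion)
})

#' Figure of merit: accuracy loss against hardware area
#'
#' `FoM = 1 / (accuracy_drop * area_percent)`, where `accuracy_drop` is the
#' classification accuracy lost relative to float (in percentage points,
#' taken positive) and `area_percent` is the fraction of the float
#' circuit's area the quantized circuit still occupies. Larger is better:
#' a configuration scores high when it loses little accuracy *and* leaves
#' little area. Reported rounded to three decimals.
#'
#' @param accuracyDrop positive accuracy loss in percentage points
#' @param areaPercent remaining area fraction in (0, 1\]
#' @param digits rounding used for reporting
#' @return the figure of merit
#' @examples
#' fom(0.49, 0.6702)      # 3.045
#' fom(0.56, 1 - 0.4486)  # 3.239
#' @export
fom <- function(accuracyDrop, areaPercent, digits = 3L) {
  if (!is.finite(accuracyDrop) || accuracyDrop <= 0 ||
      !is.finite(areaPercent) || areaPercent <= 0)
    stop("undefined figure of merit: both inputs must be positive",
         call. = FALSE)
  round(1 / (accuracyDrop * areaPercent), digits)
}

#' Binary segmentation quality metrics
#'
#' Jaccard index `|P & T| / |P | T|`, precision `|P & T| / |P|` and recall
#' `|P & T| / |T|` of a predicted mask against ground truth; a score of 1
#' means perfect consistency. An empty denominator yields 1 when both
#' masks are empty (nothing to find, nothing found) and 0 otherwise.
#'
#' @param pred,truth binary matrices of equal shape (any non-zero value
#'   counts as foreground)
#' @return named numeric vector c(jaccard, precision, recall)
#' @export
segmentationMetrics <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth)))
    stop("pred and truth must have the same shape", call. = FALSE)
  p <- pred > 0; t <- truth > 0
  inter <- sum(p & t)
  ratio <- function(num, den, bothEmpty) {
    if (den == 0) { if (bothEmpty) 1 else 0 } else num / den
  }
  empty <- !any(p) && !any(t)
  c(jaccard = ratio(inter, sum(p | t), empty),
    precision = ratio(inter, sum(p), empty),
    recall = ratio(inter, sum(t), empty))
}
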