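#' @include AllClasses.R
NULL

#' Accessors for quantization objects
#'
#' Small read-only accessors so user code never reaches into slots:
#' `bitWidth` and `qMax` report the code range of a configuration or
#' parameter set, `realScale` the exact real scale carried by a
#' [QuantParams-class], `qvalues` the integer codes of a [QTensor-class],
#' `quantRole` its stage role.
#'
#' @param object the object to query
#' @return a length-one numeric/integer, or for `qvalues` an array
#' @rdname accessors
#' @export
setGeneric("bitWidth", function(object) standardGeneric("bitWidth"))

#' @rdname accessors
#' @export
setGeneric("qMax", function(object) standardGeneric("qMax"))

#' @rdname accessors
#' @export
setGeneric("realScale", function(object) standardGeneric("realScale"))

#' @rdname accessors
#' @export
setGeneric("qvalues", function(object) standardGeneric("qvalues"))

#' @rdname accessors
#' @export
setGeneric("quantRole", function(object) standardGeneric("quantRole"))

#' Predict class probabilities for one image
#'
#' Dispatches on the model type: the float reference network runs in real
#' arithmetic, a [QuantizedModel-class] runs the integer-only datapath and
#' only returns to real numbers for the final softmax.
#'
#' @param model a [FloatCNN-class] or [QuantizedModel-class]
#' @param image numeric matrix (or h x w x c array) of real pixel values
#' @param ... passed to methods
#' @return named numeric vector of class probabilities summing to 1
#' @export
setGeneric("predictCell", function(model, image, ...) standardGeneric("predictCell"))

#' Evaluate a classifier on a labeled cell image set
#'
#' @param model a [FloatCNN-class] or [QuantizedModel-class]
#' @param dataset a [CellImageSet-class]
#' @param ... passed to methods; `split` selects "test" (default), "train"
#'   or "all" images, `floatAccuracy` (percent) fills the accuracy-drop row
#' @return an [EvalReport-class]
#' @export
setGeneric("evaluateModel", function(model, dataset, ...) standardGeneric("evaluateModel"))

#' Accessors for cell image sets
#'
#' @param object a [CellImageSet-class]
#' @rdname cellset-accessors
#' @export
setGeneric("cellImages", function(object) standardGeneric("cellImages"))

#' @rdname cellset-accessors
#' @export
setGeneric("cellMasks", function(object) standardGeneric("cellMasks"))

#' @rdname cellset-accessors
#' @export
setGeneric("cellLabels", function(object) standardGeneric("cellLabels"))

#' @rdname cellset-accessors
#' @export
setGeneric("datasetSplit", function(object) standardGeneric("datasetSplit"))
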