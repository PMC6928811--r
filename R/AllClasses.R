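#' @import methods
NULL

## ---------------------------------------------------------------------------
## Quantization parameter algebra
## ---------------------------------------------------------------------------

#' Bit-width configuration for symmetric integer quantization
#'
#' For an X-bit signed quantization the representable code range is the
#' symmetric interval \[-qmax, +qmax\] with `qmax = 2^(X-1) - 1` (so 127 for
#' int8, never -128), and the calibration denominator is `denom = 2 * qmax`
#' (254 for int8).
#'
#' @slot width integer bit width X, 2 <= X <= 8
#' @slot qmax largest representable magnitude, `2^(X-1) - 1`
#' @slot denom calibration denominator, `2 * qmax`
#' @export
setClass("BitWidthConfig",
  representation(width = "integer", qmax = "numeric", denom = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@width) != 1L || is.na(object@width))
      msg <- c(msg, "width must be a single integer")
    else {
      if (object@width < 2L || object@width > 8L)
        msg <- c(msg, "width must be between 2 and 8 bits")
      if (object@qmax != 2^(object@width - 1L) - 1)
        msg <- c(msg, "qmax must equal 2^(width-1) - 1")
      if (object@denom != 2 * object@qmax)
        msg <- c(msg, "denom must equal 2 * qmax")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Quantization parameters (s, n, o) for one tensor or kernel
#'
#' Defines the mapping between integer codes q and real values r as
#' `r = realScale * (q + o)` with `realScale ~ s * 2^-n`. The integer
#' datapath only ever uses the integer triple (s, n, o); the exact real
#' scale from calibration is carried alongside for analysis and for the
#' real-arithmetic oracle. Weight parameters carry `o = 0` by construction.
#'
#' @slot s positive integer scale mantissa (at most qmax for feature and
#'   weight parameters; accumulator-stage parameters carry the product
#'   `s_w * s_d`)
#' @slot n integer power-of-two shift
#' @slot o integer offset (0 for weights)
#' @slot realScale exact positive real scale from calibration
#' @slot width bit width the parameters were computed for
#' @export
setClass("QuantParams",
  representation(s = "numeric", n = "numeric", o = "numeric",
                 realScale = "numeric", width = "integer"),
  validity = function(object) {
    msg <- NULL
    qm <- 2^(object@width - 1L) - 1
    if (!is.finite(object@realScale) || object@realScale <= 0)
      msg <- c(msg, "realScale must be a positive finite real")
    if (object@s < 1 || object@s != round(object@s))
      msg <- c(msg, "s must be a positive integer")
    # feature/weight parameters keep s <= qmax by construction (encodeScale);
    # accumulator-stage parameters carry products s_w * s_d that exceed it,
    # so the class itself only requires integrality
    if (object@s > qm^2)
      msg <- c(msg, sprintf("s must not exceed qmax^2 = %d", qm^2))
    if (object@n != round(object@n))
      msg <- c(msg, "n must be an integer")
    if (object@o != round(object@o))
      msg <- c(msg, "o must be an integer")
    if (is.null(msg)) TRUE else msg
  })

#' Quantized tensor: integer codes plus their quantization parameters
#'
#' The `role` records the datapath stage width contract: `feature` and
#' `weight` values must fit the X-bit code range, `accumulator32` the signed
#' 32-bit range of the MAC accumulator, `wide41` the signed 41-bit range of
#' the post-bias/batch-norm value. Values are held in doubles (exact for
#' integers up to 2^53) with the hardware widths asserted, never silently
#' wrapped.
#'
#' @slot values integer-valued array of codes
#' @slot params [QuantParams-class] interpreting the codes
#' @slot role one of "feature", "weight", "accumulator32", "wide41"
#' @export
setClass("QTensor",
  representation(values = "array", params = "QuantParams", role = "character"),
  validity = function(object) {
    msg <- NULL
    if (!object@role %in% c("feature", "weight", "accumulator32", "wide41"))
      msg <- c(msg, "role must be feature, weight, accumulator32 or wide41")
    v <- object@values
    if (any(v != round(v)))
      msg <- c(msg, "values must be integers")
    lim <- switch(object@role,
      feature = , weight = 2^(object@params@width - 1L) - 1,
      accumulator32 = 2^31 - 1,
      wide41 = 2^40 - 1,
      Inf)
    if (length(v) && max(abs(v)) > lim)
      msg <- c(msg, sprintf("values exceed the %s range (|q| <= %.0f)",
                            object@role, lim))
    if (is.null(msg)) TRUE else msg
  })

## ---------------------------------------------------------------------------
## Layer-level quantized constants
## ---------------------------------------------------------------------------

#' Convolution layer specification
#'
#' @slot kh,kw kernel height and width
#' @slot cin,cout input and output channel counts
#' @slot stride convolution stride (only 1 supported)
#' @slot padding "same" or "valid"
#' @slot hasBias whether the layer adds a per-channel bias
#' @slot hasBN whether the layer applies a per-channel batch-norm multiplier
#' @slot activation "relu" or "none"
#' @slot pool "max2x2s2" or "none"
#' @export
setClass("LayerSpec",
  representation(kh = "integer", kw = "integer", cin = "integer",
                 cout = "integer", stride = "integer", padding = "character",
                 hasBias = "logical", hasBN = "logical",
                 activation = "character", pool = "character"),
  validity = function(object) {
    msg <- NULL
    if (any(c(object@kh, object@kw, object@cin, object@cout) < 1L))
      msg <- c(msg, "kernel shape entries must be positive")
    if (object@stride != 1L)
      msg <- c(msg, "only stride 1 convolution is supported")
    if (!object@padding %in% c("same", "valid"))
      msg <- c(msg, "padding must be 'same' or 'valid'")
    if (object@padding == "same" && (object@kh %% 2L == 0L || object@kw %% 2L == 0L))
      msg <- c(msg, "'same' padding requires odd kernel dimensions")
    if (!object@activation %in% c("relu", "none"))
      msg <- c(msg, "activation must be 'relu' or 'none'")
    if (!object@pool %in% c("max2x2s2", "none"))
      msg <- c(msg, "pool must be 'max2x2s2' or 'none'")
    if (is.null(msg)) TRUE else msg
  })

#' One kernel's quantized weights and unification constants
#'
#' `oConv` is the exact integer sum of the quantized kernel taps times the
#' layer's feature offset; `(sUni, nUni)` encode the ratio of the kernel's
#' accumulator scale to the layer's shared target scale, and `oUni` is the
#' real-valued combined offset of the unification equation, kept for
#' inspection.
#'
#' @slot qweights integer array (kh x kw x cin) of quantized taps
#' @slot wparams per-kernel weight [QuantParams-class]
#' @slot oConv integer, sum(qweights) * feature offset
#' @slot sUni,nUni integer mantissa/shift encoding the unification ratio
#' @slot oUni real combined unification offset (analysis only)
#' @export
setClass("KernelQuant",
  representation(qweights = "array", wparams = "QuantParams",
                 oConv = "numeric", sUni = "numeric", nUni = "numeric",
                 oUni = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (any(object@qweights != round(object@qweights)))
      msg <- c(msg, "qweights must be integers")
    if (object@oConv != round(object@oConv))
      msg <- c(msg, "oConv must be an integer")
    if (object@sUni < 1 || object@sUni != round(object@sUni))
      msg <- c(msg, "sUni must be a positive integer")
    if (is.null(msg)) TRUE else msg
  })

#' Quantized bias constants for one layer
#'
#' Per output channel k the int8 bias code `qb[k]` sits at the unified
#' accumulator scale coarsened by `2^sft`; the wide integer
#' `addend[k] = qb[k] * 2^sft + oTgt` both adds the bias and cancels the
#' representation offset, so the post-bias value is offset-free.
#'
#' @slot qb integer vector of int8 bias codes
#' @slot sft shared non-negative power-of-two alignment shift
#' @slot addend wide integer vector actually added to the accumulator
#' @slot sb,nb the bias scale mantissa/shift (sb equals the unify target s)
#' @export
setClass("BiasQuant",
  representation(qb = "numeric", sft = "numeric", addend = "numeric",
                 sb = "numeric", nb = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (any(object@qb != round(object@qb)))
      msg <- c(msg, "qb must be integers")
    if (length(object@sft) != 1L || object@sft < 0 || object@sft != round(object@sft))
      msg <- c(msg, "sft must be a single non-negative integer")
    if (any(object@addend != round(object@addend)))
      msg <- c(msg, "addend must be integers")
    if (is.null(msg)) TRUE else msg
  })

#' Quantized batch-norm multipliers for one layer
#'
#' Each real multiplier m_k is represented as `qm[k] * 2^-nm` with a shared
#' shift `nm`, so multiplying the accumulator by `qm[k]` scales every
#' channel's representation by the same power of two.
#'
#' @slot qm integer vector of int8 multiplier codes
#' @slot nm shared integer shift
#' @export
setClass("BNQuant",
  representation(qm = "numeric", nm = "numeric"),
  validity = function(object) {
    if (any(object@qm != round(object@qm))) "qm must be integers" else TRUE
  })

## ---------------------------------------------------------------------------
## Models, calibration and datasets
## ---------------------------------------------------------------------------

#' Float reference convolutional network
#'
#' A small sequential CNN held as a list of layers, each a list with a
#' [LayerSpec-class] `spec`, a weight array `W` (kh x kw x cin x cout), a
#' bias vector `b` and an optional batch-norm multiplier vector `m`. The
#' fully connected head is a 1x1 "valid" convolution over the flattened
#' feature vector, so the whole network runs through one convolution path.
#'
#' @slot layers list of layer lists (spec, W, b, m)
#' @slot inputDim integer c(height, width, channels)
#' @slot classNames character vector of output class names
#' @export
setClass("FloatCNN",
  representation(layers = "list", inputDim = "integer",
                 classNames = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@inputDim) != 3L)
      msg <- c(msg, "inputDim must be c(height, width, channels)")
    for (l in object@layers) {
      if (!is(l$spec, "LayerSpec")) { msg <- c(msg, "each layer needs a LayerSpec"); break }
      dW <- dim(l$W)
      if (length(dW) != 4L ||
          !all(dW == c(l$spec@kh, l$spec@kw, l$spec@cin, l$spec@cout))) {
        msg <- c(msg, "weight array dims must match the layer spec"); break
      }
    }
    if (is.null(msg)) TRUE else msg
  })

#' Min/max calibration statistics
#'
#' Exact per-tensor minima and maxima gathered over the whole calibration
#' set (no percentile clipping): the network input range, and for every
#' layer the raw convolution output range (pooled across kernels, before
#' bias) and the post-activation output range.
#'
#' @slot input c(min, max) of the input feature data
#' @slot layers list per layer of list(conv = c(min, max), out = c(min, max))
#' @slot nImages number of calibration images seen
#' @export
setClass("CalibStats",
  representation(input = "numeric", layers = "list", nImages = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@input) != 2L || object@input[1] > object@input[2])
      msg <- c(msg, "input must be c(min, max) with min <= max")
    for (l in object@layers)
      if (l$conv[1] > l$conv[2] || l$out[1] > l$out[2]) {
        msg <- c(msg, "layer ranges must satisfy min <= max"); break
      }
    if (is.null(msg)) TRUE else msg
  })

#' Fully quantized model: every integer constant of the datapath
#'
#' Each layer entry holds the layer spec, the input feature parameters, the
#' per-kernel [KernelQuant-class] list, the shared unify target parameters,
#' the [BiasQuant-class] and optional [BNQuant-class] constants, and the
#' output feature parameters used to requantize back to X bits.
#'
#' @slot layers list of quantized layer descriptions
#' @slot inputParams [QuantParams-class] for the network input
#' @slot cfg the [BitWidthConfig-class] the model was quantized for
#' @slot classNames output class names
#' @slot inputDim integer c(height, width, channels)
#' @export
setClass("QuantizedModel",
  representation(layers = "list", inputParams = "QuantParams",
                 cfg = "BitWidthConfig", classNames = "character",
                 inputDim = "integer"))

#' Seeded synthetic lensless cell image set
#'
#' Images are 8-bit-style grayscale matrices in \[0, 1\]; masks are the
#' pre-noise cell support; labels are 0 = lymphocyte, 1 = monocyte,
#' 2 = neutrophil; split tags each image as "train" or "test".
#'
#' @slot images list of numeric matrices
#' @slot masks list of binary matrices
#' @slot labels integer vector in 0:2
#' @slot split character vector, "train" or "test"
#' @slot seed integer seed the set was generated from
#' @slot params generator parameter list
#' @export
setClass("CellImageSet",
  representation(images = "list", masks = "list", labels = "integer",
                 split = "character", seed = "integer", params = "list"),
  validity = function(object) {
    msg <- NULL
    n <- length(object@images)
    if (length(object@masks) != n || length(object@labels) != n ||
        length(object@split) != n)
      msg <- c(msg, "images, masks, labels and split must have equal length")
    if (n && !all(object@labels %in% 0:2))
      msg <- c(msg, "labels must be in 0:2")
    if (n && !all(object@split %in% c("train", "test")))
      msg <- c(msg, "split tags must be 'train' or 'test'")
    if (n && any(!vapply(object@masks, function(m) any(m > 0), logical(1))))
      msg <- c(msg, "every mask must be non-empty")
    if (is.null(msg)) TRUE else msg
  })

#' Classification evaluation report
#'
#' @slot overall overall accuracy in percent
#' @slot perClass named per-class accuracy in percent
#' @slot confusion confusion matrix (rows = truth, cols = prediction)
#' @slot accuracyDrop float minus quantized accuracy in percentage points
#'   (negative = worse than float), NA when not applicable
#' @export
setClass("EvalReport",
  representation(overall = "numeric", perClass = "numeric",
                 confusion = "matrix", accuracyDrop = "numeric"),
  validity = function(object) {
    if (nrow(object@confusion) != ncol(object@confusion))
      "confusion matrix must be square" else TRUE
  })

#' Result of a pipeline schedule simulation
#'
#' @slot commonTotal total time of the sequential (single register group)
#'   schedule, microseconds
#' @slot dualRegTotal total time with the dual configuration register group
#' @slot overlap time hidden by overlapping next-layer configuration and
#'   data fetch with the current layer's calculation
#' @slot savedPct percent of the common-mode time saved
#' @export
setClass("ScheduleResult",
  representation(commonTotal = "numeric", dualRegTotal = "numeric",
                 overlap = "numeric", savedPct = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@overlap < 0) msg <- c(msg, "overlap must be non-negative")
    if (abs(object@dualRegTotal - (object@commonTotal - object@overlap)) > 1e-9)
      msg <- c(msg, "dualRegTotal must equal commonTotal - overlap")
    if (object@commonTotal > 0 &&
        (object@savedPct < 0 || object@savedPct >= 100))
      msg <- c(msg, "savedPct must be in [0, 100)")
    if (is.null(msg)) TRUE else msg
  })
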