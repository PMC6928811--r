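#' @include utils.R
NULL

#' Build a bit-width configuration
#'
#' @param width integer bit width X with 2 <= X <= 8
#' @return a [BitWidthConfig-class]
#' @examples
#' cfg <- bitWidthConfig(8)
#' qMax(cfg)   # 127
#' @export
bitWidthConfig <- function(width = 8L) {
  width <- as.integer(width)
  new("BitWidthConfig", width = width,
      qmax = 2^(width - 1L) - 1, denom = 2 * (2^(width - 1L) - 1))
}

#' @rdname accessors
#' @export
setMethod("bitWidth", "BitWidthConfig", function(object) object@width)

#' @rdname accessors
#' @export
setMethod("qMax", "BitWidthConfig", function(object) object@qmax)

#' @rdname accessors
#' @export
setMethod("bitWidth", "QuantParams", function(object) object@width)

#' @rdname accessors
#' @export
setMethod("qMax", "QuantParams", function(object) 2^(object@width - 1L) - 1)

#' @rdname accessors
#' @export
setMethod("realScale", "QuantParams", function(object) object@realScale)

#' @rdname accessors
#' @export
setMethod("qvalues", "QTensor", function(object) object@values)

#' @rdname accessors
#' @export
setMethod("quantRole", "QTensor", function(object) object@role)

setMethod("show", "BitWidthConfig", function(object) {
  cat(sprintf("BitWidthConfig: int%d, code range [-%d, %d], denom %d\n",
              object@width, object@qmax, object@qmax, object@denom))
})

setMethod("show", "QuantParams", function(object) {
  cat(sprintf(
    "QuantParams (int%d): s = %d, n = %d, o = %d; s*2^-n = %.8g, exact scale = %.8g\n",
    object@width, object@s, object@n, object@o,
    object@s * 2^-object@n, object@realScale))
})

setMethod("show", "QTensor", function(object) {
  d <- paste(dim(object@values), collapse = " x ")
  cat(sprintf("QTensor [%s], dims %s, codes in [%d, %d]\n", object@role, d,
              if (length(object@values)) min(object@values) else NA_integer_,
              if (length(object@values)) max(object@values) else NA_integer_))
  show(object@params)
})

#' Construct quantization parameters
#'
#' Low-level constructor; most users get parameters from [featureParams()],
#' [weightParams()] or [quantizeModel()]. If `realScale` is omitted it is
#' taken as `s * 2^-n`.
#'
#' @param s positive integer scale mantissa (at most `qmax`)
#' @param n integer shift
#' @param o integer offset (0 for weights)
#' @param width bit width the parameters target
#' @param realScale exact real scale to carry; defaults to `s * 2^-n`
#' @return a [QuantParams-class]
#' @export
quantParams <- function(s, n, o = 0, width = 8L, realScale = s * 2^-n) {
  new("QuantParams", s = as.numeric(s), n = as.numeric(n), o = as.numeric(o),
      realScale = as.numeric(realScale), width = as.integer(width))
}

#' Construct a quantized tensor
#'
#' @param values integer-valued numeric array (a matrix or vector is
#'   promoted to an array)
#' @param params the [QuantParams-class] interpreting the codes
#' @param role stage role: "feature", "weight", "accumulator32" or "wide41"
#' @return a [QTensor-class]
#' @export
qTensor <- function(values, params, role = "feature") {
  if (is.null(dim(values))) values <- array(values, dim = length(values))
  new("QTensor", values = values, params = params, role = role)
}

#' Encode a positive real scale as an integer mantissa and shift
#'
#' Finds `s = round(v * 2^n)` with `n` the largest shift keeping
#' `s <= qmax`, i.e. the most precise fixed-point representation of `v`
#' whose mantissa still fits the configured bit width. The relative error
#' is at most `1/(2*s)`, below 1% for int8.
#'
#' @param v positive real scale to encode
#' @param cfg a [BitWidthConfig-class]
#' @return list with integer `s` and `n` and the encoded `value = s * 2^-n`
#' @examples
#' encodeScale(1.0, bitWidthConfig(8))    # s = 64, n = 6 (exact)
#' encodeScale(1/127, bitWidthConfig(8))  # s = 65, n = 13
#' @export
encodeScale <- function(v, cfg = bitWidthConfig(8L)) {
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
    stop("invalid scale: v must be a single positive finite real", call. = FALSE)
  qm <- cfg@qmax
  n <- floor(log2(qm / v))
  while (.rhaz(v * 2^(n + 1)) <= qm) n <- n + 1
  while (.rhaz(v * 2^n) > qm) n <- n - 1
  s <- .rhaz(v * 2^n)
  list(s = s, n = n, value = s * 2^-n)
}

## Generalized min/max calibration: map [rmin, rmax] onto the symmetric
## grid [-gridQmax, +gridQmax]. Feature/output parameters use the X-bit
## code range as the grid; the unify target uses a finer grid because it
## lives in the wide accumulator. The mantissa (s, n) is always encoded at
## the X-bit width of `cfg`; the exact real scale is carried alongside.
.calibParams <- function(rmin, rmax, gridQmax, cfg) {
  if (!all(is.finite(c(rmin, rmax))))
    stop("invalid range: rmin and rmax must be finite", call. = FALSE)
  if (rmax < rmin)
    stop("invalid range: rmax must be >= rmin", call. = FALSE)
  if (rmax == rmin) {
    enc <- encodeScale(1, cfg)
    o <- .clamp(.rhaz(rmax), -gridQmax, gridQmax)
    return(quantParams(enc$s, enc$n, o, cfg@width, realScale = 1))
  }
  rs <- (rmax - rmin) / (2 * gridQmax)
  enc <- encodeScale(rs, cfg)
  o <- .rhaz(rmax / rs - gridQmax)
  quantParams(enc$s, enc$n, o, cfg@width, realScale = rs)
}

#' Calibrate feature-data quantization parameters from a real range
#'
#' Maps the observed real range \[rmin, rmax\] onto the symmetric code range
#' \[-qmax, +qmax\]: the real scale is `(rmax - rmin) / denom` (encoded as
#' `s * 2^-n` via [encodeScale()]) and the offset is chosen so that rmax
#' quantizes to +qmax and rmin to -qmax, up to encoding rounding. A
#' degenerate range (rmax == rmin, e.g. a constant tensor) gets unit scale
#' and an offset placing the constant at code 0, so nothing divides by zero.
#'
#' @param rmin,rmax observed real minimum and maximum, rmin <= rmax
#' @param cfg a [BitWidthConfig-class]
#' @return a [QuantParams-class] carrying the exact real scale
#' @examples
#' p <- featureParams(-1, 1, bitWidthConfig(8))
#' quantizeReal(1, p)   # 127
#' @export
featureParams <- function(rmin, rmax, cfg = bitWidthConfig(8L)) {
  .calibParams(rmin, rmax, cfg@qmax, cfg)
}

#' Calibrate weight quantization parameters from a kernel's real range
#'
#' Same real scale rule as [featureParams()], but weights carry no offset:
#' the weight mapping is `r = realScale * q` with `o = 0` always.
#'
#' @inheritParams featureParams
#' @return a [QuantParams-class] with `o = 0`
#' @export
weightParams <- function(rmin, rmax, cfg = bitWidthConfig(8L)) {
  if (!all(is.finite(c(rmin, rmax))))
    stop("invalid range: rmin and rmax must be finite", call. = FALSE)
  if (rmax < rmin)
    stop("invalid range: rmax must be >= rmin", call. = FALSE)
  if (rmax == rmin) {
    enc <- encodeScale(1, cfg)
    return(quantParams(enc$s, enc$n, 0, cfg@width, realScale = 1))
  }
  rs <- (rmax - rmin) / cfg@denom
  enc <- encodeScale(rs, cfg)
  quantParams(enc$s, enc$n, 0, cfg@width, realScale = rs)
}

#' Quantize real values to integer codes
#'
#' `q = clamp(round(r / realScale - o), -qmax, +qmax)` with rounding half
#' away from zero; clamping is the saturation contract, so out-of-range
#' reals saturate at the code range limits rather than erroring.
#'
#' @param r numeric vector/array of real values
#' @param p a [QuantParams-class]
#' @return integer codes with the same shape as `r`
#' @export
quantizeReal <- function(r, p) {
  qm <- 2^(p@width - 1L) - 1
  .clamp(.rhaz(r / p@realScale - p@o), -qm, qm)
}

#' Dequantize integer codes to real values
#'
#' `r = realScale * (q + o)`; with `o = 0` (weights, offset-free
#' accumulators) this reduces to `realScale * q`.
#'
#' @param q integer codes
#' @param p a [QuantParams-class]
#' @return numeric values with the same shape as `q`
#' @export
dequantizeCode <- function(q, p) {
  p@realScale * (q + p@o)
}

#' Requantize integer codes between two parameter sets
#'
#' Converts a code from the `src` representation to the `dst`
#' representation entirely in integers, the way the hardware quantization
#' unit does: add the source offset, multiply by the fixed-point integer
#' ratio of the two scales (a 16-bit internal multiplier constant),
#' arithmetic-shift with round-half-away-from-zero, subtract the
#' destination offset, and saturate to the destination code range.
#'
#' @param q integer codes in the `src` representation
#' @param src,dst [QuantParams-class] source and destination parameters
#' @param cfg [BitWidthConfig-class] governing the output clamp; defaults
#'   to the destination's width
#' @return integer codes in the `dst` representation
#' @export
requantizeCode <- function(q, src, dst, cfg = bitWidthConfig(dst@width)) {
  enc <- .encodeRatio(src@realScale / dst@realScale, cfg@width)
  qm <- cfg@qmax
  .clamp(.rhaz((q + src@o) * enc$s / 2^enc$n) - dst@o, -qm, qm)
}

#' Serialize quantization parameters to a plain list (for JSON)
#'
#' @param p a [QuantParams-class]
#' @return list with integer fields s, n, o, width and the exact realScale
#' @export
paramsToList <- function(p) {
  list(s = p@s, n = p@n, o = p@o, width = p@width, realScale = p@realScale)
}

#' Rebuild quantization parameters from their serialized list
#'
#' @param x a list as produced by [paramsToList()]
#' @return a [QuantParams-class]
#' @export
paramsFromList <- function(x) {
  quantParams(x$s, x$n, x$o, x$width,
              realScale = if (is.null(x$realScale)) x$s * 2^-x$n else x$realScale)
}
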