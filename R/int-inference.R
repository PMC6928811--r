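#' @include float-net.R
NULL

#' Construct per-kernel quantized constants
#'
#' @param qweights integer kh x kw x cin array of quantized taps
#' @param wparams the kernel's weight [QuantParams-class]
#' @param oConv integer offset sum `sum(qweights) * o_d` of the layer
#' @param sUni,nUni encoded unification ratio (accumulator scale over the
#'   layer's shared target scale)
#' @param oUni real combined unification offset, kept for inspection
#' @return a [KernelQuant-class]
#' @export
kernelQuant <- function(qweights, wparams, oConv, sUni, nUni, oUni = oConv) {
  new("KernelQuant", qweights = qweights, wparams = wparams,
      oConv = as.numeric(oConv), sUni = as.numeric(sUni),
      nUni = as.numeric(nUni), oUni = as.numeric(oUni))
}

#' Construct quantized bias constants
#'
#' @param qb integer vector of X-bit bias codes (one per output channel)
#' @param sft shared non-negative alignment shift
#' @param addend wide integer vector added to the unified accumulator
#'   (`qb * 2^sft + o_tgt`), performing bias addition and offset
#'   elimination in one exact integer add
#' @param sb,nb bias scale mantissa and shift (`sb` equals the unify target
#'   mantissa, `nb = n_tgt - sft`)
#' @return a [BiasQuant-class]
#' @export
biasQuant <- function(qb, sft, addend, sb, nb) {
  new("BiasQuant", qb = as.numeric(qb), sft = as.numeric(sft),
      addend = as.numeric(addend), sb = as.numeric(sb), nb = as.numeric(nb))
}

#' Construct quantized batch-norm multipliers
#'
#' @param qm integer vector of X-bit multiplier codes
#' @param nm shared shift such that the real multiplier is `qm * 2^-nm`
#' @return a [BNQuant-class]
#' @export
bnQuant <- function(qm, nm) {
  new("BNQuant", qm = as.numeric(qm), nm = as.numeric(nm))
}

## ---------------------------------------------------------------------------
## Stage operations
## ---------------------------------------------------------------------------

#' Quantized convolution: raw integer multiply-accumulate per kernel
#'
#' Computes the raw MAC sum `sum(q_w * q_d)` for every output position and
#' kernel. Padding positions are filled with the quantized zero code
#' `-o_d`, so they represent real 0 (a raw 0 code would inject the real
#' value `s*o*2^-n`). The accumulator carries the product representation:
#' offset `o_conv = sum(q_w) * o_d` and exact scale
#' `realScale(weights) * realScale(features)`. Accumulators are asserted to
#' fit the signed 32-bit MAC width.
#'
#' @param qfeat a feature [QTensor-class] (h x w x cin codes)
#' @param kernels list of [KernelQuant-class], one per output channel
#' @param spec the [LayerSpec-class]
#' @return list of accumulator32 [QTensor-class], one per kernel
#' @export
qconv2d <- function(qfeat, kernels, spec) {
  x <- qfeat@values
  if (length(dim(x)) == 2L) x <- array(x, dim = c(dim(x), 1L))
  if (dim(x)[3] != spec@cin && prod(dim(x)) == spec@cin)
    x <- .flattenFeature(x)
  p <- qfeat@params
  plan <- .im2colIndex(dim(x)[1], dim(x)[2], spec@cin, spec@kh, spec@kw,
                       spec@padding)
  P <- .patches(x, plan, fill = -p@o)
  Qw <- vapply(kernels, function(k) as.vector(k@qweights),
               numeric(spec@kh * spec@kw * spec@cin))
  acc <- P %*% matrix(Qw, ncol = length(kernels))
  .assertWidth(acc, .INT32_MAX, "accumulator32")
  lapply(seq_along(kernels), function(ki) {
    k <- kernels[[ki]]
    accParams <- quantParams(
      s = k@wparams@s * p@s, n = k@wparams@n + p@n, o = k@oConv,
      width = p@width, realScale = k@wparams@realScale * p@realScale)
    new("QTensor", values = array(acc[, ki], dim = c(plan$oh, plan$ow)),
        params = accParams, role = "accumulator32")
  })
}

#' Unify one kernel's accumulator to the layer's shared target parameters
#'
#' Each kernel convolves at its own scale; before bias, batch norm and
#' output quantization all kernels must share one representation. The
#' integer realization adds the kernel's `o_conv`, multiplies by the
#' encoded ratio `s_uni * 2^-n_uni` of the kernel scale to the target
#' scale, rounds, and subtracts the target offset.
#'
#' @param acc accumulator32 [QTensor-class] from [qconv2d()]
#' @param kernel the matching [KernelQuant-class]
#' @param target shared target [QuantParams-class] of the layer
#' @return accumulator32 [QTensor-class] in the target representation
#' @export
unifyToTarget <- function(acc, kernel, target) {
  v <- .rhaz((acc@values + kernel@oConv) * kernel@sUni / 2^kernel@nUni) - target@o
  .assertWidth(v, .INT32_MAX, "unify")
  new("QTensor", values = array(v, dim = dim(acc@values)), params = target,
      role = "accumulator32")
}

#' Stack per-kernel unified accumulators into one layer tensor
#'
#' @param accList list of unified accumulator32 [QTensor-class] sharing the
#'   same parameters
#' @return accumulator32 [QTensor-class] with values h x w x K
#' @export
mergeKernelOutputs <- function(accList) {
  d <- dim(accList[[1]]@values)
  v <- array(unlist(lapply(accList, function(a) a@values)),
             dim = c(d[1], d[2], length(accList)))
  new("QTensor", values = v, params = accList[[1]]@params,
      role = "accumulator32")
}

#' Add the quantized bias and eliminate the representation offset
#'
#' Adds the wide integer addend `q_b * 2^sft + o_tgt` per channel. Because
#' the addend is computed exactly at calibration time, the result is
#' offset-free: the integer directly equals `r * 2^n / s` for the
#' represented real value `r = r_conv + r_b`, so its sign equals the sign
#' of the real value and ReLU can act on raw integers. The result is
#' asserted to fit the 41-bit post-adder width.
#'
#' @param acc accumulator32 [QTensor-class] (h x w x K, unified)
#' @param bias a [BiasQuant-class] with one addend per channel
#' @return wide41 [QTensor-class] with offset-free parameters
#' @export
addBias <- function(acc, bias) {
  d <- dim(acc@values)
  K <- if (length(d) == 3L) d[3] else 1L
  add <- rep(bias@addend, length.out = K)
  v <- sweep(array(acc@values, dim = c(d[1], d[2], K)), 3L, add, "+")
  .assertWidth(v, .INT41_MAX, "wide41 (bias adder)")
  p <- acc@params
  new("QTensor", values = v,
      params = quantParams(p@s, p@n, 0, p@width, realScale = p@realScale),
      role = "wide41")
}

#' Multiply by the quantized batch-norm multiplier
#'
#' Integer multiply by `q_m` per channel; the representation scale gains a
#' factor `2^-n_m`, tracked in the result's parameters. Requires an
#' offset-free input (i.e. after [addBias()]).
#'
#' @param acc wide41 [QTensor-class]
#' @param bn a [BNQuant-class]
#' @return wide41 [QTensor-class]
#' @export
bnMultiply <- function(acc, bn) {
  if (acc@params@o != 0)
    stop("bnMultiply requires an offset-free input", call. = FALSE)
  d <- dim(acc@values)
  K <- if (length(d) == 3L) d[3] else 1L
  qm <- rep(bn@qm, length.out = K)
  v <- sweep(array(acc@values, dim = c(d[1], d[2], K)), 3L, qm, "*")
  .assertWidth(v, .INT41_MAX, "wide41 (batch-norm multiplier)")
  p <- acc@params
  new("QTensor", values = v,
      params = quantParams(p@s, p@n + bn@nm, 0, p@width,
                           realScale = p@realScale * 2^-bn@nm),
      role = "wide41")
}

#' Integer ReLU
#'
#' Elementwise `max(q, 0)`. On an offset-free representation with a
#' positive scale this equals the real-domain ReLU after dequantization.
#'
#' @param acc wide41 (or any offset-free) [QTensor-class]
#' @return [QTensor-class] of the same role
#' @export
reluInt <- function(acc) {
  if (acc@params@o != 0)
    stop("reluInt requires an offset-free input", call. = FALSE)
  new("QTensor", values = pmax(acc@values, 0), params = acc@params,
      role = acc@role)
}

#' Requantize the wide layer result to X-bit feature codes
#'
#' The layer result is wider than X bits and must be narrowed before being
#' passed on as the next layer's input. This is the same integer
#' multiply / shift / offset unit as [requantizeCode()], applied to the
#' wide accumulator with the layer's calibrated output parameters;
#' out-of-range values saturate.
#'
#' @param acc wide41 [QTensor-class]
#' @param outParams calibrated output feature [QuantParams-class]
#' @param cfg [BitWidthConfig-class]; defaults to the output width
#' @return feature [QTensor-class]
#' @export
outputQuantize <- function(acc, outParams, cfg = bitWidthConfig(outParams@width)) {
  v <- requantizeCode(acc@values, acc@params, outParams, cfg)
  new("QTensor", values = array(v, dim = dim(acc@values)), params = outParams,
      role = "feature")
}

#' Integer max pooling (2x2 window, stride 2)
#'
#' Order-preserving, so it commutes with dequantization; quantization
#' parameters are unchanged. Odd trailing rows/columns are dropped.
#'
#' @param qfeat feature [QTensor-class] (h x w x K)
#' @return feature [QTensor-class] with halved spatial dims
#' @export
maxpoolInt <- function(qfeat) {
  x <- qfeat@values
  if (length(dim(x)) == 2L) x <- array(x, dim = c(dim(x), 1L))
  new("QTensor", values = .maxpool2(x), params = qfeat@params,
      role = "feature")
}

## ---------------------------------------------------------------------------
## Full network forward pass
## ---------------------------------------------------------------------------

## One quantized layer in matrix form (fast path used by runNetwork).
## x: integer code array h x w x cin; returns list(codes = array, pre-pool
## stage snapshots if trace).
.runQuantLayer <- function(x, layer, cfg, trace = FALSE) {
  sp <- layer$spec
  if (dim(x)[3] != sp@cin && prod(dim(x)) == sp@cin) x <- .flattenFeature(x)
  inP <- layer$inParams
  plan <- .im2colIndex(dim(x)[1], dim(x)[2], sp@cin, sp@kh, sp@kw, sp@padding)
  P <- .patches(x, plan, fill = -inP@o)
  Qw <- vapply(layer$kernels, function(k) as.vector(k@qweights),
               numeric(sp@kh * sp@kw * sp@cin))
  acc <- P %*% matrix(Qw, ncol = sp@cout)
  .assertWidth(acc, .INT32_MAX, "accumulator32")

  tgt <- layer$tgtParams
  uni <- acc
  for (ki in seq_len(sp@cout)) {
    k <- layer$kernels[[ki]]
    uni[, ki] <- .rhaz((acc[, ki] + k@oConv) * k@sUni / 2^k@nUni) - tgt@o
  }
  .assertWidth(uni, .INT32_MAX, "unify")

  wide <- sweep(uni, 2L, layer$bias@addend, "+")
  .assertWidth(wide, .INT41_MAX, "wide41 (bias adder)")
  wideScale <- tgt@realScale
  if (sp@hasBN && !is.null(layer$bn)) {
    wide <- sweep(wide, 2L, layer$bn@qm, "*")
    .assertWidth(wide, .INT41_MAX, "wide41 (batch-norm multiplier)")
    wideScale <- wideScale * 2^-layer$bn@nm
  }
  if (sp@activation == "relu") wide <- pmax(wide, 0)

  srcParams <- quantParams(tgt@s, tgt@n, 0, tgt@width, realScale = wideScale)
  outCodes <- requantizeCode(wide, srcParams, layer$outParams, cfg)
  out <- array(outCodes, dim = c(plan$oh, plan$ow, sp@cout))
  pooled <- if (sp@pool == "max2x2s2") .maxpool2(out) else out
  res <- list(codes = pooled)
  if (trace)
    res$stages <- list(
      unified = list(codes = array(uni, dim = c(plan$oh, plan$ow, sp@cout)),
                     params = tgt),
      wide = list(codes = array(wide, dim = c(plan$oh, plan$ow, sp@cout)),
                  params = srcParams),
      out = list(codes = out, params = layer$outParams),
      pooled = list(codes = pooled, params = layer$outParams))
  res
}

#' Run the integer-only network on one image
#'
#' Quantizes the input image once, then executes every layer entirely in
#' integer arithmetic: quantized convolution, per-kernel unification, the
#' offset-eliminating bias addend, optional batch-norm multiply, integer
#' ReLU, output requantization to X bits, and max pooling. The fully
#' connected head runs as a 1x1 convolution over the flattened feature
#' vector. Only the final logits are dequantized; the softmax is computed
#' in real arithmetic.
#'
#' @param qmodel a [QuantizedModel-class]
#' @param image numeric matrix or h x w x c array of real pixel values
#' @param trace also return per-layer integer stage snapshots (codes plus
#'   their [QuantParams-class]) for debugging and oracle comparison
#' @return list with `probs`, `logits`, the predicted `class` label
#'   (0-based) and, if requested, `trace`
#' @export
runNetwork <- function(qmodel, image, trace = FALSE) {
  x <- .asInputArray(image, qmodel@inputDim)
  codes <- array(quantizeReal(x, qmodel@inputParams), dim = dim(x))
  tr <- if (trace) list(input = list(codes = codes, params = qmodel@inputParams))
  for (li in seq_along(qmodel@layers)) {
    res <- .runQuantLayer(codes, qmodel@layers[[li]], qmodel@cfg, trace = trace)
    codes <- res$codes
    if (trace) tr[[paste0("layer", li)]] <- res$stages
  }
  lastP <- qmodel@layers[[length(qmodel@layers)]]$outParams
  logits <- dequantizeCode(as.vector(codes), lastP)
  names(logits) <- qmodel@classNames
  out <- list(probs = .softmax(logits), logits = logits,
              class = unname(which.max(logits)) - 1L)
  if (trace) out$trace <- tr
  out
}

#' @rdname predictCell
#' @export
setMethod("predictCell", "QuantizedModel", function(model, image, ...) {
  runNetwork(model, image)$probs
})

setMethod("show", "QuantizedModel", function(object) {
  cat(sprintf("QuantizedModel: int%d, input %s, %d layer(s), classes: %s\n",
              object@cfg@width, paste(object@inputDim, collapse = "x"),
              length(object@layers),
              paste(object@classNames, collapse = ", ")))
  for (l in object@layers) show(l$spec)
})

#' Dump the per-stage integer trace of one image to CSV files
#'
#' Writes one CSV per layer stage (unified, wide, out, pooled) with the
#' integer codes in flattened column-major order, for debugging against a
#' hardware simulation.
#'
#' @param qmodel a [QuantizedModel-class]
#' @param image input image
#' @param dir output directory (created if needed)
#' @return invisibly, the list of files written
#' @export
dumpTrace <- function(qmodel, image, dir) {
  res <- runNetwork(qmodel, image, trace = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (ln in setdiff(names(res$trace), "input")) {
    for (sn in names(res$trace[[ln]])) {
      f <- file.path(dir, sprintf("%s_%s.csv", ln, sn))
      utils::write.csv(
        data.frame(index = seq_along(res$trace[[ln]][[sn]]$codes),
                   code = as.vector(res$trace[[ln]][[sn]]$codes)),
        f, row.names = FALSE)
      files <- c(files, f)
    }
  }
  invisible(files)
}
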