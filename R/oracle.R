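#' @include int-inference.R
NULL

#' Real-arithmetic fake-quantization oracle
#'
#' Reference forward pass that uses the same calibrated parameters as the
#' integer datapath but stays in real arithmetic, quantizing and
#' dequantizing at every stage boundary with the *exact* real scales. The
#' only thing it does not model is the fixed-point encoding of the scale
#' ratios (integer multiply + shift), so the difference between this
#' oracle and [runNetwork()] bounds the error introduced by the integer
#' realization itself. Used in tests to check stage-by-stage agreement
#' within a couple of output least-significant-bits.
#'
#' @param qmodel a [QuantizedModel-class]
#' @param image numeric matrix or h x w x c array
#' @param trace also return per-layer real-valued stage snapshots
#' @return list with `probs`, `logits`, `class` and optionally `trace`
#' @export
fakeQuantForward <- function(qmodel, image, trace = FALSE) {
  x <- .asInputArray(image, qmodel@inputDim)
  inP <- qmodel@inputParams
  x <- array(dequantizeCode(quantizeReal(x, inP), inP), dim = dim(x))
  tr <- if (trace) list()
  for (li in seq_along(qmodel@layers)) {
    layer <- qmodel@layers[[li]]
    sp <- layer$spec
    if (dim(x)[3] != sp@cin && prod(dim(x)) == sp@cin) x <- .flattenFeature(x)
    plan <- .im2colIndex(dim(x)[1], dim(x)[2], sp@cin, sp@kh, sp@kw, sp@padding)
    P <- .patches(x, plan, fill = 0)
    What <- vapply(layer$kernels,
                   function(k) as.vector(k@qweights) * k@wparams@realScale,
                   numeric(sp@kh * sp@kw * sp@cin))
    conv <- P %*% matrix(What, ncol = sp@cout)

    # unification boundary: round the real conv result to the target grid
    tgt <- layer$tgtParams
    uni <- .rhaz(conv / tgt@realScale - tgt@o) + tgt@o
    r <- tgt@realScale * uni

    # the quantized bias's represented real value (bias quantization error
    # is shared with the integer path, not counted against it)
    rb <- layer$bias@qb * 2^layer$bias@sft * tgt@realScale
    r <- sweep(r, 2L, rb, "+")
    if (sp@hasBN && !is.null(layer$bn))
      r <- sweep(r, 2L, layer$bn@qm * 2^-layer$bn@nm, "*")
    if (sp@activation == "relu") r <- pmax(r, 0)
    wideReal <- r

    outP <- layer$outParams
    qo <- quantizeReal(r, outP)
    r <- dequantizeCode(qo, outP)
    out <- array(r, dim = c(plan$oh, plan$ow, sp@cout))
    pooled <- if (sp@pool == "max2x2s2") .maxpool2(out) else out
    if (trace)
      tr[[paste0("layer", li)]] <- list(
        unified = array(tgt@realScale * uni, dim = c(plan$oh, plan$ow, sp@cout)),
        wide = array(wideReal, dim = c(plan$oh, plan$ow, sp@cout)),
        out = out, pooled = pooled)
    x <- pooled
  }
  logits <- as.vector(x)
  names(logits) <- qmodel@classNames
  res <- list(probs = .softmax(logits), logits = logits,
              class = unname(which.max(logits)) - 1L)
  if (trace) res$trace <- tr
  res
}
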