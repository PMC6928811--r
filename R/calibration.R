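#' @include oracle.R
NULL

#' Collect min/max calibration statistics over a set of images
#'
#' One float forward pass per calibration image, tracking the exact minimum
#' and maximum (no percentile clipping) of the network input, of every
#' layer's raw convolution output (pooled across kernels, before bias) and
#' of every layer's post-activation output. All quantization constants are
#' later computed offline from these ranges. Statistics are
#' permutation-invariant over the image list and can only widen as images
#' are added.
#'
#' @param model a [FloatCNN-class]
#' @param images list of images, or a [CellImageSet-class] (its "train"
#'   images are used)
#' @return a [CalibStats-class]
#' @export
collectStats <- function(model, images) {
  if (is(images, "CellImageSet")) {
    sel <- which(images@split == "train")
    if (!length(sel)) sel <- seq_along(images@images)
    images <- images@images[sel]
  }
  if (!length(images)) stop("calibration needs at least one image", call. = FALSE)
  input <- c(Inf, -Inf)
  layers <- replicate(length(model@layers),
                      list(conv = c(Inf, -Inf), out = c(Inf, -Inf)),
                      simplify = FALSE)
  for (img in images) {
    st <- floatForward(model, img, withStats = TRUE)$stats
    input <- c(min(input[1], st$input[1]), max(input[2], st$input[2]))
    for (li in seq_along(layers)) {
      layers[[li]]$conv <- c(min(layers[[li]]$conv[1], st$layers[[li]]$conv[1]),
                             max(layers[[li]]$conv[2], st$layers[[li]]$conv[2]))
      layers[[li]]$out <- c(min(layers[[li]]$out[1], st$layers[[li]]$out[1]),
                            max(layers[[li]]$out[2], st$layers[[li]]$out[2]))
    }
  }
  new("CalibStats", input = input, layers = layers,
      nImages = length(images))
}

setMethod("show", "CalibStats", function(object) {
  cat(sprintf("CalibStats over %d image(s); input range [%.4g, %.4g]\n",
              object@nImages, object@input[1], object@input[2]))
  for (li in seq_along(object@layers))
    cat(sprintf("  layer %d: conv [%.4g, %.4g], out [%.4g, %.4g]\n", li,
                object@layers[[li]]$conv[1], object@layers[[li]]$conv[2],
                object@layers[[li]]$out[1], object@layers[[li]]$out[2]))
})

## Quantize one layer's constants from the float layer plus its calibrated
## ranges. inParams are the feature parameters of this layer's input.
.quantizeLayer <- function(layer, inParams, ranges, cfg) {
  sp <- layer$spec
  qm <- cfg@qmax

  kernels <- vector("list", sp@cout)
  for (ki in seq_len(sp@cout)) {
    wk <- layer$W[, , , ki, drop = FALSE]
    wp <- weightParams(min(wk), max(wk), cfg)
    qw <- array(.clamp(.rhaz(wk / wp@realScale), -qm, qm),
                dim = c(sp@kh, sp@kw, sp@cin))
    kernels[[ki]] <- list(wp = wp, qw = qw)
  }

  # shared unify target from the pooled real conv-output range of the
  # layer, on the fine double-width accumulator grid (see .unifyQmax)
  tgt <- .calibParams(ranges$conv[1], ranges$conv[2], .unifyQmax(cfg@width), cfg)
  for (ki in seq_len(sp@cout)) {
    k <- kernels[[ki]]
    convScale <- k$wp@realScale * inParams@realScale
    enc <- .encodeRatio(convScale / tgt@realScale, cfg@width)
    oConv <- sum(k$qw) * inParams@o
    oUni <- oConv - tgt@o * tgt@realScale / convScale
    kernels[[ki]] <- kernelQuant(k$qw, k$wp, oConv, enc$s, enc$n, oUni)
  }

  # bias codes at the target scale coarsened by 2^sft; the wide addend also
  # cancels the target offset, so every layer gets an addend even without a
  # trained bias (pure offset elimination then)
  b <- if (sp@hasBias && length(layer$b)) layer$b else numeric(sp@cout)
  sft <- 0
  maxb <- max(abs(b))
  if (maxb > 0)
    while (.rhaz(maxb / (tgt@realScale * 2^sft)) > qm) sft <- sft + 1
  qb <- .clamp(.rhaz(b / (tgt@realScale * 2^sft)), -qm, qm)
  addend <- qb * 2^sft + tgt@o
  bias <- biasQuant(qb, sft, addend, sb = tgt@s, nb = tgt@n - sft)

  bn <- NULL
  if (sp@hasBN && length(layer$m)) {
    m <- layer$m
    maxm <- max(abs(m))
    if (maxm == 0) {
      bn <- bnQuant(rep(0, sp@cout), 0)
    } else {
      nm <- encodeScale(maxm, cfg)$n
      bn <- bnQuant(.clamp(.rhaz(m * 2^nm), -qm, qm), nm)
    }
  }

  outParams <- featureParams(ranges$out[1], ranges$out[2], cfg)
  list(spec = sp, inParams = inParams, kernels = kernels, tgtParams = tgt,
       bias = bias, bn = bn, outParams = outParams)
}

#' Quantize a float model into a fully integer model
#'
#' Computes every quantization constant offline from the calibration
#' statistics: per-layer feature parameters, per-kernel weight parameters
#' and quantized taps, the per-kernel `o_conv` sums, the shared unify
#' target of each layer with per-kernel encoded unification ratios, the
#' offset-eliminating bias constants (code, alignment shift `sft` and exact
#' wide addend), optional batch-norm multiplier codes, and each layer's
#' output feature parameters. Each layer's input parameters are the
#' previous layer's output parameters, so features are requantized exactly
#' once per layer.
#'
#' @param model a [FloatCNN-class]
#' @param stats a [CalibStats-class] from [collectStats()], covering every
#'   layer of the model
#' @param cfg target [BitWidthConfig-class]
#' @return a [QuantizedModel-class]
#' @export
quantizeModel <- function(model, stats, cfg = bitWidthConfig(8L)) {
  if (length(stats@layers) != length(model@layers))
    stop("calibration statistics do not cover every layer", call. = FALSE)
  inputParams <- featureParams(stats@input[1], stats@input[2], cfg)
  layers <- vector("list", length(model@layers))
  inP <- inputParams
  for (li in seq_along(model@layers)) {
    layers[[li]] <- .quantizeLayer(model@layers[[li]], inP,
                                   stats@layers[[li]], cfg)
    inP <- layers[[li]]$outParams
  }
  new("QuantizedModel", layers = layers, inputParams = inputParams,
      cfg = cfg, classNames = model@classNames, inputDim = model@inputDim)
}

#' Retrieve every stored quantization constant of one layer by symbol
#'
#' Returns the layer's constants under the conventional symbol names of the
#' quantization algebra (`s_d`, `n_d`, `o_d` for the input features; per
#' kernel `s_w`, `n_w`, `o_conv`, `s_uni`, `n_uni`, `o_uni`; bias `s_b`,
#' `n_b`, `sft`, `q_b`; batch-norm `s_m`, `n_m`, `q_m`; output `s_out`,
#' `n_out`, `o_out`; unify target `s_tgt`, `n_tgt`, `o_tgt`), mainly so
#' completeness can be audited.
#'
#' @param qmodel a [QuantizedModel-class]
#' @param layer layer index
#' @return named list of constants
#' @export
layerConstants <- function(qmodel, layer) {
  l <- qmodel@layers[[layer]]
  list(
    s_d = l$inParams@s, n_d = l$inParams@n, o_d = l$inParams@o,
    s_w = vapply(l$kernels, function(k) k@wparams@s, numeric(1)),
    n_w = vapply(l$kernels, function(k) k@wparams@n, numeric(1)),
    o_conv = vapply(l$kernels, function(k) k@oConv, numeric(1)),
    s_uni = vapply(l$kernels, function(k) k@sUni, numeric(1)),
    n_uni = vapply(l$kernels, function(k) k@nUni, numeric(1)),
    o_uni = vapply(l$kernels, function(k) k@oUni, numeric(1)),
    s_tgt = l$tgtParams@s, n_tgt = l$tgtParams@n, o_tgt = l$tgtParams@o,
    s_b = l$bias@sb, n_b = l$bias@nb, sft = l$bias@sft, q_b = l$bias@qb,
    s_m = if (is.null(l$bn)) NULL else 1,
    n_m = if (is.null(l$bn)) NULL else l$bn@nm,
    q_m = if (is.null(l$bn)) NULL else l$bn@qm,
    s_out = l$outParams@s, n_out = l$outParams@n, o_out = l$outParams@o)
}

#' Accuracy of a float model quantized at several bit widths
#'
#' Quantizes the model once per requested width (one [collectStats()] pass
#' is shared) and evaluates the integer network on the labeled evaluation
#' set, reporting overall and per-class accuracy next to the float
#' reference row.
#'
#' @param model a trained [FloatCNN-class]
#' @param dataset a labeled [CellImageSet-class]; calibration uses its
#'   "train" images, evaluation its "test" images
#' @param widths integer vector of bit widths to sweep
#' @param report optional path; when given the table is also written as CSV
#' @return data.frame with columns width ("float" row first), overall, and
#'   one per-class accuracy column (percent)
#' @export
bitwidthSweep <- function(model, dataset, widths = 2:8, report = NULL) {
  stats <- collectStats(model, dataset)
  floatEval <- evaluateModel(model, dataset, split = "test")
  rows <- data.frame(width = "float", overall = floatEval@overall,
                     t(floatEval@perClass), check.names = FALSE)
  for (X in sort(as.integer(widths), decreasing = TRUE)) {
    qm <- quantizeModel(model, stats, bitWidthConfig(X))
    ev <- evaluateModel(qm, dataset, split = "test",
                        floatAccuracy = floatEval@overall)
    rows <- rbind(rows, data.frame(width = paste0("int", X),
                                   overall = ev@overall, t(ev@perClass),
                                   check.names = FALSE))
  }
  rownames(rows) <- NULL
  if (!is.null(report)) utils::write.csv(rows, report, row.names = FALSE)
  rows
}
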