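#' @include quant-core.R
NULL

#' Construct a convolution layer specification
#'
#' @param kh,kw kernel height and width
#' @param cin,cout input and output channels
#' @param stride convolution stride (only 1 supported)
#' @param padding "same" (zero-padded, output keeps spatial dims) or "valid"
#' @param hasBias whether a per-channel bias is added
#' @param hasBN whether a per-channel batch-norm multiplier is applied
#' @param activation "relu" or "none"
#' @param pool "max2x2s2" (2x2 window, stride 2 max pooling) or "none"
#' @return a [LayerSpec-class]
#' @export
layerSpec <- function(kh, kw, cin, cout, stride = 1L, padding = "same",
                      hasBias = TRUE, hasBN = FALSE, activation = "relu",
                      pool = "none") {
  new("LayerSpec", kh = as.integer(kh), kw = as.integer(kw),
      cin = as.integer(cin), cout = as.integer(cout),
      stride = as.integer(stride), padding = padding,
      hasBias = hasBias, hasBN = hasBN, activation = activation, pool = pool)
}

setMethod("show", "LayerSpec", function(object) {
  cat(sprintf("LayerSpec: %dx%dx%d -> %d, stride %d, %s padding%s%s%s%s\n",
              object@kh, object@kw, object@cin, object@cout, object@stride,
              object@padding,
              if (object@hasBias) ", bias" else "",
              if (object@hasBN) ", batch-norm" else "",
              if (object@activation == "relu") ", relu" else "",
              if (object@pool == "max2x2s2") ", maxpool 2x2/2" else ""))
})

setMethod("show", "FloatCNN", function(object) {
  cat(sprintf("FloatCNN: input %s, %d layer(s), classes: %s\n",
              paste(object@inputDim, collapse = "x"), length(object@layers),
              paste(object@classNames, collapse = ", ")))
  for (l in object@layers) show(l$spec)
})

## ---------------------------------------------------------------------------
## im2col convolution plumbing (stride 1; "same" zero padding or "valid")
## ---------------------------------------------------------------------------

## Linear indices into the padded (h+2ph) x (w+2pw) x cin array such that
## patches[pos, tap] * Wmat[tap, k] implements the convolution. Tap order is
## kh fastest, then kw, then cin -- the column-major order of the kernel
## array, so matrix(W, kh*kw*cin, cout) lines up.
.im2colIndex <- function(h, w, cin, kh, kw, padding) {
  if (padding == "same") { ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L }
  else { ph <- 0L; pw <- 0L }
  oh <- h + 2L * ph - kh + 1L
  ow <- w + 2L * pw - kw + 1L
  H2 <- h + 2L * ph
  base <- rep(seq_len(oh), times = ow) + (rep(seq_len(ow), each = oh) - 1L) * H2
  off <- rep(seq_len(kh) - 1L, times = kw * cin) +
    rep(rep(seq_len(kw) - 1L, each = kh), times = cin) * H2 +
    rep(seq_len(cin) - 1L, each = kh * kw) * H2 * (w + 2L * pw)
  list(idx = outer(base, off, "+"), oh = oh, ow = ow,
       ph = ph, pw = pw, H2 = H2, W2 = w + 2L * pw)
}

## Pad an h x w x c array with a constant fill (0 for real arithmetic, the
## quantized zero code for the integer path).
.padArray <- function(x, ph, pw, fill = 0) {
  if (ph == 0L && pw == 0L) return(x)
  d <- dim(x)
  out <- array(fill, dim = c(d[1] + 2L * ph, d[2] + 2L * pw, d[3]))
  out[ph + seq_len(d[1]), pw + seq_len(d[2]), ] <- x
  out
}

## Extract the patch matrix (positions x taps) for one image.
.patches <- function(x, plan, fill = 0) {
  xp <- .padArray(x, plan$ph, plan$pw, fill)
  matrix(xp[plan$idx], nrow = nrow(plan$idx))
}

## 2x2 stride-2 max pooling; odd trailing row/column dropped (floor
## semantics). With indices = TRUE also returns the quadrant masks the
## training backward pass needs (ties break to the first quadrant, in
## column-major order, so runs are deterministic).
.maxpool2 <- function(x, indices = FALSE) {
  d <- dim(x)
  h2 <- d[1] %/% 2L; w2 <- d[2] %/% 2L
  i1 <- seq(1L, 2L * h2, 2L); i2 <- i1 + 1L
  j1 <- seq(1L, 2L * w2, 2L); j2 <- j1 + 1L
  a <- x[i1, j1, , drop = FALSE]; b <- x[i2, j1, , drop = FALSE]
  cc <- x[i1, j2, , drop = FALSE]; dd <- x[i2, j2, , drop = FALSE]
  out <- pmax(a, b, cc, dd)
  if (!indices) return(out)
  m1 <- a == out
  m2 <- (b == out) & !m1
  m3 <- (cc == out) & !(m1 | m2)
  m4 <- !(m1 | m2 | m3)
  list(out = out, masks = list(m1, m2, m3, m4), inDim = d,
       poolDim = dim(out))
}

## Scatter pooled gradients back to the argmax positions.
.maxpool2Backward <- function(grad, pooled) {
  d <- pooled$inDim
  h2 <- pooled$poolDim[1]; w2 <- pooled$poolDim[2]
  i1 <- seq(1L, 2L * h2, 2L); i2 <- i1 + 1L
  j1 <- seq(1L, 2L * w2, 2L); j2 <- j1 + 1L
  dx <- array(0, dim = d)
  m <- pooled$masks
  dx[i1, j1, ] <- grad * m[[1]]
  dx[i2, j1, ] <- grad * m[[2]]
  dx[i1, j2, ] <- grad * m[[3]]
  dx[i2, j2, ] <- grad * m[[4]]
  dx
}

## ---------------------------------------------------------------------------
## Model construction and float forward pass
## ---------------------------------------------------------------------------

#' Build the WBC classification network (float reference)
#'
#' A LeNet-style single-convolution classifier for lensless white-blood-cell
#' images: one 3x3 convolution with `kernels` output channels, stride 1 and
#' same padding, ReLU, 2x2 stride-2 max pooling, then a fully connected
#' softmax head over the flattened feature map. With the default 168 x 168
#' grayscale input the pooled feature map is 84 x 84 x 8, so the fully
#' connected layer has 56,448 inputs and 3 outputs (lymphocyte, monocyte,
#' neutrophil). Weights use seeded He-style initialization.
#'
#' @param inputSize spatial input size in pixels (square, grayscale)
#' @param kernels number of convolution kernels
#' @param classes number of output classes
#' @param seed integer seed for reproducible initialization
#' @param classNames names for the output classes
#' @return a [FloatCNN-class]
#' @examples
#' m <- buildWbcModel(seed = 1)
#' flattenedSize(m)   # 56448
#' @export
buildWbcModel <- function(inputSize = 168L, kernels = 8L, classes = 3L,
                          seed = 1L,
                          classNames = c("lymphocyte", "monocyte", "neutrophil")[seq_len(classes)]) {
  inputSize <- as.integer(inputSize)
  if (inputSize < 2L) stop("inputSize must be at least 2", call. = FALSE)
  set.seed(as.integer(seed))
  convSpec <- layerSpec(3L, 3L, 1L, kernels, padding = "same",
                        hasBias = TRUE, activation = "relu", pool = "max2x2s2")
  W1 <- array(stats::rnorm(3 * 3 * kernels, sd = sqrt(2 / 9)),
              dim = c(3L, 3L, 1L, kernels))
  b1 <- numeric(kernels)
  nFlat <- (inputSize %/% 2L)^2 * kernels
  fcSpec <- layerSpec(1L, 1L, nFlat, classes, padding = "valid",
                      hasBias = TRUE, activation = "none", pool = "none")
  W2 <- array(stats::rnorm(nFlat * classes, sd = sqrt(2 / nFlat)),
              dim = c(1L, 1L, nFlat, classes))
  b2 <- numeric(classes)
  new("FloatCNN",
      layers = list(list(spec = convSpec, W = W1, b = b1, m = numeric(0)),
                    list(spec = fcSpec, W = W2, b = b2, m = numeric(0))),
      inputDim = c(inputSize, inputSize, 1L),
      classNames = classNames)
}

#' Flattened feature count entering the fully connected head
#'
#' @param model a [FloatCNN-class]
#' @return integer count (56,448 for the default 168 x 168 x 1 network)
#' @export
flattenedSize <- function(model) {
  n <- length(model@layers)
  model@layers[[n]]$spec@cin
}

.asInputArray <- function(image, inputDim) {
  if (is.matrix(image)) image <- array(image, dim = c(dim(image), 1L))
  if (!all(dim(image) == inputDim))
    stop(sprintf("image dims (%s) do not match the model input (%s)",
                 paste(dim(image), collapse = "x"),
                 paste(inputDim, collapse = "x")), call. = FALSE)
  image
}

## Reshape a feature array into the 1 x 1 x n input of the FC-as-convolution
## head (column-major flatten, consistent between float and integer paths).
.flattenFeature <- function(x) array(as.vector(x), dim = c(1L, 1L, length(x)))

#' Float-arithmetic forward pass
#'
#' Runs the reference network in real arithmetic. With
#' `withStats = TRUE` the per-layer raw convolution outputs (before bias)
#' and post-activation outputs are returned as ranges, which is what
#' [collectStats()] aggregates into calibration statistics.
#'
#' @param model a [FloatCNN-class]
#' @param image numeric matrix or h x w x c array
#' @param withStats also return per-layer value ranges
#' @return list with `probs`, `logits` and, if requested, `stats`
#' @export
floatForward <- function(model, image, withStats = FALSE) {
  x <- .asInputArray(image, model@inputDim)
  stats <- if (withStats) list(input = range(x), layers = list())
  for (li in seq_along(model@layers)) {
    layer <- model@layers[[li]]
    sp <- layer$spec
    if (sp@cin != dim(x)[3]) x <- .flattenFeature(x)
    plan <- .im2colIndex(dim(x)[1], dim(x)[2], sp@cin, sp@kh, sp@kw, sp@padding)
    P <- .patches(x, plan, fill = 0)
    conv <- P %*% matrix(layer$W, ncol = sp@cout)
    out <- conv
    if (sp@hasBias) out <- sweep(out, 2L, layer$b, "+")
    if (sp@hasBN && length(layer$m)) out <- sweep(out, 2L, layer$m, "*")
    if (sp@activation == "relu") out <- pmax(out, 0)
    if (withStats)
      stats$layers[[li]] <- list(conv = range(conv), out = range(out))
    x <- array(out, dim = c(plan$oh, plan$ow, sp@cout))
    if (sp@pool == "max2x2s2") x <- .maxpool2(x)
  }
  logits <- as.vector(x)
  names(logits) <- model@classNames
  res <- list(probs = .softmax(logits), logits = logits)
  if (withStats) res$stats <- stats
  res
}

#' @rdname predictCell
#' @export
setMethod("predictCell", "FloatCNN", function(model, image, ...) {
  floatForward(model, image)$probs
})

## ---------------------------------------------------------------------------
## Training (plain mini-batch SGD with cross-entropy)
## ---------------------------------------------------------------------------

#' Train the float reference network
#'
#' Mini-batch gradient descent on the softmax cross-entropy, specialized
#' to the conv + ReLU + maxpool + fully-connected architecture of
#' [buildWbcModel()]. The default optimizer is adaptive-moment gradient
#' descent (Adam): the convolution gradient sums over tens of thousands of
#' spatial positions while the fully connected head does not, so no single
#' plain-SGD step size serves both layers (large rates kill the ReLUs,
#' small ones freeze the head); per-parameter adaptive scaling resolves
#' that. Plain SGD remains available via `optimizer = "sgd"`.
#' Deterministic under the seed: shuffling uses R's seeded RNG and ties in
#' the pooling argmax break to the first position.
#'
#' @param model a 2-layer [FloatCNN-class] from [buildWbcModel()]
#' @param dataset a [CellImageSet-class]; only "train" images are used
#'   unless `split = "all"`
#' @param lr learning rate
#' @param batch mini-batch size
#' @param epochs number of passes over the training images
#' @param seed RNG seed for shuffling
#' @param split which images to train on
#' @param optimizer "adam" (default) or "sgd"
#' @param clipNorm global gradient-norm clipping threshold (Inf disables);
#'   the fully connected head's gradient norm scales with its 56k-feature
#'   input, so unclipped early steps can overshoot and kill the ReLUs
#' @param stopLoss convergence target: training stops after the first
#'   epoch whose mean cross-entropy falls below this value (`epochs` is
#'   the cap)
#' @param weightDecay decoupled L2 penalty applied to the weight matrices
#'   (not the biases) after each optimizer step; the 56k-parameter fully
#'   connected head otherwise memorizes a 420-image training set by a
#'   seed-dependent amount, which makes test-set margins irreproducible
#' @param verbose print per-epoch loss
#' @return list with the trained `model` and the per-epoch mean
#'   cross-entropy `lossHistory`
#' @export
trainFloat <- function(model, dataset, lr = 0.001, batch = 32L, epochs = 10L,
                       seed = 1L, split = "train", optimizer = "adam",
                       clipNorm = 5, stopLoss = 0, weightDecay = 1e-4,
                       verbose = FALSE) {
  sel <- if (split == "all") seq_along(dataset@images)
         else which(dataset@split == split)
  if (!length(sel)) stop("no images in the requested split", call. = FALSE)
  images <- dataset@images[sel]
  labels <- dataset@labels[sel] + 1L
  if (length(model@layers) != 2L)
    stop("trainFloat supports the 2-layer conv + fc architecture", call. = FALSE)

  sp1 <- model@layers[[1]]$spec
  W1 <- matrix(model@layers[[1]]$W, ncol = sp1@cout)
  b1 <- model@layers[[1]]$b
  sp2 <- model@layers[[2]]$spec
  W2 <- matrix(model@layers[[2]]$W, ncol = sp2@cout)
  b2 <- model@layers[[2]]$b
  nClass <- sp2@cout

  h <- model@inputDim[1]; w <- model@inputDim[2]
  plan <- .im2colIndex(h, w, sp1@cin, sp1@kh, sp1@kw, sp1@padding)

  optimizer <- match.arg(optimizer, c("adam", "sgd"))
  if (optimizer == "adam") {
    beta1 <- 0.9; beta2 <- 0.999; adamEps <- 1e-8
    mW1 <- vW1 <- matrix(0, nrow(W1), ncol(W1)); mb1 <- vb1 <- numeric(sp1@cout)
    mW2 <- vW2 <- matrix(0, nrow(W2), ncol(W2)); mb2 <- vb2 <- numeric(nClass)
    step <- 0L
  }

  set.seed(as.integer(seed))
  lossHistory <- numeric(epochs)
  n <- length(images)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    epLoss <- 0
    for (start in seq(1L, n, by = batch)) {
      ids <- ord[start:min(start + batch - 1L, n)]
      dW1 <- matrix(0, nrow(W1), ncol(W1)); db1 <- numeric(sp1@cout)
      dW2 <- matrix(0, nrow(W2), ncol(W2)); db2 <- numeric(nClass)
      for (id in ids) {
        x <- .asInputArray(images[[id]], model@inputDim)
        P <- .patches(x, plan, fill = 0)
        conv <- sweep(P %*% W1, 2L, b1, "+")
        act <- pmax(conv, 0)
        pooled <- .maxpool2(array(act, dim = c(plan$oh, plan$ow, sp1@cout)),
                            indices = TRUE)
        f <- as.vector(pooled$out)
        z <- drop(crossprod(W2, f)) + b2
        p <- .softmax(z)
        y <- labels[id]
        epLoss <- epLoss - log(max(p[y], 1e-12))
        dz <- p; dz[y] <- dz[y] - 1
        dW2 <- dW2 + tcrossprod(f, dz)
        db2 <- db2 + dz
        df <- drop(W2 %*% dz)
        dAct <- .maxpool2Backward(array(df, dim = pooled$poolDim), pooled)
        dConv <- matrix(dAct, ncol = sp1@cout) * (conv > 0)
        dW1 <- dW1 + crossprod(P, dConv)
        db1 <- db1 + colSums(dConv)
      }
      m <- length(ids)
      dW1 <- dW1 / m; db1 <- db1 / m; dW2 <- dW2 / m; db2 <- db2 / m
      if (is.finite(clipNorm)) {
        gn <- sqrt(sum(dW1^2) + sum(db1^2) + sum(dW2^2) + sum(db2^2))
        if (gn > clipNorm) {
          sc <- clipNorm / gn
          dW1 <- dW1 * sc; db1 <- db1 * sc
          dW2 <- dW2 * sc; db2 <- db2 * sc
        }
      }
      if (optimizer == "sgd") {
        W1 <- W1 - lr * dW1; b1 <- b1 - lr * db1
        W2 <- W2 - lr * dW2; b2 <- b2 - lr * db2
      } else {
        step <- step + 1L
        corr <- sqrt(1 - beta2^step) / (1 - beta1^step)
        mW1 <- beta1 * mW1 + (1 - beta1) * dW1
        vW1 <- beta2 * vW1 + (1 - beta2) * dW1^2
        W1 <- W1 - lr * corr * mW1 / (sqrt(vW1) + adamEps)
        mb1 <- beta1 * mb1 + (1 - beta1) * db1
        vb1 <- beta2 * vb1 + (1 - beta2) * db1^2
        b1 <- b1 - lr * corr * mb1 / (sqrt(vb1) + adamEps)
        mW2 <- beta1 * mW2 + (1 - beta1) * dW2
        vW2 <- beta2 * vW2 + (1 - beta2) * dW2^2
        W2 <- W2 - lr * corr * mW2 / (sqrt(vW2) + adamEps)
        mb2 <- beta1 * mb2 + (1 - beta1) * db2
        vb2 <- beta2 * vb2 + (1 - beta2) * db2^2
        b2 <- b2 - lr * corr * mb2 / (sqrt(vb2) + adamEps)
      }
      if (weightDecay > 0) {
        W1 <- W1 * (1 - lr * weightDecay)
        W2 <- W2 * (1 - lr * weightDecay)
      }
    }
    lossHistory[ep] <- epLoss / n
    if (!is.finite(lossHistory[ep]))
      stop("training diverged: loss is not finite", call. = FALSE)
    if (verbose)
      message(sprintf("epoch %d: mean cross-entropy %.4f", ep, lossHistory[ep]))
    if (lossHistory[ep] <= stopLoss) {
      lossHistory <- lossHistory[seq_len(ep)]
      break
    }
  }
  model@layers[[1]]$W <- array(W1, dim = dim(model@layers[[1]]$W))
  model@layers[[1]]$b <- b1
  model@layers[[2]]$W <- array(W2, dim = dim(model@layers[[2]]$W))
  model@layers[[2]]$b <- b2
  list(model = model, lossHistory = lossHistory)
}
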