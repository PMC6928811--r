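# Shared fixtures: tiny float networks and random images, all built in code.

# A one-conv-layer float model with explicit weights (no pooling), used to
# exercise the quantized datapath against the real-arithmetic oracle.
toyConvModel <- function(kernels = 2L, inputSize = 8L, seed = 1L,
                         sd = 0.5, biasSd = 0.3, pool = "none",
                         activation = "relu", hasBN = FALSE, m = numeric(0)) {
  set.seed(seed)
  spec <- layerSpec(3L, 3L, 1L, kernels, padding = "same", hasBias = TRUE,
                    hasBN = hasBN, activation = activation, pool = pool)
  W <- array(stats::rnorm(9L * kernels, sd = sd), dim = c(3L, 3L, 1L, kernels))
  b <- stats::rnorm(kernels, sd = biasSd)
  new("FloatCNN",
      layers = list(list(spec = spec, W = W, b = b, m = m)),
      inputDim = c(inputSize, inputSize, 1L),
      classNames = paste0("k", seq_len(kernels)))
}

randomImages <- function(n, size = 8L, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) matrix(stats::runif(size * size), size, size))
}

# Calibrate + quantize a toy model on a small random image set.
toyQuantized <- function(model, nCalib = 6L, width = 8L, seed = 2L) {
  imgs <- randomImages(nCalib, size = model@inputDim[1], seed = seed)
  stats <- collectStats(model, imgs)
  list(qmodel = quantizeModel(model, stats, bitWidthConfig(width)),
       images = imgs, stats = stats)
}

# Tiny labeled image set (non-synthetic-module path) for trainer edge cases.
tinyImageSet <- function(images, labels, split = rep("train", length(images)),
                         seed = 1L) {
  new("CellImageSet", images = images,
      masks = lapply(images, function(x) matrix(1, nrow(x), ncol(x))),
      labels = as.integer(labels), split = split, seed = as.integer(seed),
      params = list(imageSize = nrow(images[[1]])))
}
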