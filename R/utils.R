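#' @include AllGenerics.R
NULL

## Round half away from zero: the one rounding rule used everywhere in the
## integer datapath so the bit pattern is reproducible across platforms.
.rhaz <- function(x) sign(x) * floor(abs(x) + 0.5)

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## signed width limits mirrored from the hardware stage contracts
.INT32_MAX <- 2^31 - 1
.INT41_MAX <- 2^40 - 1

## Grid half-range for the shared unify target of a layer at datapath
## width X. The unified value lives in the wide accumulator, not in an
## X-bit feature, so its grid is finer than the X-bit code range: the
## circuit carries internal constants at double the feature width, giving
## a (2X-1)-bit signed grid (+-32767 for int8). The bias alignment shift
## 2^sft exists exactly because the unified grid is finer than the X-bit
## bias code grid.
.unifyQmax <- function(width) 2^(2L * width - 1L) - 1

## Mantissa range of the fixed-point ratio multipliers inside the
## requantization units (unify and output quantization). These are
## internal datapath constants like o_conv - not X-bit quantization
## parameters - and like the unify grid they carry double the feature
## width: 2X bits of mantissa (relative error below 2^-16 for int8).
.ratioQmax <- function(width) 2^(2L * width) - 1

## encodeScale's algorithm at the ratio-multiplier precision
.encodeRatio <- function(v, width = 8L) {
  if (!is.finite(v) || v <= 0)
    stop("invalid scale: ratio must be a positive finite real", call. = FALSE)
  qm <- .ratioQmax(width)
  n <- floor(log2(qm / v))
  while (.rhaz(v * 2^(n + 1)) <= qm) n <- n + 1
  while (.rhaz(v * 2^n) > qm) n <- n - 1
  list(s = .rhaz(v * 2^n), n = n, value = .rhaz(v * 2^n) * 2^-n)
}

.assertWidth <- function(x, limit, stage) {
  if (length(x) && max(abs(x)) > limit)
    stop(sprintf("integer overflow at stage '%s': |value| = %.0f exceeds %.0f",
                 stage, max(abs(x)), limit), call. = FALSE)
  invisible(x)
}

.isCount <- function(x) length(x) == 1L && is.finite(x) && x == round(x) && x >= 1

## stable softmax in real arithmetic
.softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

## stratified per-class index split, deterministic given ordering
.splitTags <- function(labels, trainFrac) {
  tags <- character(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    nTrain <- ceiling(length(idx) * trainFrac)
    tags[idx[seq_len(nTrain)]] <- "train"
    tags[idx[-seq_len(nTrain)]] <- "test"
  }
  tags
}
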