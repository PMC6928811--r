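#' @include wbc-metrics.R
NULL

#' Parameters of the synthetic lensless cell image generator
#'
#' The generator emulates the imaging characteristics of a lensless
#' sensor - low resolution, soft (diffraction-blurred) boundaries and
#' visible noise - with morphology-by-construction cells: a lymphocyte is
#' one large round nucleus filling most of the cell, a monocyte has a
#' kidney/bean-shaped nucleus, a neutrophil has 2-5 separate nuclear
#' lobes. Classes are separable but noisy, which is what bit-width
#' degradation sweeps need.
#'
#' @param imageSize square image side in pixels
#' @param radiusRange cell radius range in pixels
#' @param blurSigma Gaussian blur sigma in pixels (diffraction softening)
#' @param noiseSd additive Gaussian noise standard deviation
#' @param background background intensity in \[0, 1\]
#' @param cytoplasm cytoplasm intensity
#' @param nucleusIntensity per-class nucleus intensity
#'   c(lymphocyte, monocyte, neutrophil)
#' @param centerJitter maximum cell center offset from the image center
#' @param gainRange per-image illumination gain range (the whole rendered
#'   scene is multiplied by one uniform draw, emulating exposure /
#'   illumination variation between lensless captures)
#' @param flashProb probability that a capture is overexposed: its gain is
#'   drawn from `flashRange` instead of `gainRange`. Overexposed captures
#'   are rare but produce the largest network activations, so they pin the
#'   upper end of every min/max-calibrated range - the activation-outlier
#'   sensitivity that exact min/max calibration is known for
#' @param flashRange gain range of overexposed captures
#' @param clumpProb probability that a capture contains a clump of 2-3
#'   adjacent cells of the same class instead of a single cell, as happens
#'   in flow imaging; clumped captures produce rare, extreme network
#'   activations, the activation outliers that exact min/max calibration
#'   is known to be sensitive to
#' @return named list of generator parameters
#' @export
syntheticCellParams <- function(imageSize = 168L, radiusRange = c(42, 52),
                                blurSigma = 2, noiseSd = 0.06,
                                background = 0.08, cytoplasm = 0.30,
                                nucleusIntensity = c(0.50, 0.50, 0.50),
                                centerJitter = 5,
                                gainRange = c(0.4, 0.7),
                                flashProb = 0.05,
                                flashRange = c(1.5, 1.9),
                                clumpProb = 0) {
  stopifnot(imageSize >= 32, all(radiusRange > 0), blurSigma >= 0,
            noiseSd >= 0, all(gainRange > 0), diff(gainRange) >= 0,
            length(nucleusIntensity) == 3L,
            flashProb >= 0, flashProb <= 1, all(flashRange > 0),
            clumpProb >= 0, clumpProb <= 1)
  list(imageSize = as.integer(imageSize), radiusRange = radiusRange,
       blurSigma = blurSigma, noiseSd = noiseSd, background = background,
       cytoplasm = cytoplasm, nucleusIntensity = nucleusIntensity,
       centerJitter = centerJitter, gainRange = gainRange,
       flashProb = flashProb, flashRange = flashRange,
       clumpProb = clumpProb)
}

## rotated ellipse support on a size x size pixel grid
.ellipseMask <- function(size, cx, cy, rx, ry, theta = 0) {
  X <- matrix(rep(seq_len(size), each = size), size, size)
  Y <- matrix(rep(seq_len(size), times = size), size, size)
  dx <- X - cx; dy <- Y - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / rx)^2 + (v / ry)^2 <= 1
}

## class-specific nucleus support, clipped to the cell
.nucleusMask <- function(classId, size, cx, cy, r, cell) {
  nuc <- switch(as.character(classId),
    "0" = {                                  # lymphocyte: one big round nucleus
      rn <- r * stats::runif(1, 0.72, 0.82)  # high nucleus/cell area ratio
      .ellipseMask(size, cx + stats::runif(1, -2, 2),
                   cy + stats::runif(1, -2, 2), rn, rn)
    },
    "1" = {                                  # monocyte: kidney/bean nucleus
      rn <- r * stats::runif(1, 0.60, 0.68)
      th <- stats::runif(1, 0, 2 * pi)
      body <- .ellipseMask(size, cx, cy, rn, rn * stats::runif(1, 0.85, 1),
                           stats::runif(1, 0, pi))
      bite <- .ellipseMask(size, cx + 0.75 * rn * cos(th),
                           cy + 0.75 * rn * sin(th),
                           0.5 * rn, 0.5 * rn)
      body & !bite
    },
    "2" = {                                  # neutrophil: 2-5 separate lobes
      k <- sample(2:5, 1)
      rot <- stats::runif(1, 0, 2 * pi)
      lobes <- matrix(FALSE, size, size)
      for (li in seq_len(k)) {
        th <- rot + (li - 1) * 2 * pi / k + stats::runif(1, -0.08, 0.08)
        d <- r * stats::runif(1, 0.42, 0.5)
        rl <- r * stats::runif(1, 0.17, 0.22)
        lobes <- lobes | .ellipseMask(size, cx + d * cos(th),
                                      cy + d * sin(th), rl, rl)
      }
      lobes
    },
    stop("classId must be 0 (lymphocyte), 1 (monocyte) or 2 (neutrophil)",
         call. = FALSE))
  nuc & cell
}

#' Render one synthetic lensless cell image
#'
#' Draws a cell with class-consistent nucleus morphology, applies Gaussian
#' blur and additive noise, and clips to \[0, 1\]. The returned mask is the
#' pre-noise cell support. With zero blur and zero noise the mask equals
#' the support of pixels above background exactly.
#'
#' @param classId 0 = lymphocyte, 1 = monocyte, 2 = neutrophil
#' @param params generator parameters from [syntheticCellParams()]
#' @param seed optional integer; when given the image is a pure function
#'   of (classId, params, seed)
#' @return list with `image` and binary `mask` matrices
#' @export
generateCellImage <- function(classId, params = syntheticCellParams(),
                              seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  size <- params$imageSize
  clumpProb <- if (is.null(params$clumpProb)) 0 else params$clumpProb
  nCells <- if (stats::runif(1) < clumpProb) sample(2:3, 1) else 1L
  cell <- matrix(FALSE, size, size)
  nuc <- matrix(FALSE, size, size)
  baseAngle <- stats::runif(1, 0, 2 * pi)
  for (ci in seq_len(nCells)) {
    r <- stats::runif(1, params$radiusRange[1], params$radiusRange[2])
    # clumped cells sit around the centre at touching distance
    off <- if (nCells == 1L) c(0, 0)
           else 1.05 * r * c(cos(baseAngle + (ci - 1) * 2 * pi / nCells),
                             sin(baseAngle + (ci - 1) * 2 * pi / nCells))
    cx <- size / 2 + off[1] +
      stats::runif(1, -params$centerJitter, params$centerJitter)
    cy <- size / 2 + off[2] +
      stats::runif(1, -params$centerJitter, params$centerJitter)
    body <- .ellipseMask(size, cx, cy, r, r * stats::runif(1, 0.88, 1),
                         stats::runif(1, 0, pi))
    cell <- cell | body
    nuc <- nuc | .nucleusMask(classId, size, cx, cy, r, body)
  }
  gr <- if (is.null(params$gainRange)) c(1, 1) else params$gainRange
  fp <- if (is.null(params$flashProb)) 0 else params$flashProb
  if (stats::runif(1) < fp) gr <- params$flashRange
  gain <- stats::runif(1, gr[1], gr[2])
  img <- matrix(gain * params$background, size, size)
  img[cell] <- gain * params$cytoplasm
  img[nuc] <- gain * params$nucleusIntensity[classId + 1L]
  if (params$blurSigma > 0)
    img <- EBImage::imageData(EBImage::gblur(img, sigma = params$blurSigma))
  if (params$noiseSd > 0)
    img <- img + matrix(stats::rnorm(size^2, sd = params$noiseSd), size, size)
  list(image = .clamp(img, 0, 1), mask = cell * 1)
}

#' Generate a seeded, stratified synthetic cell dataset
#'
#' `3 * nPerClass` images with ground-truth masks and labels, split into
#' disjoint train/test subsets per class by index. Fully deterministic
#' under the seed: each image gets its own sub-seed drawn from the seeded
#' master stream, with no time or platform dependence.
#'
#' @param nPerClass images per class (>= 1)
#' @param params generator parameters from [syntheticCellParams()]
#' @param seed master integer seed
#' @param trainFrac fraction of each class tagged "train"
#' @return a [CellImageSet-class]
#' @export
generateDataset <- function(nPerClass, params = syntheticCellParams(),
                            seed = 1L, trainFrac = 0.7) {
  if (!.isCount(nPerClass)) stop("nPerClass must be a positive integer",
                                 call. = FALSE)
  set.seed(as.integer(seed))
  n <- 3L * as.integer(nPerClass)
  subseeds <- sample.int(.Machine$integer.max, n)
  labels <- rep(0:2, each = nPerClass)
  images <- vector("list", n)
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    cellImg <- generateCellImage(labels[i], params, seed = subseeds[i])
    images[[i]] <- cellImg$image
    masks[[i]] <- cellImg$mask
  }
  new("CellImageSet", images = images, masks = masks,
      labels = as.integer(labels), split = .splitTags(labels, trainFrac),
      seed = as.integer(seed), params = params)
}

#' @rdname cellset-accessors
#' @export
setMethod("cellImages", "CellImageSet", function(object) object@images)

#' @rdname cellset-accessors
#' @export
setMethod("cellMasks", "CellImageSet", function(object) object@masks)

#' @rdname cellset-accessors
#' @export
setMethod("cellLabels", "CellImageSet", function(object) object@labels)

#' @rdname cellset-accessors
#' @export
setMethod("datasetSplit", "CellImageSet", function(object) object@split)

setMethod("show", "CellImageSet", function(object) {
  cat(sprintf("CellImageSet: %d images (%s), seed %d\n",
              length(object@images),
              paste(sprintf("%s: %d", c("lymphocyte", "monocyte", "neutrophil"),
                            tabulate(object@labels + 1L, 3L)), collapse = ", "),
              object@seed))
  cat(sprintf("  split: %d train / %d test; image size %d px\n",
              sum(object@split == "train"), sum(object@split == "test"),
              object@params$imageSize))
})
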