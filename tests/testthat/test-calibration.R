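test_that("calibration statistics are exact min/max over the image set", {
  m <- toyConvModel(kernels = 2L, seed = 41)
  # a single constant image gives a degenerate input range
  st1 <- collectStats(m, list(matrix(0.5, 8, 8)))
  expect_identical(st1@input, c(0.5, 0.5))

  imgs <- randomImages(5, seed = 42)
  stA <- collectStats(m, imgs)
  stB <- collectStats(m, rev(imgs))           # permutation invariance
  expect_identical(stA@input, stB@input)
  expect_identical(stA@layers, stB@layers)

  # adding an image can only widen every range
  stMore <- collectStats(m, c(imgs, randomImages(3, seed = 43)))
  expect_lte(stMore@input[1], stA@input[1])
  expect_gte(stMore@input[2], stA@input[2])
  for (li in seq_along(stA@layers)) {
    expect_lte(stMore@layers[[li]]$conv[1], stA@layers[[li]]$conv[1])
    expect_gte(stMore@layers[[li]]$conv[2], stA@layers[[li]]$conv[2])
    expect_gte(stMore@layers[[li]]$out[2], stA@layers[[li]]$out[2])
  }

  expect_error(collectStats(m, list()), "at least one")
})

test_that("per-kernel weight ranges give per-kernel scales", {
  # hand-picked ranges [-1, 1] and [-0.5, 0.5] -> scales 1/127 and 1/254
  m <- toyConvModel(kernels = 2L, seed = 44)
  W <- array(0, dim = c(3, 3, 1, 2))
  W[, , 1, 1] <- seq(-1, 1, length.out = 9)
  W[, , 1, 2] <- seq(-0.5, 0.5, length.out = 9)
  m@layers[[1]]$W <- W
  qm <- toyQuantized(m, seed = 45)$qmodel
  expect_equal(realScale(qm@layers[[1]]$kernels[[1]]@wparams), 1 / 127)
  expect_equal(realScale(qm@layers[[1]]$kernels[[2]]@wparams), 1 / 254)
})

test_that("identical kernels yield identical unification constants", {
  m <- toyConvModel(kernels = 3L, seed = 46)
  W1 <- m@layers[[1]]$W[, , , 1]
  for (k in 2:3) m@layers[[1]]$W[, , , k] <- W1
  m@layers[[1]]$b[] <- m@layers[[1]]$b[1]
  qm <- toyQuantized(m, seed = 47)$qmodel
  ks <- qm@layers[[1]]$kernels
  for (k in 2:3) {
    expect_identical(ks[[k]]@sUni, ks[[1]]@sUni)
    expect_identical(ks[[k]]@nUni, ks[[1]]@nUni)
    expect_identical(ks[[k]]@oConv, ks[[1]]@oConv)
    expect_identical(ks[[k]]@qweights, ks[[1]]@qweights)
  }
})

test_that("dequantized int8 weights reproduce float weights within half a step", {
  # symmetric kernel ranges: the offset-free weight rule (no o term) maps
  # an asymmetric range's longer side into saturation, so the half-step
  # roundtrip bound is stated for symmetric kernels
  m <- toyConvModel(kernels = 2L, seed = 48)
  for (k in 1:2) {
    a <- max(abs(m@layers[[1]]$W[, , , k]))
    m@layers[[1]]$W[1, 1, 1, k] <- -a
    m@layers[[1]]$W[3, 3, 1, k] <- a
  }
  qm <- toyQuantized(m, seed = 49)$qmodel
  for (ki in 1:2) {
    k <- qm@layers[[1]]$kernels[[ki]]
    back <- as.vector(k@qweights) * realScale(k@wparams)
    expect_lte(max(abs(back - as.vector(m@layers[[1]]$W[, , , ki]))),
               realScale(k@wparams) / 2 + 1e-12)
  }
})

test_that("quantize_model recovers scales from a model on a known int8 grid", {
  # weights constructed as integer multiples of a known grid step, with
  # the extreme codes +-127 present so the min/max rule sees the full range
  set.seed(50)
  for (rep in 1:5) {
    g <- exp(stats::runif(1, log(1e-4), log(0.1)))   # true grid step
    codes <- c(-127, 127, sample(-126:126, 7))
    m <- toyConvModel(kernels = 1L, seed = 50 + rep)
    m@layers[[1]]$W <- array(codes * g, dim = c(3, 3, 1, 1))
    qm <- toyQuantized(m, seed = 60 + rep)$qmodel
    k <- qm@layers[[1]]$kernels[[1]]
    # exact real scale recovered exactly; encoded mantissa within its bound
    expect_equal(realScale(k@wparams), g)
    expect_lt(abs(k@wparams@s * 2^-k@wparams@n - g) / g, 1 / 127)
    # and the quantized taps are exactly the constructed codes
    expect_identical(as.vector(k@qweights), codes)
  }
})

test_that("every symbol of the quantization algebra is retrievable", {
  m <- toyConvModel(kernels = 2L, seed = 51, hasBN = TRUE, m = c(0.9, 1.2))
  cst <- layerConstants(toyQuantized(m, seed = 52)$qmodel, 1)
  needed <- c("s_d", "n_d", "o_d", "s_w", "n_w", "o_conv", "s_uni", "n_uni",
              "o_uni", "s_tgt", "n_tgt", "o_tgt", "s_b", "n_b", "sft", "q_b",
              "s_m", "n_m", "q_m", "s_out", "n_out", "o_out")
  for (nm in needed) expect_false(is.null(cst[[nm]]), info = nm)
  expect_length(cst$s_w, 2)
  expect_length(cst$q_m, 2)
})

test_that("batch-norm multipliers share one shift and honor the code bound", {
  m <- toyConvModel(kernels = 3L, seed = 53, hasBN = TRUE,
                    m = c(0.25, 1.0, 3.7))
  qm <- toyQuantized(m, seed = 54)$qmodel
  bn <- qm@layers[[1]]$bn
  expect_length(bn@nm, 1)
  expect_lte(max(abs(bn@qm)), 127)
  expect_equal(bn@qm * 2^-bn@nm, c(0.25, 1.0, 3.7), tolerance = 0.01)
})

test_that("stats must cover every layer", {
  m <- toyConvModel(kernels = 2L, seed = 55)
  st <- collectStats(m, randomImages(3, seed = 56))
  broken <- new("CalibStats", input = st@input, layers = list(),
                nImages = st@nImages)
  expect_error(quantizeModel(m, broken), "every layer")
})

test_that("the bit-width sweep reports float and per-width accuracy", {
  set.seed(57)
  imgs <- c(lapply(1:6, function(i) matrix(stats::runif(64, 0, 0.4), 8, 8)),
            lapply(1:6, function(i) matrix(stats::runif(64, 0.5, 1), 8, 8)))
  ds <- tinyImageSet(imgs, labels = rep(c(0L, 1L), each = 6),
                     split = rep(c("train", "test"), 6))
  m <- buildWbcModel(inputSize = 8L, kernels = 2L, classes = 2L, seed = 58,
                     classNames = c("dim", "bright"))
  fit <- trainFloat(m, ds, lr = 0.02, epochs = 5, seed = 59)
  tab <- bitwidthSweep(fit$model, ds, widths = c(8, 4))
  expect_identical(tab$width, c("float", "int8", "int4"))
  expect_true(all(tab$overall >= 0 & tab$overall <= 100))
  expect_identical(ncol(tab), 4L)              # width, overall, 2 classes

  # reproducible under a fixed seed
  tab2 <- bitwidthSweep(fit$model, ds, widths = c(8, 4))
  expect_identical(tab, tab2)

  # CSV report written on request
  f <- withr::local_tempfile(fileext = ".csv")
  bitwidthSweep(fit$model, ds, widths = 8, report = f)
  expect_identical(nrow(utils::read.csv(f)), 2L)
})
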