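test_that("quantized convolution computes the raw integer MAC", {
  # single 1x1 tap: q_w = 127 (real 1.0 at scale 1/127), q_d = 50, o_d = 0
  wp <- quantParams(65, 13, 0, 8, realScale = 1 / 127)
  k <- kernelQuant(array(127, dim = c(1, 1, 1)), wp, oConv = 0,
                   sUni = 64, nUni = 6)
  fp <- quantParams(65, 13, 0, 8, realScale = 1 / 127)
  qfeat <- qTensor(array(50, dim = c(1, 1, 1)), fp, "feature")
  spec <- layerSpec(1, 1, 1, 1, padding = "valid", activation = "none")
  acc <- qconv2d(qfeat, list(k), spec)
  expect_identical(as.vector(qvalues(acc[[1]])), 6350)
  expect_identical(quantRole(acc[[1]]), "accumulator32")

  # all-zero weights annihilate everything
  k0 <- kernelQuant(array(0, dim = c(1, 1, 1)), wp, oConv = 0,
                    sUni = 64, nUni = 6)
  acc0 <- qconv2d(qfeat, list(k0), spec)
  expect_identical(as.vector(qvalues(acc0[[1]])), 0)
})

test_that("the accumulator plus o_conv dequantizes to the real convolution", {
  # two taps: q_w = [1, 1], q_d = [5, 5], o_d = 10
  dRS <- 1 / 64; wRS <- 1 / 32
  fp <- quantParams(64, 12, 10, 8, realScale = dRS)
  wp <- quantParams(64, 11, 0, 8, realScale = wRS)
  k <- kernelQuant(array(c(1, 1), dim = c(1, 2, 1)), wp,
                   oConv = sum(c(1, 1)) * 10, sUni = 64, nUni = 6)
  qfeat <- qTensor(array(c(5, 5), dim = c(1, 2, 1)), fp, "feature")
  spec <- layerSpec(1, 2, 1, 1, padding = "valid", activation = "none")
  acc <- qconv2d(qfeat, list(k), spec)
  expect_identical(as.vector(qvalues(acc[[1]])), 10)
  expect_identical(acc[[1]]@params@o, 20)
  # r_conv = sum over taps of r_w * r_d with r_d = dRS*(q+o), r_w = wRS*q
  rconv <- 2 * (wRS * 1) * (dRS * (5 + 10))
  expect_equal(dequantizeCode(qvalues(acc[[1]]), acc[[1]]@params),
               array(rconv, dim = c(1, 1)))
})

test_that("same-padding uses the quantized zero code so pads mean real zero", {
  # offset 127 (range [0,2]): the zero code is -127; a kernel summing its
  # neighbourhood over a constant image must see real 0 outside the border
  fp <- featureParams(0, 2)                   # o = 127
  wp <- quantParams(64, 6, 0, 8, realScale = 1)
  k <- kernelQuant(array(1, dim = c(3, 3, 1)), wp,
                   oConv = 9 * fp@o, sUni = 64, nUni = 6)
  img <- matrix(1, 4, 4)                       # constant real 1
  qfeat <- qTensor(array(quantizeReal(img, fp), dim = c(4, 4, 1)), fp, "feature")
  spec <- layerSpec(3, 3, 1, 1, padding = "same", activation = "none")
  acc <- qconv2d(qfeat, list(k), spec)
  r <- dequantizeCode(qvalues(acc[[1]]), acc[[1]]@params)
  # interior position sees 9 real units, the corner only 4
  expect_equal(r[2, 2], 9, tolerance = 0.02)
  expect_equal(r[1, 1], 4, tolerance = 0.02)
})

test_that("unification rescales each kernel onto the shared target grid", {
  # ratio 1/2, no offsets
  accP <- quantParams(65 * 65, 26, 0, 8, realScale = 1 / 127^2)
  acc <- new("QTensor", values = array(1000, dim = c(1, 1)), params = accP,
             role = "accumulator32")
  tgt <- quantParams(65, 13, 0, 8, realScale = 2 / 127^2)
  enc <- encodeScale(0.5)
  k <- kernelQuant(array(1, dim = c(1, 1, 1)),
                   quantParams(65, 13, 0, 8, realScale = 1 / 127),
                   oConv = 0, sUni = enc$s, nUni = enc$n)
  out <- unifyToTarget(acc, k, tgt)
  expect_identical(as.vector(qvalues(out)), 500)

  # identity ratio maps represented values onto themselves
  kid <- kernelQuant(array(1, dim = c(1, 1, 1)),
                     quantParams(65, 13, 0, 8, realScale = 1 / 127),
                     oConv = 0, sUni = 64, nUni = 6)
  tgtSame <- quantParams(65 * 65, 26, 0, 8, realScale = 1 / 127^2)
  expect_identical(as.vector(qvalues(unifyToTarget(acc, kid, tgtSame))), 1000)
})

test_that("kernels with different scales agree with the oracle after unify", {
  m <- toyConvModel(kernels = 2L, seed = 5)
  # force different per-kernel ranges
  m@layers[[1]]$W[, , , 2] <- m@layers[[1]]$W[, , , 2] * 0.4
  tq <- toyQuantized(m, width = 8L, seed = 6)
  qm <- tq$qmodel
  img <- tq$images[[2]]
  tr <- runNetwork(qm, img, trace = TRUE)$trace
  l <- qm@layers[[1]]
  intReal <- dequantizeCode(tr$layer1$unified$codes, l$tgtParams)
  orcReal <- fakeQuantForward(qm, img, trace = TRUE)$trace$layer1$unified
  expect_lt(max(abs(intReal - orcReal)), realScale(l$tgtParams) * (1 + 1e-9))
})

test_that("the bias addend adds the bias and leaves an offset-free code", {
  tgt <- quantParams(64, 10, 37, 8, realScale = 2^-10)
  acc <- new("QTensor", values = array(c(-100, 0, 250), dim = c(3, 1, 1)),
             params = tgt, role = "accumulator32")
  # real bias 0: the addend only cancels the offset
  b0 <- biasQuant(qb = 0, sft = 0, addend = 0 * 2^0 + tgt@o, sb = tgt@s,
                  nb = tgt@n)
  out <- addBias(acc, b0)
  expect_identical(out@params@o, 0)
  expect_equal(as.vector(qvalues(out)), c(-100, 0, 250) + 37)
  # offset-free representation: integer sign equals real-value sign
  expect_identical(sign(as.vector(qvalues(out))),
                   sign(as.vector(dequantizeCode(qvalues(out), out@params))))

  # zero accumulator, offsets zero, bias real 1.0 at the accumulator scale
  # with sft = 4: the wide addend is q_b * 16
  tgt0 <- quantParams(64, 10, 0, 8, realScale = 2^-10)
  accZ <- new("QTensor", values = array(0, dim = c(1, 1, 1)), params = tgt0,
              role = "accumulator32")
  qb <- round(1.0 / (2^-10 * 2^4))            # 64
  bq <- biasQuant(qb = qb, sft = 4, addend = qb * 2^4 + 0, sb = 64, nb = 6)
  outZ <- addBias(accZ, bq)
  expect_identical(as.vector(qvalues(outZ)), qb * 16)
  expect_equal(as.vector(dequantizeCode(qvalues(outZ), outZ@params)), 1.0)
})

test_that("bias addition overflowing the 41-bit adder is an error", {
  tgt <- quantParams(64, 10, 0, 8, realScale = 2^-10)
  acc <- new("QTensor", values = array(0, dim = c(1, 1, 1)), params = tgt,
             role = "accumulator32")
  huge <- biasQuant(qb = 127, sft = 34, addend = 127 * 2^34, sb = 64, nb = 6)
  expect_error(addBias(acc, huge), "overflow")
})

test_that("batch-norm multiplication scales codes and tracks the shift", {
  p <- quantParams(64, 10, 0, 8, realScale = 2^-10)
  acc <- new("QTensor", values = array(100, dim = c(1, 1, 1)), params = p,
             role = "wide41")
  # q_m = 64 encodes real 1.0 with n_m = 6
  out <- bnMultiply(acc, bnQuant(64, 6))
  expect_identical(as.vector(qvalues(out)), 6400)
  expect_equal(realScale(out@params), 2^-10 * 2^-6)
  expect_equal(dequantizeCode(qvalues(out), out@params),
               dequantizeCode(qvalues(acc), p))   # real 1.0 multiplier

  # annihilation
  expect_identical(as.vector(qvalues(bnMultiply(acc, bnQuant(0, 0)))), 0)

  # encode_scale error bound: a random multiplier is represented within 1%
  set.seed(8)
  for (i in 1:20) {
    rm <- stats::runif(1, 0.05, 3)
    enc <- encodeScale(rm)
    out <- bnMultiply(acc, bnQuant(enc$s, enc$n))
    got <- dequantizeCode(qvalues(out), out@params)
    want <- dequantizeCode(qvalues(acc), p) * rm
    expect_lt(abs(got - want) / want, 0.01)
  }
})

test_that("integer ReLU matches real ReLU on offset-free codes", {
  p <- quantParams(64, 10, 0, 8, realScale = 2^-10)
  acc <- new("QTensor", values = array(c(-5, 0, 7), dim = c(3, 1, 1)),
             params = p, role = "wide41")
  expect_identical(as.vector(qvalues(reluInt(acc))), c(0, 0, 7))
  allNeg <- new("QTensor", values = array(c(-3, -1), dim = c(2, 1, 1)),
                params = p, role = "wide41")
  expect_identical(as.vector(qvalues(reluInt(allNeg))), c(0, 0))
  # commutes with dequantization
  set.seed(4)
  v <- array(sample(-1000:1000, 24), dim = c(4, 3, 2))
  t <- new("QTensor", values = v, params = p, role = "wide41")
  expect_equal(dequantizeCode(qvalues(reluInt(t)), p),
               pmax(dequantizeCode(v, p), 0))
  # an offset-carrying representation is rejected
  pOff <- quantParams(64, 10, 5, 8, realScale = 2^-10)
  tOff <- new("QTensor", values = v, params = pOff, role = "wide41")
  expect_error(reluInt(tOff), "offset-free")
})

test_that("output quantization narrows the wide result to feature codes", {
  outP <- featureParams(0, 2)                  # o_out = 127
  srcP <- quantParams(64, 12, 0, 8, realScale = 2^-12)
  # a wide code representing exactly r_outmax maps to +qmax
  acc <- new("QTensor", values = array(2 * 2^12, dim = c(1, 1, 1)),
             params = srcP, role = "wide41")
  expect_identical(as.vector(qvalues(outputQuantize(acc, outP))), 127)
  # zero maps to the zero code -o_out
  accZ <- new("QTensor", values = array(0, dim = c(1, 1, 1)), params = srcP,
              role = "wide41")
  expect_identical(as.vector(qvalues(outputQuantize(accZ, outP))), -127)

  # narrowing then dequantizing loses at most half an output step
  set.seed(12)
  v <- array(sample(0:(2 * 2^12), 60), dim = c(60, 1, 1))
  t <- new("QTensor", values = v, params = srcP, role = "wide41")
  q <- outputQuantize(t, outP)
  expect_lt(max(abs(dequantizeCode(qvalues(q), outP) - dequantizeCode(v, srcP))),
            realScale(outP) * 0.51)
})

test_that("integer max pooling halves dims and commutes with dequantization", {
  p <- featureParams(-1, 1)
  v <- array(0, dim = c(2, 2, 1))
  v[, , 1] <- matrix(c(1, 3, 5, 2), 2, 2)      # window [1 5; 3 2]
  t <- qTensor(v, p, "feature")
  expect_identical(as.vector(qvalues(maxpoolInt(t))), 5)

  const <- qTensor(array(7, dim = c(6, 6, 2)), p, "feature")
  pooled <- maxpoolInt(const)
  expect_identical(dim(qvalues(pooled)), c(3L, 3L, 2L))
  expect_true(all(qvalues(pooled) == 7))

  set.seed(3)
  v <- array(sample(-127:127, 8 * 8 * 2, TRUE), dim = c(8, 8, 2))
  t <- qTensor(v, p, "feature")
  want <- array(0, dim = c(4, 4, 2))
  rv <- dequantizeCode(v, p)
  for (ch in 1:2) for (i in 1:4) for (j in 1:4)
    want[i, j, ch] <- max(rv[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), ch])
  expect_equal(dequantizeCode(qvalues(maxpoolInt(t)), p), want)
})

test_that("runNetwork returns a softmax distribution and is deterministic", {
  m <- toyConvModel(kernels = 3L, seed = 11, pool = "max2x2s2")
  tq <- toyQuantized(m, width = 8L, seed = 12)
  img <- tq$images[[1]]
  r1 <- runNetwork(tq$qmodel, img, trace = TRUE)
  r2 <- runNetwork(tq$qmodel, img, trace = TRUE)
  expect_equal(sum(r1$probs), 1)
  expect_true(all(r1$probs >= 0))
  expect_identical(r1$logits, r2$logits)
  expect_identical(r1$trace, r2$trace)          # identical integer trace
})

test_that("a zero-weight network yields uniform class probabilities", {
  m <- toyConvModel(kernels = 3L, seed = 2)
  m@layers[[1]]$W[] <- 0
  m@layers[[1]]$b[] <- 0
  tq <- toyQuantized(m, width = 8L, seed = 3)
  r <- runNetwork(tq$qmodel, matrix(0, 8, 8))
  # equal logits everywhere -> exactly uniform distribution
  expect_equal(unname(r$probs), rep(1 / length(r$probs), length(r$probs)))
})

test_that("integer-path argmax agrees with the oracle on nearly all images", {
  m <- toyConvModel(kernels = 3L, inputSize = 16L, seed = 21, pool = "max2x2s2")
  tq <- toyQuantized(m, width = 8L, seed = 22)
  set.seed(23)
  agree <- 0L
  n <- 300L
  for (i in seq_len(n)) {
    img <- matrix(stats::runif(256), 16, 16)
    a <- runNetwork(tq$qmodel, img)$class
    b <- fakeQuantForward(tq$qmodel, img)$class
    agree <- agree + (a == b)
  }
  expect_gte(agree / n, 0.98)
})

test_that("shape mismatches are rejected", {
  m <- toyConvModel(kernels = 2L, seed = 1)
  tq <- toyQuantized(m, seed = 2)
  expect_error(runNetwork(tq$qmodel, matrix(0, 5, 5)), "dims")
})

test_that("the per-stage trace dumps to CSV", {
  m <- toyConvModel(kernels = 2L, seed = 31)
  tq <- toyQuantized(m, seed = 32)
  dir <- withr::local_tempdir()
  files <- dumpTrace(tq$qmodel, tq$images[[1]], dir)
  expect_true(all(file.exists(files)))
  tab <- utils::read.csv(files[1])
  expect_true(all(tab$code == round(tab$code)))
})
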