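test_that("bit-width configurations have symmetric code ranges", {
  cfg8 <- bitWidthConfig(8)
  expect_identical(qMax(cfg8), 127)
  expect_identical(cfg8@denom, 254)
  for (X in 2:8) {
    cfg <- bitWidthConfig(X)
    expect_equal(qMax(cfg), 2^(X - 1) - 1)
    expect_equal(cfg@denom, 2 * qMax(cfg))
  }
  expect_error(bitWidthConfig(9), "width")
  expect_error(bitWidthConfig(1), "width")
})

test_that("feature parameters map the calibrated range onto [-qmax, qmax]", {
  p <- featureParams(-1, 1, bitWidthConfig(8))
  expect_equal(realScale(p), 1 / 127)
  expect_identical(p@o, 0)

  # range not centred on zero: offset shifts the grid so that the
  # endpoints land on -127 / +127
  p2 <- featureParams(0, 2, bitWidthConfig(8))
  expect_equal(realScale(p2), 1 / 127)
  expect_identical(p2@o, 127)
  expect_identical(quantizeReal(0, p2), -127)
  expect_identical(quantizeReal(2, p2), 127)

  # generalized denominator at 4 bits: 2 * (2^3 - 1) = 14
  p3 <- featureParams(-1, 1, bitWidthConfig(4))
  expect_equal(realScale(p3), 1 / 7)
  expect_identical(p3@o, 0)

  expect_error(featureParams(1, -1), "range")
  expect_error(featureParams(NaN, 1), "range")
  expect_error(featureParams(-Inf, 1), "range")
})

test_that("range endpoints quantize to the extreme codes within one count", {
  set.seed(42)
  cfg <- bitWidthConfig(8)
  for (i in 1:50) {
    lo <- stats::runif(1, -10, 5)
    hi <- lo + stats::runif(1, 0.01, 20)
    p <- featureParams(lo, hi, cfg)
    expect_lte(abs(quantizeReal(hi, p) - 127), 1)
    expect_lte(abs(quantizeReal(lo, p) - (-127)), 1)
  }
})

test_that("weight parameters never carry an offset", {
  p <- weightParams(-1, 1, bitWidthConfig(8))
  expect_equal(realScale(p), 1 / 127)
  expect_identical(p@o, 0)
  expect_equal(realScale(weightParams(-0.5, 0.5)), 1 / 254)
  set.seed(7)
  for (i in 1:25) {
    r <- stats::runif(1, 0.01, 50)
    expect_identical(weightParams(-r, r)@o, 0)
  }
})

test_that("degenerate (constant) ranges quantize to a single code", {
  p <- featureParams(3, 3, bitWidthConfig(8))
  expect_equal(realScale(p), 1)
  expect_identical(quantizeReal(3, p), 0)
  # constant zero as well
  p0 <- featureParams(0, 0, bitWidthConfig(8))
  expect_identical(quantizeReal(0, p0), 0)
})

test_that("encodeScale matches its worked examples", {
  cfg <- bitWidthConfig(8)
  e1 <- encodeScale(1.0, cfg)
  expect_identical(c(e1$s, e1$n), c(64, 6))
  expect_identical(e1$value, 1)

  e2 <- encodeScale(0.5, cfg)
  expect_identical(c(e2$s, e2$n), c(64, 7))

  # 2^13/127 = 64.50... rounds away from zero
  e3 <- encodeScale(1 / 127, cfg)
  expect_identical(c(e3$s, e3$n), c(65, 13))
  expect_lt(abs(e3$value - 1 / 127) * 127, 0.01)

  expect_error(encodeScale(0, cfg), "scale")
  expect_error(encodeScale(-2, cfg), "scale")
})

test_that("encodeScale achieves the exhaustive-search optimum", {
  # independent oracle: try every mantissa and every shift
  bruteBest <- function(v, qmax) {
    best <- Inf
    for (n in -31:31) {
      err <- abs((1:qmax) * 2^-n - v)
      best <- min(best, min(err))
    }
    best
  }
  set.seed(123)
  vs <- exp(stats::runif(1000, log(1e-6), log(100)))
  cfg <- bitWidthConfig(8)
  for (v in vs) {
    enc <- encodeScale(v, cfg)
    expect_lte(abs(enc$value - v), bruteBest(v, 127) + 1e-15 * v)
  }
})

test_that("quantize saturates and roundtrips within half a step", {
  p <- quantParams(65, 13, 0, 8, realScale = 1 / 127)
  expect_identical(quantizeReal(1.0, p), 127)
  expect_identical(quantizeReal(0, p), 0)
  expect_identical(quantizeReal(2.0, p), 127)    # saturation
  expect_identical(quantizeReal(-2.0, p), -127)

  expect_equal(dequantizeCode(127, p), 1.0)
  pOff <- quantParams(65, 13, 127, 8, realScale = 1 / 127)
  expect_equal(dequantizeCode(0, pOff), 1.0)

  set.seed(9)
  for (i in 1:200) {
    r <- stats::runif(1, -1, 1)
    expect_lte(abs(dequantizeCode(quantizeReal(r, p), p) - r),
               realScale(p) / 2 + 1e-12)
  }
})

test_that("requantize converts codes between representations in integers", {
  src <- quantParams(65, 13, 0, 8, realScale = 1 / 127)
  dstHalf <- quantParams(65, 12, 0, 8, realScale = 2 / 127)
  dstOff <- quantParams(65, 13, 27, 8, realScale = 1 / 127)

  # identity
  for (q in c(-127, -5, 0, 50, 127))
    expect_identical(requantizeCode(q, src, src), q)
  # halving the scale halves the code
  expect_identical(requantizeCode(100, src, dstHalf), 50)
  # same scale, destination offset shifts the code
  expect_identical(requantizeCode(100, src, dstOff), 73)
})

test_that("requantize composed with its inverse returns the code within one count", {
  # the lossless domain: the intermediate grid is at least as fine as the
  # source grid (no coarsening) and codes stay inside the clamp range
  set.seed(31)
  for (i in 1:100) {
    hi <- stats::runif(1, 0.1, 3)
    a <- featureParams(-hi, hi)
    shrink <- stats::runif(1, 0.5, 1)
    b <- featureParams(-hi * shrink, hi * shrink)
    q <- sample(-60:60, 1)
    back <- requantizeCode(requantizeCode(q, a, b), b, a)
    expect_lte(abs(back - q), 1)
  }
})

test_that("quantization operations are pure", {
  p <- featureParams(-1.3, 2.7)
  q1 <- quantizeReal(c(-1, 0, 0.5, 2), p)
  q2 <- quantizeReal(c(-1, 0, 0.5, 2), p)
  expect_identical(q1, q2)
  e1 <- encodeScale(0.123)
  e2 <- encodeScale(0.123)
  expect_identical(e1, e2)
})

test_that("quantization parameters survive a serialization roundtrip", {
  p <- featureParams(-0.7, 1.9, bitWidthConfig(6))
  p2 <- paramsFromList(paramsToList(p))
  expect_identical(p2@s, p@s)
  expect_identical(p2@n, p@n)
  expect_identical(p2@o, p@o)
  expect_identical(realScale(p2), realScale(p))
  expect_identical(bitWidth(p2), bitWidth(p))
})

test_that("QTensor validity enforces the stage width contracts", {
  p <- featureParams(-1, 1)
  expect_s4_class(qTensor(c(-127, 0, 127), p, "feature"), "QTensor")
  expect_error(qTensor(c(-128, 0), p, "feature"), "range")
  expect_error(qTensor(2^31, p, "accumulator32"), "range")
  expect_error(qTensor(0.5, p, "feature"), "integers")
  big <- qTensor(2^33, p, "wide41")
  expect_identical(quantRole(big), "wide41")
})
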