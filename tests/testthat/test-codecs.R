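test_that("unary coding matches the worked examples", {
  expect_identical(bit_string(unary_encode(4)), "11110")
  expect_identical(bit_string(unary_encode(2)), "110")
  expect_identical(bit_string(unary_encode(0)), "0")
  expect_error(unary_encode(-1), "non-negative")
  d <- unary_decode(bitstream("11110"))
  expect_identical(d$value, 4L)
  expect_identical(d$bits_consumed, 5L)
})

test_that("truncated binary matches the worked examples", {
  # m = 3: k = 1, one short codeword (2^2 - 3 = 1)
  expect_identical(bit_string(truncbin_encode(0, 3)), "0")
  expect_identical(bit_string(truncbin_encode(1, 3)), "10")
  expect_identical(bit_string(truncbin_encode(2, 3)), "11")
  expect_identical(bit_string(truncbin_encode(0, 1)), "")
  expect_error(truncbin_encode(3, 3), "out of range")
  for (m in 1:9) {
    for (r in 0:(m - 1)) {
      enc <- truncbin_encode(r, m)
      d <- truncbin_decode(enc, m)
      expect_identical(d$value, r)
      expect_identical(d$bits_consumed, length(enc))
    }
  }
})

test_that("Golomb coding reproduces the worked example and inverts", {
  expect_identical(bit_string(golomb_encode(7, 3)), "11010")
  expect_identical(golomb_decode("11010", 3)$value, 7L)
  expect_identical(bit_string(golomb_encode(0, 3)), "00")
  # n = 1000, m = 2: quotient 500 takes 501 unary bits
  enc <- golomb_encode(1000, 2)
  expect_identical(length(unary_encode(1000 %/% 2)), 501L)
  expect_gte(length(enc), 501L)
  expect_identical(golomb_decode(enc, 2)$value, 1000L)
  expect_error(golomb_encode(5, 0), "positive integer")
})

test_that("extended Golomb coding reproduces the worked examples and inverts", {
  expect_identical(bit_string(extended_golomb_encode(7, 3)), "110110")
  expect_identical(extended_golomb_decode("110110", 3)$value, 7)
  # reserved M = 0 codeword for the integer 0
  expect_identical(bit_string(extended_golomb_encode(0, 3)), "0")
  expect_identical(extended_golomb_decode("0", 3)$value, 0L)
  # single iteration: 1 = 0*3 + 1
  expect_identical(bit_string(extended_golomb_encode(1, 3)), "100")
  expect_identical(extended_golomb_decode("100", 3)$value, 1)
  expect_error(extended_golomb_encode(5, 1), "m >= 2")
  # the iterated-division rule on n = 1000, m = 2 yields M = 10 iterations
  # and a codeword far shorter than Golomb's >= 501 bits
  eg <- extended_golomb_encode(1000, 2)
  expect_identical(unary_decode(eg)$value, 10L)
  expect_lt(length(eg), 501L)
})

test_that("codec round trips hold over a dense integer sample for all divisors", {
  set.seed(101)
  ns <- as.integer(unique(c(0:64, 2^(7:19), sample.int(1e6, 300))))
  for (m in 1:8) {
    e <- metarc:::cpp_golomb_encode(ns, m)
    d <- metarc:::cpp_golomb_decode(e$bytes, e$nbits, m, length(ns))
    expect_identical(d$values, ns)
    expect_identical(d$bits_consumed, e$nbits)
    if (m >= 2) {
      e <- metarc:::cpp_egolomb_encode(ns, m)
      d <- metarc:::cpp_egolomb_decode(e$bytes, e$nbits, m, length(ns))
      expect_identical(d$values, ns)
      expect_identical(d$bits_consumed, e$nbits)
    }
  }
})

test_that("the scalar R codecs and the C++ stream codecs agree codeword-for-codeword", {
  set.seed(11)
  v <- c(0L, 1L, sample.int(5000L, 40))
  for (m in c(1L, 3L, 7L)) {
    e <- metarc:::cpp_golomb_encode(v, m)
    bits <- unpack_bits(e$bytes, e$nbits)
    expect_identical(
      bit_string(bits),
      paste(vapply(v, function(n) bit_string(golomb_encode(n, m)), character(1)), collapse = "")
    )
    off <- 1L
    for (n in v) {
      r <- golomb_decode(bits, m, off)
      expect_identical(r$value, n)
      off <- off + r$bits_consumed
    }
    expect_identical(off - 1L, as.integer(e$nbits))
  }
  for (m in c(2L, 3L, 5L)) {
    e <- metarc:::cpp_egolomb_encode(v, m)
    expect_identical(
      bit_string(unpack_bits(e$bytes, e$nbits)),
      paste(vapply(v, function(n) bit_string(extended_golomb_encode(n, m)), character(1)),
        collapse = ""
      )
    )
  }
})

test_that("the Rice parameter matches high-precision evaluation of the closed form", {
  # expected values frozen from a 60-digit evaluation of
  # max(0, 1 + floor(log2(log(phi-1) / log(mu/(mu+1)))))
  expected <- c(
    "0.1" = 0L, "0.5" = 0L, "1" = 0L, "2" = 1L, "5.5" = 2L,
    "10" = 3L, "100" = 6L, "1234.5" = 10L, "1e+06" = 19L
  )
  for (mu in names(expected)) {
    expect_identical(rice_parameter(as.numeric(mu)), expected[[mu]])
  }
  expect_identical(rice_parameter(1e-9), 0L) # clamped at zero as mu -> 0+
  expect_error(rice_parameter(0), "positive")
})

test_that("Golomb with m = 2^k* is near-optimal for geometric data", {
  set.seed(21)
  for (mu in c(4, 20, 120)) {
    x <- as.integer(rgeom(20000, 1 / mu))
    k <- rice_parameter(mean(x))
    len_at <- function(kk) metarc:::cpp_golomb_encode(x, as.integer(2^kk))$nbits
    expect_lte(len_at(k), len_at(k + 1L))
    if (k >= 1L) expect_lte(len_at(k), len_at(k - 1L))
  }
})

test_that("zigzag maps signed integers to non-negative and back", {
  v <- c(0L, -1L, 1L, -2L, 2L, -1000L, 1000L, .Machine$integer.max %/% 2L)
  expect_identical(zigzag_encode(v), c(0L, 1L, 2L, 3L, 4L, 1999L, 2000L, 2147483646L))
  expect_identical(zigzag_decode(zigzag_encode(v)), v)
})

test_that("decoding a truncated stream signals an error", {
  expect_error(golomb_decode("111", 3), "exhausted")
  expect_error(extended_golomb_decode("11", 3), "exhausted")
  expect_error(
    metarc:::cpp_golomb_decode(pack_bits(bitstream("11"))$bytes, 2, 3L, 1),
    "exhausted"
  )
})
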