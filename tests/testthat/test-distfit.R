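test_that("coverage truncation keeps the smallest sufficient maximum", {
  expect_identical(truncate_at_coverage(1:10, 0.9), 1:9)
  expect_identical(truncate_at_coverage(1:10, 1.0), 1:10)
  expect_identical(truncate_at_coverage(rep(5L, 20), 0.5), rep(5L, 20))
  expect_error(truncate_at_coverage(1:10, 0), "coverage")
  expect_error(truncate_at_coverage(1:10, 1.5), "coverage")
  # never removes more than (1 - coverage) of the data
  set.seed(88)
  for (trial in 1:20) {
    x <- sample.int(1000L, 500, replace = TRUE)
    cov <- runif(1, 0.5, 1)
    expect_gte(length(truncate_at_coverage(x, cov)), cov * length(x))
  }
})

test_that("the power-law weight matches its closed form and decreases in i", {
  for (m in 2:5) expect_equal(power_law_pmf(1, m), 1 / (2 * (m - 1)))
  expect_equal(power_law_pmf(3, 3), 1 / 24) # 2^(-1) / 12
  for (m in 2:4) {
    w <- power_law_pmf(1:10000, m)
    expect_true(all(diff(w) < 0))
  }
  expect_error(power_law_pmf(0, 3), "support")
})

test_that("geometric fits recover parameters and match the closed form", {
  expect_equal(fit_geometric(rep(1L, 50))$p, 1)
  set.seed(99)
  x <- rgeom(1e5, 0.2) + 1L
  expect_lt(abs(fit_geometric(x, "mle")$p - 0.2), 0.01)
  expect_lt(abs(fit_geometric(x, "least_squares")$p - 0.2), 0.02)
  expect_equal(fit_geometric(x, "mle")$p, 1 / mean(x))
  expect_error(fit_geometric(integer()), "empty")
})

test_that("negative binomial MLE recovers (r, p) within 10%", {
  set.seed(100)
  x <- rnbinom(1e5, size = 5, prob = 0.3) + 1L
  fit <- fit_negbin(x)
  expect_lt(abs(fit$r - 5) / 5, 0.10)
  expect_lt(abs(fit$p - 0.3) / 0.3, 0.10)
  expect_lt(abs(fit$mu - mean(x)) / mean(x), 0.01)
  expect_error(fit_negbin(rep(3L, 10)), "degenerate")
  # underdispersed input cannot be negative binomial
  set.seed(101)
  y <- rbinom(5000, 10, 0.5) + 1L
  expect_error(fit_negbin(y), "overdispersion")
})

test_that("recommend_codec picks Golomb for geometric and extended Golomb for power-law data", {
  set.seed(102)
  geo <- rgeom(2e4, 0.05) + 1L
  expect_identical(recommend_codec(geo)$codec, "golomb")

  N <- 20000L
  w <- power_law_pmf(seq_len(N), 3)
  pl <- sample.int(N, 2e4, replace = TRUE, prob = w / sum(w))
  rec <- recommend_codec(pl)
  expect_identical(rec$codec, "extended_golomb")
  expect_identical(rec$archival, "huffman")

  expect_identical(recommend_codec(rep(7L, 10))$codec, "huffman")
})

test_that("histograms export as plain (integer, count) text", {
  td <- withr::local_tempdir()
  p <- export_histogram(c(1L, 1L, 3L), file.path(td, "h.tsv"))
  h <- utils::read.delim(p)
  expect_identical(h$integer, c(1L, 3L))
  expect_identical(h$count, c(2L, 1L))
})
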