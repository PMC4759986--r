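test_that("reference and read generation is fully deterministic under the seed", {
  spec <- community_spec(n_species = 3, genome_length = 5000, n_reads = 400, seed = 5)
  expect_identical(make_references(spec), make_references(spec))
  refs <- make_references(spec)
  s1 <- simulate_reads(refs, spec)
  s2 <- simulate_reads(refs, spec)
  expect_identical(s1, s2)
  expect_identical(nchar(refs), stats::setNames(rep(5000L, 3), names(refs)))
  # zero species -> empty set; zero reads -> empty outputs
  expect_length(make_references(community_spec(n_species = 0, n_reads = 0)), 0L)
  s0 <- simulate_reads(refs, community_spec(n_species = 3, genome_length = 5000, n_reads = 0, seed = 5))
  expect_identical(nrow(s0$reads1), 0L)
  expect_error(community_spec(genome_length = 50, read_length = 100), "at least the read length")
})

test_that("zero error rate yields exact reference substrings", {
  sm <- small_sim(n_species = 2, n_reads = 200, seed = 9, error_rate = 0)
  p <- parse_sam(sm$sim$sam, sm$refs)
  expect_identical(nrow(p$aligned$variations), 0L)
})

test_that("species read fractions track abundance weights at large n", {
  spec <- community_spec(
    n_species = 4, genome_length = 20000,
    abundance = c(0.4, 0.3, 0.2, 0.1), n_reads = 1e5, seed = 12
  )
  refs <- make_references(spec)
  sim <- simulate_reads(refs, spec)
  frac <- sim$taxonomy / sum(sim$taxonomy)
  # equal genome lengths: sampling weight reduces to the abundance itself
  expect_true(all(abs(frac - c(0.4, 0.3, 0.2, 0.1)) < 0.02))
})

test_that("the empirical mismatch rate matches the configured 1%", {
  sm <- small_sim(n_reads = 20000L, seed = 14L)
  p <- parse_sam(sm$sim$sam, sm$refs)
  rate <- nrow(p$aligned$variations) / sum(p$aligned$reads$read_len)
  expect_lt(abs(rate - 0.01), 0.002)
})

test_that("generated taxonomy reports invert through parse_report", {
  counts <- stats::setNames(c(600L, 250L, 150L), c("101", "102", "103"))
  rep_lines <- make_kraken_report(counts)
  e <- parse_report(rep_lines)
  sp <- e[e$is_species, ]
  expect_identical(stats::setNames(sp$clade_reads, as.character(sp$taxid)), counts)
  # empty counts -> root line only; single species -> one species line
  expect_identical(sum(parse_report(make_kraken_report(
    stats::setNames(integer(), character())
  ))$is_species), 0L)
  one <- parse_report(make_kraken_report(stats::setNames(42L, "107")))
  expect_identical(one$clade_reads[one$is_species], 42L)
})
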