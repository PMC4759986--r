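test_that("mate labeling and splitting are exact inverses", {
  td <- withr::local_tempdir()
  r1 <- data.frame(id = c("x.1", "x.2"), seq = c("ACGT", "GGGG"), stringsAsFactors = FALSE)
  r2 <- data.frame(id = c("x.1", "x.2"), seq = c("TTTT", "CCCC"), stringsAsFactors = FALSE)
  f1 <- file.path(td, "a.fasta")
  f2 <- file.path(td, "b.fasta")
  write_fasta(r1, f1)
  write_fasta(r2, f2)
  lab <- label_mates(f1, f2)
  expect_identical(lab$id, c("x.1_1", "x.2_1", "x.1_2", "x.2_2"))
  back <- split_mates(lab)
  expect_identical(back[[1]], r1)
  expect_identical(back[[2]], r2)
  # count mismatch errors
  write_fasta(r1[1, ], f2)
  expect_error(label_mates(f1, f2), "disagree")
  # empty pair -> empty stream
  writeLines(character(), f1)
  writeLines(character(), f2)
  expect_identical(nrow(label_mates(f1, f2)), 0L)
})

test_that("strip_quality converts FASTQ to FASTA plus a quality sidecar", {
  td <- withr::local_tempdir()
  fq <- file.path(td, "x.fastq")
  writeLines(c(
    "@r.1 desc", "ACGTN", "+", "IIIII",
    "@r.2", "TTAA", "+", "FFFA"
  ), fq)
  fa <- file.path(td, "x.fasta")
  strip_quality(fq, fa)
  out <- read_seqs(fa)
  expect_identical(out$id, c("r.1", "r.2"))
  expect_identical(out$seq, c("ACGTN", "TTAA"))
  expect_identical(readLines(paste0(fa, ".qual")), c("IIIII", "FFFA"))
  # malformed records
  writeLines(c("@r", "ACGT", "+"), fq)
  expect_error(strip_quality(fq, fa), "multiple of 4")
  writeLines(c("@r", "ACGT", "x", "IIII"), fq)
  expect_error(strip_quality(fq, fa), "separator")
  writeLines(c("@r", "ACGT", "+", "III"), fq)
  expect_error(strip_quality(fq, fa), "quality length")
  # FASTA passes through unchanged
  write_fasta(out, fq)
  strip_quality(fq, fa)
  expect_identical(read_seqs(fa), out)
})

test_that("ID factoring finds the longest common prefix and inverts", {
  f <- factor_ids(c("SRR359032.1", "SRR359032.2"))
  expect_identical(f$scheme$prefix, "SRR359032.")
  expect_identical(f$scheme$kind, "numeric")
  expect_identical(f$suffixes, c("1", "2"))
  expect_identical(restore_ids(f$scheme, f$suffixes), c("SRR359032.1", "SRR359032.2"))

  single <- factor_ids("onlyone")
  expect_identical(single$scheme$prefix, "onlyone")
  expect_identical(single$suffixes, "")

  set.seed(77)
  for (trial in 1:20) {
    ids <- paste0(
      sample(c("run.", "X", ""), 1),
      replicate(30, paste(sample(c(letters, 0:9), 6, replace = TRUE), collapse = ""))
    )
    f <- factor_ids(ids)
    expect_identical(restore_ids(f$scheme, f$suffixes), ids)
  }
  # leading zeros must not be classified numeric (would not round-trip)
  f <- factor_ids(c("s01", "s2"))
  expect_identical(f$scheme$kind, "opaque")
  expect_identical(restore_ids(f$scheme, f$suffixes), c("s01", "s2"))
})

test_that("uniform placeholder qualities collapse to '*'", {
  rec <- function(qual) {
    sprintf("r\t0\tchr1\t1\t60\t4M\t*\t0\t0\tACGT\t%s", qual)
  }
  out <- sam_quality_placeholder(c("@HD\tVN:1.6", rec("IIII"), rec("*"), rec("IFII")))
  qual <- vapply(strsplit(out[-1], "\t"), `[[`, character(1), 11L)
  expect_identical(qual, c("*", "*", "IFII"))
})

test_that("merge_sort_split sorts numerically and splits mates", {
  td <- withr::local_tempdir()
  aligned <- data.frame(
    id = c("s.10", "s.2"), mate = c(1L, 2L),
    seq = c("AAAA", "CCCC"), stringsAsFactors = FALSE
  )
  unaligned <- data.frame(
    id = c("s.2", "s.10"), mate = c(1L, 2L),
    seq = c("GGGG", "TTTT"), stringsAsFactors = FALSE
  )
  paths <- merge_sort_split(aligned, unaligned, TRUE, file.path(td, "out"))
  m1 <- read_seqs(paths[1])
  m2 <- read_seqs(paths[2])
  expect_identical(m1$id, c("s.2", "s.10")) # numeric, not lexicographic
  expect_identical(m1$seq, c("GGGG", "AAAA"))
  expect_identical(m2$id, c("s.2", "s.10"))
  # duplicates are an error
  expect_error(
    merge_sort_split(aligned, aligned, TRUE, file.path(td, "dup")),
    "duplicate"
  )
  # unpaired: one file
  un <- merge_sort_split(
    data.frame(id = "q.1", mate = 0L, seq = "AA", stringsAsFactors = FALSE),
    data.frame(id = character(), mate = integer(), seq = character(), stringsAsFactors = FALSE),
    FALSE, file.path(td, "sing")
  )
  expect_length(un, 1L)
  expect_identical(read_seqs(un)$id, "q.1")
})
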