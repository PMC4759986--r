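test_that("the built-in aligner recovers planted alignments on both strands", {
  set.seed(120)
  ref <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE), collapse = "")
  refs <- c(gX = ref)
  fwd <- substr(ref, 101, 200)
  rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(substr(ref, 1001, 1100))
  ))
  # a read with one substitution still verifies (<= 3 mismatches)
  noisy <- substr(ref, 2001, 2100)
  substr(noisy, 50, 50) <- setdiff(c("A", "C", "G", "T"), substr(noisy, 50, 50))[1]
  foreign <- paste(rep("ACGT", 25), collapse = "")
  reads <- data.frame(
    id = c("a_1", "b_1", "c_1", "d_1"),
    seq = c(fwd, rev, noisy, foreign), stringsAsFactors = FALSE
  )
  sam <- align_builtin(reads, refs)
  p <- parse_sam(sam, refs)
  r <- p$aligned$reads
  expect_identical(r$id[r$start == 101L], "a")
  expect_false(r$reverse[r$id == "a"])
  expect_identical(r$start[r$id == "b"], 1001L)
  expect_true(r$reverse[r$id == "b"])
  expect_identical(r$start[r$id == "c"], 2001L)
  expect_identical(p$unaligned$id, "d")
  # reconstruction returns the original read sequences
  recon <- metarc:::reconstruct_all(p$aligned, refs)
  expect_setequal(recon, c(fwd, rev, noisy))
})

test_that("template lengths are signed, symmetric and zero for lone mates", {
  set.seed(121)
  ref <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE), collapse = "")
  refs <- c(gY = ref)
  reads <- data.frame(
    id = c("p.1_1", "p.1_2", "q.2_1"),
    seq = c(
      substr(ref, 501, 600),
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(substr(ref, 701, 800))
      )),
      substr(ref, 901, 1000)
    ),
    stringsAsFactors = FALSE
  )
  p <- parse_sam(align_builtin(reads, refs), refs)
  r <- p$aligned$reads
  expect_identical(r$tlen[r$id == "p.1" & r$mate == 1L], 300L)
  expect_identical(r$tlen[r$id == "p.1" & r$mate == 2L], -300L)
  expect_identical(r$tlen[r$id == "q.2"], 0L)
})

test_that("contig search maps contigs to the genome they came from", {
  td <- withr::local_tempdir()
  spec <- community_spec(n_species = 3, genome_length = 8000, n_reads = 0, seed = 33)
  refs <- make_references(spec)
  write_refs_dir(refs, td)
  contigs <- stats::setNames(
    c(substr(refs[["g102"]], 1000, 1600), substr(refs[["g103"]], 300, 900)),
    c("contig_1", "contig_2")
  )
  hits <- metarc:::kmer_contig_search(contigs, td)
  expect_identical(hits$taxid[hits$contig == "contig_1"], 102L)
  expect_identical(hits$taxid[hits$contig == "contig_2"], 103L)
  expect_identical(nrow(metarc:::kmer_contig_search(character(), td)), 0L)
})
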