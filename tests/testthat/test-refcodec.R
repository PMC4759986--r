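toy_refs <- c(chr1 = "ACGTACGTACGTACGTACGT")

sam_line <- function(qname = "r_1", flag = 0L, rname = "chr1", pos = 1L,
                     cigar = "10M", tlen = 0L, seq = substr(toy_refs[[1]], pos, pos + 9L),
                     qual = "*") {
  sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t%d\t%s\t%s", qname, flag, rname, pos, cigar, tlen, seq, qual)
}

test_that("parse_sam routes records correctly", {
  lines <- c(
    "@HD\tVN:1.6",
    sam_line("a_1", 0L, pos = 3L), # exact match
    sam_line("b_1", 4L, rname = "*", pos = 0L, cigar = "*", seq = "TTTTTTTTTT"), # unmapped
    sam_line("c_1", 256L, pos = 5L), # secondary: skipped
    sam_line("d_2", 0L, pos = 2L, cigar = "5M1P4M") # unsupported op -> fallback
  )
  p <- parse_sam(lines, toy_refs)
  expect_identical(p$aligned$reads$id, "a")
  expect_identical(p$aligned$reads$mate, 1L)
  expect_identical(p$aligned$reads$start, 3L)
  expect_identical(nrow(p$aligned$variations), 0L)
  expect_setequal(p$unaligned$id, c("b", "d"))
})

test_that("parse_sam derives substitution variations by reference comparison", {
  seq <- substr(toy_refs[[1]], 1, 10)
  substr(seq, 4, 4) <- "T" # offset 3, ref has T at... ensure a real mismatch
  if (substr(toy_refs[[1]], 4, 4) == "T") substr(seq, 4, 4) <- "A"
  p <- parse_sam(sam_line("a_1", 0L, pos = 1L, seq = seq), toy_refs)
  vt <- p$aligned$variations
  expect_identical(nrow(vt), 1L)
  expect_identical(vt$ref_offset, 3L)
  expect_identical(vt$kind, "sub")
  expect_identical(vt$bases, substr(seq, 4, 4))
})

test_that("parse_sam errors name the offending line or reference", {
  expect_error(parse_sam(c("@HD", "short\tline"), toy_refs), "line 2")
  expect_error(parse_sam(sam_line(rname = "chrX"), toy_refs), "chrX")
  expect_error(
    parse_sam(sam_line("a_1", 0L, pos = 15L, seq = "ACGTACGTAC"), toy_refs),
    "past the end"
  )
})

test_that("reconstruct_read applies variations and strand correctly", {
  rec <- list(
    start = 3L, reverse = FALSE, read_len = 8L,
    variations = data.frame(
      ref_offset = 2L, kind = "sub", len = 1L, bases = "T",
      stringsAsFactors = FALSE
    )
  )
  ref <- toy_refs[[1]]
  want <- substr(ref, 3, 10)
  substr(want, 3, 3) <- "T"
  expect_identical(reconstruct_read(ref, rec), want)
  # reverse flag: double reverse-complement identity
  rec$reverse <- TRUE
  got <- reconstruct_read(ref, rec)
  expect_identical(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(got))), want)
  # empty variations, forward: exact reference substring
  rec0 <- list(start = 5L, reverse = FALSE, read_len = 6L, variations = NULL)
  expect_identical(reconstruct_read(ref, rec0), substr(ref, 5, 10))
  # variation beyond the alignment span is corruption
  bad <- list(
    start = 1L, reverse = FALSE, read_len = 4L,
    variations = data.frame(
      ref_offset = 9L, kind = "sub", len = 1L, bases = "A",
      stringsAsFactors = FALSE
    )
  )
  expect_error(reconstruct_read(ref, bad), "beyond")
})

test_that("indel and softclip CIGARs reconstruct byte-for-byte", {
  ref <- paste(rep("ACGGTTCA", 20), collapse = "")
  refs <- c(g1 = ref)
  # 4M2I4M: insertion of CC after 4 matched bases
  seq_ins <- paste0(substr(ref, 11, 14), "CC", substr(ref, 15, 18))
  # 4M2D6M: deletion of 2 reference bases
  seq_del <- paste0(substr(ref, 21, 24), substr(ref, 27, 32))
  # 2S8M: leading soft clip
  seq_soft <- paste0("TT", substr(ref, 41, 48))
  lines <- c(
    sam_line("i_1", 0L, "g1", 11L, "4M2I4M", seq = seq_ins),
    sam_line("d_1", 0L, "g1", 21L, "4M2D6M", seq = seq_del),
    sam_line("s_1", 16L, "g1", 41L, "2S8M", seq = seq_soft)
  )
  p <- parse_sam(lines, refs)
  expect_identical(nrow(p$aligned$reads), 3L)
  got <- metarc:::reconstruct_all(p$aligned, refs)
  expect_identical(got[1], seq_ins)
  expect_identical(got[2], seq_del)
  expect_identical(got[3], as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(seq_soft))
  ))
})

test_that("truth SAM from the simulator reconstructs every read exactly", {
  sm <- small_sim(n_reads = 1000L, seed = 19L, indel_rate = 0.05)
  p <- parse_sam(sm$sim$sam, sm$refs)
  expect_identical(nrow(p$unaligned), 0L)
  recon <- metarc:::reconstruct_all(p$aligned, sm$refs)
  orig <- c(
    stats::setNames(sm$sim$reads1$seq, paste0(sm$sim$reads1$id, "_1")),
    stats::setNames(sm$sim$reads2$seq, paste0(sm$sim$reads2$id, "_2"))
  )
  key <- paste0(p$aligned$reads$id, "_", p$aligned$reads$mate)
  expect_identical(unname(recon), unname(orig[key]))
})

block_fixture <- function(seed = 7L, indel_rate = 0) {
  sm <- small_sim(n_reads = 1500L, seed = seed, indel_rate = indel_rate)
  p <- parse_sam(sm$sim$sam, sm$refs)
  a <- p$aligned
  a$reads$id_suffix <- sub("SIM001.", "", a$reads$id, fixed = TRUE)
  rid <- a$reads$ref_id[1]
  idx <- which(a$reads$ref_id == rid)
  vt <- a$variations[a$variations$read %in% idx, , drop = FALSE]
  vt$read <- match(vt$read, idx)
  aligned_reads(a$reads[idx, , drop = FALSE], vt)
}

test_that("encode_block/decode_block invert under every codec, with indels", {
  for (case in list(list(7L, 0), list(13L, 0.05))) {
    blk <- block_fixture(case[[1]], case[[2]])
    ordx <- order(blk$reads$start, as.integer(blk$reads$id_suffix), blk$reads$mate,
      method = "radix"
    )
    for (codec in c("huffman", "golomb", "extended_golomb")) {
      dec <- decode_block(encode_block(blk, codec_config(codec, 3L)))
      for (col in c("id_suffix", "mate", "ref_id", "start", "reverse", "read_len", "tlen")) {
        expect_identical(dec$reads[[col]], blk$reads[[col]][ordx])
      }
      vo <- blk$variations[order(match(blk$variations$read, ordx), seq_len(nrow(blk$variations))), ]
      expect_identical(dec$variations$ref_offset, vo$ref_offset)
      expect_identical(dec$variations$kind, vo$kind)
      expect_identical(dec$variations$len, vo$len)
      expect_identical(dec$variations$bases, vo$bases)
    }
  }
})

test_that("position stream is first-absolute-then-deltas over sorted starts", {
  blk <- block_fixture()
  member <- encode_block(blk, codec_config("golomb", 3L))
  # skip the member header, then the first stream is the position stream
  p <- metarc:::read_lpstr(member, 1L)
  pos <- p$pos + 4L + 1L + 4L
  r <- metarc:::read_stream(member, pos)
  deltas <- decode_integers(r$stream)
  starts <- sort(blk$reads$start)
  expect_identical(deltas[1L], starts[1L])
  expect_identical(cumsum(deltas), starts)
  expect_true(all(deltas[-1L] >= 0L))
})

test_that("two reads at starts 100 and 250 encode as (100, 150)", {
  reads <- data.frame(
    id = c("2", "1"), id_suffix = c("2", "1"), mate = c(0L, 0L),
    ref_id = "chr1", start = c(250L, 100L), reverse = FALSE,
    read_len = 10L, tlen = 0L, stringsAsFactors = FALSE
  )
  member <- encode_block(aligned_reads(reads), codec_config("golomb"))
  p <- metarc:::read_lpstr(member, 1L)
  r <- metarc:::read_stream(member, p$pos + 9L)
  expect_identical(decode_integers(r$stream), c(100L, 150L))
})

test_that("mixed ref_id blocks and empty blocks are rejected", {
  reads <- data.frame(
    id = c("1", "2"), id_suffix = c("1", "2"), mate = 0L,
    ref_id = c("a", "b"), start = 1L, reverse = FALSE, read_len = 5L,
    tlen = 0L, stringsAsFactors = FALSE
  )
  expect_error(encode_block(aligned_reads(reads)), "single ref_id")
  expect_error(encode_block(metarc:::empty_aligned()), "id_suffix|empty")
})

test_that("a zero-error fully aligned block stays below 2 bits per base", {
  sm <- small_sim(n_reads = 2000L, seed = 23L, error_rate = 0)
  p <- parse_sam(sm$sim$sam, sm$refs)
  a <- p$aligned
  a$reads$id_suffix <- sub("SIM001.", "", a$reads$id, fixed = TRUE)
  total_bits <- 0
  for (rid in unique(a$reads$ref_id)) {
    idx <- which(a$reads$ref_id == rid)
    vt <- a$variations[a$variations$read %in% idx, , drop = FALSE]
    vt$read <- match(vt$read, idx)
    blk <- aligned_reads(a$reads[idx, , drop = FALSE], vt)
    total_bits <- total_bits + 8 * length(encode_block(blk, codec_config("huffman")))
  }
  expect_lt(total_bits / sum(a$reads$read_len), 2)
})

test_that("compressed size shrinks as alignment identity grows", {
  sizes <- vapply(c(0.03, 0.01, 0), function(err) {
    sm <- small_sim(n_reads = 1500L, seed = 31L, error_rate = err)
    p <- parse_sam(sm$sim$sam, sm$refs)
    a <- p$aligned
    a$reads$id_suffix <- sub("SIM001.", "", a$reads$id, fixed = TRUE)
    sum(vapply(unique(a$reads$ref_id), function(rid) {
      idx <- which(a$reads$ref_id == rid)
      vt <- a$variations[a$variations$read %in% idx, , drop = FALSE]
      vt$read <- match(vt$read, idx)
      length(encode_block(aligned_reads(a$reads[idx, , drop = FALSE], vt), codec_config("huffman")))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(sizes) < 0))
})

test_that("archives round-trip byte-identically and verify checksums", {
  td <- withr::local_tempdir()
  members <- list(
    "ref:g1" = as.raw(sample(0:255, 500, replace = TRUE)),
    "ref:g2" = as.raw(sample(0:255, 300, replace = TRUE)),
    "ref:g3" = raw(0),
    fallback = as.raw(1:10)
  )
  manifest <- list(codec = "huffman", m = 3L, n_reads = 0L)
  path <- file.path(td, "t.arch")
  pack_archive(manifest, members, path)
  back <- unpack_archive(path)
  expect_identical(back$members, members)
  expect_identical(back$manifest$codec, "huffman")
  # manifest readable in isolation
  man <- read_manifest(path)
  expect_identical(
    vapply(man$member_index, `[[`, character(1), "name"),
    names(members)
  )
  # corruption detection
  bytes <- readBin(path, "raw", file.size(path))
  bytes[length(bytes) - 2L] <- as.raw(bitwXor(as.integer(bytes[length(bytes) - 2L]), 255L))
  writeBin(bytes, path)
  expect_error(unpack_archive(path), "checksum")
  # empty archive round-trips
  empty <- file.path(td, "e.arch")
  pack_archive(list(n_reads = 0L), list(), empty)
  expect_identical(unpack_archive(empty)$members, list())
})
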