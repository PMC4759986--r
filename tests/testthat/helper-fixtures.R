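# Small synthetic communities shared across test files. Everything is
# generated in code under fixed seeds; no stored fixtures.

small_sim <- function(n_species = 3L, genome_length = 20000L, n_reads = 2000L,
                      seed = 7L, ...) {
  spec <- community_spec(
    n_species = n_species, genome_length = genome_length,
    n_reads = n_reads, seed = seed, ...
  )
  refs <- make_references(spec)
  list(spec = spec, refs = refs, sim = simulate_reads(refs, spec))
}

# write a community to disk in the pipeline's expected layout
sim_to_files <- function(sm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  db <- file.path(dir, "db")
  write_refs_dir(sm$refs, db)
  f1 <- file.path(dir, "r1.fasta")
  write_fasta(sm$sim$reads1, f1)
  f2 <- NULL
  if (!is.null(sm$sim$reads2)) {
    f2 <- file.path(dir, "r2.fasta")
    write_fasta(sm$sim$reads2, f2)
  }
  list(
    db = db, f1 = f1, f2 = f2,
    report = make_kraken_report(sm$sim$taxonomy)
  )
}

# numeric-suffix sort used to normalize read files before comparison
sorted_reads <- function(df, stem = "SIM001.") {
  df[order(as.integer(sub(stem, "", df$id, fixed = TRUE))), , drop = FALSE]
}

expect_same_reads <- function(path, original, stem = "SIM001.") {
  got <- read_seqs(path)
  want <- sorted_reads(original, stem)
  expect_identical(got$id, want$id)
  expect_identical(got$seq, want$seq)
}

# brute-force optimal prefix-code cost for <= 5 symbols: enumerate all
# length assignments satisfying the Kraft inequality
brute_force_prefix_cost <- function(counts) {
  n <- length(counts)
  grids <- do.call(expand.grid, rep(list(seq_len(max(1L, n - 1L))), n))
  kraft <- rowSums(2^-grids) <= 1 + 1e-12
  min(as.matrix(grids[kraft, , drop = FALSE]) %*% counts)
}

file_bytes <- function(path) readBin(path, "raw", file.size(path))
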