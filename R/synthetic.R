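#' Synthetic metagenomic community specification
#'
#' Defines the simulated study conditions: a mixture of uniform-random
#' bacterial-sized genomes, reads drawn proportionally to abundance times
#' genome length, uniform start positions and strands, i.i.d. substitution
#' errors at 1% (the Illumina-like profile; an optional indel rate
#' exercises the I/D code paths), and paired-end fragments with normal
#' insert sizes. The seed fixes every random draw.
#'
#' @param n_species number of species in the mixture.
#' @param genome_length genome length in bp (recycled across species).
#' @param abundance abundance weights (normalized internally); default is
#'   a 1/rank rank-abundance profile.
#' @param error_rate per-base substitution error rate.
#' @param indel_rate per-read probability of one short (1-3 bp) indel.
#' @param paired simulate paired-end fragments?
#' @param read_length read length in bp.
#' @param insert_mean,insert_sd normal insert-size model (bp).
#' @param n_reads total number of reads (mates counted individually).
#' @param id_stem common read-ID prefix, SRA style.
#' @param seed integer seed fixing all randomness.
#' @return A list of class `community_spec`.
#' @export
community_spec <- function(n_species = 10L, genome_length = 100000L,
                           abundance = NULL, error_rate = 0.01,
                           indel_rate = 0, paired = TRUE,
                           read_length = 100L, insert_mean = 300L,
                           insert_sd = 25L, n_reads = 100000L,
                           id_stem = "SIM001.", seed = 1L) {
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must lie in [0, 1)")
  genome_length <- rep_len(as.integer(genome_length), max(n_species, 1L))
  if (n_species > 0L && any(genome_length < read_length)) {
    stop("genome length must be at least the read length")
  }
  if (is.null(abundance)) abundance <- 1 / seq_len(max(n_species, 1L))
  abundance <- rep_len(abundance, max(n_species, 1L))
  if (n_species > 0L) abundance <- abundance / sum(abundance)
  if (paired && n_reads %% 2L != 0L) stop("paired simulation needs an even n_reads")
  structure(
    list(
      n_species = as.integer(n_species), genome_length = genome_length,
      abundance = abundance, error_rate = error_rate, indel_rate = indel_rate,
      paired = paired, read_length = as.integer(read_length),
      insert_mean = insert_mean, insert_sd = insert_sd,
      n_reads = as.integer(n_reads), id_stem = id_stem, seed = as.integer(seed)
    ),
    class = "community_spec"
  )
}

spec_taxids <- function(spec) 100L + seq_len(spec$n_species)

#' Generate synthetic reference genomes
#'
#' I.i.d. uniform ACGT sequences, one per species, deterministic under
#' the spec seed. Reference ids are `g<taxid>` with taxids `101, 102, ...`.
#'
#' @param spec a [community_spec()].
#' @return Named character vector of genome sequences.
#' @export
make_references <- function(spec) {
  set.seed(spec$seed)
  if (spec$n_species == 0L) {
    return(stats::setNames(character(), character()))
  }
  seqs <- vapply(seq_len(spec$n_species), function(i) {
    paste(sample(c("A", "C", "G", "T"), spec$genome_length[i], replace = TRUE), collapse = "")
  }, character(1))
  stats::setNames(seqs, paste0("g", spec_taxids(spec)))
}

#' Write references into a one-FASTA-per-taxid directory
#'
#' The layout the compressor's reference database expects:
#' `<dir>/<taxid>.fasta`, each holding one genome named `g<taxid>`.
#'
#' @param refs named character vector from [make_references()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_refs_dir <- function(refs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(refs)) {
    taxid <- sub("^g", "", nm)
    write_fasta(
      data.frame(id = nm, seq = refs[[nm]], stringsAsFactors = FALSE),
      file.path(dir, paste0(taxid, ".fasta"))
    )
  }
  invisible(dir)
}

#' Simulate an error-bearing read mixture with ground truth
#'
#' Draws fragments from the references proportional to abundance times
#' genome length, applies substitution errors (and optional short
#' indels), and returns the read files together with a ground-truth SAM
#' (exact positions, CIGARs and the erroneous sequences, from which
#' mismatches are recoverable) and the true per-species read counts.
#'
#' @param refs named character vector from [make_references()].
#' @param spec a [community_spec()].
#' @return A list with `reads1`, `reads2` (data.frames `id`, `seq`;
#'   `reads2` is `NULL` for unpaired), `sam` (character lines) and
#'   `taxonomy` (named integer vector of read counts per taxid).
#' @export
simulate_reads <- function(refs, spec) {
  set.seed(spec$seed + 1L)
  rl <- spec$read_length
  taxids <- spec_taxids(spec)
  empty <- data.frame(id = character(), seq = character(), stringsAsFactors = FALSE)
  header <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", names(refs), nchar(refs))
  )
  if (spec$n_reads == 0L) {
    return(list(
      reads1 = empty, reads2 = if (spec$paired) empty else NULL,
      sam = header, taxonomy = stats::setNames(integer(spec$n_species), taxids)
    ))
  }
  n_frag <- if (spec$paired) spec$n_reads %/% 2L else spec$n_reads
  w <- spec$abundance * spec$genome_length
  sp <- sample.int(spec$n_species, n_frag, replace = TRUE, prob = w / sum(w))
  L <- spec$genome_length[sp]
  refname <- names(refs)[sp]
  ids <- paste0(spec$id_stem, seq_len(n_frag))

  if (spec$paired) {
    ins <- pmin(L, pmax(2L * rl, as.integer(round(stats::rnorm(n_frag, spec$insert_mean, spec$insert_sd)))))
    fstart <- as.integer(floor(stats::runif(n_frag) * (L - ins + 1))) + 1L
    lpos <- fstart
    rpos <- fstart + ins - rl
    left <- extract_with_errors(refs, sp, refname, lpos, rl, spec)
    right <- extract_with_errors(refs, sp, refname, rpos, rl, spec)
    # which physical strand the fragment came from decides which mate is
    # the forward (left) read
    flip <- stats::runif(n_frag) < 0.5
    m1 <- ifelse(flip, right$orig, left$orig)
    m2 <- ifelse(flip, left$orig, right$orig)
    # original read orientation: the right-hand mate is reverse-strand
    m1 <- ifelse(flip, revcomp_vec(m1), m1)
    m2 <- ifelse(flip, m2, revcomp_vec(m2))
    reads1 <- data.frame(id = ids, seq = m1, stringsAsFactors = FALSE)
    reads2 <- data.frame(id = ids, seq = m2, stringsAsFactors = FALSE)

    qn1 <- paste0(ids, "_1")
    qn2 <- paste0(ids, "_2")
    rec <- function(qn, pos, seqs, cig, rev, tl) {
      sprintf(
        "%s\t%d\t%s\t%d\t60\t%s\t*\t0\t%d\t%s\t*",
        qn, ifelse(rev, 16L, 0L), refname, pos, cig, tl, seqs
      )
    }
    sam <- c(
      header,
      rec(ifelse(flip, qn2, qn1), lpos, left$seq, left$cigar, rep(FALSE, n_frag), ins),
      rec(ifelse(flip, qn1, qn2), rpos, right$seq, right$cigar, rep(TRUE, n_frag), -ins)
    )
    counts <- tabulate(sp, nbins = spec$n_species) * 2L
  } else {
    pos <- as.integer(floor(stats::runif(n_frag) * (L - rl + 1))) + 1L
    ex <- extract_with_errors(refs, sp, refname, pos, rl, spec)
    rev <- stats::runif(n_frag) < 0.5
    reads1 <- data.frame(
      id = ids,
      seq = ifelse(rev, revcomp_vec(ex$orig), ex$orig),
      stringsAsFactors = FALSE
    )
    reads2 <- NULL
    sam <- c(header, sprintf(
      "%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
      ids, ifelse(rev, 16L, 0L), refname, pos, ex$cigar, ex$seq
    ))
    counts <- tabulate(sp, nbins = spec$n_species)
  }
  list(
    reads1 = reads1, reads2 = reads2, sam = sam,
    taxonomy = stats::setNames(counts, taxids)
  )
}

revcomp_vec <- function(x) {
  out <- x
  nz <- nzchar(x)
  if (any(nz)) out[nz] <- revcomp(x[nz])
  out
}

# Extract reference segments, apply substitution errors, optionally one
# short indel per selected read. Returns forward-orientation sequences
# (`seq`, what a SAM record stores), their CIGARs, and `orig` = seq (the
# sequencer output before any orientation flip).
extract_with_errors <- function(refs, sp, refname, pos, rl, spec) {
  n <- length(pos)
  segs <- substr(refs[refname], pos, pos + rl - 1L)
  names(segs) <- NULL
  cigar <- rep(paste0(rl, "M"), n)

  if (spec$indel_rate > 0) {
    hit <- which(stats::runif(n) < spec$indel_rate)
    for (i in hit) {
      ilen <- sample(3L, 1L)
      off <- sample(seq(2L, rl - ilen - 1L), 1L) # M run on both sides
      if (stats::runif(1) < 0.5) { # insertion
        insbases <- paste(sample(c("A", "C", "G", "T"), ilen, replace = TRUE), collapse = "")
        kept <- substr(segs[i], 1L, rl - ilen)
        segs[i] <- paste0(substr(kept, 1L, off), insbases, substr(kept, off + 1L, rl - ilen))
        cigar[i] <- sprintf("%dM%dI%dM", off, ilen, rl - ilen - off)
      } else { # deletion: consume extra reference
        L <- nchar(refs[[refname[i]]])
        if (pos[i] + rl + ilen - 1L <= L) {
          ext <- substr(refs[[refname[i]]], pos[i], pos[i] + rl + ilen - 1L)
          segs[i] <- paste0(substr(ext, 1L, off), substr(ext, off + ilen + 1L, rl + ilen))
          cigar[i] <- sprintf("%dM%dD%dM", off, ilen, rl - off)
        }
      }
    }
  }

  if (spec$error_rate > 0) {
    mask <- matrix(stats::runif(n * rl) < spec$error_rate, nrow = n)
    ij <- which(mask, arr.ind = TRUE)
    if (nrow(ij)) {
      ij <- ij[order(ij[, 1L], ij[, 2L]), , drop = FALSE]
      orig <- substring(segs[ij[, 1L]], ij[, 2L], ij[, 2L])
      code <- match(orig, c("A", "C", "G", "T"))
      shift <- sample.int(3L, nrow(ij), replace = TRUE)
      newb <- c("A", "C", "G", "T")[(code - 1L + shift) %% 4L + 1L]
      for (k in seq_len(nrow(ij))) {
        substr(segs[ij[k, 1L]], ij[k, 2L], ij[k, 2L]) <- newb[k]
      }
    }
  }
  list(seq = segs, cigar = cigar, orig = segs)
}

#' Emit a Kraken-style report from true species counts
#'
#' Produces the tab-separated dialect that [parse_report()] inverts: a
#' root line plus one species-rank line per taxon with nonzero handling
#' left to the caller.
#'
#' @param counts named integer vector: reads per taxid.
#' @param names optional scientific names, parallel to `counts`.
#' @return Character vector of report lines.
#' @export
make_kraken_report <- function(counts, names = paste0("Synthetica species", seq_along(counts))) {
  total <- sum(counts)
  root <- sprintf("%.2f\t%d\t%d\tR\t1\troot", if (total > 0) 100 else 0, total, 0L)
  if (length(counts) == 0L) {
    return(root)
  }
  sp <- sprintf(
    "%.2f\t%d\t%d\tS\t%s\t    %s",
    if (total > 0) 100 * counts / total else rep(0, length(counts)),
    counts, counts, names(counts), names
  )
  c(root, sp)
}
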