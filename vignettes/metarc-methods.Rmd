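---
title: "Reference-based compression of metagenomic reads: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-based compression of metagenomic reads: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metarc)
```

## The problem

A metagenomic sequencing run samples reads from a mixture of microbial
genomes, most of them unknown a priori. Classical reference-based read
compressors (CRAM-style) assume one known reference; applied naively to a
metagenome they have nothing to align against, so the only off-the-shelf
option is reference-free general compression. `metarc` closes that gap:
it *discovers* usable references from the sample itself — first by ranking
the taxa a classifier reports by abundance, then by assembling whatever
did not align and searching the contigs against a genome database — and
stores each aligned read as a pointer into a reference plus its
differences. Residual reads fall back to a reference-free 2-bit codec.
The default mode is lossless: decompression reproduces the exact multiset
of (read ID, sequence) pairs.

## Pipeline

`run_compress()` executes, in order:

1. **Pre-processing.** FASTQ qualities are stripped to a plain-text
   sidecar (quality compression is a separate concern with dedicated
   tools; see `strip_quality()`). Paired files are merged with `_1`/`_2`
   mate labels (`label_mates()`). The shared read-ID stem (e.g.
   `"SRR359032."`) is factored out once (`factor_ids()`).
2. **Taxonomy-driven reference selection.** A Kraken-style report is
   parsed (`parse_report()`) and species are ranked by clade read count.
   The default policy keeps the top 75 species; a minimum-abundance
   threshold is the alternative (`selection_policy()`). Both semantics
   exist because either count-based or abundance-based cutoffs are
   reasonable, and they behave differently on long-tailed communities.
3. **Alignment and differential encoding.** Reads are aligned to the
   selected genomes; primary mapped records with CIGAR ops in
   {M, I, D, S} become differential records (`parse_sam()`), everything
   else goes to the unaligned pool. Per reference, reads are sorted by
   start position and eight integer streams are emitted
   (`encode_block()`): start-position deltas, per-read variation counts,
   within-read variation-offset deltas, variation kind/length/base
   symbols, read lengths, strand/mate flags, zigzagged template offsets,
   and ID-suffix deltas.
4. **Reference discovery (round 2).** Unaligned reads are assembled; the
   contigs are searched against the reference database; newly hit
   genomes are loaded and the unaligned pool is realigned against them.
   At most two rounds are run — in our experiments the second round
   captures nearly all of the recoverable mass and further rounds do not
   pay for their cost. If assembly fails the round is skipped
   automatically.
5. **Fallback and packing.** The residue is stored reference-free
   (`fallback_encode()`): 2-bit packed A/C/G/T with an escape list of N
   positions. Everything is packed into one archive whose JSON manifest
   (codec, ID stem, read counts, per-round alignment rates, reference
   list) is readable without extracting members — so a collection of
   archives can be *selected* by taxon in the compressed domain
   (`archive_stats()`, `read_manifest()`).

`run_decompress()` inverts each step and finishes with
`merge_sort_split()`: reads sorted by ID ascending and mates split back
into two files. Note the contract is the sorted order, not the original
file order; for SRA-style numeric IDs the sort is numeric on the suffix.

## Integer codecs

All per-field streams are non-negative integers (signed template offsets
are zigzag-mapped first), coded with one of three codecs chosen per run:

- **Unary**: integer $i$ as $i$ ones and a terminating zero.
- **Truncated binary** over an alphabet of size $m$: with
  $k=\lfloor\log_2 m\rfloor$, the first $2^{k+1}-m$ symbols get $k$ bits,
  the rest $k+1$ bits; $m=1$ needs zero bits.
- **Golomb** with divisor $m$: quotient in unary, remainder in truncated
  binary; optimal for geometric sources. The Rice restriction
  $m=2^{k}$ has the closed-form optimum
  $k^{*}=\max\{0,\,1+\lfloor\log_2(\log(\phi-1)/\log(\mu/(\mu+1)))\rfloor\}$
  with $\phi$ the golden ratio (`rice_parameter()`).
- **Extended Golomb** with divisor $m\ge 2$: divide by $m$ until the
  quotient is 0, emit the iteration count $M$ in unary and the
  remainders most-recent-first; suited to power-law sources and far
  shorter than Golomb for large integers (for $n=1000$, $m=2$ the
  Golomb quotient alone takes 501 bits).
- **Canonical Huffman**: optimal prefix code for the empirical symbol
  table; the canonical convention (sort by (length, symbol), assign
  codewords sequentially) means only the length table is stored.

Three conventions are under-determined by the usual description of the
extended Golomb code, and were fixed as follows:

- The final remainder $r_M$ can never be 0 (otherwise division would
  have stopped earlier), so it is coded on the reduced alphabet
  $\{1..m-1\}$ as $r_M-1$ in truncated binary of size $m-1$. This is the
  only convention consistent with the worked codeword for $n=7$, $m=3$
  being `110110` ($r_2=2\mapsto$ `1`).
- The integer 0 produces no remainders at all; it takes the reserved
  $M=0$ codeword, a single `0` bit, which no $n\ge 1$ can emit.
- Applying the iteration rule to $n=1000$, $m=2$ gives quotients
  $500,250,\dots,1,0$, i.e. $M=10$; the package implements this
  demonstrated rule throughout rather than any shortcut.

Huffman ties are broken deterministically (earlier-created node wins),
so length tables — and therefore archives — are reproducible across
platforms; canonical assignment makes the codebook unique given the
lengths regardless. Bits are packed MSB-first and every member header
records the exact bit length, so padding is never read as data.

## Choosing the codec from the data

`recommend_codec()` compares a geometric fit against the power-law family
$P_i = 2^{-\log_m i}\,\frac{1}{2i(m-1)}$ on the 90%-coverage truncation
of the sample (the long sparse tail otherwise dominates the comparison;
the same truncation is used for all fits since that is the regime the
comparison is about). As printed, $P_i$ does not sum to 1 over $i\ge 1$,
so for likelihood comparison both models are renormalized over the
truncated support; the weight itself is exposed unnormalized
(`power_law_pmf()`). A geometric winner maps to Golomb, a power-law
winner to extended Golomb with the best $m\in\{2,3,4\}$; $m=3$ is the
package default for both Golomb codes. Huffman is always reported as the
archival-ratio option: it is optimal for the empirical table and in
practice gives the best ratios, at the cost of storing length tables.

Geometric support is $\{1,2,\dots\}$ (positions and gaps are at least
1), with MLE $\hat p = 1/\bar x$; the least-squares alternative
minimizes summed squared pmf residuals. The negative binomial fit
shifts values by one onto $\{0,1,\dots\}$ and uses the standard MLE
optimizer (`MASS::fitdistr`, `optim` default `reltol = 1e-8`); it
requires overdispersion and says so otherwise.

## The synthetic community

`community_spec()` defaults encode the study conditions used throughout
the tests: 10 species, 100 kb uniform-random genomes, a 1/rank
rank-abundance profile, $10^5$ paired reads of 100 bp, insert sizes
$\mathcal{N}(300, 25^2)$, and i.i.d. substitution errors at 1% — the
error profile of an Illumina-like simulator. Substitution-only is the
default; `indel_rate` plants one short (1–3 bp) indel per selected read
to exercise the I/D code paths. The generator emits ground-truth SAM
(exact positions, strands, CIGARs) and true per-species read counts,
from which a Kraken-style report is fabricated (`make_kraken_report()`).

What this does *not* emulate: real genome composition (repeats, shared
genes, conserved regions between related species), quality-correlated
errors, coverage biases, and classifier noise. Passing tests therefore
demonstrate the correctness of the machinery (losslessness, determinism,
directional behaviour of the discovery loop) — not field compression
ratios on real samples, which depend on how well real references match
real reads.

The built-in aligner is a deliberately naive seed-and-verify scheme:
exact 16-mer seeds at three fixed offsets, both strands, ungapped
verification accepting up to 3 mismatches, best candidate by mismatch
count with deterministic tie-breaks. "Aligns sufficiently well" is thus
delegated to the aligner's own mapped/unmapped decision. With 1% errors
the chance that all three seeds of a present-species read are hit is
about $0.15^3$, giving the ~98% alignment rates seen in the tests; an
external aligner can be plugged in via `adapter_command_aligner()`. The
mock assembler places unaligned reads at their ground-truth coordinates
and reports the maximal covered stretches as contigs (so contigs carry
read errors but true layout); the contig search is a real, naive k-mer
vote against the database and receives no truth.

## Numerical and format choices

- Coordinates are 1-based (SAM convention); variation offsets are
  0-based relative to the alignment start, stored in read-walk order
  with non-decreasing offsets (indels can legally touch the same
  reference offset twice).
- Variations are stored in reference orientation carrying the read's
  base; the reverse-complement is applied last on decode, which makes
  the double-reverse-complement identity directly testable.
- Only primary alignments are encoded; secondary records are skipped
  entirely (routing them anywhere else would duplicate reads and break
  the multiset contract).
- Reads whose CIGAR contains ops outside {M, I, D, S} go to the
  fallback whole — losslessness over coverage.
- The archive is a custom indexed container (magic, length-prefixed
  JSON manifest, raw members with Adler-32 checksums), emulating the
  CRAM idea structurally; bit-exact CRAM interop is out of scope.
- One codec id applies to all streams of a run, mirroring the three
  operating modes (Huffman / Golomb / extended Golomb).
- `drop_ids` is the lossy mode: sequences, mates and counts survive,
  IDs are re-minted sequentially on decompression. The archive is
  strictly smaller; pairing by original ID is gone.
- Stages without data dependencies (per-reference block encoding, the
  fallback encode) run through `parallel_schedule()` /
  `run_stage_plan()`; results are collected by stage name, so parallel
  and serial execution produce byte-identical archives.

## Problem sizes in the test suite

The suite exercises the full pipeline at $10^5$ paired reads over 10
species (the default spec) for the losslessness check, and smaller
communities (2–6 species, $10^2$–$10^4$ reads) for the behavioural
properties; codec round trips run over a dense sample of $[0, 10^6]$
for every divisor in $\{1..8\}$. Parameter-recovery checks use
$10^5$-sample simulations. These sizes were chosen so the whole suite
completes in about a minute while keeping every estimate comfortably
inside its tolerance.

## Known limitations

- The built-in aligner is ungapped; reads with true indels relative to
  their reference are recoverable only via the truth SAM path or an
  external aligner, otherwise they ride the fallback.
- Reference genomes are not deduplicated; closely related selected
  genomes cost index memory and may split a species' reads across
  blocks (harmless for correctness, mildly bad for ratio).
- The archive format is this package's own; it is versioned and
  self-describing but not interchangeable with CRAM tooling.
- Quality scores are preserved only as the plain-text sidecar written
  at pre-processing; compressing them is explicitly out of scope.
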