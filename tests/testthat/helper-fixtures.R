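# Shared fixture builders. Everything is generated in code at test time.

random_seq <- function(n, seed) {
  refasm:::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                 collapse = ""))
}

# Error-free reads tiling `s` at the given step, both strands, fixed quality.
tile_read_pairs <- function(s, read_len = 70L, step = 1L, q = 40L) {
  starts <- unique(c(seq(1L, nchar(s) - read_len + 1L, by = step),
                     nchar(s) - read_len + 1L))
  fwd <- substring(s, starts, starts + read_len - 1L)
  seqs <- c(fwd, reverse_complement(fwd))
  qs <- strrep(intToUtf8(q + 33L), read_len)
  read_pairs(sprintf("r%04d", seq_along(seqs)),
             seqs, rep(qs, length(seqs)),
             reverse_complement(seqs), rep(qs, length(seqs)))
}

# A reference carrying the same `block` at two distant loci, for ambiguity
# fixtures: contigs cut from the block map to both copies.
repeat_reference <- function(block_len = 1000L, spacer_len = 4000L, seed = 99L) {
  block <- random_seq(block_len, seed)
  left <- random_seq(spacer_len, seed + 1L)
  mid <- random_seq(spacer_len, seed + 2L)
  right <- random_seq(spacer_len, seed + 3L)
  list(genome = genome(c(chr1 = paste0(left, block, mid, block, right))),
       block = block,
       block_starts = c(spacer_len, 2L * spacer_len + block_len))
}

# Reference bases covered by >= 2 mapping records.
multiply_covered_bases <- function(mappings) {
  if (nrow(mappings) == 0) return(0L)
  tot <- 0L
  for (chrom in unique(mappings$ref_chrom)) {
    m <- mappings[mappings$ref_chrom == chrom, , drop = FALSE]
    cov <- IRanges::coverage(IRanges::IRanges(m$ref_start + 1L, m$ref_end))
    tot <- tot + sum(S4Vectors::runLength(cov)[S4Vectors::runValue(cov) >= 2])
  }
  tot
}

# Re-apply a truth log to the ancestral sequence (same event semantics as
# the evolver: SNPs first, then deletions, then insertions appended after
# their anchor).
apply_truth <- function(ref_chrom_seq, truth) {
  v <- strsplit(ref_chrom_seq, "", fixed = TRUE)[[1]]
  s <- truth[truth$type == "SNP", , drop = FALSE]
  v[s$pos] <- s$alt
  d <- truth[truth$type == "DEL", , drop = FALSE]
  for (i in seq_len(nrow(d))) {
    v[d$pos[i]:(d$pos[i] + nchar(d$ref[i]) - 1L)] <- ""
  }
  ins <- truth[truth$type == "INS", , drop = FALSE]
  v[ins$pos] <- paste0(v[ins$pos], ins$alt)
  paste(v, collapse = "")
}
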