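#' Pseudoread generation parameters
#'
#' Pseudoreads are artificial paired-end reads tiled from the reference at a
#' fixed step so the assembler sees uniform, full coverage of the reference.
#' `m` is the read length, `n` the start step, `d` the outer fragment length
#' (distance from the mate-1 start to the mate-2 window end), and `q` the
#' deliberately low Phred quality given to every pseudoread base so that real
#' experimental reads dominate the assembly consensus.
#'
#' @param m read length in bases (default 100).
#' @param n tiling step in bases (default 30).
#' @param d outer mate distance in bases (default 1000); must be >= `m`.
#' @param q Phred quality in \[0, 93\] (default 10).
#' @export
pseudoread_params <- function(m = 100L, n = 30L, d = 1000L, q = 10L) {
  m <- as.integer(m); n <- as.integer(n); d <- as.integer(d); q <- as.integer(q)
  if (m < 1L) stop("m must be >= 1", call. = FALSE)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (d < m) stop("d must be >= m (the mate-2 window must be well formed)", call. = FALSE)
  if (q < 0L || q > 93L) stop("q must lie in [0, 93]", call. = FALSE)
  structure(list(m = m, n = n, d = d, q = q), class = "pseudoread_params")
}

#' Generate uniformly tiled low-quality pseudoreads from a reference
#'
#' For each chromosome of length `Len` and each start `p` in
#' `0, n, 2n, ...` with `p + d <= Len`, one pair is emitted: mate 1 is the
#' forward window `[p, p + m)`, mate 2 the reverse complement of
#' `[p + d - m, p + d)`. All qualities equal `q`. Pairs whose mate-2 window
#' would overrun the chromosome are skipped entirely (no truncated reads), so
#' a chromosome yields `floor((Len - d) / n) + 1` pairs when `Len >= d` and
#' none otherwise. Generation is deterministic; ids are
#' `pseudo|<chrom>|<p>`.
#'
#' Windows containing N are emitted unchanged; the assembler skips k-mers
#' across N.
#'
#' @param genome a [genome()].
#' @param params a [pseudoread_params()].
#' @return A [read_pairs()] object.
#' @export
generate_pseudoreads <- function(genome, params = pseudoread_params()) {
  m <- params$m; n <- params$n; d <- params$d
  qchar <- intToUtf8(params$q + 33L)
  out <- vector("list", length(genome))
  for (i in seq_along(genome)) {
    chrom <- names(genome)[i]
    s <- unclass(genome)[[i]]
    len <- nchar(s)
    if (len < d) next
    p <- seq.int(0L, len - d, by = n)
    mate1 <- substring(s, p + 1L, p + m)
    mate2 <- reverse_complement(substring(s, p + d - m + 1L, p + d))
    out[[i]] <- data.frame(id = sprintf("pseudo|%s|%d", chrom, p),
                           seq1 = mate1, qual1 = strrep(qchar, m),
                           seq2 = mate2, qual2 = strrep(qchar, m),
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) return(read_pairs())
  df <- do.call(rbind, out)
  read_pairs(df$id, df$seq1, df$qual1, df$seq2, df$qual2)
}
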