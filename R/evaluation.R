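#' Total assembly length
#' @param contigs a [contig_set()] (or any character vector of sequences).
#' @return Total length in bases (0 for an empty set).
#' @export
total_length <- function(contigs) {
  if (length(contigs) == 0) return(0L)
  sum(nchar(unclass(contigs)))
}

#' N50 of a contig set
#'
#' The length of the shortest contig in the minimal set of largest contigs
#' that together cover at least 50% of the total assembly length.
#'
#' @param contigs a non-empty [contig_set()] (or a numeric vector of contig
#'   lengths).
#' @return N50 in bases.
#' @export
n50 <- function(contigs) {
  lens <- if (is.numeric(contigs)) as.numeric(contigs) else nchar(unclass(contigs))
  if (length(lens) == 0) stop("N50 is undefined for an empty contig set", call. = FALSE)
  lens <- sort(unname(lens), decreasing = TRUE)
  lens[which(cumsum(lens) >= sum(lens) / 2)[1]]
}

#' Length-weighted mean percent identity of a mapping set
#' @param mappings a [mapping_records()] data frame.
#' @export
weighted_idy <- function(mappings) {
  if (nrow(mappings) == 0) stop("no mappings; identity undefined", call. = FALSE)
  sum(mappings$L * mappings$idy) / sum(mappings$L)
}

#' Split long chromosomes into alignment-sized chunks
#'
#' Genome-vs-genome identity is computed by mapping fixed-size pieces of the
#' assembly to the target and averaging; this cuts each sequence longer than
#' about 1.5 chunks into near-equal pieces.
#'
#' @param g a [genome()].
#' @param chunk_size target piece size in bases (default 10000).
#' @return A [contig_set()] with ids `<chrom>|<offset>`.
#' @export
chunk_genome <- function(g, chunk_size = 10000L) {
  seqs <- character(0)
  ids <- character(0)
  for (chrom in names(g)) {
    s <- unclass(g)[[chrom]]
    len <- nchar(s)
    if (len <= 1.5 * chunk_size) {
      seqs <- c(seqs, s)
      ids <- c(ids, paste0(chrom, "|0"))
    } else {
      k <- ceiling(len / chunk_size)
      cuts <- floor(len * (0:k) / k)
      starts <- cuts[-length(cuts)]
      ends <- cuts[-1]
      seqs <- c(seqs, substring(s, starts + 1L, ends))
      ids <- c(ids, paste0(chrom, "|", starts))
    }
  }
  contig_set(seqs, ids = ids)
}

#' Percent identity and error of an assembly against a target genome
#'
#' Maps the assembly to the target with [map_contigs()] and returns the
#' length-weighted average of the per-segment percent identities (the mapped
#' segment lengths are the weights), together with `Error = 100 - IDY`.
#' A `genome` input is chunked with [chunk_genome()] first. When the same
#' assembly region maps more than once, all mappings enter the weighted
#' average. If nothing maps the identity is undefined and an error is raised.
#'
#' @param assembly a [contig_set()] or [genome()].
#' @param target the target [genome()].
#' @param min_match_len,min_idy passed to [map_contigs()].
#' @param chunk_size chunk size for genome input.
#' @return A list with `idy`, `error`, and the `mappings` used.
#' @export
idy_and_error <- function(assembly, target, min_match_len = 65L, min_idy = 90,
                          chunk_size = 10000L) {
  if (inherits(assembly, "genome")) {
    assembly <- chunk_genome(assembly, chunk_size)
  } else if (!inherits(assembly, "contig_set")) {
    assembly <- contig_set(unclass(assembly), ids = names(assembly))
  }
  maps <- map_contigs(assembly, target, min_match_len = min_match_len,
                      min_idy = min_idy)
  if (nrow(maps) == 0) {
    stop("no alignments between assembly and target; identity undefined",
         call. = FALSE)
  }
  idy <- weighted_idy(maps)
  list(idy = idy, error = 100 - idy, mappings = maps)
}

#' Number of identical bases implied by total length and identity
#'
#' `identical bases = TL * IDY / 100`, in the same units as `TL` (bases or
#' megabases).
#'
#' @param total_length assembly total length.
#' @param idy percent identity in \[0, 100\].
#' @export
identical_bases <- function(total_length, idy) {
  if (any(idy < 0 | idy > 100)) stop("idy must lie in [0, 100]", call. = FALSE)
  total_length * idy / 100
}

#' Fold coverage of a genome by a read set
#'
#' `Cov = read_length * n_reads / genome_size`. Note that one read pair
#' contributes two reads.
#'
#' @param read_length read length in bases.
#' @param n_reads number of reads.
#' @param genome_size genome size in bases.
#' @export
coverage <- function(read_length, n_reads, genome_size) {
  if (genome_size <= 0) stop("genome_size must be positive", call. = FALSE)
  read_length * n_reads / genome_size
}

.ranges_by_chrom <- function(mappings) {
  split(IRanges::IRanges(start = mappings$ref_start + 1L, end = mappings$ref_end),
        mappings$ref_chrom)
}

#' Target bases covered by a mapping set
#'
#' Union length (not sum) of the mapped target intervals; overlapping
#' mappings are counted once and adjacent intervals merge.
#'
#' @param mappings a [mapping_records()] data frame of assembly-to-target
#'   mappings.
#' @return Covered bases.
#' @export
covered_target_bases <- function(mappings) {
  if (nrow(mappings) == 0) return(0L)
  sum(vapply(.ranges_by_chrom(mappings),
             function(r) sum(IRanges::width(IRanges::reduce(r))), numeric(1)))
}

#' Number of largest contigs needed to cover half the target
#'
#' Adds contigs in decreasing length order and reports how many are needed
#' before the union of their mapped target intervals reaches 50% of the
#' target genome length; `NA` if 50% is never reached.
#'
#' @param contigs the [contig_set()].
#' @param mappings assembly-to-target [mapping_records()].
#' @param target the target [genome()].
#' @return An integer count, or `NA_integer_` if unreachable.
#' @export
n_contigs_to_half_target <- function(contigs, mappings, target) {
  half <- genome_length(target) / 2
  if (nrow(mappings) == 0) return(NA_integer_)
  lens <- nchar(unclass(contigs))
  ord <- names(contigs)[order(-lens, names(contigs))]
  acc <- mapping_records()
  covered <- 0
  for (i in seq_along(ord)) {
    sel <- mappings[mappings$contig_id == ord[i], , drop = FALSE]
    if (nrow(sel) > 0) {
      acc <- rbind(acc, sel)
      covered <- covered_target_bases(acc)
    }
    if (covered >= half) return(i)
  }
  NA_integer_
}

#' Full evaluation report for an assembly against a target genome
#'
#' Computes the assembly-quality metric suite: total length (TL), N50,
#' length-weighted identity (IDY) and Error = 100 - IDY, identical bases
#' (IDY x TL), covered target bases, the number of largest contigs covering
#' half the target, and (optionally) fold coverage of the experimental
#' reads.
#'
#' @param contigs a [contig_set()].
#' @param target the target [genome()].
#' @param read_length,n_reads optional; when both are given, fold coverage
#'   of the target by the read set is included.
#' @param min_match_len,min_idy passed to [map_contigs()].
#' @return A list of class `evaluation_report`.
#' @export
evaluate_assembly <- function(contigs, target, read_length = NULL, n_reads = NULL,
                              min_match_len = 65L, min_idy = 90) {
  tl <- total_length(contigs)
  ie <- idy_and_error(contigs, target, min_match_len = min_match_len,
                      min_idy = min_idy)
  rep <- list(
    tl_bases = tl,
    tl_mb = round_half_up(tl / 1e6, 2),
    n50 = n50(contigs),
    idy = ie$idy,
    error = ie$error,
    identical_bases = identical_bases(tl, ie$idy),
    identical_mb = round_half_up(identical_bases(tl, ie$idy) / 1e6, 2),
    covered_target_bases = covered_target_bases(ie$mappings),
    n_contigs_to_half_target = n_contigs_to_half_target(contigs, ie$mappings, target),
    cov = if (!is.null(read_length) && !is.null(n_reads)) {
      coverage(read_length, n_reads, genome_length(target))
    } else NA_real_
  )
  structure(rep, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("TL: %.2f Mb (%d bases)   N50: %d b\n", x$tl_mb, x$tl_bases, x$n50))
  cat(sprintf("IDY: %.2f%%   Error: %.2f%%   identical bases: %.2f Mb\n",
              x$idy, x$error, x$identical_mb))
  cat(sprintf("covered target bases: %d   contigs to half target: %s\n",
              x$covered_target_bases, as.character(x$n_contigs_to_half_target)))
  if (!is.na(x$cov)) cat(sprintf("read coverage: %.2fx\n", x$cov))
  invisible(x)
}
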