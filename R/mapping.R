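#' Mapping quality score
#'
#' The quality of a contig-to-reference mapping is estimated as the number of
#' identical bases it implies, `Q_map = L * idy`, where `L` is the length of
#' the mapped contig segment and `idy` the percent identity of the
#' alignment. Longer and more identical mappings are both more likely to be
#' placed correctly, and `Q_map` ranks them accordingly.
#'
#' @param mappings a [mapping_records()] data frame (or any data frame with
#'   `L` and `idy` columns).
#' @return Numeric vector of scores, one per record.
#' @examples
#' m <- mapping_records("chr1", 0, 500, "c1", 0, 500, "+", 98)
#' qmap(m)  # 49000
#' @export
qmap <- function(mappings) mappings$L * mappings$idy

#' Map contigs to a reference genome
#'
#' Seed-and-extend alignment: maximal exact seed matches (k-mer index over
#' every reference position, both contig orientations) are clustered by
#' diagonal and chained; the gaps between chained anchors and the two flanks
#' are closed with unit-cost edit-distance alignment. One record is emitted
#' per alignment locus with `idy = 100 * matches / alignment columns`
#' (gap columns count, reported to 2 decimals); a contig may yield zero, one,
#' or several records. Records with `idy < min_idy`, or from contigs shorter
#' than `min_match_len`, or whose anchor support is too thin to give a useful
#' alignment, are suppressed.
#'
#' @param contigs a [contig_set()].
#' @param reference a [genome()].
#' @param min_match_len minimum useful alignment length (default 65).
#' @param min_idy identity floor in percent (default 90; the pipeline assumes
#'   very closely related genomes).
#' @param seed_len exact seed length (default 15).
#' @param seed_step contig seed sampling step (default 5).
#' @param max_seed_hits seeds occurring more often than this in the reference
#'   are considered repetitive and skipped (default 100).
#' @return A [mapping_records()] data frame.
#' @export
map_contigs <- function(contigs, reference, min_match_len = 65L, min_idy = 90,
                        seed_len = 15L, seed_step = 5L, max_seed_hits = 100L) {
  if (length(contigs) == 0 || length(reference) == 0) return(mapping_records())
  res <- cpp_map_contigs(unname(unclass(reference)), unname(unclass(contigs)),
                         as.integer(min_match_len), as.numeric(min_idy),
                         as.integer(seed_len), as.integer(seed_step),
                         as.integer(max_seed_hits))
  if (length(res$contig) == 0) return(mapping_records())
  mapping_records(ref_chrom = names(reference)[res$chrom],
                  ref_start = res$ref_start,
                  ref_end = res$ref_end,
                  contig_id = names(contigs)[res$contig],
                  contig_start = rep(0L, length(res$contig)),
                  contig_end = res$contig_len,
                  strand = res$strand,
                  idy = res$idy)
}

#' Fraction of ambiguously mapped contigs
#'
#' The proportion of mapped contigs that map to two or more reference loci:
#' `(# contigs with >= 2 mappings) / (# contigs with >= 1 mapping)`;
#' 0 when nothing maps.
#'
#' @param mappings a [mapping_records()] data frame.
#' @return A proportion in \[0, 1\].
#' @export
ambiguous_fraction <- function(mappings) {
  if (nrow(mappings) == 0) return(0)
  tab <- table(mappings$contig_id)
  sum(tab >= 2) / length(tab)
}
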