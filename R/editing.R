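#' Select each contig's best mapping by Q_map
#'
#' Keeps, for every contig with at least one mapping, the single record that
#' maximises [qmap()]. Ties are broken deterministically towards the smaller
#' (chromosome name, ref_start, strand with '+' first). Contigs with no
#' mapping are simply absent.
#'
#' @param mappings a [mapping_records()] data frame.
#' @return A [mapping_records()] data frame with at most one row per contig.
#' @export
select_best_mappings <- function(mappings) {
  if (nrow(mappings) == 0) return(mappings)
  o <- order(mappings$contig_id, -qmap(mappings), mappings$ref_chrom,
             mappings$ref_start, mappings$strand)
  m <- mappings[o, , drop = FALSE]
  m <- m[!duplicated(m$contig_id), , drop = FALSE]
  rownames(m) <- NULL
  m
}

# Proportional projection of a reference-column trim onto contig bases:
# coords-level input carries no per-column alignment, so trimmed reference
# columns are scaled by the contig/reference length ratio of the mapping,
# rounding toward fewer contig bases.
.contig_cut <- function(ref_trim, contig_len, ref_len) {
  as.integer(floor(as.numeric(ref_trim) * as.numeric(contig_len) / ref_len))
}

#' Resolve residual overlaps between selected placements
#'
#' After best-mapping selection the only remaining ambiguity is overlapping
#' reference intervals. It is resolved greedily by preferring the beginning
#' of contigs to their ends: wherever two placements overlap, the one whose
#' interval starts later keeps its beginning and the earlier one has its tail
#' trimmed. A placement fully nested inside this rule may split the upstream
#' placement in two; both flanks are retained. Placements whose effective
#' interval becomes empty are dropped. The returned effective reference
#' intervals are pairwise disjoint per chromosome.
#'
#' Trimmed reference columns shorten the contig segment proportionally
#' (coords-level mappings carry no per-column alignment detail).
#'
#' @param selected a [mapping_records()] data frame with at most one row per
#'   contig (see [select_best_mappings()]).
#' @return A placement data frame: columns `ref_chrom`, `ref_start`,
#'   `ref_end` (effective interval), `contig_id`, `contig_start`,
#'   `contig_end`, `strand`, `idy`, and `cut_left`/`cut_right` (bases trimmed
#'   from the reference-oriented contig segment ends).
#' @export
resolve_overlaps <- function(selected) {
  empty <- data.frame(ref_chrom = character(0), ref_start = integer(0),
                      ref_end = integer(0), contig_id = character(0),
                      contig_start = integer(0), contig_end = integer(0),
                      strand = character(0), idy = numeric(0),
                      cut_left = integer(0), cut_right = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(selected) == 0) return(empty)
  if (anyDuplicated(selected$contig_id)) {
    stop("resolve_overlaps() expects at most one mapping per contig", call. = FALSE)
  }
  pieces <- list()
  for (chrom in unique(selected$ref_chrom)) {
    s <- selected[selected$ref_chrom == chrom, , drop = FALSE]
    s <- s[order(s$ref_start, s$ref_end, s$contig_id), , drop = FALSE]
    bp <- sort(unique(c(s$ref_start, s$ref_end)))
    cur_w <- 0L; cur_a <- NA_integer_; cur_b <- NA_integer_
    flush <- function() {
      if (cur_w > 0L) {
        pieces[[length(pieces) + 1L]] <<- list(row = s[cur_w, , drop = FALSE],
                                               a = cur_a, b = cur_b)
      }
    }
    for (i in seq_len(length(bp) - 1L)) {
      a <- bp[i]; b <- bp[i + 1L]
      cov <- which(s$ref_start <= a & s$ref_end >= b)
      if (length(cov) == 0) { flush(); cur_w <- 0L; next }
      # the later-starting placement wins; ties to the longer, then by id
      w <- cov[order(-s$ref_start[cov], -s$ref_end[cov], s$contig_id[cov])][1]
      if (cur_w == w && cur_b == a) {
        cur_b <- b
      } else {
        flush()
        cur_w <- w; cur_a <- a; cur_b <- b
      }
    }
    flush()
  }
  if (length(pieces) == 0) return(empty)
  out <- do.call(rbind, lapply(pieces, function(p) {
    r <- p$row
    clen <- r$contig_end - r$contig_start
    rlen <- r$ref_end - r$ref_start
    cutL <- .contig_cut(p$a - r$ref_start, clen, rlen)
    cutR <- .contig_cut(r$ref_end - p$b, clen, rlen)
    if (clen - cutL - cutR <= 0L) return(NULL)
    data.frame(ref_chrom = r$ref_chrom, ref_start = p$a, ref_end = p$b,
               contig_id = r$contig_id, contig_start = r$contig_start,
               contig_end = r$contig_end, strand = r$strand, idy = r$idy,
               cut_left = cutL, cut_right = cutR, stringsAsFactors = FALSE)
  }))
  if (is.null(out)) return(empty)
  out <- out[order(out$ref_chrom, out$ref_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Splice placed contigs into the reference
#'
#' Each chromosome is rebuilt left to right: unreplaced reference stretches
#' are copied verbatim, and each placement's effective reference interval is
#' replaced by the corresponding contig segment (reverse-complemented first
#' for minus-strand placements, so the edited reference stays in reference
#' orientation). The edited chromosome length may differ from the original
#' when contig and reference segment lengths differ (indels).
#'
#' @param reference a [genome()].
#' @param placements a placement data frame from [resolve_overlaps()]; its
#'   effective intervals must be pairwise disjoint per chromosome
#'   (overlaps are a contract violation and raise an error).
#' @param contigs the [contig_set()] the placements refer to.
#' @param with_identity also compute the percent identity of the edited
#'   reference against the original (via [idy_and_error()]); off by default
#'   because it costs a genome-scale alignment.
#' @return A list with `edited` (a [genome()]) and `report`, an edit report
#'   holding `edited_length`, `replaced_length`, `pct_ref` (replaced length
#'   as a percentage of the reference), `pct_asm` (contig bases used as a
#'   percentage of total contig bases), `n_contigs_used`, and
#'   `pct_idy_vs_ref` (NA unless `with_identity`).
#' @export
splice_reference <- function(reference, placements, contigs,
                             with_identity = FALSE) {
  g <- unclass(reference)
  ctg <- unclass(contigs)
  edited <- setNames(character(length(g)), names(g))
  replaced <- 0L
  used <- 0L
  used_ids <- character(0)
  for (chrom in names(g)) {
    s <- g[[chrom]]
    p <- placements[placements$ref_chrom == chrom, , drop = FALSE]
    if (nrow(p) == 0) { edited[[chrom]] <- s; next }
    p <- p[order(p$ref_start), , drop = FALSE]
    if (nrow(p) > 1 && any(p$ref_start[-1] < p$ref_end[-nrow(p)])) {
      stop("overlapping placements on ", chrom,
           "; run resolve_overlaps() first", call. = FALSE)
    }
    if (p$ref_end[nrow(p)] > nchar(s)) {
      stop("placement beyond the end of ", chrom, call. = FALSE)
    }
    pos <- 0L
    parts <- character(0)
    for (i in seq_len(nrow(p))) {
      parts <- c(parts, substr(s, pos + 1L, p$ref_start[i]))
      seg <- substr(ctg[[p$contig_id[i]]], p$contig_start[i] + 1L, p$contig_end[i])
      if (p$strand[i] == "-") seg <- reverse_complement(seg)
      cutL <- if ("cut_left" %in% names(p)) p$cut_left[i] else 0L
      cutR <- if ("cut_right" %in% names(p)) p$cut_right[i] else 0L
      seg <- substr(seg, cutL + 1L, nchar(seg) - cutR)
      parts <- c(parts, seg)
      pos <- p$ref_end[i]
      replaced <- replaced + (p$ref_end[i] - p$ref_start[i])
      used <- used + nchar(seg)
      used_ids <- c(used_ids, p$contig_id[i])
    }
    parts <- c(parts, substr(s, pos + 1L, nchar(s)))
    edited[[chrom]] <- paste(parts, collapse = "")
  }
  edited <- genome(edited)
  ref_len <- genome_length(reference)
  total_ctg <- sum(nchar(ctg))
  report <- structure(list(
    edited_length = genome_length(edited),
    reference_length = ref_len,
    replaced_length = replaced,
    contig_bases_used = used,
    pct_ref = 100 * replaced / ref_len,
    pct_asm = if (total_ctg > 0) 100 * used / total_ctg else 0,
    n_contigs_used = length(unique(used_ids)),
    pct_idy_vs_ref = NA_real_
  ), class = "edit_report")
  if (with_identity) {
    report$pct_idy_vs_ref <- idy_and_error(edited, reference)$idy
  }
  list(edited = edited, report = report)
}

#' @export
print.edit_report <- function(x, ...) {
  cat(sprintf("edited reference: %d bases (reference %d)\n",
              x$edited_length, x$reference_length))
  cat(sprintf("  replaced: %d bases (%.1f%% of reference, %.1f%% of assembly), %d contig(s)\n",
              x$replaced_length, x$pct_ref, x$pct_asm, x$n_contigs_used))
  if (!is.na(x$pct_idy_vs_ref)) {
    cat(sprintf("  identity vs original reference: %.3f%%\n", x$pct_idy_vs_ref))
  }
  invisible(x)
}
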