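#' Construct a genome object
#'
#' A genome is an ordered, named character vector of chromosome sequences over
#' the alphabet \{A, C, G, T, N\}. Lowercase input is folded to uppercase.
#' The reference, the target, and the edited reference are all this type.
#'
#' @param sequences named character vector, one element per chromosome.
#' @return An object of class `genome`.
#' @examples
#' g <- genome(c(chr1 = "ACGT"))
#' genome_length(g)
#' @export
genome <- function(sequences) {
  if (!is.character(sequences)) stop("sequences must be a character vector", call. = FALSE)
  if (length(sequences) == 0) stop("a genome needs at least one chromosome", call. = FALSE)
  nm <- names(sequences)
  if (is.null(nm) || any(is.na(nm)) || any(!nzchar(nm))) {
    stop("every chromosome must have a non-empty name", call. = FALSE)
  }
  if (anyDuplicated(nm)) {
    stop("duplicate chromosome name: ", nm[duplicated(nm)][1], call. = FALSE)
  }
  sequences <- toupper(sequences)
  if (any(!nzchar(sequences))) {
    stop("empty sequence for chromosome ", nm[!nzchar(sequences)][1], call. = FALSE)
  }
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) {
    stop("chromosome ", nm[bad][1],
         " contains characters outside {A, C, G, T, N}", call. = FALSE)
  }
  structure(sequences, class = "genome")
}

#' Total genome length in bases
#' @param g a `genome`.
#' @export
genome_length <- function(g) sum(nchar(unclass(g)))

#' @export
print.genome <- function(x, ...) {
  cat("genome:", length(x), "chromosome(s),", genome_length(x), "bases\n")
  for (nm in names(x)) cat(" ", nm, ":", nchar(x[[nm]]), "bases\n")
  invisible(x)
}

#' Construct a contig set
#'
#' An ordered collection of assembled sequences with unique ids.
#'
#' @param sequences character vector of contig sequences.
#' @param ids optional character vector of ids; defaults to `contig_00001`, ...
#' @return An object of class `contig_set` (a named character vector).
#' @export
contig_set <- function(sequences = character(0), ids = NULL) {
  sequences <- as.character(sequences)
  if (!is.null(ids)) names(sequences) <- ids
  if (length(sequences) == 0) {
    return(structure(setNames(character(0), character(0)), class = "contig_set"))
  }
  if (is.null(names(sequences))) {
    names(sequences) <- sprintf("contig_%05d", seq_along(sequences))
  }
  if (anyDuplicated(names(sequences))) {
    stop("duplicate contig id: ", names(sequences)[duplicated(names(sequences))][1],
         call. = FALSE)
  }
  sequences <- toupper(sequences)
  if (any(grepl("[^ACGTN]", sequences))) {
    stop("contig sequence contains characters outside {A, C, G, T, N}", call. = FALSE)
  }
  structure(sequences, class = "contig_set")
}

#' @export
print.contig_set <- function(x, ...) {
  cat("contig_set:", length(x), "contig(s),", sum(nchar(unclass(x))), "bases\n")
  invisible(x)
}

#' Construct paired-end reads
#'
#' Both experimental reads and pseudoreads use this representation: a data
#' frame with one row per pair, holding both mate sequences and their
#' per-base Phred qualities (stored Sanger/Phred+33 encoded).
#'
#' @param id character vector of pair ids (without `/1`, `/2` suffixes).
#' @param seq1,seq2 mate sequences.
#' @param qual1,qual2 qualities: either Phred+33 strings or lists of integer
#'   Phred vectors.
#' @return A data frame of class `read_pairs` with columns
#'   `id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
read_pairs <- function(id = character(0), seq1 = character(0), qual1 = character(0),
                       seq2 = character(0), qual2 = character(0)) {
  if (is.list(qual1)) qual1 <- vapply(qual1, phred_encode, character(1))
  if (is.list(qual2)) qual2 <- vapply(qual2, phred_encode, character(1))
  seq1 <- toupper(seq1); seq2 <- toupper(seq2)
  df <- data.frame(id = as.character(id), seq1 = seq1, qual1 = qual1,
                   seq2 = seq2, qual2 = qual2, stringsAsFactors = FALSE)
  if (nrow(df) > 0) {
    if (any(nchar(df$seq1) != nchar(df$qual1)) || any(nchar(df$seq2) != nchar(df$qual2))) {
      stop("sequence and quality lengths differ", call. = FALSE)
    }
    if (any(grepl("[^ACGTN]", c(df$seq1, df$seq2)))) {
      stop("read sequence contains characters outside {A, C, G, T, N}", call. = FALSE)
    }
  }
  class(df) <- c("read_pairs", "data.frame")
  df
}

#' Concatenate read-pair sets
#' @param ... `read_pairs` objects.
#' @export
combine_reads <- function(...) {
  parts <- list(...)
  out <- do.call(rbind, lapply(parts, function(p) as.data.frame(unclass(p))))
  rownames(out) <- NULL
  class(out) <- c("read_pairs", "data.frame")
  out
}

#' Construct a set of contig-to-reference mapping records
#'
#' All coordinates are 0-based half-open; MUMmer-style coords files are
#' converted at the boundary by [read_coords()]/[write_coords()]. `L` is the
#' length of the mapped contig segment, `idy` the percent identity of the
#' alignment in \[0, 100\].
#'
#' @param ref_chrom,ref_start,ref_end reference interval.
#' @param contig_id,contig_start,contig_end contig interval.
#' @param strand `"+"` or `"-"`.
#' @param idy percent identity.
#' @return A data frame with one row per mapping and an `L` column.
#' @export
mapping_records <- function(ref_chrom = character(0), ref_start = integer(0),
                            ref_end = integer(0), contig_id = character(0),
                            contig_start = integer(0), contig_end = integer(0),
                            strand = character(0), idy = numeric(0)) {
  df <- data.frame(ref_chrom = as.character(ref_chrom),
                   ref_start = as.integer(ref_start),
                   ref_end = as.integer(ref_end),
                   contig_id = as.character(contig_id),
                   contig_start = as.integer(contig_start),
                   contig_end = as.integer(contig_end),
                   strand = as.character(strand),
                   idy = as.numeric(idy),
                   stringsAsFactors = FALSE)
  df$L <- df$contig_end - df$contig_start
  if (nrow(df) > 0) {
    if (any(df$ref_start >= df$ref_end)) stop("ref_start must be < ref_end", call. = FALSE)
    if (any(df$contig_start >= df$contig_end)) {
      stop("contig_start must be < contig_end", call. = FALSE)
    }
    if (any(df$idy < 0 | df$idy > 100)) stop("idy must lie in [0, 100]", call. = FALSE)
    if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'", call. = FALSE)
  }
  rownames(df) <- NULL
  df
}
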