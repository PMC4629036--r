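# Readers and writers for FASTA, paired FASTQ (Sanger quality encoding) and
# the show-coords tab dialect. Parsing is delegated to Biostrings; this layer
# adds the package's validation rules (strict {A,C,G,T,N} alphabet, unique
# names, paired-file consistency) and the coordinate-convention boundary:
# files are 1-based inclusive, everything in memory is 0-based half-open.

.fasta_error <- function(path, msg) {
  lines <- tryCatch(readLines(path, warn = FALSE), error = function(e) character(0))
  is_seq <- !startsWith(lines, ">")
  bad <- which(is_seq & grepl("[^ACGTNacgtn[:space:]]", lines))
  if (length(bad) > 0) {
    stop("FASTA format error in '", path, "' at line ", bad[1],
         ": residue outside {A, C, G, T, N}", call. = FALSE)
  }
  stop("FASTA format error in '", path, "': ", msg, call. = FALSE)
}

.read_fasta_seqs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ss <- tryCatch(Biostrings::readDNAStringSet(path),
                 error = function(e) .fasta_error(path, conditionMessage(e)))
  if (length(ss) == 0) .fasta_error(path, "empty file (no records)")
  nms <- sub("\\s.*$", "", names(ss))  # drop description after first whitespace
  if (any(!nzchar(nms))) .fasta_error(path, "record with empty name")
  if (anyDuplicated(nms)) {
    stop("FASTA format error in '", path, "': duplicate sequence name '",
         nms[duplicated(nms)][1], "'", call. = FALSE)
  }
  seqs <- toupper(as.character(ss))
  if (any(!nzchar(seqs))) {
    .fasta_error(path, paste0("empty sequence for record '", nms[!nzchar(seqs)][1], "'"))
  }
  if (any(grepl("[^ACGTN]", seqs))) .fasta_error(path, "residue outside {A, C, G, T, N}")
  setNames(seqs, nms)
}

#' Read a FASTA file as a genome
#'
#' Sequences are folded to uppercase; record order is preserved; header text
#' after the first whitespace is dropped from the name. Residues outside
#' \{A, C, G, T, N\} (including other IUPAC ambiguity codes), duplicate or
#' empty names, and empty files raise a format error naming the offending
#' line where possible.
#'
#' @param path path to a FASTA file.
#' @return A [genome()].
#' @export
read_fasta <- function(path) genome(.read_fasta_seqs(path))

#' Read a FASTA file as a contig set
#' @param path path to a FASTA file.
#' @return A [contig_set()].
#' @export
read_contigs <- function(path) {
  s <- .read_fasta_seqs(path)
  contig_set(unname(s), ids = names(s))
}

#' Write a genome or contig set to FASTA
#'
#' Sequence lines are wrapped at 70 columns.
#'
#' @param x a `genome` or `contig_set` (any named character vector of DNA).
#' @param path output path.
#' @export
write_fasta <- function(x, path) {
  ss <- Biostrings::DNAStringSet(unclass(x))
  Biostrings::writeXStringSet(ss, filepath = path, width = 70L)
  invisible(path)
}

#' Write paired-end reads as two Sanger-encoded FASTQ files
#'
#' Mate 1 goes to `path1`, mate 2 to `path2`, in the same order, with ids
#' suffixed `/1` and `/2`. Qualities must be in the Sanger Phred range
#' \[0, 93\] (encoded as ASCII 33..126); anything outside raises an error.
#' Round-trips bit-exactly through [read_paired_fastq()].
#'
#' @param pairs a [read_pairs()] object.
#' @param path1,path2 output paths for mate 1 and mate 2.
#' @export
write_paired_fastq <- function(pairs, path1, path2) {
  chk <- function(qual) {
    r <- range(unlist(lapply(qual, utf8ToInt)))
    if (length(qual) > 0 && (r[1] < 33 || r[2] > 126)) {
      stop("quality out of [0, 93]", call. = FALSE)
    }
  }
  chk(pairs$qual1); chk(pairs$qual2)
  # records written directly: the dialect pins a bare "+" separator line
  w <- function(seqs, quals, ids, path) {
    con <- file(path, "wb")
    on.exit(close(con))
    if (length(seqs) > 0) {
      writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals),
                 con, sep = "\n")
    }
  }
  w(pairs$seq1, pairs$qual1, paste0(pairs$id, "/1"), path1)
  w(pairs$seq2, pairs$qual2, paste0(pairs$id, "/2"), path2)
  invisible(c(path1, path2))
}

#' Read two paired FASTQ files (Sanger encoding)
#'
#' Expects the two files record-by-record in the same order with ids
#' suffixed `/1` and `/2` (suffixes are stripped; a bare common id is also
#' accepted).
#'
#' @param path1,path2 mate-1 and mate-2 FASTQ paths.
#' @return A [read_pairs()] object.
#' @export
read_paired_fastq <- function(path1, path2) {
  rd <- function(path, suffix) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    ss <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
    list(id = sub(paste0("/", suffix, "$"), "", names(ss)),
         seq = toupper(as.character(ss)),
         qual = as.character(S4Vectors::mcols(ss)$qualities))
  }
  a <- rd(path1, "1")
  b <- rd(path2, "2")
  if (length(a$id) != length(b$id) || !all(a$id == b$id)) {
    stop("paired FASTQ files disagree on read ids or order", call. = FALSE)
  }
  read_pairs(a$id, unname(a$seq), unname(a$qual), unname(b$seq), unname(b$qual))
}

#' Parse a show-coords tab file into mapping records
#'
#' The expected dialect is tab-separated
#' `S1 E1 S2 E2 LEN1 LEN2 %IDY ref_name query_name` with 1-based inclusive
#' coordinates; query coordinates are reversed (`S2 > E2`) on the minus
#' strand. Coordinates are converted to 0-based half-open and the strand is
#' inferred from the query coordinate order.
#'
#' @param path path to the coords file; an empty file yields zero records.
#' @return A [mapping_records()] data frame.
#' @export
read_coords <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(mapping_records())
  df <- utils::read.table(text = lines, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("s1", "e1", "s2", "e2", "len1", "len2",
                                        "idy", "ref", "qry"))
  for (col in c("s1", "e1", "s2", "e2", "len1", "len2", "idy")) {
    if (!is.numeric(df[[col]])) {
      stop("coords format error in '", path, "': non-numeric field in column ",
           col, call. = FALSE)
    }
  }
  if (any(df$s1 > df$e1)) {
    stop("coords format error in '", path,
         "': reference start exceeds end (S1 > E1)", call. = FALSE)
  }
  minus <- df$s2 > df$e2
  mapping_records(ref_chrom = df$ref,
                  ref_start = df$s1 - 1L,
                  ref_end = df$e1,
                  contig_id = df$qry,
                  contig_start = pmin(df$s2, df$e2) - 1L,
                  contig_end = pmax(df$s2, df$e2),
                  strand = ifelse(minus, "-", "+"),
                  idy = df$idy)
}

#' Write mapping records as a show-coords tab file
#'
#' Inverse of [read_coords()]: 0-based half-open intervals become 1-based
#' inclusive, and minus-strand query coordinates are written reversed.
#'
#' @param mappings a [mapping_records()] data frame.
#' @param path output path.
#' @export
write_coords <- function(mappings, path) {
  m <- mappings
  if (nrow(m) == 0) {
    file.create(path)
    return(invisible(path))
  }
  plus <- m$strand == "+"
  df <- data.frame(s1 = m$ref_start + 1L,
                   e1 = m$ref_end,
                   s2 = ifelse(plus, m$contig_start + 1L, m$contig_end),
                   e2 = ifelse(plus, m$contig_end, m$contig_start + 1L),
                   len1 = m$ref_end - m$ref_start,
                   len2 = m$contig_end - m$contig_start,
                   idy = sprintf("%.2f", m$idy),
                   ref = m$ref_chrom,
                   qry = m$contig_id)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
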