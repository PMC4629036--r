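#' Internal assembler configuration
#'
#' @param k odd k-mer size in \[11, 31\].
#' @param min_contig_len minimum emitted contig length (>= k).
#' @param min_kmer_count solid-k-mer threshold; the default of 1 relies on
#'   pseudoreads guaranteeing coverage everywhere and on desk-scale inputs
#'   where error k-mers are tolerable; raise it for noisy simulations.
#' @export
assembler_config <- function(k = 21L, min_contig_len = 100L, min_kmer_count = 1L) {
  k <- as.integer(k)
  min_contig_len <- as.integer(min_contig_len)
  min_kmer_count <- as.integer(min_kmer_count)
  if (k %% 2L == 0L) stop("k must be odd", call. = FALSE)
  if (k < 11L || k > 31L) stop("k must lie in [11, 31]", call. = FALSE)
  if (min_contig_len < k) stop("min_contig_len must be >= k", call. = FALSE)
  if (min_kmer_count < 1L) stop("min_kmer_count must be >= 1", call. = FALSE)
  structure(list(k = k, min_contig_len = min_contig_len,
                 min_kmer_count = min_kmer_count), class = "assembler_config")
}

#' Co-assemble reads into contigs with the quality-aware de Bruijn assembler
#'
#' Builds a de Bruijn graph on canonical k-mers (k-mers containing N are
#' skipped), prunes k-mers seen fewer than `min_kmer_count` times, and
#' extracts paths greedily. At every branch the successor with the highest
#' summed base quality wins (exact ties go to the alphabetically earliest
#' base), so high-quality experimental bases outvote low-quality pseudoread
#' bases wherever the two disagree; this is the mechanism that lets the
#' co-assembly recover the sequenced genome rather than the reference.
#' Contigs shorter than `min_contig_len` are dropped. Deterministic given
#' input order and configuration.
#'
#' @param reads a [read_pairs()] object (experimental reads, pseudoreads, or
#'   a [combine_reads()] of both).
#' @param config an [assembler_config()].
#' @return A [contig_set()]; empty (with a warning) if every read is shorter
#'   than k.
#' @export
assemble <- function(reads, config = assembler_config()) {
  if (nrow(reads) == 0) return(contig_set())
  seqs <- c(reads$seq1, reads$seq2)
  quals <- c(reads$qual1, reads$qual2)
  if (all(nchar(seqs) < config$k)) {
    warning("all reads are shorter than k = ", config$k, "; no contigs assembled")
    return(contig_set())
  }
  ctg <- cpp_assemble(seqs, quals, config$k, config$min_kmer_count,
                      config$min_contig_len)
  contig_set(ctg)
}

#' Run an external assembler through a command template
#'
#' Any assembler can stand in for the internal one. The template must contain
#' the placeholders `{reads}` (replaced by the space-separated read paths)
#' and `{out}` (the contig FASTA the command is expected to produce);
#' `{workdir}` is also substituted. With `dry_run = TRUE` the substituted
#' command string is returned without executing anything. A missing binary or
#' a non-zero exit raises an explicit error (never a silent fallback).
#'
#' @param cmd_template command template string.
#' @param reads_paths character vector of read file paths.
#' @param workdir working directory for the run.
#' @param contigs_file name of the FASTA the command writes (joined to
#'   `workdir` to form `{out}`).
#' @param dry_run if TRUE, return the command string instead of running it.
#' @return The substituted command (`dry_run = TRUE`) or a [contig_set()].
#' @export
run_external_assembler <- function(cmd_template, reads_paths, workdir,
                                   contigs_file = "contigs.fa", dry_run = FALSE) {
  out <- file.path(workdir, contigs_file)
  cmd <- cmd_template
  cmd <- gsub("{reads}", paste(reads_paths, collapse = " "), cmd, fixed = TRUE)
  cmd <- gsub("{out}", out, cmd, fixed = TRUE)
  cmd <- gsub("{workdir}", workdir, cmd, fixed = TRUE)
  if (dry_run) return(cmd)
  prog <- strsplit(trimws(cmd), "[[:space:]]+")[[1]][1]
  if (Sys.which(prog) == "") {
    stop("external assembler not found on PATH: ", prog, call. = FALSE)
  }
  status <- system(cmd)
  if (status != 0) {
    stop("external assembler exited with status ", status, ": ", cmd, call. = FALSE)
  }
  if (!file.exists(out)) {
    stop("external assembler did not produce ", out, call. = FALSE)
  }
  read_contigs(out)
}
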