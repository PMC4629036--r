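# End-to-end orchestration: pseudoreads -> co-assembly -> mapping ->
# best-mapping selection -> overlap resolution -> splicing, with optional
# evaluation against a known target genome (simulation mode) and optional
# persistence of every intermediate artifact.

.as_genome_input <- function(x, what = "reference") {
  if (inherits(x, "genome")) return(x)
  if (is.character(x) && length(x) == 1 && is.null(names(x))) {
    if (!file.exists(x)) {
      stop("config error: ", what, " file not found: ", x, call. = FALSE)
    }
    return(read_fasta(x))
  }
  genome(x)
}

.as_reads_input <- function(x) {
  if (inherits(x, "read_pairs")) return(x)
  if (is.character(x) && length(x) == 2) {
    missing <- x[!file.exists(x)]
    if (length(missing) > 0) {
      stop("config error: reads file not found: ", missing[1], call. = FALSE)
    }
    return(read_paired_fastq(x[1], x[2]))
  }
  stop("reads must be a read_pairs object or a length-2 vector of FASTQ paths",
       call. = FALSE)
}

#' Run the reference-assisted assembly pipeline end to end
#'
#' Generates pseudoreads from the reference, co-assembles them with the
#' experimental reads, maps the contigs back to the reference, selects each
#' contig's best mapping by Q_map, resolves residual overlaps greedily, and
#' splices the surviving contig segments into the reference to produce the
#' edited reference. If a target genome is supplied (simulation mode) the
#' contigs and the edited reference are additionally evaluated against it.
#' The run is deterministic given its inputs.
#'
#' @param reference a [genome()] or FASTA path.
#' @param reads a [read_pairs()] object or a length-2 vector of paired FASTQ
#'   paths.
#' @param pseudo_params a [pseudoread_params()].
#' @param assembler an [assembler_config()], or a command-template string to
#'   delegate to [run_external_assembler()].
#' @param min_match_len,min_idy contig-mapping thresholds (see
#'   [map_contigs()]).
#' @param target optional target [genome()] or FASTA path for evaluation.
#' @param out_dir optional directory; when given, every intermediate artifact
#'   is persisted there (pseudoread FASTQ, contig FASTA, mappings in coords
#'   format, edited FASTA, reports as JSON).
#' @param identity_vs_ref also compute the edited-vs-original-reference
#'   identity for the edit report (costs a genome-scale alignment).
#' @param verbose log each stage with [message()].
#' @return A list with `edited`, `edit_report`, `contigs`, `mappings`,
#'   `best_mappings`, `placements`, `ambiguous_fraction`, and (in simulation
#'   mode) `evaluation` with contig metrics plus edited-vs-target and
#'   reference-vs-target identities.
#' @export
run_pipeline <- function(reference, reads,
                         pseudo_params = pseudoread_params(),
                         assembler = assembler_config(),
                         min_match_len = 65L, min_idy = 90,
                         target = NULL, out_dir = NULL,
                         identity_vs_ref = FALSE, verbose = TRUE) {
  say <- function(...) if (verbose) message("[refasm] ", ...)
  reference <- .as_genome_input(reference, "reference")
  reads <- .as_reads_input(reads)
  if (!is.null(target)) target <- .as_genome_input(target, "target")
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  say("generating pseudoreads (m=", pseudo_params$m, ", n=", pseudo_params$n,
      ", d=", pseudo_params$d, ", q=", pseudo_params$q, ")")
  pseudo <- generate_pseudoreads(reference, pseudo_params)
  say(nrow(pseudo), " pseudoread pairs, ", nrow(reads), " experimental pairs")
  if (!is.null(out_dir) && nrow(pseudo) > 0) {
    write_paired_fastq(pseudo, file.path(out_dir, "pseudoreads_1.fq"),
                       file.path(out_dir, "pseudoreads_2.fq"))
  }

  all_reads <- combine_reads(reads, pseudo)
  if (is.character(assembler)) {
    stop("to use an external assembler, call run_external_assembler() and ",
         "pass its contigs to map_contigs()/splice_reference() directly",
         call. = FALSE)
  }
  say("assembling (k=", assembler$k, ")")
  contigs <- assemble(all_reads, assembler)
  if (length(contigs) == 0) stop("assembly produced no contigs", call. = FALSE)
  say(length(contigs), " contigs, total ", total_length(contigs), " bases, N50 ",
      n50(contigs))
  if (!is.null(out_dir)) write_fasta(contigs, file.path(out_dir, "contigs.fa"))

  say("mapping contigs to the reference")
  mappings <- map_contigs(contigs, reference, min_match_len = min_match_len,
                          min_idy = min_idy)
  amb <- ambiguous_fraction(mappings)
  say(nrow(mappings), " mappings; ambiguously mapped contig fraction ",
      sprintf("%.3f", amb))
  if (!is.null(out_dir)) write_coords(mappings, file.path(out_dir, "mappings.coords"))

  best <- select_best_mappings(mappings)
  placements <- resolve_overlaps(best)
  say("splicing ", nrow(placements), " placement(s) from ",
      length(unique(placements$contig_id)), " contig(s)")
  sp <- splice_reference(reference, placements, contigs,
                         with_identity = identity_vs_ref)
  if (!is.null(out_dir)) write_fasta(sp$edited, file.path(out_dir, "edited.fa"))

  evaluation <- NULL
  if (!is.null(target)) {
    say("evaluating against the target genome")
    contig_eval <- evaluate_assembly(contigs, target, min_match_len = min_match_len,
                                     min_idy = min_idy)
    edited_idy <- idy_and_error(sp$edited, target)$idy
    ref_idy <- idy_and_error(reference, target)$idy
    say(sprintf("contig Error %.3f%%; identity to target: edited %.3f%% vs reference %.3f%%",
                contig_eval$error, edited_idy, ref_idy))
    evaluation <- list(contigs = contig_eval,
                       edited_vs_target_idy = edited_idy,
                       reference_vs_target_idy = ref_idy)
  }

  result <- list(edited = sp$edited, edit_report = sp$report, contigs = contigs,
                 mappings = mappings, best_mappings = best,
                 placements = placements, ambiguous_fraction = amb,
                 evaluation = evaluation)
  if (!is.null(out_dir)) {
    rep <- list(edit_report = unclass(sp$report),
                ambiguous_fraction = amb)
    if (!is.null(evaluation)) {
      rep$evaluation <- list(contigs = unclass(evaluation$contigs),
                             edited_vs_target_idy = evaluation$edited_vs_target_idy,
                             reference_vs_target_idy = evaluation$reference_vs_target_idy)
    }
    jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  result
}
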