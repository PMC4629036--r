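# Synthetic-data generators: a random reference, a point-mutation-scale
# genome evolver, and a wgsim-like paired-end read simulator. These are
# documented stand-ins for full evolution/read simulators, aimed at the
# regime the pipeline targets: ~1% divergence between reference and target.

#' Generate a random multi-chromosome genome
#'
#' I.i.d. bases at the requested GC fraction; deterministic per seed.
#'
#' @param lengths integer vector of chromosome lengths.
#' @param gc GC fraction in (0, 1) (default 0.5).
#' @param seed RNG seed.
#' @param names chromosome names (default `chr1`, `chr2`, ...).
#' @return A [genome()].
#' @export
random_genome <- function(lengths, gc = 0.5, seed = 1L, names = NULL) {
  stopifnot(all(lengths > 0))
  if (is.null(names)) names <- paste0("chr", seq_along(lengths))
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  with_seed(seed, {
    seqs <- vapply(lengths, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = p),
            collapse = "")
    }, character(1))
    genome(setNames(seqs, names))
  })
}

#' Genome evolution parameters
#'
#' Per-base independent event model: substitution with probability
#' `snp_rate`, insertion/deletion events at `ins_rate`/`del_rate` with
#' geometric lengths of the given mean. The defaults emulate roughly 1%
#' divergence dominated by SNPs with occasional short indels, i.e. the
#' "very closely related genomes" regime.
#'
#' @param snp_rate per-base substitution probability (default 0.01).
#' @param ins_rate,del_rate per-base indel event probabilities
#'   (default 5e-4 each).
#' @param indel_mean mean indel length; lengths are geometric (default 3).
#' @param seed RNG seed.
#' @export
evolution_params <- function(snp_rate = 0.01, ins_rate = 5e-4, del_rate = 5e-4,
                             indel_mean = 3, seed = 1L) {
  rates <- c(snp_rate, ins_rate, del_rate)
  if (any(rates < 0) || any(rates >= 1) || sum(rates) >= 1) {
    stop("rates must lie in [0, 1) and sum to < 1", call. = FALSE)
  }
  if (indel_mean < 1) stop("indel_mean must be >= 1", call. = FALSE)
  structure(list(snp_rate = snp_rate, ins_rate = ins_rate, del_rate = del_rate,
                 indel_mean = indel_mean, seed = as.integer(seed)),
            class = "evolution_params")
}

.ALT_BASES <- matrix(c("C", "G", "T",
                       "A", "G", "T",
                       "A", "C", "T",
                       "A", "C", "G"),
                     nrow = 4, byrow = TRUE,
                     dimnames = list(c("A", "C", "G", "T"), NULL))

#' Evolve a genome into a diverged target
#'
#' Applies per-base independent substitutions and short indels and records
#' every event in a truth log with reference coordinates (1-based). An
#' insertion of `alt` is placed immediately after its anchor position; a
#' deletion removes `nchar(ref)` bases starting at its position. Deletion
#' events falling inside an earlier deletion are skipped; insertions anchored
#' on a deleted base are lost with it.
#'
#' @param genome the ancestral [genome()] (used as the reference).
#' @param params an [evolution_params()].
#' @return A list with `target` (a [genome()]), `truth` (a data frame with
#'   columns `chrom`, `pos`, `type` in SNP/INS/DEL, `ref`, `alt`), and
#'   `divergence` (edited bases / reference length).
#' @export
evolve <- function(genome, params = evolution_params()) {
  snp <- params$snp_rate; ins <- params$ins_rate; del <- params$del_rate
  gdraw <- unclass(genome)
  with_seed(params$seed, {
    targets <- setNames(character(length(gdraw)), names(gdraw))
    logs <- list()
    edits <- 0
    for (chrom in names(gdraw)) {
      v <- strsplit(gdraw[[chrom]], "", fixed = TRUE)[[1]]
      L <- length(v)
      u <- runif(L)
      snp_pos <- which(u < snp & v %in% rownames(.ALT_BASES))
      ins_pos <- which(u >= snp & u < snp + ins)
      del_pos <- which(u >= snp + ins & u < snp + ins + del)

      out <- v
      snp_ref <- v[snp_pos]
      snp_alt <- character(0)
      if (length(snp_pos) > 0) {
        choice <- sample.int(3L, length(snp_pos), replace = TRUE)
        snp_alt <- .ALT_BASES[cbind(match(snp_ref, rownames(.ALT_BASES)), choice)]
        out[snp_pos] <- snp_alt
      }

      del_keep <- integer(0); del_len <- integer(0); del_ref <- character(0)
      if (length(del_pos) > 0) {
        lens <- rgeom(length(del_pos), 1 / params$indel_mean) + 1L
        last_end <- 0L
        for (j in seq_along(del_pos)) {
          p <- del_pos[j]
          if (p <= last_end) next
          len <- min(lens[j], L - p + 1L)
          del_keep <- c(del_keep, p); del_len <- c(del_len, len)
          del_ref <- c(del_ref, paste(v[p:(p + len - 1L)], collapse = ""))
          out[p:(p + len - 1L)] <- ""
          last_end <- p + len - 1L
        }
      }

      ins_seq <- character(0)
      if (length(ins_pos) > 0) {
        deleted <- !nzchar(out)
        ins_pos <- ins_pos[!deleted[ins_pos]]
        if (length(ins_pos) > 0) {
          lens <- rgeom(length(ins_pos), 1 / params$indel_mean) + 1L
          ins_seq <- vapply(lens, function(l) {
            paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
          }, character(1))
          out[ins_pos] <- paste0(out[ins_pos], ins_seq)
        }
      }

      log <- rbind(
        if (length(snp_pos)) data.frame(chrom = chrom, pos = snp_pos, type = "SNP",
                                        ref = snp_ref, alt = snp_alt,
                                        stringsAsFactors = FALSE),
        if (length(del_keep)) data.frame(chrom = chrom, pos = del_keep, type = "DEL",
                                         ref = del_ref, alt = "",
                                         stringsAsFactors = FALSE),
        if (length(ins_pos)) data.frame(chrom = chrom, pos = ins_pos, type = "INS",
                                        ref = "", alt = ins_seq,
                                        stringsAsFactors = FALSE)
      )
      if (!is.null(log)) {
        log <- log[order(log$pos, log$type), , drop = FALSE]
        logs[[chrom]] <- log
      }
      edits <- edits + length(snp_pos) + sum(del_len) +
        sum(nchar(ins_seq))
      targets[[chrom]] <- paste(out, collapse = "")
    }
    truth <- if (length(logs)) do.call(rbind, logs) else
      data.frame(chrom = character(0), pos = integer(0), type = character(0),
                 ref = character(0), alt = character(0), stringsAsFactors = FALSE)
    rownames(truth) <- NULL
    list(target = genome(targets), truth = truth,
         divergence = edits / genome_length(genome))
  })
}

#' Write / read a truth log as a tab-separated file
#' @param truth the truth data frame from [evolve()].
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Paired-end read simulation parameters
#'
#' Fragments are placed uniformly on each chromosome (proportionally to
#' chromosome length); mate 1 reads the forward strand from the fragment
#' start, mate 2 the reverse complement of the fragment end. Sequencing
#' errors are i.i.d. substitutions at `base_error_rate`; all bases carry a
#' fixed high quality (`quality`, default Q40) so that simulated experimental
#' reads outrank q=10 pseudoreads in the assembly.
#'
#' @param n_pairs number of read pairs.
#' @param read_length read length in bases (default 70).
#' @param fragment_mean,fragment_sd fragment length distribution
#'   (default 500 +/- 50).
#' @param base_error_rate per-base substitution error probability
#'   (default 0: an idealised error-free run).
#' @param quality Phred quality assigned to every base (default 40).
#' @param seed RNG seed.
#' @export
read_sim_params <- function(n_pairs, read_length = 70L, fragment_mean = 500,
                            fragment_sd = 50, base_error_rate = 0,
                            quality = 40L, seed = 1L) {
  if (n_pairs < 1) stop("n_pairs must be positive", call. = FALSE)
  if (read_length > fragment_mean) {
    stop("read_length must be <= fragment_mean", call. = FALSE)
  }
  if (base_error_rate < 0 || base_error_rate >= 1) {
    stop("base_error_rate must lie in [0, 1)", call. = FALSE)
  }
  structure(list(n_pairs = as.integer(n_pairs),
                 read_length = as.integer(read_length),
                 fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                 base_error_rate = base_error_rate,
                 quality = as.integer(quality), seed = as.integer(seed)),
            class = "read_sim_params")
}

.inject_errors <- function(seqs, rate) {
  rl <- nchar(seqs)
  ne <- rbinom(length(seqs), rl, rate)
  for (i in which(ne > 0)) {
    pos <- sample.int(rl[i], ne[i])
    for (p in pos) {
      orig <- substr(seqs[i], p, p)
      if (!orig %in% rownames(.ALT_BASES)) next
      alt <- .ALT_BASES[orig, sample.int(3L, 1L)]
      substr(seqs[i], p, p) <- alt
    }
  }
  seqs
}

#' Simulate paired-end reads from a target genome
#'
#' @param target a [genome()]; chromosomes shorter than
#'   `fragment_mean + 4 * fragment_sd` are skipped with a warning.
#' @param params a [read_sim_params()].
#' @return A [read_pairs()] object; deterministic per seed.
#' @export
simulate_reads <- function(target, params) {
  rl <- params$read_length
  need <- params$fragment_mean + 4 * params$fragment_sd
  lens <- nchar(unclass(target))
  ok <- lens >= need
  if (!any(ok)) stop("every chromosome is too short for the fragment model", call. = FALSE)
  if (!all(ok)) {
    warning("skipping chromosome(s) shorter than fragment_mean + 4*fragment_sd: ",
            paste(names(target)[!ok], collapse = ", "))
  }
  lens <- lens[ok]
  chroms <- names(target)[ok]
  n_c <- floor(as.numeric(params$n_pairs) * lens / sum(as.numeric(lens)))
  rem <- params$n_pairs - sum(n_c)
  if (rem > 0) {  # distribute the remainder to the largest chromosomes
    take <- order(-lens)[seq_len(rem)]
    n_c[take] <- n_c[take] + 1L
  }
  with_seed(params$seed, {
    parts <- vector("list", length(chroms))
    for (i in seq_along(chroms)) {
      n <- n_c[i]
      if (n == 0) next
      s <- unclass(target)[[chroms[i]]]
      len <- lens[i]
      frag <- pmax(rl, pmin(len, round(rnorm(n, params$fragment_mean,
                                             params$fragment_sd))))
      start0 <- floor(runif(n) * (len - frag + 1))
      m1 <- substring(s, start0 + 1, start0 + rl)
      m2 <- reverse_complement(substring(s, start0 + frag - rl + 1, start0 + frag))
      if (params$base_error_rate > 0) {
        m1 <- .inject_errors(m1, params$base_error_rate)
        m2 <- .inject_errors(m2, params$base_error_rate)
      }
      parts[[i]] <- data.frame(
        id = sprintf("sim|%s|%d|%d", chroms[i], start0, seq_len(n)),
        seq1 = m1, seq2 = m2, stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
    q <- strrep(intToUtf8(params$quality + 33L), rl)
    read_pairs(df$id, df$seq1, rep(q, nrow(df)), df$seq2, rep(q, nrow(df)))
  })
}
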