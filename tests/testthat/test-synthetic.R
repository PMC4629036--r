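test_that("random_genome is deterministic and hits the requested GC", {
  a <- random_genome(100, seed = 5)
  b <- random_genome(100, seed = 5)
  expect_identical(unclass(a), unclass(b))

  g <- random_genome(c(10000, 10000, 10000), seed = 6)
  expect_length(g, 3)
  expect_named(g, c("chr1", "chr2", "chr3"))
  expect_equal(genome_length(g), 30000)

  big <- random_genome(1e6, gc = 0.5, seed = 7)
  gc <- sum(strsplit(unclass(big)[[1]], "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 5e5), 3 * sqrt(1e6 * 0.25))
})

test_that("evolution with zero rates is the identity", {
  g <- random_genome(5000, seed = 8)
  ev <- evolve(g, evolution_params(0, 0, 0, seed = 1))
  expect_identical(unclass(ev$target), unclass(g))
  expect_equal(nrow(ev$truth), 0)
  expect_equal(ev$divergence, 0)
})

test_that("realized SNP counts follow the binomial expectation", {
  g <- random_genome(1e5, seed = 9)
  ev <- evolve(g, evolution_params(0.01, 0, 0, seed = 2))
  n_snp <- sum(ev$truth$type == "SNP")
  expect_lt(abs(n_snp - 1000), 4 * sqrt(1e5 * 0.01 * 0.99))
  # every SNP changes its base
  expect_true(all(ev$truth$ref != ev$truth$alt))
})

test_that("the truth log reconstructs the target exactly", {
  g <- random_genome(c(3000, 2000), seed = 10)
  ev <- evolve(g, evolution_params(0.02, 2e-3, 2e-3, 3, seed = 3))
  expect_gt(nrow(ev$truth), 0)
  for (chrom in names(g)) {
    rebuilt <- apply_truth(unclass(g)[[chrom]],
                           ev$truth[ev$truth$chrom == chrom, , drop = FALSE])
    expect_identical(rebuilt, unclass(ev$target)[[chrom]])
  }
})

test_that("alignment-based divergence recovers the evolution rate", {
  g <- random_genome(1e5, seed = 11)
  ev <- evolve(g, evolution_params(0.01, 0, 0, seed = 4))
  err <- idy_and_error(g, ev$target)$error
  expect_lt(abs(err - 1.0), 0.3)
})

test_that("error-free simulated mates are exact windows of the target", {
  target <- random_genome(20000, seed = 12)
  reads <- simulate_reads(target, read_sim_params(50, seed = 13))
  s <- unclass(target)[[1]]
  start0 <- as.integer(vapply(strsplit(reads$id, "|", fixed = TRUE), `[`, "", 3))
  expect_identical(reads$seq1, substring(s, start0 + 1, start0 + 70))
  # mate 2 reads the reverse strand of the fragment end
  expect_true(all(vapply(reads$seq2, function(x) {
    grepl(reverse_complement(x), s, fixed = TRUE)
  }, logical(1))))
})

test_that("simulated read counts tie into the fold-coverage formula", {
  target <- random_genome(1e5, seed = 14)
  reads <- simulate_reads(target, read_sim_params(1000, read_length = 70, seed = 15))
  expect_equal(nrow(reads), 1000)
  expect_equal(coverage(70, 2 * nrow(reads), genome_length(target)), 1.4)
})

test_that("injected sequencing errors match the requested rate", {
  target <- random_genome(50000, seed = 16)
  prm <- read_sim_params(2000, read_length = 70, base_error_rate = 0.01, seed = 17)
  reads <- simulate_reads(target, prm)
  s <- unclass(target)[[1]]
  start0 <- as.integer(vapply(strsplit(reads$id, "|", fixed = TRUE), `[`, "", 3))
  truth <- substring(s, start0 + 1, start0 + 70)
  mism <- sum(vapply(seq_len(nrow(reads)), function(i) {
    sum(strsplit(reads$seq1[i], "")[[1]] != strsplit(truth[i], "")[[1]])
  }, numeric(1)))
  n_bases <- 70 * nrow(reads)
  expect_lt(abs(mism - n_bases * 0.01), 4 * sqrt(n_bases * 0.01 * 0.99))
})

test_that("read simulation is deterministic per seed and warns on short chromosomes", {
  target <- random_genome(c(5000, 200), seed = 18)
  expect_warning(r1 <- simulate_reads(target, read_sim_params(100, seed = 19)),
                 "skipping")
  suppressWarnings(r2 <- simulate_reads(target, read_sim_params(100, seed = 19)))
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})

test_that("zero-error reads assemble back into most of a repeat-free target", {
  target <- random_genome(1e5, seed = 20)
  reads <- simulate_reads(target, read_sim_params(15000, seed = 21))  # ~21x
  ctg <- assemble(reads, assembler_config())
  m <- map_contigs(ctg, target)
  expect_gte(covered_target_bases(m), 0.95 * genome_length(target))
})

test_that("parameter invariants of the generators are enforced", {
  expect_error(evolution_params(snp_rate = 1.2), "rates")
  expect_error(read_sim_params(0), "positive")
  expect_error(read_sim_params(10, read_length = 600, fragment_mean = 500),
               "read_length")
})
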