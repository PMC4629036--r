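test_that("select_best_mappings keeps the highest-Q_map mapping per contig", {
  m <- mapping_records(
    rep("chr1", 3), c(1000L, 3000L, 5000L), c(1500L, 3400L, 5200L),
    c("a", "a", "b"), c(0L, 0L, 0L), c(500L, 400L, 200L),
    rep("+", 3), c(98.0, 99.5, 95))
  best <- select_best_mappings(m)
  expect_equal(nrow(best), 2)
  a <- best[best$contig_id == "a", ]
  expect_equal(a$ref_start, 1000L)  # 500 x 98.0 = 49000 > 400 x 99.5 = 39800
  expect_equal(best[best$contig_id == "b", ]$ref_start, 5000L)  # single kept
})

test_that("equal Q_map ties break to the smaller (chrom, ref_start)", {
  m <- mapping_records(
    c("chr2", "chr1", "chr1"), c(100L, 900L, 200L), c(200L, 1000L, 300L),
    rep("a", 3), rep(0L, 3), rep(100L, 3), rep("+", 3), rep(97, 3))
  best <- select_best_mappings(m)
  expect_equal(nrow(best), 1)
  expect_identical(best$ref_chrom, "chr1")
  expect_equal(best$ref_start, 200L)
})

test_that("overlaps resolve by preferring the later contig's beginning", {
  sel <- mapping_records(c("c", "c"), c(0L, 5L), c(10L, 15L), c("A", "B"),
                         c(0L, 0L), c(10L, 10L), c("+", "+"), c(99, 99))
  pl <- resolve_overlaps(sel)
  expect_equal(nrow(pl), 2)
  a <- pl[pl$contig_id == "A", ]
  b <- pl[pl$contig_id == "B", ]
  expect_equal(c(a$ref_start, a$ref_end), c(0L, 5L))   # A's tail trimmed
  expect_equal(c(b$ref_start, b$ref_end), c(5L, 15L))  # B's beginning survives
  expect_equal(a$cut_right, 5L)
  expect_equal(b$cut_left, 0L)
})

test_that("a nested placement splits its host into two flanks", {
  sel <- mapping_records(c("c", "c"), c(0L, 5L), c(20L, 10L), c("A", "B"),
                         c(0L, 0L), c(20L, 5L), c("+", "+"), c(99, 99))
  pl <- resolve_overlaps(sel)
  pl <- pl[order(pl$ref_start), ]
  expect_equal(pl$contig_id, c("A", "B", "A"))
  expect_equal(pl$ref_start, c(0L, 5L, 10L))
  expect_equal(pl$ref_end, c(5L, 10L, 20L))
  # all effective intervals pairwise disjoint
  expect_true(all(pl$ref_start[-1] >= pl$ref_end[-nrow(pl)]))
})

test_that("disjoint placements pass through overlap resolution unchanged", {
  sel <- mapping_records(c("c", "c"), c(0L, 50L), c(10L, 70L), c("A", "B"),
                         c(0L, 0L), c(10L, 20L), c("+", "+"), c(99, 98))
  pl <- resolve_overlaps(sel)
  expect_equal(nrow(pl), 2)
  expect_equal(pl$ref_start, c(0L, 50L))
  expect_equal(pl$ref_end, c(10L, 70L))
  expect_true(all(pl$cut_left == 0L & pl$cut_right == 0L))
})

test_that("splicing replaces reference segments with contig segments", {
  ref <- genome(c(chr1 = "AAAAATTTTT"))

  cs <- contig_set("CCCC", ids = "c1")
  pl <- resolve_overlaps(mapping_records("chr1", 2L, 6L, "c1", 0L, 4L, "+", 99))
  sp <- splice_reference(ref, pl, cs)
  expect_identical(unclass(sp$edited)[["chr1"]], "AACCCCTTTT")
  expect_equal(sp$report$replaced_length, 4L)
  expect_equal(sp$report$n_contigs_used, 1L)

  # a 5-base contig in a 4-base hole changes the chromosome length (indel)
  cs5 <- contig_set("CCCCC", ids = "c1")
  pl5 <- resolve_overlaps(mapping_records("chr1", 2L, 6L, "c1", 0L, 5L, "+", 99))
  sp5 <- splice_reference(ref, pl5, cs5)
  expect_equal(sp5$report$edited_length, 11L)
  expect_identical(unclass(sp5$edited)[["chr1"]], "AACCCCCTTTT")

  # minus-strand contigs are reverse-complemented into reference orientation
  csm <- contig_set("GGGG", ids = "c1")
  plm <- resolve_overlaps(mapping_records("chr1", 2L, 6L, "c1", 0L, 4L, "-", 99))
  spm <- splice_reference(ref, plm, csm)
  expect_identical(unclass(spm$edited)[["chr1"]], "AACCCCTTTT")
})

test_that("zero placements make splicing the identity", {
  ref <- random_genome(c(500, 300), seed = 9)
  sp <- splice_reference(ref, resolve_overlaps(mapping_records()), contig_set())
  expect_identical(unclass(sp$edited), unclass(ref))
  expect_equal(sp$report$replaced_length, 0L)
  expect_equal(sp$report$pct_ref, 0)
  expect_equal(sp$report$pct_asm, 0)
  expect_equal(sp$report$n_contigs_used, 0L)
})

test_that("splice conserves length: edited = ref - replaced + used", {
  ref <- random_genome(5000, seed = 41)
  s <- unclass(ref)[[1]]
  # overlapping contigs cut from the reference, with one length-changing edit
  cs <- contig_set(c(substr(s, 501, 1500), substr(s, 1301, 2200),
                     paste0(substr(s, 3001, 3500), "ACGT")),
                   ids = c("a", "b", "c"))
  m <- map_contigs(cs, ref)
  pl <- resolve_overlaps(select_best_mappings(m))
  sp <- splice_reference(ref, pl, cs)
  expect_equal(sp$report$edited_length,
               sp$report$reference_length - sp$report$replaced_length +
                 sp$report$contig_bases_used)
  expect_error(splice_reference(ref, mapping_records("chr1", c(0L, 5L), c(10L, 15L),
                                                     c("a", "b"), c(0L, 0L),
                                                     c(10L, 10L), c("+", "+"),
                                                     c(99, 99)), cs),
               "overlapping placements")
})

test_that("best-mapping selection reduces multiply covered positions", {
  fix <- repeat_reference()
  s <- unclass(fix$genome)[[1]]
  b0 <- fix$block_starts[1]
  # overlapping contigs from the duplicated block plus a unique-region contig
  cs <- contig_set(c(substr(s, b0 + 1, b0 + 700),
                     substr(s, b0 + 351, b0 + 1000),
                     substr(s, 1001, 1900)),
                   ids = c("blk1", "blk2", "uniq"))
  raw <- map_contigs(cs, fix$genome)
  expect_gt(ambiguous_fraction(raw), 0)
  best <- select_best_mappings(raw)
  expect_lt(multiply_covered_bases(best), multiply_covered_bases(raw))
})

test_that("splicing target-derived contigs moves the reference toward the target", {
  ref <- random_genome(30000, seed = 61)
  ev <- evolve(ref, evolution_params(0.01, 3e-4, 3e-4, 3, seed = 62))
  t <- unclass(ev$target)[[1]]
  starts <- seq(1L, nchar(t) - 4000L, by = 3500L)  # overlapping target windows
  cs <- contig_set(substring(t, starts, starts + 3999L))
  m <- map_contigs(cs, ref)
  sp <- splice_reference(ref, resolve_overlaps(select_best_mappings(m)), cs)
  before <- idy_and_error(ref, ev$target, chunk_size = 5000L)$idy
  after <- idy_and_error(sp$edited, ev$target, chunk_size = 5000L)$idy
  expect_gt(after, before)
})
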