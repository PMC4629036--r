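test_that("qmap is L x idy and ranks longer-but-less-identical mappings higher", {
  m <- mapping_records(rep("chr1", 3), c(0L, 0L, 0L), c(500L, 400L, 100L),
                       c("a", "b", "c"), c(0L, 0L, 0L), c(500L, 400L, 100L),
                       rep("+", 3), c(98.0, 99.5, 0))
  expect_equal(qmap(m), c(49000, 39800, 0))
  expect_gt(qmap(m)[1], qmap(m)[2])  # L = 500/98.0 outranks L = 400/99.5
})

test_that("qmap is monotone in L at fixed idy and in idy at fixed L", {
  refasm:::with_seed(5, {
    for (i in 1:10) {
      L <- sample(100:5000, 2)
      idy <- sort(runif(2, 50, 100))
      m <- mapping_records(rep("c", 2), c(0L, 0L), sort(L), c("x", "y"),
                           c(0L, 0L), sort(L), c("+", "+"), rep(idy[2], 2))
      expect_lte(qmap(m)[1], qmap(m)[2])
      m2 <- mapping_records(rep("c", 2), c(0L, 0L), rep(L[1], 2), c("x", "y"),
                            c(0L, 0L), rep(L[1], 2), c("+", "+"), idy)
      expect_lte(qmap(m2)[1], qmap(m2)[2])
    }
  })
})

test_that("map_contigs recovers exact substrings on either strand", {
  ref <- random_genome(10000, seed = 7)
  s <- unclass(ref)[[1]]
  cs <- contig_set(c(substr(s, 101, 600),                      # ref [100, 600)
                     reverse_complement(substr(s, 1, 300))),   # ref [0, 300), minus
                   ids = c("fwd", "rev"))
  m <- map_contigs(cs, ref)
  expect_equal(nrow(m), 2)
  fwd <- m[m$contig_id == "fwd", ]
  expect_equal(c(fwd$ref_start, fwd$ref_end), c(100L, 600L))
  expect_identical(fwd$strand, "+")
  expect_equal(fwd$idy, 100)
  expect_equal(fwd$L, 500L)
  rev <- m[m$contig_id == "rev", ]
  expect_equal(c(rev$ref_start, rev$ref_end), c(0L, 300L))
  expect_identical(rev$strand, "-")

  # an unrelated random contig finds no home
  none <- map_contigs(contig_set(random_seq(200, 12345), ids = "stray"), ref)
  expect_equal(nrow(none), 0)
})

test_that("contigs cut from the reference map end to end at idy 100", {
  ref <- random_genome(20000, seed = 31)
  s <- unclass(ref)[[1]]
  starts <- c(1L, 4001L, 9001L, 15001L)
  cs <- contig_set(substring(s, starts, starts + 2999L))
  m <- map_contigs(cs, ref)
  expect_equal(nrow(m), length(starts))
  expect_true(all(m$idy == 100))
  expect_true(all(m$contig_start == 0L & m$contig_end == 3000L))
  expect_equal(sort(m$ref_start), starts - 1L)
})

test_that("reported idy agrees with an independent pairwise alignment", {
  ref <- random_genome(8000, seed = 101)
  s <- unclass(ref)[[1]]
  contig <- substr(s, 2001, 3500)
  refasm:::with_seed(55, {
    # plant a handful of substitutions and a short deletion
    v <- strsplit(contig, "", fixed = TRUE)[[1]]
    pos <- sample(seq_along(v), 12)
    v[pos] <- vapply(v[pos], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    v[700:702] <- ""
    contig <- paste(v, collapse = "")
  })
  m <- map_contigs(contig_set(contig, ids = "mut"), ref)
  expect_equal(nrow(m), 1)
  refseg <- substr(s, m$ref_start + 1, m$ref_end)
  aln <- Biostrings::pairwiseAlignment(contig, refseg, type = "global")
  oracle <- 100 * Biostrings::nmatch(aln) / Biostrings::nchar(aln)
  expect_lt(abs(m$idy - oracle), 0.5)
  expect_gte(m$idy, 90)
})

test_that("ambiguous_fraction counts multiply-mapped contigs", {
  one_each <- mapping_records(rep("c", 3), c(0L, 100L, 200L), c(50L, 150L, 250L),
                              c("a", "b", "c"), rep(0L, 3), rep(50L, 3),
                              rep("+", 3), rep(99, 3))
  expect_equal(ambiguous_fraction(one_each), 0)

  dup <- mapping_records(rep("c", 4), c(0L, 100L, 200L, 300L),
                         c(50L, 150L, 250L, 350L),
                         c("a", "a", "b", "c"), rep(0L, 4), rep(50L, 4),
                         rep("+", 4), rep(99, 4))
  expect_equal(ambiguous_fraction(dup), 1 / 3)

  expect_equal(ambiguous_fraction(mapping_records()), 0)
})

test_that("a duplicated reference block makes its contigs ambiguous", {
  fix <- repeat_reference()
  chunk <- substr(fix$block, 101, 800)
  cs <- contig_set(c(chunk, random_seq(700, 77)), ids = c("from_block", "unique"))
  # "unique" is unrelated; "from_block" should map to both copies
  m <- map_contigs(cs, fix$genome)
  expect_gte(sum(m$contig_id == "from_block"), 2)
  expect_gt(ambiguous_fraction(m), 0)
})
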