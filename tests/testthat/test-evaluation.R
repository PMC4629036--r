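test_that("total_length sums contig lengths", {
  expect_equal(total_length(contig_set(strrep("A", c(5, 4, 3, 2, 1)))), 15)
  expect_equal(total_length(contig_set()), 0L)
  expect_equal(total_length(contig_set("ACGTACG")), 7)
})

test_that("n50 is the shortest contig of the minimal half-covering prefix", {
  expect_equal(n50(c(5, 4, 3, 2, 1)), 4)  # 5 + 4 = 9 >= 7.5
  expect_equal(n50(7), 7)
  expect_equal(n50(c(2, 2, 2, 2)), 2)
  expect_error(n50(numeric(0)), "empty")
})

test_that("n50 agrees with exhaustive enumeration on small sets", {
  brute_n50 <- function(lens) {
    n <- length(lens)
    half <- sum(lens) / 2
    best_size <- Inf
    best_min <- -Inf
    for (mask in 1:(2^n - 1)) {
      sel <- lens[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
      if (sum(sel) >= half) {
        if (length(sel) < best_size ||
            (length(sel) == best_size && min(sel) > best_min)) {
          best_size <- length(sel)
          best_min <- min(sel)
        }
      }
    }
    best_min
  }
  refasm:::with_seed(23, {
    for (i in 1:20) {
      lens <- sample(1:500, sample(1:8, 1), replace = TRUE)
      expect_equal(n50(lens), brute_n50(lens))
    }
  })
})

test_that("identity is the length-weighted mean of mapped-segment identities", {
  m <- mapping_records(c("t", "t"), c(0L, 200L), c(100L, 300L), c("a", "b"),
                       c(0L, 0L), c(100L, 100L), c("+", "+"), c(100, 98))
  expect_equal(weighted_idy(m), 99)

  g <- random_genome(15000, seed = 3)
  ie <- idy_and_error(g, g, chunk_size = 5000L)
  expect_equal(ie$idy, 100)
  expect_equal(ie$error, 0)

  expect_error(idy_and_error(contig_set(random_seq(300, 9), ids = "x"), g),
               "no alignments")
})

test_that("identical bases reproduce the printed TL/Error combinations", {
  # printed as (TL Mb, Error %) -> identical bases Mb at two decimals
  expect_equal(round_half_up(identical_bases(18.20, 100 - 0.85), 2), 18.05)
  expect_equal(round_half_up(identical_bases(28.82, 100 - 2.09), 2), 28.22)
  expect_equal(round_half_up(identical_bases(25.81, 100 - 0.41), 2), 25.70)
  expect_equal(round_half_up(identical_bases(30.00, 100 - 0.59), 2), 29.82)
  expect_equal(identical_bases(12.34, 100), 12.34)
  expect_error(identical_bases(10, 101), "\\[0, 100\\]")
})

test_that("fold coverage follows read_length x n_reads / genome_size", {
  expect_equal(coverage(100, 1000, 10000), 10)
  # one million pairs of 70-base reads over 30 Mb
  expect_equal(round(coverage(70, 2e6, 3e7), 2), 4.67)
  expect_equal(coverage(100, 0, 10000), 0)
  expect_error(coverage(100, 10, 0), "positive")
})

test_that("covered target bases is an interval union, not a sum", {
  m1 <- mapping_records("t", 0L, 100L, "a", 0L, 100L, "+", 99)
  expect_equal(covered_target_bases(m1), 100)

  m2 <- mapping_records(c("t", "t"), c(0L, 25L), c(50L, 75L), c("a", "b"),
                        c(0L, 0L), c(50L, 50L), c("+", "+"), c(99, 99))
  expect_equal(covered_target_bases(m2), 75)
  expect_equal(covered_target_bases(mapping_records()), 0L)

  # monotone non-decreasing in the mapping set
  expect_gte(covered_target_bases(rbind(m2, m1)), covered_target_bases(m2))
})

test_that("contigs-to-half-target counts largest contigs by covered union", {
  target <- genome(c(t = random_seq(200, 77)))
  cs <- contig_set(c(strrep("A", 100), strrep("C", 60)), ids = c("big", "small"))
  m <- mapping_records("t", 0L, 100L, "big", 0L, 100L, "+", 99)
  expect_equal(n_contigs_to_half_target(cs, m, target), 1L)
  expect_true(is.na(n_contigs_to_half_target(cs, mapping_records(), target)))
})

test_that("evaluate_assembly assembles the full metric suite coherently", {
  target <- random_genome(20000, seed = 15)
  s <- unclass(target)[[1]]
  cs <- contig_set(c(substr(s, 1, 8000), substr(s, 9001, 14000)))
  rep <- evaluate_assembly(cs, target, read_length = 70, n_reads = 2000)
  expect_equal(rep$tl_bases, 13000)
  expect_equal(rep$n50, 8000)
  expect_equal(rep$idy, 100)
  expect_equal(rep$error, 0)
  expect_equal(rep$identical_bases, 13000)
  expect_equal(rep$covered_target_bases, 13000)
  expect_equal(rep$n_contigs_to_half_target, 2L)
  expect_equal(rep$cov, 70 * 2000 / 20000)
})
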