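test_that("merge coalesces overlapping and book-ended intervals", {
  expect_length(merge_intervals(GenomicRanges::GRanges()), 0L)

  gr <- intervals(rep("chr1", 3), c(100, 200, 500), c(300, 400, 600))
  m <- merge_intervals(gr)
  expect_equal(GenomicRanges::start(m) - 1L, c(100L, 500L))
  expect_equal(GenomicRanges::end(m), c(400L, 600L))

  # book-ended intervals are coalesced
  be <- intervals(c("chr1", "chr1"), c(100, 200), c(200, 300))
  expect_length(merge_intervals(be), 1L)
  expect_equal(total_length(merge_intervals(be)), 200)
})

test_that("malformed intervals are rejected with position context", {
  expect_error(intervals("chr1", 200, 200), "malformed interval")
  expect_error(intervals("chr1", -1, 100), "malformed interval")
  expect_error(intervals("chr1", 300, 100), "chr1")
})

test_that("merge matches a brute-force per-base mask on random instances", {
  genome <- c(c1 = 40000L, c2 = 60000L)
  set.seed(42)
  for (rep in 1:30) {
    gr <- random_intervals(sample(1:500, 1), genome)
    m <- merge_intervals(gr)
    oracle <- mask_from_gr(gr, genome)
    got <- mask_from_gr(m, genome)
    expect_identical(got, oracle)
    # merged output is sorted and disjoint with gaps >= 1
    expect_true(all(GenomicRanges::width(GenomicRanges::gaps(m)) >= 1))
    expect_equal(total_length(m), sum(vapply(oracle, sum, numeric(1))))
  }
})

test_that("merge is idempotent and never increases total length", {
  genome <- c(c1 = 50000L)
  set.seed(7)
  gr <- random_intervals(200, genome)
  m <- merge_intervals(gr)
  expect_identical(merge_intervals(m), m)
  expect_lte(total_length(m), total_length(gr))
  # equality iff already disjoint
  disj <- intervals(c("c1", "c1"), c(0, 500), c(100, 700))
  expect_equal(total_length(merge_intervals(disj)), total_length(disj))
})

test_that("overlap_count respects half-open boundaries", {
  feat <- intervals("chr1", 100, 200)
  expect_equal(overlap_count(data.frame(chrom = "chr1", pos = 150), feat)$count, 1L)
  expect_equal(overlap_count(data.frame(chrom = "chr1", pos = 100), feat)$count, 1L)
  expect_equal(overlap_count(data.frame(chrom = "chr1", pos = 200), feat)$count, 0L)
  expect_equal(overlap_count(data.frame(chrom = "chr1", pos = 99), feat)$count, 0L)
  # unknown chromosome counts as non-overlapping
  res <- overlap_count(data.frame(chrom = c("chrZ", "chr1"), pos = c(150, 150)), feat)
  expect_equal(res$flags, c(FALSE, TRUE))
})

test_that("overlap_count agrees with per-base mask lookups", {
  genome <- c(c1 = 50000L, c2 = 50000L)
  set.seed(11)
  feats <- merge_intervals(random_intervals(50, genome))
  mask <- mask_from_gr(feats, genome)
  pos <- data.frame(chrom = sample(names(genome), 1000, replace = TRUE),
                    pos = sample.int(50000L, 1000, replace = TRUE) - 1L)
  res <- overlap_count(pos, feats)
  oracle <- vapply(seq_len(nrow(pos)), function(i)
    mask[[pos$chrom[i]]][pos$pos[i] + 1L], logical(1))
  expect_identical(res$flags, oracle)
  expect_equal(res$count, sum(oracle))
})

test_that("shuffle preserves the interval-length multiset and is seedable", {
  genome <- c(c1 = 100000L, c2 = 50000L)
  set.seed(3)
  gr <- random_intervals(80, genome)
  s1 <- shuffle_intervals(gr, genome, seed = 5)
  s2 <- shuffle_intervals(gr, genome, seed = 5)
  s3 <- shuffle_intervals(gr, genome, seed = 6)
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
  expect_equal(sort(GenomicRanges::width(s1)), sort(GenomicRanges::width(gr)))
  expect_equal(total_length(s1), total_length(gr))
  # same-chromosome placement by default
  expect_equal(as.character(GenomicRanges::seqnames(s1)),
               as.character(GenomicRanges::seqnames(gr)))
})

test_that("shuffle honors exclusions and forced placements", {
  # genome of exactly the interval length: only one placement possible
  one <- shuffle_intervals(intervals("c1", 0, 100), c(c1 = 100L), seed = 1)
  expect_equal(GenomicRanges::start(one), 1L)
  expect_equal(GenomicRanges::width(one), 100L)
  # exclusion respected
  excl <- intervals("c1", 0, 9000)
  s <- shuffle_intervals(intervals("c1", 0, 500), c(c1 = 10000L), excluded = excl,
                         seed = 2)
  expect_gte(GenomicRanges::start(s), 9001L)
  # impossible placement errors after bounded retries
  expect_error(shuffle_intervals(intervals("c1", 0, 500), c(c1 = 10000L),
                                 excluded = intervals("c1", 0, 9900),
                                 seed = 3, max_tries = 50),
               "could not place")
})

test_that("shuffled start positions are uniform over the allowed space", {
  genome <- c(c1 = 10000L)
  gr <- intervals("c1", 0, 100)
  set.seed(9)
  starts <- vapply(1:10000, function(i)
    GenomicRanges::start(shuffle_intervals(gr, genome)), integer(1))
  # allowed starts 1..9901; chi-squared goodness of fit over 10 bins
  bins <- cut(starts, breaks = seq(0.5, 9901.5, length.out = 11))
  p <- chisq.test(table(bins))$p.value
  expect_gt(p, 0.01)
})

test_that("BED and genome files round-trip", {
  tmp <- withr::local_tempfile(fileext = ".bed")
  genome <- c(chr1 = 100000L, chr2 = 100000L)
  set.seed(21)
  gr <- random_intervals(100, genome)
  S4Vectors::mcols(gr)$name <- sprintf("iv%03d", seq_along(gr))
  write_bed(gr, tmp)
  back <- read_bed(tmp)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(gr))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(gr))
  expect_equal(S4Vectors::mcols(back)$name, S4Vectors::mcols(gr)$name)

  # track header lines are skipped
  tmp2 <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("track name=demo", "chr1\t100\t200", "chr1\t300\t400",
               "chr2\t0\t50"), tmp2)
  gr2 <- read_bed(tmp2)
  expect_length(gr2, 3L)
  expect_equal(GenomicRanges::start(gr2)[1] - 1L, 100L)

  expect_error(suppressWarnings(read_bed(withr::local_tempfile(fileext = ".bed"))),
               "failed to parse|cannot open")

  gtmp <- withr::local_tempfile(fileext = ".txt")
  write_genome(genome, gtmp)
  expect_identical(read_genome(gtmp), genome)
})
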