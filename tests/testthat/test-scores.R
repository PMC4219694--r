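test_that("score lookup is an order-preserving array index", {
  set.seed(5)
  pos <- sample.int(10000L, 500) - 1L
  val <- rnorm(500)
  tr <- score_track(rep("c1", 500), pos, val)
  # 100 random queries equal direct indexing
  q <- sample(500, 100)
  res <- extract_scores(data.frame(chrom = "c1", pos = pos[q]), tr)
  expect_equal(res$scores, val[q])
  expect_equal(res$n_missing, 0L)
  # single value
  expect_equal(extract_scores(data.frame(chrom = "c1", pos = pos[1]), tr)$scores,
               val[1])
  # empty query
  empty <- extract_scores(data.frame(chrom = character(0), pos = integer(0)), tr)
  expect_length(empty$scores, 0L)
  # missing positions are explicit
  expect_warning(miss <- extract_scores(
    data.frame(chrom = "c1", pos = c(pos[1], 99999L)), tr), "missing")
  expect_true(miss$missing[2])
  expect_error(extract_scores(data.frame(chrom = "cX", pos = 1L), tr),
               "no queried position")
  expect_error(score_track(c("c1", "c1"), c(1, 1), c(0, 1)), "duplicate")
})

test_that("score tracks round-trip through bedGraph and read fixedStep wiggle", {
  set.seed(6)
  tr <- score_track(rep(c("c1", "c2"), each = 200),
                    rep(c(1000:1199), 2), round(rnorm(400), 3))
  tmp <- withr::local_tempfile(fileext = ".bedGraph")
  write_score_track(tr, tmp)
  back <- read_score_track(tmp)
  expect_equal(back$c1$pos, tr$c1$pos)
  expect_equal(back$c1$score, tr$c1$score, tolerance = 1e-6)
  expect_equal(back$c2$score, tr$c2$score, tolerance = 1e-6)

  wig <- withr::local_tempfile(fileext = ".wig")
  writeLines(c("fixedStep chrom=c1 start=101 step=1",
               "1.5", "2.5", "-0.25"), wig)
  wt <- read_score_track(wig)
  expect_equal(wt$c1$pos, 100:102)        # 1-based wiggle -> 0-based positions
  expect_equal(wt$c1$score, c(1.5, 2.5, -0.25))
})

test_that("G/C-matched sampling is exactly stratified and collision-free", {
  set.seed(8)
  uni <- data.frame(chrom = "c1", pos = 0:1999,
                    base = sample(c("A", "C", "G", "T"), 2000, replace = TRUE))
  # pure-G/C target
  s <- gc_matched_sample(uni, 1.0, 10, seed = 1)
  expect_true(all(s$base %in% c("G", "C")))
  # empty draw
  expect_equal(nrow(gc_matched_sample(uni, 0.5, 0)), 0L)
  # exact class counts on every draw (largest-remainder apportionment)
  for (i in 1:25) {
    d <- gc_matched_sample(uni, 0.6, 1000, seed = i)
    expect_equal(sum(d$base %in% c("G", "C")), 600L)
    expect_equal(anyDuplicated(d$pos), 0L)
  }
  # deterministic under seed
  expect_identical(gc_matched_sample(uni, 0.6, 50, seed = 4),
                   gc_matched_sample(uni, 0.6, 50, seed = 4))
  # insufficient stratum named in the error
  tiny <- data.frame(chrom = "c1", pos = 0:9, base = rep("A", 10))
  expect_error(gc_matched_sample(tiny, 0.5, 10), "stratum: gc")
})

test_that("ECDF bands are valid distribution envelopes", {
  set.seed(12)
  x <- rnorm(300)
  b <- ecdf_band(x, B = 200, seed = 1)
  expect_true(all(diff(b$point) >= 0))
  expect_true(all(b$point >= 0 & b$point <= 1))
  expect_true(all(b$lower <= b$point & b$point <= b$upper))
  expect_equal(b$point[length(b$grid)], 1.0)   # ECDF at the sample maximum
  # degenerate single-valued sample collapses to a step function
  d <- ecdf_band(rep(2.5, 50), B = 100, grid = c(2, 2.5, 3), seed = 1)
  expect_equal(d$point, c(0, 1, 1))
  expect_equal(d$lower, d$upper)
  # reproducible
  expect_identical(ecdf_band(x, B = 150, seed = 9), ecdf_band(x, B = 150, seed = 9))
})

test_that("bootstrap band attains near-nominal pointwise coverage", {
  # scaled-down check of the n=500 simulation (full version in acceptance)
  set.seed(77)
  cover <- vapply(1:40, function(i) {
    x <- rnorm(200)
    b <- ecdf_band(x, B = 300)
    truth <- pnorm(b$grid)
    mean(truth >= b$lower - 1e-12 & truth <= b$upper + 1e-12)
  }, numeric(1))
  expect_gte(mean(cover), 0.9)
})

test_that("KS comparison equals the brute-force supremum and is symmetric", {
  expect_equal(suppressWarnings(ks_compare(c(1, 2, 3), c(1, 2, 3)))$D, 0)
  expect_equal(ks_compare(c(0, 0, 0), c(1, 1, 1))$D, 1)
  set.seed(14)
  a <- rnorm(200); b <- rnorm(200, 0.3)
  ka <- ks_compare(a, b)
  expect_equal(ka$D, brute_ks_d(a, b), tolerance = 1e-12)
  kb <- ks_compare(b, a)
  expect_equal(ka$D, kb$D)
  expect_equal(ka$p, kb$p)
})

test_that("relative positions map element and flank coordinates to percent", {
  el <- intervals("c1", 1000, 1200)
  rp <- function(p) relative_positions(data.frame(chrom = "c1", pos = p), el)
  expect_equal(rp(1100), 50.0)
  expect_equal(rp(1000), 0.0)
  expect_equal(rp(950), -25.0)
  expect_equal(rp(1250), 125.0)
  expect_equal(rp(1199), 99.5)
  expect_true(is.na(rp(5000)))   # out of reach of any flank
  # ambiguity between two elements' flanks goes to the nearer element
  two <- intervals(c("c1", "c1"), c(1000, 1500), c(1200, 1700))
  near2 <- relative_positions(data.frame(chrom = "c1", pos = 1450), two)
  expect_equal(near2, (1450 - 1500) / 200 * 100)  # closer to the second element
  # equidistant tie goes to the upstream element
  tie <- intervals(c("c1", "c1"), c(1000, 1501), c(1200, 1701))
  mid <- relative_positions(data.frame(chrom = "c1", pos = 1350), tie)
  expect_equal(mid, (1350 - 1000) / 200 * 100)  # claimed by the upstream element
})

test_that("flank windows take the bases adjacent to each variant", {
  # distinct score per position makes window membership observable
  tr <- score_track(rep("c1", 200), 0:199, as.numeric(0:199))
  fl <- flank_scores(data.frame(chrom = "c1", pos = 100), tr, window = 3)
  expect_setequal(fl$upstream, c(97, 98, 99))
  expect_setequal(fl$downstream, c(101, 102, 103))
  expect_error(flank_scores(data.frame(chrom = "c1", pos = 100), tr, window = 0),
               "window")
  # pooled sample sizes are window * n_variants absent truncation
  vs <- data.frame(chrom = "c1", pos = c(50, 100, 150))
  fl3 <- flank_scores(vs, tr, window = 3)
  expect_length(fl3$upstream, 9L)
  expect_length(fl3$downstream, 9L)
  expect_equal(fl3$n_dropped, 0L)
  # truncation at the track edge is dropped and counted
  fe <- flank_scores(data.frame(chrom = "c1", pos = 1), tr, window = 3)
  expect_length(fe$upstream, 1L)
  expect_equal(fe$n_dropped, 2L)
})
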