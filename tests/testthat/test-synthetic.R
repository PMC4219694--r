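test_that("generators are fully deterministic under the configured seed", {
  cfg <- small_config()
  a <- simulate_genome(cfg)
  b <- simulate_genome(cfg)
  expect_identical(as.character(a$reference), as.character(b$reference))
  expect_identical(a$elements, b$elements)
  sa <- simulate_scores(cfg, a$elements)
  sb <- simulate_scores(cfg, a$elements)
  expect_identical(sa$track, sb$track)
  va <- simulate_variants(cfg, a$elements, sa$track, a$reference)
  vb <- simulate_variants(cfg, a$elements, sa$track, a$reference)
  expect_identical(va, vb)
  # a different seed changes the realization
  expect_false(identical(
    as.character(simulate_genome(small_config(seed = 999))$reference[[1]]),
    as.character(a$reference[[1]])))
})

test_that("genome composition follows the configured G/C fractions", {
  # all-A/T genome at G/C fraction 0
  cfg0 <- small_config(background_gc = 0, element_at = 1)
  g0 <- simulate_genome(cfg0)
  freq <- Biostrings::alphabetFrequency(g0$reference[[1]])
  expect_equal(freq[["C"]] + freq[["G"]], 0)

  # element interiors AT-enriched: realized A/T within 3 binomial SE of 0.62
  sim <- small_sim()
  uni <- small_universe()
  at <- mean(uni$base %in% c("A", "T"))
  se <- sqrt(0.62 * 0.38 / nrow(uni))
  expect_lt(abs(at - 0.62), 3 * se)
  # background stays near 0.41 G/C
  bg <- Biostrings::alphabetFrequency(sim$reference[[1]])
  gc_bg <- (bg[["C"]] + bg[["G"]]) / sum(bg[c("A", "C", "G", "T")])
  expect_equal(gc_bg, 0.41, tolerance = 0.01)
})

test_that("score track separates elements from background, with relaxed patches inside", {
  sim <- small_sim()
  uni <- small_universe()
  expect_false(anyNA(uni$score))
  # relaxed ground-truth positions all lie inside elements
  rel <- sim$scores$relaxed
  expect_true(all(overlap_count(rel, sim$elements)$flags))
  # element mean above background mean on the realized track
  flank <- GenomicRanges::setdiff(sim$scores$universe, sim$elements)
  bg_scores <- extract_scores(universe_df(flank)[1:5000, ], sim$scores$track)$scores
  expect_gt(mean(uni$score), mean(bg_scores) + 1)
  # zero-variance config gives a two-valued track
  cfg0 <- small_config(score_in = c(mean = 2, sd = 0),
                       score_out = c(mean = 0, sd = 0),
                       score_relaxed = c(mean = 2, sd = 0))
  g0 <- simulate_genome(cfg0)
  s0 <- simulate_scores(cfg0, g0$elements)
  vals <- unique(unlist(lapply(s0$track, `[[`, "score")))
  expect_setequal(vals, c(0, 2))
})

test_that("variant MAFs are class-consistent by construction", {
  sim <- small_sim()
  for (vs in sim$cohorts) {
    gt <- attr(vs, "ground_truth")
    expect_true(all(vs$maf[vs$class == "rare"] < 0.005))
    expect_true(all(vs$maf[vs$class == "prevalent"] > 0.05))
    expect_true(all(vs$maf >= 0.0005 & vs$maf <= 0.5))
    expect_false(anyNA(gt$placement_score))
    # variants lie inside elements
    expect_true(all(overlap_count(vs, sim$elements)$flags))
    # ref matches the reference base; alt differs
    expect_true(all(vs$ref != vs$alt))
  }
})

test_that("conservation-dependent placement depresses prevalent scores", {
  sim <- small_sim()
  uni <- small_universe()
  cfg <- small_config()
  # beta at score-SD-scale >= 2: prevalent mean below rare mean in every run
  for (i in 1:20) {
    v <- simulate_variants(cfg, sim$elements, sim$scores$track, sim$reference,
                           counts = c(rare = 300, prevalent = 300),
                           seed = i, universe = uni)
    gt <- attr(v, "ground_truth")
    expect_lt(mean(gt$placement_score[gt$true_class == "prevalent"]),
              mean(gt$placement_score[gt$true_class == "rare"]))
  }
  # beta = 0 removes the dependence (one-run sanity; calibration in acceptance)
  cfg0 <- small_config(beta = 0)
  v0 <- simulate_variants(cfg0, sim$elements, sim$scores$track, sim$reference,
                          counts = c(rare = 2000, prevalent = 2000),
                          seed = 3, universe = uni)
  gt0 <- attr(v0, "ground_truth")
  d <- abs(mean(gt0$placement_score[gt0$true_class == "prevalent"]) -
             mean(gt0$placement_score[gt0$true_class == "rare"]))
  expect_lt(d, 0.15)
  # requesting more variants than positions errors
  expect_error(simulate_variants(cfg, sim$elements, sim$scores$track,
                                 sim$reference,
                                 counts = c(rare = nrow(uni) + 1),
                                 universe = uni),
               "exceeds available")
})

test_that("feature tracks realize their configured densities", {
  sim <- small_sim()
  uni <- small_universe()
  set.seed(55)
  probe <- uni[sample(nrow(uni), 2000), ]
  cov_sparse <- mean(overlap_count(probe, sim$features$sparse)$flags)
  cov_dense <- mean(overlap_count(probe, sim$features$dense)$flags)
  se <- function(d) sqrt(d * (1 - d) / 2000)
  expect_lt(abs(cov_sparse - 0.25), 3 * se(0.25) + 0.02)  # slot rounding slack
  expect_lt(abs(cov_dense - 0.60), 3 * se(0.60) + 0.02)
  expect_gt(cov_dense, cov_sparse)

  # density 0 -> empty; density 1 -> every usable element base covered
  cfg0 <- small_config(sparse_density_in = 0, sparse_density_bg = 0)
  g0 <- simulate_genome(cfg0)
  s0 <- simulate_scores(cfg0, g0$elements)
  f0 <- simulate_features(cfg0, g0$elements, s0$track)
  expect_length(f0$sparse, 0L)
  cfg1 <- small_config(dense_density = 1)
  f1 <- simulate_features(cfg1, g0$elements, s0$track)
  # full slots cover all but the sub-slot remainder of each element
  expect_gt(f1$dense_coverage_in, 0.9)
})

test_that("cohorts share prevalent but not rare variants", {
  sim <- small_sim()
  tab <- sharing_table(lapply(sim$cohorts, function(v)
    v[v$class == "prevalent", ]))
  all_cell <- tab$count[rowSums(tab[, names(sim$cohorts)]) == 3]
  expect_gt(all_cell / sum(tab$count), 0.3)   # most prevalent variants shared
  tabr <- sharing_table(lapply(sim$cohorts, function(v) v[v$class == "rare", ]))
  allr <- tabr$count[rowSums(tabr[, names(sim$cohorts)]) == 3]
  expect_lt(allr / sum(tabr$count), 0.05)     # rare variants essentially private
})
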