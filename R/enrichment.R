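#' Overlap enrichment and depletion tests against matched nulls
#'
#' Variant positions are tested for overlap with a binary feature
#' annotation (e.g. clustered TFBS) in two ways: a Pearson chi-squared
#' contrast of overlap proportions against an equally sized matched random
#' position set, and repeated fixed-size resampling with Mann-Whitney
#' comparisons of per-set overlap counts.
#'
#' @name overlap-enrichment
NULL

#' Chi-squared overlap contrast between a query and a null position set
#'
#' Builds the 2x2 table (overlap / non-overlap x query / null) and applies
#' Pearson's chi-squared test without continuity correction. The relative
#' overlap (query rate / null rate) is reported alongside; values below 1
#' indicate depletion of the query in the feature set.
#'
#' @param query_positions,null_positions Data frames with `chrom`, `pos`.
#' @param features Merged feature `GRanges`.
#' @return An `overlap_test` list: counts, totals, `statistic`, `p`,
#'   `relative_overlap`, `degenerate`, `low_expected` flags.
#' @export
overlap_chi2 <- function(query_positions, null_positions, features) {
  stopifnot(nrow(query_positions) > 0, nrow(null_positions) > 0)
  qc <- overlap_count(query_positions, features)$count
  nc <- overlap_count(null_positions, features)$count
  qt <- nrow(query_positions); nt <- nrow(null_positions)
  tab <- matrix(c(qc, qt - qc, nc, nt - nc), nrow = 2,
                dimnames = list(c("overlap", "no_overlap"), c("query", "null")))
  degenerate <- any(rowSums(tab) == 0)
  if (degenerate) {
    stat <- NA_real_; p <- NA_real_; low <- TRUE
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    stat <- unname(ct$statistic); p <- ct$p.value
    low <- any(ct$expected < 5)
  }
  structure(list(query_overlap = qc, query_total = qt,
                 null_overlap = nc, null_total = nt,
                 statistic = stat, p = p,
                 relative_overlap = if (nc > 0) (qc / qt) / (nc / nt) else NA_real_,
                 degenerate = degenerate, low_expected = low),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("overlap_test: query %d/%d (%.3f), null %d/%d (%.3f)\n",
              x$query_overlap, x$query_total, x$query_overlap / x$query_total,
              x$null_overlap, x$null_total, x$null_overlap / x$null_total))
  cat(sprintf("  relative overlap %.3f, X-squared = %.3f, p = %.3g%s\n",
              x$relative_overlap, x$statistic, x$p,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Repeated fixed-size resampling of overlap counts
#'
#' Draws `n_sets` sets of `set_size` positions from a pool (without
#' replacement within a set, independently across sets) and counts feature
#' overlaps per set -- the "per 1000 positions" overlap summary. The mean
#' and a percentile 95% CI of the per-set counts are reported.
#'
#' @param pool Data frame of candidate positions (`chrom`, `pos`).
#' @param features Merged feature `GRanges`.
#' @param n_sets Number of resampled sets.
#' @param set_size Positions per set; must not exceed the pool size.
#' @param seed Optional integer seed.
#' @return A `resample_result` list: `counts`, `set_size`, `n_sets`,
#'   `mean`, `ci` (2.5/97.5 percentiles of per-set counts).
#' @export
resample_overlap <- function(pool, features, n_sets = 100L, set_size = 1000L,
                             seed = NULL) {
  if (nrow(pool) < set_size) stop("position pool (", nrow(pool),
                                  ") smaller than set_size (", set_size, ")")
  # one overlap lookup for the whole pool, then index per set
  flags <- overlap_count(pool, features)$flags
  counts <- with_seed(seed, vapply(seq_len(n_sets), function(i)
    sum(flags[sample.int(nrow(pool), set_size)]), numeric(1)))
  structure(list(counts = counts, set_size = set_size, n_sets = n_sets,
                 mean = mean(counts),
                 ci = unname(quantile(counts, c(0.025, 0.975)))),
            class = "resample_result")
}

#' @export
print.resample_result <- function(x, ...) {
  cat(sprintf("resample_result: %d sets of %d; mean overlap %.1f [%.1f, %.1f]\n",
              x$n_sets, x$set_size, x$mean, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Mann-Whitney comparison of two resampled overlap distributions
#'
#' Two-tailed rank-sum test on the per-set overlap counts, via
#' [stats::wilcox.test()] (normal approximation with tie correction at
#' these set counts; exact when both inputs are small and tie-free).
#'
#' @param a,b `resample_result` objects with >= 2 sets each.
#' @return List with `U` (statistic for `a`), `p`, `higher` (which input
#'   has the larger median: `"a"`, `"b"` or `"tie"`).
#' @export
compare_resamples <- function(a, b) {
  stopifnot(inherits(a, "resample_result"), inherits(b, "resample_result"),
            a$n_sets >= 2, b$n_sets >= 2)
  if (all(c(a$counts, b$counts) == a$counts[1])) {
    return(list(U = a$n_sets * b$n_sets / 2, p = 1, higher = "tie"))
  }
  wt <- suppressWarnings(wilcox.test(a$counts, b$counts,
                                     alternative = "two.sided"))
  ma <- stats::median(a$counts); mb <- stats::median(b$counts)
  list(U = unname(wt$statistic), p = wt$p.value,
       higher = if (ma > mb) "a" else if (mb > ma) "b" else "tie")
}

#' Per-frequency-class feature depletion report
#'
#' For each MAF class present in the variant set, draws a G/C-matched
#' random position set of equal size from the element universe and tests
#' the class's feature overlap against it with [overlap_chi2()]. Relative
#' overlap is reported with the matched random set normalised to 1.
#'
#' @param variants Variant set data frame (with `class` column).
#' @param universe Data frame from [universe_positions()].
#' @param features Merged feature `GRanges`.
#' @param classes Which classes to report.
#' @param seed Optional integer seed (one substream per class).
#' @param p_adjust Multiple-testing correction across the reported classes
#'   (any [stats::p.adjust()] method). Default `"none"`, mirroring per-set
#'   testing; set `"bonferroni"` for a family-wise bound.
#' @return Data frame with one row per class: sizes, overlap rates,
#'   `relative_overlap`, `statistic`, `p` (and `p_adj` when adjusted),
#'   `degenerate`.
#' @export
class_depletion_report <- function(variants, universe, features,
                                   classes = c("rare", "prevalent"),
                                   seed = NULL, p_adjust = "none") {
  rows <- lapply(classes, function(cl) {
    vc <- variants[variants$class == cl, , drop = FALSE]
    if (nrow(vc) == 0L) stop("no variants in class ", cl)
    comp <- base_composition(vc$base %||% universe_base_at(universe, vc))
    s <- if (is.null(seed)) NULL else derive_seed(seed, paste0("gcmatch_", cl))
    null <- gc_matched_sample(universe, comp, nrow(vc), seed = s)
    res <- overlap_chi2(vc, null, features)
    data.frame(class = cl, n = nrow(vc),
               query_rate = res$query_overlap / res$query_total,
               null_rate = res$null_overlap / res$null_total,
               relative_overlap = res$relative_overlap,
               statistic = res$statistic, p = res$p,
               degenerate = res$degenerate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!identical(p_adjust, "none")) out$p_adj <- stats::p.adjust(out$p, p_adjust)
  out
}

# reference base of each variant looked up from the universe table
universe_base_at <- function(universe, variants) {
  i <- match(paste(variants$chrom, variants$pos),
             paste(universe$chrom, universe$pos))
  if (anyNA(i)) stop(sum(is.na(i)), " variant position(s) outside the universe")
  universe$base[i]
}
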