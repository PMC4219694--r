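#' Per-base conservation score tracks and distributional comparisons
#'
#' A `score_track` stores one conservation score (phyloP-like: positive =
#' conserved, negative = accelerated) per base over the analysis universe
#' only -- typically the element set plus flanking margins -- so memory is
#' bounded by the universe, not the genome. Positions absent from the
#' track are explicit lookup misses, never silent zeroes.
#'
#' @name conservation-scores
NULL

#' Construct a score track from per-base values
#'
#' @param chrom,pos,score Parallel vectors; `pos` 0-based single bases.
#' @return A `score_track` object (per-chromosome sorted position/score
#'   pairs).
#' @export
score_track <- function(chrom, pos, score) {
  stopifnot(length(chrom) == length(pos), length(pos) == length(score))
  if (anyDuplicated(paste(chrom, pos))) stop("duplicate positions in score track")
  by_chr <- split(seq_along(pos), chrom)
  track <- lapply(by_chr, function(i) {
    o <- order(pos[i])
    list(pos = as.integer(pos[i][o]), score = as.numeric(score[i][o]))
  })
  structure(track, class = "score_track")
}

#' @export
print.score_track <- function(x, ...) {
  n <- sum(vapply(x, function(c) length(c$pos), integer(1)))
  cat("score_track:", n, "positions on", length(x), "chromosome(s)\n")
  invisible(x)
}

#' Read a score track from fixedStep wiggle or bedGraph
#'
#' Parsing is delegated to [rtracklayer::import()]; interval records
#' (bedGraph, variableStep/fixedStep spans) are expanded to single bases.
#' An optional universe restricts which bases are retained.
#'
#' @param path Wiggle (`.wig`) or bedGraph (`.bedGraph`) path.
#' @param format `"auto"` guesses from the extension and content.
#' @param universe Optional `GRanges`; only bases inside are kept.
#' @return A `score_track`.
#' @export
read_score_track <- function(path, format = c("auto", "wig", "bedGraph"),
                             universe = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(wig|wiggle)(\\.gz)?$", path)) "wig" else
      if (grepl("\\.(bedgraph|bdg)(\\.gz)?$", path, ignore.case = TRUE)) "bedGraph" else {
        first <- readLines(path, n = 5L)
        if (any(grepl("^(fixedStep|variableStep)", first))) "wig" else "bedGraph"
      }
  }
  gr <- rtracklayer::import(path, format = format)
  if (!is.null(universe)) {
    GenomeInfoDb::seqlevels(gr) <- union(GenomeInfoDb::seqlevels(gr),
                                         GenomeInfoDb::seqlevels(universe))
    gr <- IRanges::subsetByOverlaps(gr, universe)
  }
  w <- GenomicRanges::width(gr)
  chrom <- rep(as.character(GenomicRanges::seqnames(gr)), w)
  pos <- sequence(w, from = GenomicRanges::start(gr)) - 1L
  score <- rep(S4Vectors::mcols(gr)$score, w)
  keep <- !duplicated(paste(chrom, pos))
  st <- score_track(chrom[keep], pos[keep], score[keep])
  if (!is.null(universe)) {
    updf <- universe_df(universe)
    st <- subset_track(st, updf)
  }
  st
}

# restrict a track to the positions of a (chrom,pos) data frame
subset_track <- function(track, positions) {
  by_chr <- split(positions$pos, positions$chrom)
  out <- lapply(names(by_chr), function(chr) {
    tc <- track[[chr]]
    if (is.null(tc)) return(NULL)
    i <- match(as.integer(by_chr[[chr]]), tc$pos)
    i <- i[!is.na(i)]
    list(pos = tc$pos[sort(i)], score = tc$score[sort(i)])
  })
  names(out) <- names(by_chr)
  structure(out[!vapply(out, is.null, logical(1))], class = "score_track")
}

# enumerate all 0-based positions of an interval set
universe_df <- function(gr) {
  w <- GenomicRanges::width(gr)
  data.frame(
    chrom = rep(as.character(GenomicRanges::seqnames(gr)), w),
    pos = sequence(w, from = GenomicRanges::start(gr)) - 1L,
    stringsAsFactors = FALSE)
}

# exact numeric key for (chrom, pos) pairs; chrom mapped within `levels`
.pos_key <- function(chrom, pos, levels) {
  match(chrom, levels) * 2^40 + as.numeric(pos)
}

#' Enumerate the positions of an element universe with reference bases
#'
#' @param elements A `GRanges` (merge first).
#' @param reference A [Biostrings::DNAStringSet] named by chromosome.
#' @return Data frame with `chrom`, `pos` (0-based) and `base`.
#' @export
universe_positions <- function(elements, reference) {
  df <- universe_df(elements)
  df$base <- NA_character_
  for (chr in unique(df$chrom)) {
    sel <- df$chrom == chr
    seq <- reference[[chr]]
    if (is.null(seq)) stop("chromosome absent from reference: ", chr)
    df$base[sel] <- unname(as.character(Biostrings::extractAt(
      seq, IRanges::IRanges(df$pos[sel] + 1L, df$pos[sel] + 1L))))
  }
  df
}

#' Look up scores for single-base positions
#'
#' Order-preserving: one score per input position. Positions missing from
#' the track are returned separately; more than 5% missing raises a
#' warning, all missing an error.
#'
#' @param positions Data frame with `chrom` and `pos` (0-based).
#' @param track A [score_track()].
#' @return List with `scores` (numeric, `NA` at misses), `missing`
#'   (logical), `n_missing`.
#' @export
extract_scores <- function(positions, track) {
  n <- nrow(positions)
  scores <- rep(NA_real_, n)
  for (chr in unique(positions$chrom)) {
    tc <- track[[chr]]
    if (is.null(tc)) next
    sel <- which(positions$chrom == chr)
    i <- match(as.integer(positions$pos[sel]), tc$pos)
    scores[sel] <- tc$score[i]
  }
  missing <- is.na(scores)
  if (n > 0 && all(missing)) stop("no queried position has a score in the track")
  if (n > 0 && mean(missing) > 0.05)
    warning(sprintf("%.1f%% of positions missing from score track", 100 * mean(missing)))
  list(scores = scores, missing = missing, n_missing = sum(missing))
}

#' G/C vs A/T composition of a base vector
#'
#' @param bases Character vector of reference bases.
#' @return List with `gc` and `at` fractions (summing to 1).
#' @export
base_composition <- function(bases) {
  b <- toupper(bases)
  known <- b %in% c("A", "C", "G", "T")
  if (!any(known)) stop("no A/C/G/T bases supplied")
  gc <- mean(b[known] %in% c("G", "C"))
  list(gc = gc, at = 1 - gc)
}

#' Draw a G/C-composition-matched random position sample
#'
#' Samples `n` positions from the universe, without replacement, stratified
#' on the binary base class (G/C vs A/T) of the reference base so the
#' sample's composition matches `target`. Per-class counts are fixed by
#' largest-remainder apportionment of `n * target`, making the composition
#' of every draw identical, not merely expected.
#'
#' @param universe Data frame from [universe_positions()] (`chrom`, `pos`,
#'   `base`).
#' @param target Either a list with element `gc` (see [base_composition()])
#'   or a numeric G/C fraction.
#' @param n Sample size.
#' @param seed Optional integer seed.
#' @return Data frame of sampled rows of `universe`.
#' @export
gc_matched_sample <- function(universe, target, n, seed = NULL) {
  if (n == 0L) return(universe[0, , drop = FALSE])
  gc_frac <- if (is.list(target)) target$gc else as.numeric(target)
  stopifnot(gc_frac >= 0, gc_frac <= 1, n >= 0)
  is_gc <- toupper(universe$base) %in% c("G", "C")
  # largest-remainder apportionment between the two strata
  raw <- c(gc = n * gc_frac, at = n * (1 - gc_frac))
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    top <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[top] <- cnt[top] + 1
  }
  avail <- c(gc = sum(is_gc), at = sum(!is_gc))
  short <- cnt > avail
  if (any(short)) stop("insufficient universe positions in stratum: ",
                       paste(names(cnt)[short], collapse = ", "))
  with_seed(seed, {
    idx <- c(sample(which(is_gc), cnt[["gc"]]),
             sample(which(!is_gc), cnt[["at"]]))
    universe[sort(idx), , drop = FALSE]
  })
}

#' Empirical CDF with a bootstrap confidence envelope
#'
#' The point estimate is the standard right-continuous ECDF. The envelope
#' is the pointwise 2.5/97.5 percentile of `B` bootstrap-resampled ECDFs
#' evaluated on the grid; resampling is done by multinomial weighting of
#' the sorted sample, which is distributionally identical to resampling
#' with replacement.
#'
#' @param x Numeric sample (n >= 2 unless degenerate bands are acceptable).
#' @param B Bootstrap replicates (>= 100).
#' @param grid Evaluation grid; default 512 equally spaced points spanning
#'   the sample (plus the exact sorted sample values for step fidelity).
#' @param level Envelope coverage level.
#' @param seed Optional integer seed.
#' @return An `ecdf_band` list: `grid`, `point`, `lower`, `upper`, `B`, `n`.
#' @export
ecdf_band <- function(x, B = 1000L, grid = NULL, level = 0.95, seed = NULL) {
  stopifnot(length(x) >= 1, B >= 100)
  xs <- sort(x)
  n <- length(xs)
  if (is.null(grid)) {
    grid <- sort(unique(c(seq(min(xs), max(xs), length.out = 512L), xs)))
  } else grid <- sort(unique(grid))
  idx <- findInterval(grid, xs)            # how many sample points <= grid value
  point <- idx / n
  W <- with_seed(seed, rmultinom(B, n, rep(1 / n, n)))   # n x B bootstrap weights
  cum <- apply(W, 2L, cumsum) / n                         # ECDF of each replicate at xs
  reps <- rbind(0, cum)[idx + 1L, , drop = FALSE]         # evaluate on grid
  a <- (1 - level) / 2
  qs <- apply(reps, 1L, quantile, probs = c(a, 1 - a), names = FALSE, type = 7)
  structure(list(grid = grid, point = point,
                 lower = pmin(qs[1L, ], point), upper = pmax(qs[2L, ], point),
                 B = B, n = n, level = level),
            class = "ecdf_band")
}

#' @export
print.ecdf_band <- function(x, ...) {
  cat(sprintf("ecdf_band: n=%d, B=%d, %.0f%% envelope on %d grid points\n",
              x$n, x$B, 100 * x$level, length(x$grid)))
  invisible(x)
}

#' Two-sided Kolmogorov-Smirnov comparison
#'
#' `D = sup |ECDF_a - ECDF_b|` with the asymptotic two-sided p-value,
#' via [stats::ks.test()].
#'
#' @param a,b Non-empty numeric samples.
#' @return List with `D`, `p`, and sample sizes.
#' @export
ks_compare <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  kt <- suppressWarnings(ks.test(a, b, alternative = "two.sided", exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value,
       n_a = length(a), n_b = length(b))
}

#' Position of variants relative to their host element
#'
#' Maps each variant to percent along its host element: `[0, 100)` inside
#' (start = 0%, end = 100%), `[-100, 0)` in the upstream flank and
#' `[100, 200)` in the downstream flank, where each flank has the same
#' length as the host element. A variant in range of two elements' flanks
#' is assigned to the nearer element; ties go to the upstream (left)
#' element.
#'
#' @param variants Data frame with `chrom` and `pos` (0-based).
#' @param elements A merged `GRanges`.
#' @return Numeric vector of relative positions (percent); `NA` for
#'   variants farther than one element length from every element.
#' @export
relative_positions <- function(variants, elements) {
  elements <- GenomicRanges::sort(elements)
  edf <- data.frame(chrom = as.character(GenomicRanges::seqnames(elements)),
                    start = GenomicRanges::start(elements) - 1L,
                    end = GenomicRanges::end(elements))
  out <- rep(NA_real_, nrow(variants))
  for (i in seq_len(nrow(variants))) {
    sel <- edf$chrom == variants$chrom[i]
    if (!any(sel)) next
    e <- edf[sel, , drop = FALSE]
    p <- variants$pos[i]
    len <- e$end - e$start
    # candidate iff within one element length of the element's span
    lo <- e$start - len; hi <- e$end + len
    cand <- which(p >= lo & p < hi)
    if (!length(cand)) next
    # distance 0 if inside, else distance to nearest edge; tie -> upstream
    dist <- pmax(0, pmax(e$start[cand] - 1 - p, p - e$end[cand]))
    inside <- p >= e$start[cand] & p < e$end[cand]
    dist[inside] <- -1
    j <- cand[order(dist, e$start[cand])][1L]
    out[i] <- (p - e$start[j]) / (e$end[j] - e$start[j]) * 100
  }
  out
}

#' Conservation scores of bases flanking each variant
#'
#' For every variant, looks up the scores of the `window` bases immediately
#' 5' and the `window` bases immediately 3' of the variant base (the
#' variant base itself is excluded), pooling across variants into one
#' upstream and one downstream sample. Bases missing from the track are
#' dropped and counted.
#'
#' @param variants Data frame with `chrom` and `pos`.
#' @param track A [score_track()].
#' @param window Flank width in bp (>= 1).
#' @return List with `upstream`, `downstream` (numeric samples) and
#'   `n_dropped`.
#' @export
flank_scores <- function(variants, track, window = 3L) {
  if (window < 1L) stop("window must be >= 1")
  offs <- seq_len(window)
  up <- data.frame(chrom = rep(variants$chrom, each = window),
                   pos = rep(variants$pos, each = window) - offs)
  dn <- data.frame(chrom = rep(variants$chrom, each = window),
                   pos = rep(variants$pos, each = window) + offs)
  us <- suppressWarnings(extract_scores(up, track))
  ds <- suppressWarnings(extract_scores(dn, track))
  list(upstream = us$scores[!us$missing],
       downstream = ds$scores[!ds$missing],
       n_dropped = us$n_missing + ds$n_missing)
}

#' Write a score track as bedGraph
#'
#' Adjacent equal-valued bases are run-length collapsed.
#'
#' @param track A [score_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_track <- function(track, path) {
  lines <- character(0)
  for (chr in names(track)) {
    tc <- track[[chr]]
    if (!length(tc$pos)) next
    brk <- c(TRUE, diff(tc$pos) != 1L | diff(tc$score) != 0)
    run <- cumsum(brk)
    start <- tapply(tc$pos, run, function(p) p[1L])
    end <- tapply(tc$pos, run, function(p) p[length(p)] + 1L)
    val <- tapply(tc$score, run, function(s) s[1L])
    lines <- c(lines, sprintf("%s\t%d\t%d\t%s", chr, start, end,
                              format(val, scientific = FALSE, trim = TRUE, digits = 8)))
  }
  writeLines(lines, path)
  invisible(path)
}
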