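# Brute-force oracles and shared fixtures. Oracles are deliberately naive
# (per-base boolean masks, O(n^2) pairwise counts) and independent of the
# implementation paths they check.

# per-base boolean coverage mask of 0-based half-open intervals on one genome
mask_from_intervals <- function(chrom, start, end, genome) {
  masks <- lapply(genome, function(L) logical(L))
  for (i in seq_along(chrom)) {
    masks[[chrom[i]]][(start[i] + 1):end[i]] <- TRUE
  }
  masks
}

mask_from_gr <- function(gr, genome) {
  mask_from_intervals(as.character(GenomicRanges::seqnames(gr)),
                      GenomicRanges::start(gr) - 1L,
                      GenomicRanges::end(gr), genome)
}

# random interval set on a toy genome
random_intervals <- function(n, genome, max_width = 500L) {
  chrom <- sample(names(genome), n, replace = TRUE)
  w <- sample.int(max_width, n, replace = TRUE)
  start <- vapply(seq_len(n), function(i)
    sample.int(genome[[chrom[i]]] - w[i], 1L) - 1L, integer(1))
  intervals(chrom, start, start + w)
}

# O(n^2) Mann-Whitney U for sample a (wins + half ties)
brute_u <- function(a, b) {
  u <- 0
  for (x in a) u <- u + sum(x > b) + 0.5 * sum(x == b)
  u
}

# brute-force two-sample KS sup over all pooled breakpoints
brute_ks_d <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
}

# hand 2x2 Pearson chi-squared, no correction
brute_chi2 <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# small synthetic scenario shared across test files (built once per run)
.small_cache <- new.env(parent = emptyenv())

small_config <- function(seed = 101L, ...) {
  synthetic_config(genome = c(chrA = 150000L, chrB = 150000L),
                   n_elements = 40L, element_length = c(200L, 400L),
                   n_rare = 500L, n_intermediate = 200L, n_prevalent = 500L,
                   populations = c("POP-A", "POP-B", "POP-C"),
                   seed = seed, ...)
}

small_sim <- function() {
  if (is.null(.small_cache$sim)) .small_cache$sim <- simulate_all(small_config())
  .small_cache$sim
}

small_universe <- function() {
  if (is.null(.small_cache$uni)) {
    sim <- small_sim()
    .small_cache$uni <- element_universe(sim$elements, sim$reference,
                                         sim$scores$track)
  }
  .small_cache$uni
}
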