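#' Interval algebra on half-open genomic coordinates
#'
#' Elements, feature tracks and random universes are represented as
#' [GenomicRanges::GRanges] objects. All tabular input and output
#' (BED files, position data frames) uses the BED convention:
#' 0-based, half-open `[start, end)`. Conversion to the 1-based closed
#' convention of `GRanges` happens at the I/O boundary and nowhere else.
#'
#' @name interval-algebra
NULL

#' Build a GRanges from 0-based half-open coordinates
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors; 0-based half-open.
#' @param name Optional labels.
#' @param genome Optional named vector of chromosome lengths; when given,
#'   intervals extending past a chromosome end are rejected.
#' @return A `GRanges`.
#' @export
intervals <- function(chrom, start, end, name = NULL, genome = NULL) {
  bad <- which(!(start >= 0 & end > start))
  if (length(bad)) {
    stop(sprintf("malformed interval at record %d: %s:[%s,%s) (need 0 <= start < end)",
                 bad[1], chrom[bad[1]], start[bad[1]], end[bad[1]]))
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  if (!is.null(name)) S4Vectors::mcols(gr)$name <- name
  if (!is.null(genome)) {
    miss <- setdiff(as.character(GenomeInfoDb::seqnames(gr)), names(genome))
    if (length(miss)) stop("chromosome(s) absent from genome: ", paste(miss, collapse = ", "))
    over <- end > genome[as.character(GenomicRanges::seqnames(gr))]
    if (any(over)) stop("interval extends past chromosome end at record ", which(over)[1])
    GenomeInfoDb::seqlevels(gr) <- names(genome)
    GenomeInfoDb::seqlengths(gr) <- unname(genome)
  }
  gr
}

#' Total genomic span of an interval set
#'
#' @param gr A `GRanges`.
#' @return Total length in bp (sum of widths; overlapping bases counted once
#'   only after [merge_intervals()]).
#' @export
total_length <- function(gr) sum(as.numeric(GenomicRanges::width(gr)))

#' Merge overlapping and book-ended intervals
#'
#' Coalesces a set of intervals into the minimal sorted, disjoint set with
#' identical per-base coverage. Book-ended intervals (`[100,200)`,
#' `[200,300)`) are merged, matching the default of the interval-merge
#' tools commonly used to assemble element catalogues.
#'
#' @param gr A `GRanges`.
#' @return A sorted, disjoint `GRanges` covering the same bases.
#' @export
merge_intervals <- function(gr) {
  GenomicRanges::reduce(GenomicRanges::sort(gr), min.gapwidth = 1L)
}

# Single-base positions (0-based) -> width-1 GRanges
positions_gr <- function(chrom, pos) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, pos + 1L))
}

#' Count single-base positions overlapping a feature set
#'
#' A position `p` overlaps a feature `[s, e)` iff `s <= p < e`. Positions on
#' chromosomes absent from the feature set count as non-overlapping.
#'
#' @param positions Data frame with columns `chrom` and `pos` (0-based).
#' @param features A `GRanges` feature set (merge first if overlapping).
#' @return List with `count` (total overlapping positions) and `flags`
#'   (logical vector, one per position, in input order).
#' @export
overlap_count <- function(positions, features) {
  stopifnot(all(c("chrom", "pos") %in% names(positions)))
  if (nrow(positions) == 0L) return(list(count = 0L, flags = logical(0)))
  known <- positions$chrom %in% GenomeInfoDb::seqlevels(features)
  flags <- logical(nrow(positions))
  if (any(known)) {
    q <- positions_gr(positions$chrom[known], positions$pos[known])
    GenomeInfoDb::seqlevels(q) <- GenomeInfoDb::seqlevels(features)
    flags[known] <- IRanges::overlapsAny(q, features)
  }
  list(count = sum(flags), flags = flags)
}

#' Randomly relocate intervals, preserving their lengths
#'
#' Each interval is placed uniformly at random on its chromosome (or, with
#' `same_chrom = FALSE`, on a random chromosome long enough to hold it),
#' avoiding an optional exclusion set, by rejection sampling. The multiset
#' of interval lengths -- and hence the total length -- is preserved
#' exactly; this is the random universe used for "random genomic regions of
#' the same total length" contrasts.
#'
#' @param gr Intervals to relocate.
#' @param genome Named vector of chromosome lengths.
#' @param excluded Optional `GRanges` the output must not touch.
#' @param same_chrom Keep each interval on its original chromosome.
#' @param seed Optional integer seed for reproducibility.
#' @param max_tries Rejection-sampling attempts per interval before erroring.
#' @return A `GRanges` with the same widths as `gr`.
#' @export
shuffle_intervals <- function(gr, genome, excluded = NULL, same_chrom = TRUE,
                              seed = NULL, max_tries = 1000L) {
  excl <- if (is.null(excluded)) GenomicRanges::GRanges() else merge_intervals(excluded)
  widths <- GenomicRanges::width(gr)
  chroms <- as.character(GenomicRanges::seqnames(gr))
  with_seed(seed, {
    out_chrom <- character(length(gr))
    out_start <- integer(length(gr))  # 1-based
    for (i in seq_along(gr)) {
      w <- widths[i]
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        chr <- if (same_chrom) chroms[i] else {
          fits <- names(genome)[genome >= w]
          if (!length(fits)) break
          sample(fits, 1L, prob = genome[fits] - w + 1)
        }
        if (!chr %in% names(genome)) stop("chromosome absent from genome: ", chr)
        span <- genome[[chr]] - w + 1L
        if (span < 1L) break
        s <- sample.int(span, 1L)
        cand <- GenomicRanges::GRanges(chr, IRanges::IRanges(s, s + w - 1L))
        if (length(excl) == 0L || !any(IRanges::overlapsAny(cand, excl))) {
          out_chrom[i] <- chr; out_start[i] <- s; ok <- TRUE; break
        }
      }
      if (!ok) stop(sprintf(
        "could not place interval %d (width %d) after %d tries; allowed space too fragmented",
        i, w, max_tries))
    }
    GenomicRanges::GRanges(out_chrom, IRanges::IRanges(out_start, width = widths))
  })
}

#' Read a BED file
#'
#' BED3+ (tab-separated, 0-based half-open); `track` and `browser` header
#' lines are skipped. Parsing is delegated to [rtracklayer::import()].
#'
#' @param path BED file path.
#' @param genome Optional named chromosome-length vector to attach.
#' @return A `GRanges`.
#' @export
read_bed <- function(path, genome = NULL) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop("failed to parse BED file '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  gr <- GenomicRanges::GRanges(gr)  # drop UCSCData subclass
  S4Vectors::mcols(gr) <- S4Vectors::mcols(gr)[, intersect("name", names(S4Vectors::mcols(gr))), drop = FALSE]
  if (!is.null(genome)) {
    GenomeInfoDb::seqlevels(gr) <- union(GenomeInfoDb::seqlevels(gr), names(genome))
    GenomeInfoDb::seqlengths(gr)[names(genome)] <- unname(genome)
  }
  gr
}

#' Write a BED file
#'
#' Writes BED3 (or BED4 when a `name` column is present), tab-separated,
#' 0-based half-open.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  nm <- S4Vectors::mcols(gr)$name
  if (!is.null(nm)) df$name <- nm
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column genome file
#'
#' @param path Tab-separated file with columns chromosome name and length.
#' @return Named integer vector of chromosome lengths.
#' @export
read_genome <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "length"),
                   colClasses = c("character", "numeric"))
  setNames(as.integer(df$length), df$chrom)
}

#' Write a two-column genome file
#' @param genome Named integer vector of chromosome lengths.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  writeLines(sprintf("%s\t%d", names(genome), as.integer(genome)), path)
  invisible(path)
}
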