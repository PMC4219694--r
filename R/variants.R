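#' Variant sets and minor-allele-frequency stratification
#'
#' Variant calls are held in plain data frames with columns `chrom`,
#' `pos` (0-based), `ref`, `alt`, `maf` and `population`. Variant identity
#' is the key `(chrom, pos, alt)`; a `ref` mismatch at an identical key is
#' treated as a data inconsistency, not as two variants.
#'
#' @name variant-sets
NULL

#' Default MAF class thresholds
#'
#' Rare: MAF < 0.5%; prevalent: MAF > 5%; intermediate otherwise.
#' Inequalities are strict, so the boundary values fall in the
#' intermediate class.
#' @export
maf_thresholds <- function(rare = 0.005, prevalent = 0.05) {
  stopifnot(rare > 0, prevalent > rare, prevalent < 0.5)
  list(rare = rare, prevalent = prevalent)
}

#' Classify minor allele frequencies
#'
#' @param maf Numeric vector of minor allele frequencies in `[0, 0.5]`.
#' @param thresholds See [maf_thresholds()].
#' @return Factor with levels `rare`, `intermediate`, `prevalent`.
#' @export
#' @examples
#' classify_maf(c(0.004, 0.02, 0.06))
classify_maf <- function(maf, thresholds = maf_thresholds()) {
  if (any(is.na(maf)) || any(maf < 0 | maf > 0.5)) {
    stop("maf must lie in [0, 0.5] (fold alternate-allele frequencies first)")
  }
  cls <- ifelse(maf < thresholds$rare, "rare",
                ifelse(maf > thresholds$prevalent, "prevalent", "intermediate"))
  factor(cls, levels = c("rare", "intermediate", "prevalent"))
}

#' Construct / validate a variant set
#'
#' @param df Data frame with columns `chrom`, `pos`, `ref`, `alt`, `maf`.
#' @param population Dataset label stamped on every record.
#' @return The validated data frame with a `population` column and
#'   `class` factor added.
#' @export
variant_set <- function(df, population = NA_character_) {
  need <- c("chrom", "pos", "ref", "alt", "maf")
  stopifnot(all(need %in% names(df)))
  if (nrow(df)) {
    if (any(nchar(df$ref) != 1L | nchar(df$alt) != 1L))
      stop("variant_set holds single-nucleotide variants only")
    if (any(df$ref == df$alt)) stop("ref and alt must differ")
    key <- paste(df$chrom, df$pos, df$alt)
    if (anyDuplicated(key)) stop("duplicate (chrom, pos, alt) key in variant set")
    refkey <- paste(df$chrom, df$pos)
    if (anyDuplicated(unique(data.frame(refkey, df$ref))$refkey))
      stop("conflicting ref alleles at one position")
  }
  df$maf <- as.numeric(df$maf)
  df$class <- classify_maf(df$maf)
  df$population <- population
  df[order(df$chrom, df$pos, df$alt), , drop = FALSE]
}

variant_key <- function(vs) paste(vs$chrom, vs$pos, vs$alt)

#' Read SNVs from a VCF
#'
#' Reads a VCF (4.x, plain or bgzipped), decomposes multiallelic records,
#' keeps biallelic SNVs only, optionally restricts to a region set, and
#' folds the alternate-allele frequency from an INFO field to a minor
#' allele frequency (`f > 0.5` becomes `1 - f`). Positions are converted
#' to 0-based. Records lacking the frequency field are dropped and counted.
#'
#' @param path VCF path.
#' @param regions Optional `GRanges`; only variants inside are kept.
#' @param af_field INFO key carrying the per-alternate allele frequency.
#' @param population Dataset label for the resulting set.
#' @return A variant set data frame (see [variant_set()]) with attributes
#'   `n_skipped_no_af` and `n_skipped_not_snv` recording filter counts.
#' @export
read_vcf_snvs <- function(path, regions = NULL, af_field = "AF",
                          population = NA_character_) {
  v <- VariantAnnotation::readVcf(path, genome = "unknown")
  v <- VariantAnnotation::expand(v)
  rr <- SummarizedExperiment::rowRanges(v)
  ref <- as.character(VariantAnnotation::ref(v))
  alt <- as.character(VariantAnnotation::alt(v))
  af <- VariantAnnotation::info(v)[[af_field]]
  if (is.null(af)) af <- rep(NA_real_, length(v))
  if (is.list(af) || methods::is(af, "List")) af <- as.numeric(unlist(af))
  af <- as.numeric(af)

  is_snv <- nchar(ref) == 1L & nchar(alt) == 1L & ref != alt
  n_not_snv <- sum(!is_snv)
  has_af <- !is.na(af)
  n_no_af <- sum(is_snv & !has_af)
  if (n_no_af > 0) warning(n_no_af, " SNV record(s) lacked INFO/", af_field,
                           " and were skipped")
  keep <- is_snv & has_af
  rr <- rr[keep]; ref <- ref[keep]; alt <- alt[keep]; af <- af[keep]
  if (!is.null(regions) && length(rr)) {
    GenomeInfoDb::seqlevels(rr) <- union(GenomeInfoDb::seqlevels(rr),
                                         GenomeInfoDb::seqlevels(regions))
    inside <- IRanges::overlapsAny(rr, regions)
    rr <- rr[inside]; ref <- ref[inside]; alt <- alt[inside]; af <- af[inside]
  }
  maf <- ifelse(af > 0.5, 1 - af, af)
  out <- variant_set(data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr) - 1L,
    ref = ref, alt = alt, maf = maf,
    stringsAsFactors = FALSE), population)
  attr(out, "n_skipped_no_af") <- n_no_af
  attr(out, "n_skipped_not_snv") <- n_not_snv
  out
}

#' Write a variant set as a minimal VCF
#'
#' Emits VCF 4.2 with the MAF in an `AF` INFO field (1-based positions).
#' Round-tripping through [read_vcf_snvs()] recovers identical keys and
#' frequencies.
#'
#' @param vs Variant set data frame.
#' @param path Output path.
#' @param genome Optional named chromosome lengths for `##contig` headers.
#' @return `path`, invisibly.
#' @export
write_vcf_snvs <- function(vs, path, genome = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">")
  if (!is.null(genome)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(genome), unname(genome)))
  }
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tAF=%s",
                  vs$chrom, vs$pos + 1L, vs$ref, vs$alt,
                  format(vs$maf, scientific = FALSE, trim = TRUE, digits = 10))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Intersect two call sets
#'
#' Consensus calls are those present (same `(chrom, pos, alt)` key) in both
#' sets -- the "called by both programs" filter of dual-caller designs. The
#' MAF of a consensus call is taken from set `a`, mirroring designs where
#' one caller's pooled frequency estimates are authoritative.
#'
#' @param a,b Variant set data frames.
#' @return List with `consensus` (a variant set), `n_only_a`, `n_only_b`.
#' @export
intersect_callsets <- function(a, b) {
  ka <- variant_key(a); kb <- variant_key(b)
  keep <- ka %in% kb
  cons <- a[keep, , drop = FALSE]
  rownames(cons) <- NULL
  list(consensus = cons,
       n_only_a = sum(!keep),
       n_only_b = sum(!(kb %in% ka)))
}

#' Cross-dataset sharing table (Venn cells)
#'
#' Tabulates, for the union of variant keys across the given sets, every
#' membership pattern (which sets contain the key). Cells sum to the union
#' size.
#'
#' @param sets Named list of >= 2 variant set data frames.
#' @return Data frame with one logical column per set plus `count`.
#' @export
sharing_table <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2L)
  if (is.null(names(sets)) || any(names(sets) == ""))
    names(sets) <- paste0("set", seq_along(sets))
  keys <- lapply(sets, variant_key)
  univ <- unique(unlist(keys))
  member <- vapply(keys, function(k) univ %in% k, logical(length(univ)))
  if (length(univ) == 1L) member <- matrix(member, nrow = 1,
                                           dimnames = list(NULL, names(sets)))
  pat <- apply(member, 1L, paste, collapse = "")
  grid <- expand.grid(rep(list(c(TRUE, FALSE)), length(sets)))
  names(grid) <- names(sets)
  grid <- grid[rowSums(grid) > 0, , drop = FALSE]
  gpat <- apply(grid, 1L, function(r) paste(as.logical(r), collapse = ""))
  grid$count <- as.integer(table(factor(pat, levels = gpat))[gpat])
  rownames(grid) <- NULL
  grid
}

#' SNV rate per Mb per sample
#'
#' @param n_snvs Number of variants observed.
#' @param target_length_bp Length of the surveyed region in bp.
#' @param n_samples Number of individuals in the dataset.
#' @return Variants per megabase of target per sample.
#' @export
#' @examples
#' snv_rate(10, 1e6, 10)  # 1.0
snv_rate <- function(n_snvs, target_length_bp, n_samples) {
  stopifnot(n_snvs >= 0)
  if (target_length_bp <= 0) stop("target_length_bp must be > 0")
  if (n_samples <= 0) stop("n_samples must be > 0")
  n_snvs / (target_length_bp / 1e6) / n_samples
}

#' Pooled sequencing design
#'
#' @param n_samples Individuals pooled across all libraries.
#' @param n_pools Number of pooled libraries.
#' @param mean_pool_coverage Mean fold-coverage per pool across the target.
#' @return A `pool_design` list.
#' @export
pool_design <- function(n_samples, n_pools, mean_pool_coverage) {
  stopifnot(n_samples >= n_pools, n_pools >= 1, mean_pool_coverage >= 0)
  structure(list(n_samples = n_samples, n_pools = n_pools,
                 mean_pool_coverage = mean_pool_coverage),
            class = "pool_design")
}

#' Per-allele coverage of a pooled design
#'
#' A pool of `n_samples / n_pools` diploid individuals carries
#' `2 * n_samples / n_pools` chromosome copies, so the depth attributable
#' to one copy is `mean_pool_coverage / (2 * n_samples / n_pools)`.
#' Full precision is returned; printed summaries usually round to the
#' nearest integer.
#'
#' @param design A [pool_design()].
#' @return Fold-coverage per sequenced allele.
#' @export
#' @examples
#' per_allele_coverage(pool_design(501, 48, 430))  # ~20
per_allele_coverage <- function(design) {
  stopifnot(inherits(design, "pool_design"))
  design$mean_pool_coverage / (2 * design$n_samples / design$n_pools)
}
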