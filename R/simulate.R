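#' Synthetic data with the statistical structure the analysis assumes
#'
#' The generator produces a small genome with a realistic base
#' composition, AT-rich conserved elements embedded in it, a per-base
#' conservation score elevated inside elements (with contiguous "relaxed"
#' low-score patches), feature tracks whose placement follows the score,
#' and frequency-stratified variant sets whose placement probability
#' depends on the local score -- so the full pipeline can run, and be
#' calibrated, without any external download.
#'
#' @name synthetic-data
NULL

#' Default synthetic scenario configuration
#'
#' Defaults describe the study conditions the analyses are calibrated
#' against: a 10 Mb two-chromosome genome at 41% G/C, 300 AT-rich
#' elements of 200-600 bp, phyloP-like scores centred at +2 inside
#' elements (with 15% of element bases in relaxed patches centred at 0)
#' and 0 outside, 2000 rare / 1000 intermediate / 2000 prevalent variants
#' per population, and a prevalent placement log-odds decrease `beta` of
#' 2.5 per score unit (a score-SD-scaled effect of 2, the strong-selection
#' regime in which all headline contrasts are unequivocal).
#'
#' @param genome Named chromosome lengths.
#' @param background_gc G/C fraction of the genomic background.
#' @param n_elements Number of conserved elements.
#' @param element_length Min/max element length (bp); minimum 200.
#' @param element_at A/T fraction inside elements (elements are AT-rich).
#' @param score_in,score_relaxed,score_out `c(mean, sd)` of the score
#'   inside elements, in relaxed patches, and outside elements.
#' @param relaxed_fraction Fraction of element bases inside relaxed
#'   patches.
#' @param relaxed_patch_length Length of one relaxed patch (bp).
#' @param n_rare,n_intermediate,n_prevalent Variants per frequency class
#'   per population.
#' @param beta Log-odds decrease of prevalent-variant placement per score
#'   unit (0 = placement independent of conservation). Intermediate
#'   variants use `beta / 2`.
#' @param score_center Score at which the logistic placement acceptance
#'   is 1/2.
#' @param gc_bias Relative placement odds of G/C-base positions for all
#'   variant classes (variant positions are G/C-enriched).
#' @param populations Population labels for cohort simulation.
#' @param prevalent_sharing Fraction of the master prevalent catalogue
#'   observed by each population (drives cross-population sharing).
#' @param feature_length Feature (binding-site) interval length (bp).
#' @param sparse_density_in Feature coverage fraction inside elements for
#'   the sparse (TFBS-like) track.
#' @param sparse_density_bg Feature coverage fraction of the non-element
#'   background for the sparse track.
#' @param dense_density Coverage fraction of the element universe for the
#'   dense (super-enhancer-like) track.
#' @param feature_score_coupling Log-odds increase of feature placement
#'   per score unit (binding sites sit at conserved bases).
#' @param seed Top-level seed; every stage derives a named substream.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(genome = c(chrS1 = 5e6, chrS2 = 5e6),
                             background_gc = 0.41,
                             n_elements = 300L,
                             element_length = c(200L, 600L),
                             element_at = 0.62,
                             score_in = c(mean = 2.0, sd = 0.8),
                             score_relaxed = c(mean = 0.0, sd = 0.8),
                             score_out = c(mean = 0.0, sd = 1.0),
                             relaxed_fraction = 0.15,
                             relaxed_patch_length = 40L,
                             n_rare = 2000L, n_intermediate = 1000L,
                             n_prevalent = 2000L,
                             beta = 2.5, score_center = 1.0, gc_bias = 2.0,
                             populations = c("POP-A", "POP-B", "POP-C"),
                             prevalent_sharing = 0.8,
                             feature_length = 20L,
                             sparse_density_in = 0.25,
                             sparse_density_bg = 0.01,
                             dense_density = 0.6,
                             feature_score_coupling = 3.0,
                             seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(all(cfg$genome > 0), cfg$n_elements >= 0,
            cfg$element_length[1] >= 200L,
            cfg$element_length[2] >= cfg$element_length[1],
            cfg$background_gc >= 0, cfg$background_gc <= 1,
            cfg$element_at >= 0, cfg$element_at <= 1,
            cfg$relaxed_fraction >= 0, cfg$relaxed_fraction <= 1,
            cfg$n_rare >= 0, cfg$n_intermediate >= 0, cfg$n_prevalent >= 0,
            cfg$gc_bias > 0, cfg$prevalent_sharing >= 0, cfg$prevalent_sharing <= 1,
            cfg$sparse_density_in >= 0, cfg$sparse_density_in <= 1,
            cfg$sparse_density_bg >= 0, cfg$sparse_density_bg <= 1,
            cfg$dense_density >= 0, cfg$dense_density <= 1)
  if (sum(cfg$genome) < cfg$n_elements * (cfg$element_length[2] + 2400))
    stop("element total length (with spacing) exceeds genome size")
  structure(cfg, class = "synthetic_config")
}

# i.i.d. base codes at a given GC fraction; codes 1..4 = A,C,G,T
.sample_codes <- function(n, gc) {
  sample.int(4L, n, replace = TRUE,
             prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Simulate the reference genome and embedded conserved elements
#'
#' Background bases are i.i.d. at `background_gc`; element interiors are
#' resampled at the (AT-enriched) element composition. Elements are
#' placed disjointly with a spacing buffer so that each element's flanks
#' (used for flank-score analyses) do not run into a neighbouring
#' element.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed; default derived from `config$seed`.
#' @return List with `reference` ([Biostrings::DNAStringSet]), `genome`
#'   (named lengths) and `elements` (named `GRanges`).
#' @export
simulate_genome <- function(config, seed = derive_seed(config$seed, "genome")) {
  with_seed(seed, {
    genome <- config$genome
    codes <- lapply(genome, function(L) .sample_codes(L, config$background_gc))
    # place elements disjointly with a buffer of one max element length per side
    buf <- config$element_length[2] * 2L
    n <- config$n_elements
    lens <- if (n > 0) sample(seq(config$element_length[1], config$element_length[2]), n,
                              replace = TRUE) else integer(0)
    chrom <- character(n); start1 <- integer(n)   # 1-based starts
    acc <- lapply(genome, function(L) list(s = integer(0), e = integer(0)))
    for (i in seq_len(n)) {
      done <- FALSE
      for (try in 1:1000) {
        chr <- sample(names(genome), 1L, prob = genome)
        s <- sample.int(genome[[chr]] - lens[i] + 1L, 1L)
        e <- s + lens[i] - 1L
        a <- acc[[chr]]
        if (!any(s - buf <= a$e & e + buf >= a$s)) {
          chrom[i] <- chr; start1[i] <- s
          acc[[chr]]$s <- c(a$s, s); acc[[chr]]$e <- c(a$e, e)
          done <- TRUE
          break
        }
      }
      if (!done) stop("could not place element ", i, "; genome too crowded")
    }
    elements <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start1, width = lens))
    o <- GenomicRanges::order(elements)
    elements <- elements[o]
    S4Vectors::mcols(elements)$name <- sprintf("elem%04d", seq_len(n))
    GenomeInfoDb::seqlevels(elements) <- names(genome)
    GenomeInfoDb::seqlengths(elements) <- unname(genome)
    # resample element interiors at the AT-enriched composition
    echr <- as.character(GenomicRanges::seqnames(elements))
    for (chr in unique(echr)) {
      sel <- which(echr == chr)
      idx <- unlist(lapply(sel, function(i)
        GenomicRanges::start(elements)[i]:GenomicRanges::end(elements)[i]))
      codes[[chr]][idx] <- .sample_codes(length(idx), 1 - config$element_at)
    }
    alphabet <- utf8ToInt("ACGT")
    seqs <- vapply(codes, function(cv) intToUtf8(alphabet[cv]), character(1))
    reference <- Biostrings::DNAStringSet(seqs)
    names(reference) <- names(genome)
    list(reference = reference, genome = genome, elements = elements)
  })
}

#' Enumerate the element universe with reference bases and scores
#'
#' @param elements Element `GRanges`.
#' @param reference Reference `DNAStringSet`.
#' @param track Optional [score_track()]; adds a `score` column.
#' @return Data frame with `chrom`, `pos`, `base` and (optionally)
#'   `score`, one row per element base.
#' @export
element_universe <- function(elements, reference, track = NULL) {
  uni <- universe_positions(merge_intervals(elements), reference)
  if (!is.null(track)) uni$score <- extract_scores(uni, track)$scores
  uni
}

# element universe extended by one element length on each side (clipped)
score_universe <- function(elements, genome) {
  w <- GenomicRanges::width(elements)
  ext <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(elements),
    IRanges::IRanges(pmax(1L, GenomicRanges::start(elements) - w),
                     pmin(genome[as.character(GenomicRanges::seqnames(elements))],
                          GenomicRanges::end(elements) + w)))
  merge_intervals(ext)
}

#' Simulate a per-base conservation score track
#'
#' Scores are Gaussian: `score_in` inside elements, `score_relaxed` in
#' contiguous relaxed patches covering `relaxed_fraction` of each
#' element, and `score_out` over the flanking margin (one element length
#' per side). The relaxed patch positions are returned as ground truth.
#'
#' @param config A [synthetic_config()].
#' @param elements Element `GRanges` from [simulate_genome()].
#' @param seed Integer seed.
#' @return List with `track` (a [score_track()]), `relaxed` (data frame
#'   of relaxed positions) and `universe` (the scored `GRanges`).
#' @export
simulate_scores <- function(config, elements,
                            seed = derive_seed(config$seed, "scores")) {
  with_seed(seed, {
    genome <- config$genome
    uni <- score_universe(elements, genome)
    updf <- universe_df(uni)
    key_in <- overlap_count(updf, elements)$flags
    # carve relaxed patches inside each element
    plen <- config$relaxed_patch_length
    relaxed_list <- lapply(seq_along(elements), function(i) {
      w <- GenomicRanges::width(elements)[i]
      n_patch <- round(config$relaxed_fraction * w / plen)
      if (n_patch == 0) return(NULL)
      slots <- floor(w / plen)
      pick <- sample.int(slots, min(n_patch, slots))
      s0 <- GenomicRanges::start(elements)[i] - 1L  # 0-based element start
      pos <- unlist(lapply(pick, function(k) s0 + (k - 1L) * plen + 0:(plen - 1L)))
      data.frame(chrom = as.character(GenomicRanges::seqnames(elements)[i]),
                 pos = pos, stringsAsFactors = FALSE)
    })
    relaxed <- do.call(rbind, relaxed_list)
    if (is.null(relaxed)) relaxed <- data.frame(chrom = character(0), pos = integer(0))
    lev <- names(genome)
    is_relaxed <- .pos_key(updf$chrom, updf$pos, lev) %in%
      .pos_key(relaxed$chrom, relaxed$pos, lev)
    n <- nrow(updf)
    score <- rnorm(n, config$score_out[["mean"]], config$score_out[["sd"]])
    score[key_in] <- rnorm(sum(key_in), config$score_in[["mean"]], config$score_in[["sd"]])
    score[is_relaxed] <- rnorm(sum(is_relaxed), config$score_relaxed[["mean"]],
                               config$score_relaxed[["sd"]])
    list(track = score_track(updf$chrom, updf$pos, score),
         relaxed = relaxed, universe = uni)
  })
}

# weighted sampling of n distinct indices with weights w (exponential race)
.weighted_draw <- function(w, n) {
  if (n == 0L) return(integer(0))
  if (n > length(w)) stop("requested count exceeds available positions")
  order(stats::rexp(length(w)) / w)[seq_len(n)]
}

#' Simulate one population's frequency-stratified variant set
#'
#' Rare variants are placed uniformly over element positions (up to the
#' G/C placement bias shared by all classes). Prevalent variants are
#' placed with logistic acceptance decreasing in the local score
#' (log-odds slope `-beta`), intermediate variants with slope `-beta/2`.
#' MAFs are drawn uniformly from the class-consistent ranges; the
#' alternate base is drawn uniformly among the three non-reference bases.
#'
#' @param config A [synthetic_config()].
#' @param elements Element `GRanges`.
#' @param track Score track covering the elements.
#' @param reference Reference `DNAStringSet`.
#' @param population Label for the output set.
#' @param counts Named vector of per-class counts; defaults from `config`.
#' @param seed Integer seed.
#' @param universe Optional precomputed scored universe from
#'   [element_universe()]; avoids recomputation in repeated-draw studies.
#' @return A variant set data frame with attribute `ground_truth` (data
#'   frame of placement scores and true classes).
#' @export
simulate_variants <- function(config, elements, track, reference,
                              population = "SIM",
                              counts = c(rare = config$n_rare,
                                         intermediate = config$n_intermediate,
                                         prevalent = config$n_prevalent),
                              seed = derive_seed(config$seed,
                                                 paste0("variants_", population)),
                              universe = NULL) {
  with_seed(seed, {
    uni <- universe %||% element_universe(elements, reference, track)
    sc <- uni$score
    if (anyNA(sc)) stop("score track does not cover the element universe")
    base_w <- ifelse(toupper(uni$base) %in% c("G", "C"), config$gc_bias, 1)
    slope <- c(rare = 0, intermediate = config$beta / 2, prevalent = config$beta)
    avail <- rep(TRUE, nrow(uni))
    out <- list(); gt <- list()
    for (cl in c("rare", "intermediate", "prevalent")) {
      k <- if (cl %in% names(counts)) counts[[cl]] else 0L
      if (is.na(k) || k == 0) next
      w <- base_w * stats::plogis(-slope[[cl]] * (sc - config$score_center))
      w[!avail] <- 0
      if (sum(avail) < k) stop("requested ", cl, " count exceeds available positions")
      idx <- .weighted_draw(w, k)
      avail[idx] <- FALSE
      maf <- switch(cl,
                    rare = runif(k, 0.0005, 0.005),
                    intermediate = runif(k, 0.005, 0.05),
                    prevalent = runif(k, 0.05, 0.5))
      ref <- toupper(uni$base[idx])
      alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                    character(1), USE.NAMES = FALSE)
      out[[cl]] <- data.frame(chrom = uni$chrom[idx], pos = uni$pos[idx],
                              ref = ref, alt = alt, maf = maf,
                              stringsAsFactors = FALSE)
      gt[[cl]] <- data.frame(chrom = uni$chrom[idx], pos = uni$pos[idx],
                             true_class = cl, placement_score = sc[idx],
                             stringsAsFactors = FALSE)
    }
    vs <- variant_set(do.call(rbind, out), population)
    attr(vs, "ground_truth") <- do.call(rbind, gt)
    vs
  })
}

#' Simulate cohort variant sets with cross-population sharing
#'
#' A master catalogue of prevalent variants is generated once; each
#' population observes a fraction `prevalent_sharing` of it (same sites,
#' same global MAFs), while rare and intermediate variants are drawn
#' independently per population. This yields the qualitative sharing
#' structure of multi-cohort surveys: prevalent variants mostly shared,
#' rare variants mostly private.
#'
#' @inheritParams simulate_variants
#' @return Named list of variant set data frames, one per population.
#' @export
simulate_cohorts <- function(config, elements, track, reference,
                             seed = derive_seed(config$seed, "cohorts")) {
  uni <- element_universe(elements, reference, track)
  master <- simulate_variants(config, elements, track, reference,
                              population = "master",
                              counts = c(rare = 0, intermediate = 0,
                                         prevalent = config$n_prevalent),
                              seed = derive_seed(seed, "master_prevalent"),
                              universe = uni)
  sets <- lapply(config$populations, function(popn) {
    priv <- simulate_variants(config, elements, track, reference,
                              population = popn,
                              counts = c(rare = config$n_rare,
                                         intermediate = config$n_intermediate,
                                         prevalent = 0),
                              seed = derive_seed(seed, paste0("private_", popn)),
                              universe = uni)
    n_obs <- round(config$prevalent_sharing * nrow(master))
    obs <- with_seed(derive_seed(seed, paste0("observe_", popn)),
                     sort(sample.int(nrow(master), n_obs)))
    shared <- master[obs, , drop = FALSE]
    # drop the rare collision where a private variant hits a catalogue site
    dup <- paste(shared$chrom, shared$pos) %in% paste(priv$chrom, priv$pos)
    merged <- rbind(priv[, c("chrom", "pos", "ref", "alt", "maf")],
                    shared[!dup, c("chrom", "pos", "ref", "alt", "maf")])
    gt <- rbind(attr(priv, "ground_truth"),
                attr(master, "ground_truth")[obs, ][!dup, ])
    vs <- variant_set(merged, popn)
    attr(vs, "ground_truth") <- gt
    vs
  })
  names(sets) <- config$populations
  sets
}

# pick k of n feature slots per element, weighted by slot mean score
.select_slots <- function(elements, track, flen, density, coupling, center) {
  if (density == 0 || length(elements) == 0L) return(NULL)
  edf <- universe_df(elements)                       # in element order
  idx_elem <- rep(seq_along(elements), GenomicRanges::width(elements))
  sc <- extract_scores(edf, track)$scores
  spl <- split(seq_along(idx_elem), idx_elem)
  picks <- vector("list", length(elements))
  for (i in seq_along(elements)) {
    rows <- spl[[as.character(i)]]
    w <- length(rows)
    slots <- floor(w / flen)
    if (slots == 0L) next
    k <- round(slots * density)
    if (k == 0L) next
    s0 <- edf$pos[rows[1L]]                          # 0-based element start
    used <- seq_len(slots * flen)
    ms <- rowsum(sc[rows[used]], rep(seq_len(slots), each = flen))[, 1L] / flen
    wt <- if (coupling == 0) rep(1, slots) else stats::plogis(coupling * (ms - center))
    pick <- .weighted_draw(wt, min(k, slots))
    starts <- s0 + (pick - 1L) * flen
    picks[[i]] <- data.frame(chrom = edf$chrom[rows[1L]], start = starts,
                             end = starts + flen, stringsAsFactors = FALSE)
  }
  do.call(rbind, picks)
}

#' Simulate sparse (TFBS-like) and dense (SE-like) feature tracks
#'
#' Both tracks are built from disjoint fixed-length intervals. The sparse
#' track covers `sparse_density_in` of each element (slots selected with
#' log-odds weight `feature_score_coupling` per score unit, so binding
#' sites prefer conserved bases) plus a `sparse_density_bg` background
#' outside elements. The dense track covers `dense_density` of each
#' element uniformly, emulating the much higher per-base regulatory
#' occupancy of super-enhancer territory.
#'
#' @param config A [synthetic_config()].
#' @param elements Element `GRanges`.
#' @param track Score track (needed for score-coupled placement).
#' @param seed Integer seed.
#' @return List with `sparse`, `dense` (`GRanges`) and realized coverage
#'   fractions `sparse_coverage_in`, `dense_coverage_in`.
#' @export
simulate_features <- function(config, elements, track,
                              seed = derive_seed(config$seed, "features")) {
  with_seed(seed, {
    flen <- config$feature_length
    genome <- config$genome
    sp_in <- .select_slots(elements, track, flen, config$sparse_density_in,
                           config$feature_score_coupling, config$score_center)
    dn_in <- .select_slots(elements, track, flen, config$dense_density,
                           0, config$score_center)
    # background features: uniform placement outside elements
    n_bg <- round(config$sparse_density_bg *
                    (sum(genome) - total_length(elements)) / flen)
    bg <- NULL
    if (n_bg > 0) {
      got <- 0L; acc <- list()
      while (got < n_bg) {
        m <- ceiling((n_bg - got) * 1.3)
        chr <- sample(names(genome), m, replace = TRUE, prob = genome)
        st <- vapply(chr, function(c2) sample.int(genome[[c2]] - flen + 1L, 1L),
                     integer(1), USE.NAMES = FALSE)
        cand <- GenomicRanges::GRanges(chr, IRanges::IRanges(st, st + flen - 1L))
        keep <- !IRanges::overlapsAny(cand, elements)
        cand <- cand[keep]
        take <- min(length(cand), n_bg - got)
        if (take > 0) acc[[length(acc) + 1L]] <- cand[seq_len(take)]
        got <- got + take
      }
      bg <- do.call(c, acc)
    }
    to_gr <- function(df) if (is.null(df) || nrow(df) == 0L) GenomicRanges::GRanges() else
      intervals(df$chrom, df$start, df$end)
    sparse <- merge_intervals(c(to_gr(sp_in), bg %||% GenomicRanges::GRanges()))
    dense <- merge_intervals(to_gr(dn_in))
    elen <- total_length(elements)
    cov_in <- function(f) sum(GenomicRanges::width(
      GenomicRanges::intersect(f, merge_intervals(elements)))) / elen
    list(sparse = sparse, dense = dense,
         sparse_coverage_in = cov_in(sparse), dense_coverage_in = cov_in(dense))
  })
}

#' Run all generators for one scenario
#'
#' @param config A [synthetic_config()].
#' @return List with `config`, `reference`, `genome`, `elements`,
#'   `scores` (track + relaxed ground truth), `cohorts` (per-population
#'   variant sets) and `features`.
#' @export
simulate_all <- function(config = synthetic_config()) {
  g <- simulate_genome(config)
  s <- simulate_scores(config, g$elements)
  cohorts <- simulate_cohorts(config, g$elements, s$track, g$reference)
  f <- simulate_features(config, g$elements, s$track)
  list(config = config, reference = g$reference, genome = g$genome,
       elements = g$elements, scores = s, cohorts = cohorts, features = f)
}

#' Write a simulated scenario to disk in standard formats
#'
#' FASTA reference, two-column genome file, element and feature BEDs,
#' bedGraph score track, one VCF per population (MAF in `INFO/AF`) and a
#' ground-truth TSV of true classes and placement scores.
#'
#' @param sim Output of [simulate_all()].
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_synthetic_data <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  Biostrings::writeXStringSet(sim$reference, p("reference.fa"))
  write_genome(sim$genome, p("genome.txt"))
  write_bed(sim$elements, p("elements.bed"))
  write_bed(sim$features$sparse, p("features_sparse.bed"))
  write_bed(sim$features$dense, p("features_dense.bed"))
  write_score_track(sim$scores$track, p("scores.bedGraph"))
  vcfs <- character(0)
  for (popn in names(sim$cohorts)) {
    f <- p(sprintf("variants_%s.vcf", gsub("[^A-Za-z0-9_.-]", "_", popn)))
    write_vcf_snvs(sim$cohorts[[popn]], f, sim$genome)
    vcfs[popn] <- f
  }
  gt <- do.call(rbind, lapply(names(sim$cohorts), function(popn) {
    g <- attr(sim$cohorts[[popn]], "ground_truth")
    g$population <- popn
    g
  }))
  write.table(gt, p("ground_truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(reference = p("reference.fa"), genome = p("genome.txt"),
                 elements = p("elements.bed"),
                 features_sparse = p("features_sparse.bed"),
                 features_dense = p("features_dense.bed"),
                 scores = p("scores.bedGraph"), vcfs = vcfs,
                 ground_truth = p("ground_truth.tsv")))
}
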