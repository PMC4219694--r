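#' Pipeline orchestration: run the full analysis from a configuration
#'
#' Three stages mirror the analysis structure: characterization (variant
#' rates and cross-dataset sharing), conservation (score distributions of
#' MAF classes against G/C-matched nulls, positional and flank-window
#' analyses) and enrichment (feature-overlap depletion tests and
#' resampled per-1000 overlap comparisons). Each stage reads standard
#' formats, writes TSV reports plus a JSON results bundle, and draws its
#' randomness from a named substream of one top-level seed.
#'
#' @name pipeline
NULL

#' Build and validate a run configuration
#'
#' @param elements_bed Path to the element (e.g. UCE) BED.
#' @param vcf Named character vector of VCF paths, one per population.
#' @param n_samples Named numeric vector of cohort sizes (same names).
#' @param score_track Path to a wiggle/bedGraph score track.
#' @param reference_fasta Path to the reference FASTA (needed for G/C
#'   matching).
#' @param features_bed Path to the sparse feature (TFBS-like) BED.
#' @param dense_features_bed Optional dense (SE-like) feature BED; the
#'   dense-vs-sparse comparison is skipped with a notice when absent.
#' @param genome_file Optional two-column genome file (chrom, length).
#' @param thresholds MAF class thresholds, see [maf_thresholds()].
#' @param af_field INFO key carrying allele frequencies in the VCFs.
#' @param B Bootstrap replicates for ECDF bands.
#' @param n_sets,set_size Resampling design for per-1000 overlap tests.
#' @param seed Top-level integer seed.
#' @param out_dir Output directory.
#' @param force Overwrite existing outputs.
#' @return A validated `run_config` list.
#' @export
run_config <- function(elements_bed, vcf, n_samples, score_track = NULL,
                       reference_fasta = NULL, features_bed = NULL,
                       dense_features_bed = NULL, genome_file = NULL,
                       thresholds = maf_thresholds(), af_field = "AF",
                       B = 1000L, n_sets = 100L, set_size = 1000L,
                       seed = 1L, out_dir = "ucevar-out", force = FALSE) {
  cfg <- as.list(environment())
  paths <- c(elements_bed, vcf, score_track, reference_fasta, features_bed,
             dense_features_bed, genome_file)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("input path(s) not found: ", paste(missing, collapse = ", "))
  if (is.null(names(vcf)) || any(names(vcf) == ""))
    stop("vcf must be a named vector (one VCF per population)")
  if (!all(names(vcf) %in% names(n_samples)))
    stop("n_samples must name every population in vcf")
  structure(cfg, class = "run_config")
}

#' Load a run configuration from YAML or JSON
#'
#' @param path Config file; top-level keys are [run_config()] arguments.
#' @param ... Overrides applied on top of the file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  lst <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to read YAML configs")
    yaml::read_yaml(path)
  }
  over <- list(...)
  lst[names(over)] <- over
  for (key in c("vcf", "n_samples")) {
    if (!is.null(lst[[key]])) lst[[key]] <- unlist(lst[[key]])
  }
  if (!is.null(lst$thresholds))
    lst$thresholds <- do.call(maf_thresholds, as.list(lst$thresholds))
  do.call(run_config, lst)
}

.out_path <- function(cfg, f) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(cfg$out_dir, f)
  if (file.exists(p) && !isTRUE(cfg$force))
    stop("output exists (use force = TRUE to overwrite): ", p)
  p
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# tiny FNV-1a over the JSON form of the config, for the manifest
.config_hash <- function(cfg) {
  js <- as.character(jsonlite::toJSON(cfg[!vapply(cfg, is.function, logical(1))],
                                      auto_unbox = TRUE, force = TRUE))
  h <- 2166136261
  for (b in utf8ToInt(js)) h <- bitwXor(as.integer(h %% 2^31), b) * 16777619 %% 2^31
  sprintf("%08x", as.integer(abs(h) %% 2^31))
}

write_manifest <- function(cfg, stage) {
  man <- list(stage = stage,
              config = cfg[!vapply(cfg, is.null, logical(1))],
              config_hash = .config_hash(cfg),
              seed = cfg$seed,
              package_version = as.character(utils::packageVersion("ucevar")),
              r_version = R.version.string,
              timestamp = format(Sys.time(), tz = "UTC"))
  p <- file.path(cfg$out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(man, p, auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(p)
}

.load_cohorts <- function(cfg, elements) {
  sets <- lapply(names(cfg$vcf), function(popn) {
    vs <- read_vcf_snvs(cfg$vcf[[popn]], regions = elements,
                        af_field = cfg$af_field, population = popn)
    message(sprintf(
      "[%s] %d SNVs retained in elements (%d non-SNV records dropped, %d without %s)",
      popn, nrow(vs), attr(vs, "n_skipped_not_snv"),
      attr(vs, "n_skipped_no_af"), cfg$af_field))
    vs
  })
  names(sets) <- names(cfg$vcf)
  for (popn in names(sets)) {
    sets[[popn]]$class <- classify_maf(sets[[popn]]$maf, cfg$thresholds)
  }
  sets
}

#' Stage 1: variant rates and cross-dataset sharing
#'
#' Writes `rates.tsv` (per population x MAF class: counts and variants
#' per Mb per sample) and `sharing_<subset>.tsv` membership tables for
#' all / rare / prevalent variants (when >= 2 populations are given).
#'
#' @param cfg A [run_config()].
#' @return List with `rates` and `sharing` (invisible); TSVs written to
#'   `cfg$out_dir`.
#' @export
run_characterization <- function(cfg) {
  elements <- merge_intervals(read_bed(cfg$elements_bed))
  span <- total_length(elements)
  sets <- .load_cohorts(cfg, elements)
  rows <- list()
  for (popn in names(sets)) {
    vs <- sets[[popn]]
    for (cl in c("all", levels(vs$class))) {
      n <- if (cl == "all") nrow(vs) else sum(vs$class == cl)
      rows[[length(rows) + 1L]] <- data.frame(
        population = popn, class = cl, n_snvs = n,
        target_mb = span / 1e6,
        rate_per_mb_per_sample = snv_rate(n, span, cfg$n_samples[[popn]]))
    }
  }
  rates <- do.call(rbind, rows)
  .write_tsv(rates, .out_path(cfg, "rates.tsv"))
  sharing <- NULL
  if (length(sets) >= 2L) {
    sharing <- list(all = sharing_table(sets),
                    rare = sharing_table(lapply(sets, function(v) v[v$class == "rare", ])),
                    prevalent = sharing_table(lapply(sets, function(v) v[v$class == "prevalent", ])))
    for (nm in names(sharing))
      .write_tsv(sharing[[nm]], .out_path(cfg, paste0("sharing_", nm, ".tsv")))
  }
  write_manifest(cfg, "characterization")
  invisible(list(rates = rates, sharing = sharing, n_elements = length(elements),
                 span_bp = span))
}

#' Stage 2: conservation-score analyses
#'
#' Per population: extracts scores at rare / intermediate / prevalent
#' variant positions, draws a G/C-matched random element-position sample
#' of equal size with a bootstrap ECDF band, and runs two-sided KS tests
#' of every class against the matched null and of prevalent against
#' rare. Also writes per-variant relative positions within host elements
#' and 3-bp flank-window KS results.
#'
#' @param cfg A [run_config()] with `score_track` and `reference_fasta`.
#' @return Invisible list of per-population results; TSVs written.
#' @export
run_conservation <- function(cfg) {
  if (is.null(cfg$score_track) || is.null(cfg$reference_fasta))
    stop("run_conservation needs score_track and reference_fasta")
  elements <- merge_intervals(read_bed(cfg$elements_bed))
  genome <- if (!is.null(cfg$genome_file)) read_genome(cfg$genome_file) else NULL
  uni_ext <- if (is.null(genome)) elements else score_universe(elements, genome)
  track <- read_score_track(cfg$score_track, universe = uni_ext)
  reference <- Biostrings::readDNAStringSet(cfg$reference_fasta)
  names(reference) <- sub("\\s.*$", "", names(reference))
  universe <- universe_positions(elements, reference)
  uni_scores <- extract_scores(universe, track)$scores
  sets <- .load_cohorts(cfg, elements)
  ks_rows <- list(); flank_rows <- list(); relpos_rows <- list()
  results <- list()
  for (popn in names(sets)) {
    vs <- sets[[popn]]
    vs$relative_position <- relative_positions(vs, elements)
    relpos_rows[[popn]] <- vs[, c("population", "chrom", "pos", "class",
                                  "relative_position")]
    per_class <- list()
    for (cl in levels(vs$class)) {
      vc <- vs[vs$class == cl, , drop = FALSE]
      if (nrow(vc) == 0L) next
      sc <- extract_scores(vc, track)
      obs <- sc$scores[!sc$missing]
      comp <- base_composition(universe_base_at(universe, vc))
      null <- gc_matched_sample(universe, comp, nrow(vc),
                                seed = derive_seed(cfg$seed, paste0("null_", popn, "_", cl)))
      null_scores <- extract_scores(null, track)$scores
      band <- ecdf_band(null_scores, B = cfg$B,
                        seed = derive_seed(cfg$seed, paste0("band_", popn, "_", cl)))
      ks_null <- ks_compare(obs, null_scores)
      fl <- flank_scores(vc, track, window = 3L)
      ks_rows[[paste(popn, cl)]] <- data.frame(
        population = popn, class = cl, n = length(obs),
        mean_score = mean(obs), null_mean_score = mean(null_scores),
        ks_D_vs_null = ks_null$D, ks_p_vs_null = ks_null$p)
      flank_rows[[paste(popn, cl)]] <- data.frame(
        population = popn, class = cl,
        n_upstream = length(fl$upstream), n_downstream = length(fl$downstream),
        mean_upstream = mean(fl$upstream), mean_downstream = mean(fl$downstream),
        ks_p_up_vs_site = ks_compare(fl$upstream, obs)$p,
        ks_p_down_vs_site = ks_compare(fl$downstream, obs)$p)
      per_class[[cl]] <- list(scores = obs, null_scores = null_scores,
                              band = band, flanks = fl)
    }
    ks_pr <- if (all(c("rare", "prevalent") %in% names(per_class))) {
      ks_compare(per_class$prevalent$scores, per_class$rare$scores)
    } else NULL
    results[[popn]] <- list(classes = per_class, ks_prevalent_vs_rare = ks_pr)
    if (!is.null(ks_pr)) {
      ks_rows[[paste(popn, "prevalent_vs_rare")]] <- data.frame(
        population = popn, class = "prevalent_vs_rare",
        n = ks_pr$n_a + ks_pr$n_b,
        mean_score = mean(per_class$prevalent$scores),
        null_mean_score = mean(per_class$rare$scores),
        ks_D_vs_null = ks_pr$D, ks_p_vs_null = ks_pr$p)
    }
  }
  .write_tsv(do.call(rbind, ks_rows), .out_path(cfg, "conservation_ks.tsv"))
  .write_tsv(do.call(rbind, flank_rows), .out_path(cfg, "flank_windows.tsv"))
  .write_tsv(do.call(rbind, relpos_rows), .out_path(cfg, "relative_positions.tsv"))
  write_manifest(cfg, "conservation")
  invisible(results)
}

#' Stage 3: feature-overlap enrichment and depletion
#'
#' Per population: a per-class chi-squared depletion report against
#' G/C-matched element positions (random = 1), plus resampled per-1000
#' overlap distributions of element positions against the sparse track
#' and -- when a dense track is configured -- the dense track, compared
#' by a two-tailed Mann-Whitney test.
#'
#' @param cfg A [run_config()] with `features_bed` (and optionally
#'   `dense_features_bed`).
#' @return Invisible list with `depletion` (data frame) and `resample`;
#'   TSVs written.
#' @export
run_enrichment <- function(cfg) {
  if (is.null(cfg$features_bed)) stop("run_enrichment needs features_bed")
  if (is.null(cfg$reference_fasta)) stop("run_enrichment needs reference_fasta")
  elements <- merge_intervals(read_bed(cfg$elements_bed))
  features <- merge_intervals(read_bed(cfg$features_bed))
  reference <- Biostrings::readDNAStringSet(cfg$reference_fasta)
  names(reference) <- sub("\\s.*$", "", names(reference))
  universe <- universe_positions(elements, reference)
  sets <- .load_cohorts(cfg, elements)
  dep <- do.call(rbind, lapply(names(sets), function(popn) {
    rep <- class_depletion_report(sets[[popn]], universe, features,
                                  seed = derive_seed(cfg$seed, paste0("dep_", popn)))
    rep$population <- popn
    rep
  }))
  .write_tsv(dep, .out_path(cfg, "depletion.tsv"))
  rs_sparse <- resample_overlap(universe, features, n_sets = cfg$n_sets,
                                set_size = cfg$set_size,
                                seed = derive_seed(cfg$seed, "resample_sparse"))
  resample <- list(sparse = rs_sparse)
  rs_rows <- data.frame(track = "sparse", mean = rs_sparse$mean,
                        ci_lo = rs_sparse$ci[1], ci_hi = rs_sparse$ci[2],
                        n_sets = rs_sparse$n_sets, set_size = rs_sparse$set_size,
                        mw_p_vs_sparse = NA_real_)
  if (!is.null(cfg$dense_features_bed)) {
    dense <- merge_intervals(read_bed(cfg$dense_features_bed))
    rs_dense <- resample_overlap(universe, dense, n_sets = cfg$n_sets,
                                 set_size = cfg$set_size,
                                 seed = derive_seed(cfg$seed, "resample_dense"))
    cmp <- compare_resamples(rs_dense, rs_sparse)
    resample$dense <- rs_dense
    resample$dense_vs_sparse <- cmp
    rs_rows <- rbind(rs_rows, data.frame(
      track = "dense", mean = rs_dense$mean, ci_lo = rs_dense$ci[1],
      ci_hi = rs_dense$ci[2], n_sets = rs_dense$n_sets,
      set_size = rs_dense$set_size, mw_p_vs_sparse = cmp$p))
  } else {
    message("no dense feature track configured; dense-vs-sparse comparison skipped")
  }
  .write_tsv(rs_rows, .out_path(cfg, "resample_overlap.tsv"))
  write_manifest(cfg, "enrichment")
  invisible(list(depletion = dep, resample = resample))
}

#' Run all three stages
#'
#' @param cfg A [run_config()].
#' @return Invisible list of per-stage results.
#' @export
run_all <- function(cfg) {
  res <- list(characterization = run_characterization(cfg))
  if (!is.null(cfg$score_track)) res$conservation <- run_conservation(cfg)
  if (!is.null(cfg$features_bed)) res$enrichment <- run_enrichment(cfg)
  invisible(res)
}
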