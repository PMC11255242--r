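#' Write peaks as BED6+ and read them back
#'
#' BED6 columns (0-based half-open) plus `summit` (1-based), `cpm` and
#' `p_value`; the BED score is `round(1000 * min(1, intensity/max))`.
#'
#' @param peaks `GRanges` from [call_peaks()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_peaks_bed <- function(peaks, path) {
  mx <- if (length(peaks)) max(S4Vectors::mcols(peaks)$intensity, 1e-12) else 1
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(peaks)),
    start = GenomicRanges::start(peaks) - 1L,
    end = GenomicRanges::end(peaks),
    name = S4Vectors::mcols(peaks)$name %||%
      sprintf("peak_%05d", seq_along(peaks)),
    score = round(1000 * pmin(1, S4Vectors::mcols(peaks)$intensity / mx)),
    strand = as.character(GenomicRanges::strand(peaks)),
    summit = S4Vectors::mcols(peaks)$summit,
    cpm = S4Vectors::mcols(peaks)$intensity,
    p_value = S4Vectors::mcols(peaks)$p_value)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_peaks_bed
#' @param path Input BED6+ file.
#' @export
read_peaks_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
    col.names = c("chrom", "start", "end", "name", "score", "strand",
                  "summit", "cpm", "p_value"))
  GenomicRanges::GRanges(df$chrom,
    IRanges::IRanges(df$start + 1L, df$end), strand = df$strand,
    summit = as.integer(df$summit), intensity = df$cpm,
    p_value = df$p_value, name = df$name)
}

#' Pipeline configuration
#'
#' One global seed derives every stage seed (see [stage_seed()]), so each
#' stage is independently reproducible. The peak/coverage arm (emulating
#' strand-specific R-loop mapping) runs on profile A only; the count/DE
#' arm runs on both profiles, mirroring a design with R-loop mapping in
#' one species and expression profiling in both.
#'
#' @param seed Global integer seed.
#' @param out_dir Output directory (NULL = do not write files).
#' @param profile_a,profile_b The two [species_profile()]s.
#' @param sim A [simulation_config()] (its seed is overridden per stage).
#' @param law A [motif_law()].
#' @param peaks [peak_params()] for the caller.
#' @param lfc_thresh,q_thresh DE class thresholds.
#' @param min_trun Minimum T-run length for the association rule.
#' @param scan_window,scan_step Genome-scan geometry in bp; the default
#'   window is matched to the typical called peak width so that scan
#'   windows and classifier training regions have comparable composition.
#' @param scan_min_trun Minimum tail T-run length for a scan window to be
#'   scored; set to the planted grammar's minimum T-run length, stricter
#'   than the association rule.
#' @param flank Metaprofile half-window in bp.
#' @return A list of class `PipelineConfig`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = NULL,
                            profile_a = species_profile("human_like"),
                            profile_b = species_profile("mouse_like"),
                            sim = simulation_config(),
                            law = motif_law(),
                            peaks = peak_params(),
                            lfc_thresh = 1, q_thresh = 0.05,
                            min_trun = 5L,
                            scan_window = 150L, scan_step = 50L,
                            scan_min_trun = 8L,
                            flank = 500L) {
  structure(as.list(environment()), class = "PipelineConfig")
}

#' Validate a pipeline configuration
#'
#' Schema, range and cross-field checks. Violations are returned, not
#' thrown.
#'
#' @param config A [pipeline_config()].
#' @return Character vector of violations; empty when the config is valid.
#' @export
validate_config <- function(config) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  if (!inherits(config, "PipelineConfig")) add("not a PipelineConfig")
  if (!inherits(config$profile_a, "SpeciesProfile") ||
      !inherits(config$profile_b, "SpeciesProfile"))
    add("profiles must be SpeciesProfile objects")
  s <- config$sim
  if (!inherits(s, "SimulationConfig")) add("sim must be a SimulationConfig")
  else {
    if (s$depth <= 0) add("depth must be > 0")
    if (s$nb_dispersion <= 0) add("nb_dispersion must be > 0")
    if (s$kd_effect < 0) add("kd_effect must be >= 0")
    if (s$n_replicates < 2) add("n_replicates < 2: DE testing needs >= 2 per condition")
  }
  p <- config$peaks
  if (!inherits(p, "PeakParams")) add("peaks must be PeakParams")
  if (config$scan_window < config$peaks$min_width)
    add("scan_window must be >= peak min_width")
  if (config$scan_step < 1 || config$scan_step > config$scan_window)
    add("scan_step must lie in [1, scan_window]")
  if (config$q_thresh <= 0 || config$q_thresh > 1)
    add("q_thresh must lie in (0, 1]")
  v
}

simulate_species <- function(profile, config, tag) {
  sim <- config$sim
  sim$seed <- stage_seed(config$seed, paste0("species_", tag))
  bundle <- simulate_genome(profile, seed = stage_seed(sim$seed, "genome"))
  planted <- plant_motifs(bundle, sim, config$law)
  counts <- cbind(simulate_counts(planted$truth, sim, "control"),
                  simulate_counts(planted$truth, sim, "kd"))
  list(bundle = planted$bundle, truth = planted$truth, counts = counts,
       sim = sim)
}

de_arm <- function(sp, config, motif_counts = NULL) {
  condition <- rep(c("control", "kd"), each = config$sim$n_replicates)
  de <- de_test(sp$counts, condition)
  classes <- classify_genes(de, config$lfc_thresh, config$q_thresh)
  g <- sp$truth$genes
  lens <- stats::setNames(g$length, g$gene_id)[names(classes)]
  mg <- motif_counts %||% stats::setNames(g$m_g, g$gene_id)
  report <- association_report(classes, lens, mg[names(classes)])
  list(de = de, classes = classes, report = report)
}

#' Run the full synthetic analysis pipeline
#'
#' Executes, for one global seed: genome simulation and motif planting for
#' two species profiles; stranded coverage simulation, peak calling,
#' condition comparison, context annotation, width statistics and summit
#' metaprofile for profile A; sequence features, T-run association, G% by
#' T-run-length bins and head/tail k-mer enrichment on profile A's peaks;
#' classifier training (T-run-associated peaks vs length-matched random
#' T-run-containing gene regions), genome scanning and per-gene hit
#' counting; differential
#' expression, gene classification and length/motif-burden association for
#' both species; and the cross-species contrast. Any stage failure aborts
#' with the stage name.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `RunReport` with per-stage summary tables; when
#'   `config$out_dir` is set, report tables, peak BED files, the model
#'   file and a JSON summary are also written there.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  viol <- validate_config(config)
  abort_if(length(viol) > 0, "invalid config: %s", paste(viol, collapse = "; "))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  rep <- list(seed = config$seed)

  A <- stage("simulate_A", simulate_species(config$profile_a, config, "A"))
  B <- stage("simulate_B", simulate_species(config$profile_b, config, "B"))

  cov_ctrl <- stage("coverage_control",
                    simulate_coverage(A$bundle, A$truth, "control", A$sim))
  cov_kd <- stage("coverage_kd",
                  simulate_coverage(A$bundle, A$truth, "kd", A$sim))
  pk_ctrl <- stage("peaks_control", call_peaks(cov_ctrl, config$peaks))
  pk_kd <- stage("peaks_kd", call_peaks(cov_kd, config$peaks))
  cmp <- stage("compare", compare_peak_sets(pk_ctrl, pk_kd))
  ctx_kd <- stage("context", annotate_context(pk_kd, A$bundle))
  common_idx <- cmp$common$b
  gained_idx <- cmp$gained
  frac_gb <- function(idx) {
    if (!length(idx)) return(NA_real_)
    mean(ctx_kd$labels[idx] == "GB")
  }
  rep$peaks <- data.frame(
    set = c("control", "kd", "common", "gained", "lost"),
    n = c(length(pk_ctrl), length(pk_kd), nrow(cmp$common),
          length(cmp$gained), length(cmp$lost)))
  rep$widths <- stage("widths", {
    st <- peak_length_stats(pk_ctrl, pk_kd)
    data.frame(median_control = st$median_a, median_kd = st$median_b,
               U = st$U, p = st$p_value)
  })
  rep$context <- data.frame(label = names(ctx_kd$fractions),
                            fraction_kd = as.numeric(ctx_kd$fractions))
  rep$gb_fractions <- data.frame(set = c("common", "gained"),
                                 gb_fraction = c(frac_gb(common_idx),
                                                 frac_gb(gained_idx)))
  rep$metaprofile <- stage("metaprofile", {
    anch <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(pk_kd),
      IRanges::IRanges(S4Vectors::mcols(pk_kd)$summit, width = 1L),
      strand = GenomicRanges::strand(pk_kd))
    mp <- metaprofile(cov_kd, anch, flank = config$flank)
    data.frame(offset = mp$offsets, mean_signal = mp$profile)
  })

  feats <- stage("features",
                 region_features(pk_kd, A$bundle, min_len = config$min_trun))
  assoc <- feats$t_run_associated
  rep$trun <- data.frame(
    n_peaks_kd = length(pk_kd), n_trun_associated = sum(assoc),
    gb_share_assoc_common = mean(ctx_kd$labels[intersect(common_idx,
      which(assoc))] == "GB"),
    gb_share_assoc_gained = mean(ctx_kd$labels[intersect(gained_idx,
      which(assoc))] == "GB"))
  rep$gpct_bins <- stage("gpct_bins", {
    # mirror the published analysis: genebody T-run-associated peaks only,
    # so incidental promoter T-runs do not dilute the trend
    sel <- assoc & ctx_kd$labels == "GB"
    gb <- gpct_by_trun_bins(feats[sel, , drop = FALSE])
    cbind(gb$bins, spearman_rho = gb$spearman_rho)
  })
  rep$kmers <- stage("kmers", {
    ap <- pk_kd[assoc]
    seqs <- extract_sense_sequence(ap, A$bundle)
    off <- summit_offset_sense(ap)
    ok <- off >= 6 & nchar(seqs) - off >= 6
    heads <- substring(seqs[ok], 1L, off[ok])
    tails <- substring(seqs[ok], off[ok] + 1L, nchar(seqs[ok]))
    bg <- extract_sense_sequence(
      sample_random_regions(A$bundle, length(heads) * 2L,
        nchar(seqs[ok]), seed = stage_seed(config$seed, "kmer_bg")),
      A$bundle)
    data.frame(half = c("head", "tail"),
               top_kmer = c(kmer_enrichment(heads, bg)$kmer[1L],
                            kmer_enrichment(tails, bg)$kmer[1L]))
  })

  model <- stage("classifier", {
    pos <- feats[assoc, , drop = FALSE]
    neg_gr <- sample_trun_regions(A$bundle, sum(assoc),
      IRanges::width(pk_kd)[assoc], min_trun = config$min_trun,
      seed = stage_seed(config$seed, "negatives"))
    neg <- region_features(neg_gr, A$bundle, min_len = config$min_trun)
    train_classifier(pos, neg, seed = stage_seed(config$seed, "cv"))
  })
  rep$classifier <- data.frame(cv_accuracy = model$cv_accuracy,
                               cv_auc = model$cv_auc)
  hits <- stage("scan", scan_genome(model, A$bundle,
                                    window = config$scan_window,
                                    step = config$scan_step,
                                    min_trun = config$scan_min_trun))
  hit_counts <- count_hits_per_gene(hits, A$bundle)
  rep$scan <- data.frame(n_hits = length(hits),
    spearman_vs_truth = suppressWarnings(stats::cor(
      hit_counts[A$truth$genes$gene_id], A$truth$genes$m_g,
      method = "spearman")))

  deA <- stage("de_A", de_arm(A, config, motif_counts = hit_counts))
  deB <- stage("de_B", de_arm(B, config))
  rep$de <- data.frame(
    species = c("A", "B"),
    n_down = c(sum(deA$classes == "down"), sum(deB$classes == "down")),
    n_up = c(sum(deA$classes == "up"), sum(deB$classes == "up")),
    n_nochange = c(sum(deA$classes == "nochange"),
                   sum(deB$classes == "nochange")))
  rep$association <- rbind(cbind(species = "A", deA$report$tests),
                           cbind(species = "B", deB$report$tests))
  n_orth <- min(length(deA$classes), length(deB$classes))
  contrast <- stage("species_contrast", cross_species_compare(
    deA$report, deB$report,
    data.frame(a = names(deA$classes)[seq_len(n_orth)],
               b = names(deB$classes)[seq_len(n_orth)])))
  rep$species <- data.frame(
    affected_ratio = contrast$affected_ratio,
    median_length_a = contrast$median_length[["A"]],
    median_length_b = contrast$median_length[["B"]],
    p_len_a = contrast$length_tests$p_len[1L],
    p_len_b = contrast$length_tests$p_len[2L])

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_peaks_bed(pk_ctrl, file.path(config$out_dir, "peaks_control.bed"))
    write_peaks_bed(pk_kd, file.path(config$out_dir, "peaks_kd.bed"))
    write_classifier(model, file.path(config$out_dir, "model.txt"))
    utils::write.table(cbind(gene_id = names(hit_counts),
                             hits = hit_counts),
                       file.path(config$out_dir, "scan_hits_per_gene.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (nm in setdiff(names(rep), "seed"))
      utils::write.table(rep[[nm]],
                         file.path(config$out_dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(rep, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  structure(rep, class = "RunReport")
}

#' @export
print.RunReport <- function(x, ...) {
  cat("RunReport (seed", x$seed, ")\n")
  cat(" peaks:\n"); print(x$peaks, row.names = FALSE)
  cat(" GB fractions:\n"); print(x$gb_fractions, row.names = FALSE)
  cat(" classifier:\n"); print(x$classifier, row.names = FALSE)
  cat(" DE classes:\n"); print(x$de, row.names = FALSE)
  cat(" species contrast:\n"); print(x$species, row.names = FALSE)
  invisible(x)
}
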