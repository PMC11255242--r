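#' Species profile for the synthetic genome generator
#'
#' Describes the gene architecture of a simulated species: how many genes to
#' place on the chromosome, and the log-normal laws for intron and exon
#' lengths. Two presets are provided. The `human_like` profile has long,
#' highly dispersed introns (meanlog 8.0, sdlog 1.0; median ~3 kb), giving a
#' heavy upper tail of very long genes. The `mouse_like` profile has both
#' shorter and less dispersed introns (meanlog 7.0, sdlog 0.7), so its
#' analogues of the longest human-like genes are considerably shorter --
#' the architecture contrast that drives the two-species comparison.
#'
#' @param name `"human_like"` or `"mouse_like"`, or any label when all laws
#'   are supplied explicitly.
#' @param n_genes Number of genes to place.
#' @param chrom_length Chromosome length in bp; `NULL` (default) sizes the
#'   chromosome automatically to fit `n_genes` with headroom.
#' @param intron_meanlog,intron_sdlog Log-normal law for intron lengths (bp).
#' @param exon_meanlog,exon_sdlog Log-normal law for exon lengths (bp).
#' @param exons_per_gene Integer vector of admissible exon counts per gene,
#'   sampled uniformly.
#' @param base_freqs Named background base frequencies over A, C, G, T;
#'   must sum to 1.
#' @return An object of class `SpeciesProfile`.
#' @examples
#' species_profile("human_like", n_genes = 50)
#' @export
species_profile <- function(name = c("human_like", "mouse_like"),
                            n_genes = 800,
                            chrom_length = NULL,
                            intron_meanlog = NULL, intron_sdlog = NULL,
                            exon_meanlog = 5.0, exon_sdlog = 0.4,
                            exons_per_gene = 4:8,
                            base_freqs = c(A = 0.295, C = 0.205,
                                           G = 0.205, T = 0.295)) {
  name <- if (length(name) > 1L) match.arg(name) else name
  preset <- switch(name,
    human_like = list(imu = 8.0, isd = 1.0),
    mouse_like = list(imu = 7.0, isd = 0.7),
    list(imu = 7.5, isd = 0.8))
  intron_meanlog <- intron_meanlog %||% preset$imu
  intron_sdlog <- intron_sdlog %||% preset$isd
  abort_if(abs(sum(base_freqs) - 1) > 1e-9, "base_freqs must sum to 1")
  abort_if(!all(c("A", "C", "G", "T") %in% names(base_freqs)),
           "base_freqs must be named A, C, G, T")
  abort_if(n_genes < 1 || intron_sdlog <= 0 || exon_sdlog <= 0,
           "invalid profile parameters")
  mean_introns <- mean(exons_per_gene) - 1
  e_gene <- mean_introns * exp(intron_meanlog + intron_sdlog^2 / 2) +
    mean(exons_per_gene) * exp(exon_meanlog + exon_sdlog^2 / 2)
  if (is.null(chrom_length))
    chrom_length <- ceiling(1.3 * n_genes * (e_gene + 2000))
  structure(list(name = name, n_genes = as.integer(n_genes),
                 chrom_length = as.double(chrom_length),
                 intron_meanlog = intron_meanlog, intron_sdlog = intron_sdlog,
                 exon_meanlog = exon_meanlog, exon_sdlog = exon_sdlog,
                 exons_per_gene = as.integer(exons_per_gene),
                 base_freqs = base_freqs[c("A", "C", "G", "T")]),
            class = "SpeciesProfile")
}

#' Simulation configuration
#'
#' Collects the stochastic-model parameters shared by the coverage and count
#' simulators. Defaults state the generator's world: background read depth 2
#' per strand, an exponential coverage kernel with 30 bp scale (chosen so
#' called peaks are of order 100-170 bp and summits localize to ~10 bp),
#' 2 replicates per condition, negative-binomial dispersion 0.1, and a
#' knockdown effect of -0.5 log2 units per planted motif capped at 4 motifs.
#'
#' @param seed Global integer seed; all stage seeds derive from it.
#' @param depth Mean background coverage per strand (reads per bp).
#' @param peak_kernel_scale Exponential decay scale (bp) of the coverage
#'   kernel placed at each planted anchor.
#' @param n_replicates Replicates per condition for the count simulator.
#' @param nb_dispersion Negative-binomial dispersion phi (variance
#'   mu + phi mu^2).
#' @param kd_effect Per-motif knockdown log2 fold-change magnitude beta;
#'   a gene with m planted motifs has true log2FC `-beta * min(m, cap_m)`.
#' @param cap_m Motif-count cap for the expression effect.
#' @param frac_compensatory_up Compensatory upregulation rate: the number
#'   of upregulated genes is this fraction of the number of motif-bearing
#'   genes, drawn among motif-free genes (so the up class is motif-poor
#'   and scales with the perturbation's impact).
#' @param up_effect log2 fold-change of compensatory upregulated genes.
#' @param mu0_meanlog,mu0_sdlog Log-normal law of baseline expression means.
#' @param read_length Read-length equivalent used to convert coverage sums
#'   into library sizes for CPM.
#' @return An object of class `SimulationConfig`.
#' @export
simulation_config <- function(seed = 1L, depth = 2, peak_kernel_scale = 30,
                              n_replicates = 2L, nb_dispersion = 0.1,
                              kd_effect = 0.5, cap_m = 4L,
                              frac_compensatory_up = 0.1, up_effect = 1.5,
                              mu0_meanlog = 5, mu0_sdlog = 1,
                              read_length = 100) {
  abort_if(nb_dispersion <= 0, "nb_dispersion must be > 0")
  abort_if(kd_effect < 0, "kd_effect must be >= 0")
  abort_if(depth <= 0, "depth must be > 0")
  abort_if(n_replicates < 1, "n_replicates must be >= 1")
  structure(list(seed = as.integer(seed), depth = depth,
                 peak_kernel_scale = peak_kernel_scale,
                 n_replicates = as.integer(n_replicates),
                 nb_dispersion = nb_dispersion, kd_effect = kd_effect,
                 cap_m = as.integer(cap_m),
                 frac_compensatory_up = frac_compensatory_up,
                 up_effect = up_effect, mu0_meanlog = mu0_meanlog,
                 mu0_sdlog = mu0_sdlog, read_length = read_length),
            class = "SimulationConfig")
}

#' Motif law for planted G-cluster/T-run motifs
#'
#' Parameters of the planted sequence grammar: an upstream G cluster, a
#' short spacer drawn from the background composition, and a downstream
#' T-run, placed in introns with probability proportional to intron length.
#' G-cluster length is coupled negatively to T-run length
#' (`g = round(g_intercept - g_slope * L)` plus +/-2 jitter, clamped to
#' `g_range`), stating the generator's world that longer T-runs reduce the
#' reliance on G richness. Motifs come in a strong class (called in both
#' conditions) and a weak class (below the caller's detection threshold in
#' control, lifted above it by `kd_gain_weak` under knockdown); promoter
#' peaks lacking the motif are planted at a fraction of TSSs in both
#' conditions so that the common peak set has a TSS component.
#'
#' @param density Expected planted motifs per intron bp.
#' @param t_len_range,gap_range Inclusive integer ranges for T-run and
#'   spacer lengths.
#' @param g_intercept,g_slope,g_range G-cluster/T-run coupling parameters.
#' @param frac_weak Fraction of motifs in the weak-amplitude class.
#' @param amp_strong,amp_weak Base coverage amplitudes of the two classes.
#' @param kd_gain_strong,kd_gain_weak Multiplicative knockdown gain per class.
#' @param tss_prob Probability that a gene receives a promoter peak.
#' @param tss_amplitude,kd_gain_tss Amplitude and gain of promoter peaks.
#' @param margin Minimum distance (bp) between a planted motif and the
#'   intron boundaries.
#' @return A list of class `MotifLaw`.
#' @export
motif_law <- function(density = 1.5e-5,
                      t_len_range = c(8L, 19L), gap_range = c(5L, 15L),
                      g_intercept = 31, g_slope = 0.9, g_range = c(10L, 30L),
                      frac_weak = 0.6, amp_strong = 50, amp_weak = 5,
                      kd_gain_strong = 1.5, kd_gain_weak = 6,
                      tss_prob = 0.6, tss_amplitude = 50, kd_gain_tss = 1,
                      margin = 100L) {
  structure(as.list(environment()), class = "MotifLaw")
}

#' Simulate a genome with gene models
#'
#' Draws a random background chromosome from the profile's base composition
#' and places `n_genes` non-overlapping multi-exon genes on it, alternating
#' strands at random. Exon and intron lengths follow the profile's
#' log-normal laws (floored at 30 and 60 bp respectively); genes are
#' separated by exponential intergenic gaps.
#'
#' @param profile A [species_profile()].
#' @param seed Integer seed; output is deterministic given
#'   `(profile, seed)`.
#' @return A `GenomeBundle`: list with `seq` (named
#'   [Biostrings::DNAStringSet-class]), `genes` and `exons`
#'   ([GenomicRanges::GRanges-class] with `gene_id`), and the profile.
#' @examples
#' b <- simulate_genome(species_profile("human_like", n_genes = 5), seed = 7)
#' length(b$genes)
#' @export
simulate_genome <- function(profile, seed = 1L) {
  stopifnot(inherits(profile, "SpeciesProfile"))
  local_seed(seed, {
    n <- profile$n_genes
    nex <- sample(profile$exons_per_gene, n, replace = TRUE)
    strand <- ifelse(stats::runif(n) < 0.5, "+", "-")
    gaps <- 500 + round(stats::rexp(n, 1 / 1500))
    gene_rows <- vector("list", n)
    exon_rows <- vector("list", n)
    pos <- 1
    for (i in seq_len(n)) {
      pos <- pos + gaps[i]
      el <- pmax(30, round(stats::rlnorm(nex[i], profile$exon_meanlog,
                                         profile$exon_sdlog)))
      il <- if (nex[i] > 1)
        pmax(60, round(stats::rlnorm(nex[i] - 1, profile$intron_meanlog,
                                     profile$intron_sdlog))) else integer(0)
      starts <- pos + cumsum(c(0, el[-nex[i]] + il))
      ends <- starts + el - 1
      gend <- ends[nex[i]]
      abort_if(gend > profile$chrom_length - 1000,
               "chrom_length %d too small to place %d genes (stopped at gene %d)",
               as.integer(profile$chrom_length), n, i)
      gid <- sprintf("g%05d", i)
      gene_rows[[i]] <- data.frame(start = pos, end = gend,
                                   strand = strand[i], gene_id = gid)
      exon_rows[[i]] <- data.frame(start = starts, end = ends,
                                   strand = strand[i], gene_id = gid)
      pos <- gend + 1
    }
    gdf <- do.call(rbind, gene_rows)
    edf <- do.call(rbind, exon_rows)
    seq <- Biostrings::DNAStringSet(random_dna(profile$chrom_length,
                                               profile$base_freqs))
    names(seq) <- "chr1"
    genes <- GenomicRanges::GRanges("chr1",
      IRanges::IRanges(gdf$start, gdf$end), strand = gdf$strand,
      gene_id = gdf$gene_id)
    exons <- GenomicRanges::GRanges("chr1",
      IRanges::IRanges(edf$start, edf$end), strand = edf$strand,
      gene_id = edf$gene_id)
    GenomeInfoDb::seqlengths(genes) <- profile$chrom_length
    GenomeInfoDb::seqlengths(exons) <- profile$chrom_length
    structure(list(seq = seq, genes = genes, exons = exons,
                   profile = profile), class = "GenomeBundle")
  })
}

#' @export
print.GenomeBundle <- function(x, ...) {
  cat(sprintf("GenomeBundle: %s, %d chrom (%s bp), %d genes, %d exons\n",
              x$profile$name, length(x$seq),
              format(sum(Biostrings::width(x$seq)), big.mark = ","),
              length(x$genes), length(x$exons)))
  invisible(x)
}

# introns derived from exon gaps, carrying gene_id
intron_granges <- function(bundle) {
  ex <- bundle$exons
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(ex)),
                   start = GenomicRanges::start(ex),
                   end = GenomicRanges::end(ex),
                   strand = as.character(GenomicRanges::strand(ex)),
                   gene_id = S4Vectors::mcols(ex)$gene_id)
  df <- df[order(df$gene_id, df$start), ]
  same <- c(df$gene_id[-1] == df$gene_id[-nrow(df)], FALSE)
  i <- which(same)            # exon i and i+1 belong to the same gene
  keep <- i[df$end[i] + 1L <= df$start[i + 1L] - 1L]
  if (!length(keep))
    return(GenomicRanges::GRanges(seqlengths = GenomeInfoDb::seqlengths(ex)))
  GenomicRanges::GRanges(df$chrom[keep],
                         IRanges::IRanges(df$end[keep] + 1L,
                                          df$start[keep + 1L] - 1L),
                         strand = df$strand[keep],
                         gene_id = df$gene_id[keep],
                         seqlengths = GenomeInfoDb::seqlengths(ex))
}

#' Plant G-cluster/T-run motifs and build the ground truth
#'
#' Overwrites intronic loci of the genome with the literal sense-strand
#' grammar `G^g . spacer . T^L` (reverse-complemented on the plus strand for
#' minus-strand genes), assigns coverage amplitudes and knockdown gains per
#' motif class, optionally plants promoter peaks at TSSs, and records the
#' per-motif and per-gene ground truth, including each gene's baseline
#' expression mean and true knockdown log2 fold-change
#' `-kd_effect * min(m_g, cap_m)` (or `+up_effect` for the compensatory
#' upregulated subset of motif-free genes).
#'
#' The planted anchor (`center`) of each motif is the boundary between the
#' G cluster and the spacer, the position where coverage peaks are centred.
#' Introns too short for a motif plus margins are skipped with a warning.
#'
#' @param bundle A `GenomeBundle` from [simulate_genome()].
#' @param config A [simulation_config()].
#' @param law A [motif_law()].
#' @return List with the modified `bundle` and a `TruthTable` (list of
#'   data frames `motifs` and `genes`).
#' @export
plant_motifs <- function(bundle, config, law = motif_law()) {
  stopifnot(inherits(bundle, "GenomeBundle"),
            inherits(config, "SimulationConfig"))
  local_seed(stage_seed(config$seed, "plant_motifs"), {
    introns <- intron_granges(bundle)
    tot_bp <- sum(IRanges::width(introns))
    n_mot <- stats::rpois(1, law$density * tot_bp)
    motifs <- list()
    occupied <- rep(list(integer(0)), length(introns))
    n_skip <- 0L
    if (n_mot > 0 && length(introns) > 0) {
      pick <- sample.int(length(introns), n_mot, replace = TRUE,
                         prob = IRanges::width(introns))
      for (j in seq_len(n_mot)) {
        i <- pick[j]
        t_len <- sample_range(law$t_len_range[1], law$t_len_range[2])
        gap_len <- sample_range(law$gap_range[1], law$gap_range[2])
        g_len <- max(law$g_range[1], min(law$g_range[2],
                 round(law$g_intercept - law$g_slope * t_len) +
                   sample_range(-2L, 2L)))
        m_len <- g_len + gap_len + t_len
        iw <- IRanges::width(introns)[i]
        if (iw < m_len + 2 * law$margin) {
          warning(sprintf("intron of %s too short (%d bp) for a %d bp motif; skipped",
                          S4Vectors::mcols(introns)$gene_id[i], iw, m_len))
          n_skip <- n_skip + 1L
          next
        }
        off <- sample.int(iw - m_len - 2 * law$margin + 1L, 1) + law$margin - 1L
        s <- IRanges::start(introns)[i] + off       # 1-based genomic start
        e <- s + m_len - 1L
        if (any(occupied[[i]] %in% (s - 1L):(e + 1L))) next  # collision: drop
        occupied[[i]] <- c(occupied[[i]], (s - 1L):(e + 1L))
        st <- as.character(GenomicRanges::strand(introns))[i]
        spacer <- random_dna(gap_len, bundle$profile$base_freqs)
        # the spacer must not end in T and the base after the run must not
        # be T, so the planted T-run is maximal at exactly t_len
        nf <- bundle$profile$base_freqs[c("A", "C", "G")]
        non_t <- function() sample(names(nf), 1L, prob = nf)
        substr(spacer, gap_len, gap_len) <- non_t()
        sense <- paste0(strrep("G", g_len), spacer, strrep("T", t_len),
                        non_t())
        if (st == "+") {
          Biostrings::subseq(bundle$seq[[1L]], s, e + 1L) <-
            Biostrings::DNAString(sense)
        } else {
          Biostrings::subseq(bundle$seq[[1L]], s - 1L, e) <-
            Biostrings::DNAString(reverse_complement_chr(sense))
        }
        center <- if (st == "+") s + g_len else e - g_len
        weak <- stats::runif(1) < law$frac_weak
        motifs[[length(motifs) + 1L]] <- data.frame(
          gene_id = S4Vectors::mcols(introns)$gene_id[i], chrom = "chr1",
          strand = st, start = s, end = e, g_len = g_len, gap_len = gap_len,
          t_len = t_len, center = center, kind = "gb",
          base_amplitude = if (weak) law$amp_weak else law$amp_strong,
          kd_gain = if (weak) law$kd_gain_weak else law$kd_gain_strong)
      }
    }
    if (n_skip > 0) message(n_skip, " motifs skipped (intron too short)")
    # promoter peaks: present in both conditions, no sequence edit
    g <- bundle$genes
    has_tss <- stats::runif(length(g)) < law$tss_prob
    if (any(has_tss)) {
      plus <- as.character(GenomicRanges::strand(g)) == "+"
      ctr <- ifelse(plus, GenomicRanges::start(g) + 100L,
                    GenomicRanges::end(g) - 100L)
      motifs[[length(motifs) + 1L]] <- data.frame(
        gene_id = S4Vectors::mcols(g)$gene_id[has_tss], chrom = "chr1",
        strand = as.character(GenomicRanges::strand(g))[has_tss],
        start = ctr[has_tss], end = ctr[has_tss], g_len = 0L, gap_len = 0L,
        t_len = 0L, center = ctr[has_tss], kind = "tss",
        base_amplitude = law$tss_amplitude, kd_gain = law$kd_gain_tss)
    }
    mot <- if (length(motifs)) do.call(rbind, motifs) else
      data.frame(gene_id = character(), chrom = character(),
                 strand = character(), start = integer(), end = integer(),
                 g_len = integer(), gap_len = integer(), t_len = integer(),
                 center = integer(), kind = character(),
                 base_amplitude = numeric(), kd_gain = numeric())
    mot$motif_id <- if (nrow(mot)) sprintf("m%05d", seq_len(nrow(mot))) else
      character(0)
    gid <- S4Vectors::mcols(g)$gene_id
    m_g <- as.integer(table(factor(mot$gene_id[mot$kind == "gb"],
                                   levels = gid)))
    true_lfc <- -config$kd_effect * pmin(m_g, config$cap_m)
    # compensatory upregulation responds to the perturbation: its count
    # scales with the number of motif-burdened genes, drawn among
    # motif-free genes only (so the up class is motif-poor)
    n_up <- min(round(config$frac_compensatory_up * sum(m_g > 0)),
                sum(m_g == 0))
    up <- rep(FALSE, length(g))
    if (n_up > 0)
      up[sample(which(m_g == 0), n_up)] <- TRUE
    true_lfc[up] <- config$up_effect
    genes <- data.frame(gene_id = gid, chrom = "chr1",
                        strand = as.character(GenomicRanges::strand(g)),
                        start = GenomicRanges::start(g),
                        end = GenomicRanges::end(g),
                        length = IRanges::width(g), m_g = m_g,
                        mu0 = stats::rlnorm(length(g), config$mu0_meanlog,
                                            config$mu0_sdlog),
                        true_lfc = true_lfc, compensatory_up = up)
    truth <- structure(list(motifs = mot, genes = genes),
                       class = "TruthTable")
    list(bundle = bundle, truth = truth)
  })
}

#' Simulate strand-specific coverage for one condition
#'
#' Per-position counts are Poisson with rate
#' `depth + sum_i A_i * exp(-|x - center_i| / scale)` on the strand of each
#' planted anchor's host gene, where `A_i` is the motif's base amplitude
#' multiplied by its knockdown gain when `condition = "kd"`. The seed is
#' derived from the configuration seed and the condition, so the two
#' conditions are independent but individually reproducible.
#'
#' @param bundle A `GenomeBundle`.
#' @param truth A `TruthTable` from [plant_motifs()].
#' @param condition `"control"` or `"kd"`.
#' @param config A [simulation_config()].
#' @return A `StrandedCoverage`: list with integer vectors
#'   `plus$<chrom>`, `minus$<chrom>` and `lib_size` (total coverage).
#' @export
simulate_coverage <- function(bundle, truth, condition = c("control", "kd"),
                              config) {
  condition <- match.arg(condition)
  stopifnot(inherits(config, "SimulationConfig"))
  local_seed(stage_seed(config$seed, paste0("coverage_", condition)), {
    L <- Biostrings::width(bundle$seq)[1L]
    b <- config$peak_kernel_scale
    win <- ceiling(6 * b)
    rate <- list(`+` = rep(config$depth, L), `-` = rep(config$depth, L))
    mot <- truth$motifs
    if (nrow(mot)) {
      amp <- mot$base_amplitude *
        (if (condition == "kd") mot$kd_gain else rep(1, nrow(mot)))
      for (j in seq_len(nrow(mot))) {
        ctr <- mot$center[j]
        lo <- max(1L, ctr - win); hi <- min(L, ctr + win)
        d <- abs(seq.int(lo, hi) - ctr)
        rate[[mot$strand[j]]][lo:hi] <-
          rate[[mot$strand[j]]][lo:hi] + amp[j] * exp(-d / b)
      }
    }
    plus <- stats::rpois(L, rate[["+"]])
    minus <- stats::rpois(L, rate[["-"]])
    structure(list(plus = stats::setNames(list(plus), names(bundle$seq)[1L]),
                   minus = stats::setNames(list(minus), names(bundle$seq)[1L]),
                   lib_size = sum(plus) + sum(minus),
                   read_length = config$read_length, condition = condition),
              class = "StrandedCoverage")
  })
}

#' Simulate a gene-level count matrix for one condition
#'
#' Counts are negative binomial with mean
#' `mu0 * 2^(true_lfc)` under knockdown (baseline `mu0` under control) and
#' dispersion `nb_dispersion`; replicates are independent.
#'
#' @param truth A `TruthTable`.
#' @param config A [simulation_config()].
#' @param condition `"control"` or `"kd"`.
#' @return Integer matrix, genes x replicates, with gene ids as rownames.
#' @export
simulate_counts <- function(truth, config, condition = c("control", "kd")) {
  condition <- match.arg(condition)
  g <- truth$genes
  mu <- g$mu0 * if (condition == "kd") 2^g$true_lfc else 1
  local_seed(stage_seed(config$seed, paste0("counts_", condition)), {
    m <- matrix(stats::rnbinom(nrow(g) * config$n_replicates, mu = mu,
                               size = 1 / config$nb_dispersion),
                nrow = nrow(g), ncol = config$n_replicates)
    dimnames(m) <- list(g$gene_id,
                        paste0(condition, "_", seq_len(config$n_replicates)))
    m
  })
}

# ---- on-disk round trip ----------------------------------------------------

coverage_track_gr <- function(vec, chrom) {
  r <- rle(vec)
  e <- cumsum(r$lengths)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(c(1L, e[-length(e)] + 1L), e),
                         score = r$values)
}

#' Write a complete synthetic dataset to disk
#'
#' Emits `genome.fa` (60-column FASTA), `genes.gff` (GFF3, 1-based closed),
#' `cov.{plus,minus}.{ctrl,kd}.bedGraph` (0-based half-open), `counts.tsv`,
#' `truth_motifs.tsv` / `truth_genes.tsv`, and `manifest.tsv` listing each
#' file with its MD5 digest.
#'
#' @param dataset List with elements `bundle`, `truth`, `coverage` (list
#'   `control`/`kd` of `StrandedCoverage`, optional) and `counts` (list
#'   `control`/`kd` of matrices, optional).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the manifest data frame (`file`, `md5`).
#' @export
write_dataset <- function(dataset, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  bundle <- dataset$bundle
  files <- character(0)
  wr <- function(f) { files[[length(files) + 1L]] <<- f; f }

  Biostrings::writeXStringSet(bundle$seq, wr(file.path(out_dir, "genome.fa")),
                              width = 60L)
  genes <- bundle$genes; exons <- bundle$exons
  S4Vectors::mcols(genes)$type <- "gene"
  S4Vectors::mcols(genes)$ID <- S4Vectors::mcols(genes)$gene_id
  S4Vectors::mcols(exons)$type <- "exon"
  S4Vectors::mcols(exons)$Parent <- S4Vectors::mcols(exons)$gene_id
  rtracklayer::export(c(GenomicRanges::granges(genes, use.mcols = TRUE),
                        GenomicRanges::granges(exons, use.mcols = TRUE)),
                      wr(file.path(out_dir, "genes.gff")), format = "GFF3")
  cond_tag <- c(control = "ctrl", kd = "kd")
  for (cond in names(dataset$coverage %||% list())) {
    cov <- dataset$coverage[[cond]]
    for (strand in c("plus", "minus")) {
      f <- wr(file.path(out_dir, sprintf("cov.%s.%s.bedGraph",
                                         strand, cond_tag[[cond]])))
      gr <- coverage_track_gr(cov[[strand]][[1L]], names(cov[[strand]])[1L])
      rtracklayer::export(gr, f, format = "bedGraph")
    }
  }
  if (!is.null(dataset$counts)) {
    cnt <- do.call(cbind, dataset$counts)
    utils::write.table(data.frame(gene_id = rownames(cnt), cnt),
                       wr(file.path(out_dir, "counts.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(dataset$truth$motifs,
                     wr(file.path(out_dir, "truth_motifs.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$truth$genes,
                     wr(file.path(out_dir, "truth_genes.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Read a genome bundle back from FASTA + GFF3
#'
#' Inverse of the genome/annotation part of [write_dataset()].
#'
#' @param fasta,gff File paths.
#' @param profile Optional `SpeciesProfile` to attach.
#' @return A `GenomeBundle`.
#' @export
read_genome_bundle <- function(fasta, gff, profile = NULL) {
  seq <- Biostrings::readDNAStringSet(fasta)
  names(seq) <- sub("\\s.*$", "", names(seq))
  ann <- rtracklayer::import(gff, format = "GFF3")
  genes <- ann[S4Vectors::mcols(ann)$type == "gene"]
  exons <- ann[S4Vectors::mcols(ann)$type == "exon"]
  S4Vectors::mcols(genes) <- S4Vectors::DataFrame(
    gene_id = as.character(S4Vectors::mcols(genes)$ID))
  S4Vectors::mcols(exons) <- S4Vectors::DataFrame(
    gene_id = as.character(unlist(S4Vectors::mcols(exons)$Parent)))
  sl <- stats::setNames(Biostrings::width(seq), names(seq))
  GenomeInfoDb::seqlevels(genes) <- names(sl)
  GenomeInfoDb::seqlengths(genes) <- sl
  GenomeInfoDb::seqlevels(exons) <- names(sl)
  GenomeInfoDb::seqlengths(exons) <- sl
  structure(list(seq = seq, genes = genes, exons = exons,
                 profile = profile %||%
                   species_profile("custom", n_genes = length(genes),
                                   chrom_length = sum(Biostrings::width(seq)))),
            class = "GenomeBundle")
}

#' Read a bedGraph coverage track into a per-position vector
#'
#' @param plus_file,minus_file bedGraph paths for the two strands.
#' @param read_length Read-length equivalent for CPM conversion.
#' @return A `StrandedCoverage`.
#' @export
read_coverage <- function(plus_file, minus_file, read_length = 100) {
  one <- function(f) {
    gr <- rtracklayer::import(f, format = "bedGraph")
    chrom <- as.character(GenomeInfoDb::seqnames(gr))[1L]
    rl <- GenomicRanges::coverage(gr, weight = "score")[[chrom]]
    stats::setNames(list(as.integer(rl)), chrom)
  }
  p <- one(plus_file); m <- one(minus_file)
  structure(list(plus = p, minus = m,
                 lib_size = sum(unlist(p)) + sum(unlist(m)),
                 read_length = read_length, condition = NA_character_),
            class = "StrandedCoverage")
}
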