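test_that("simulate_genome places the requested genes deterministically", {
  prof <- species_profile("human_like", n_genes = 100)
  b1 <- simulate_genome(prof, seed = 7)
  expect_equal(length(b1$genes), 100L)
  b2 <- simulate_genome(prof, seed = 7)
  expect_identical(as.character(b1$seq), as.character(b2$seq))
  expect_identical(GenomicRanges::start(b1$genes),
                   GenomicRanges::start(b2$genes))
  b3 <- simulate_genome(prof, seed = 8)
  expect_false(identical(as.character(b1$seq), as.character(b3$seq)))
})

test_that("simulate_genome reports a capacity error for a short chromosome", {
  prof <- species_profile("human_like", n_genes = 50, chrom_length = 5e4)
  expect_error(simulate_genome(prof, seed = 1), "too small")
})

test_that("genes are non-overlapping and exons lie within their gene", {
  b <- simulate_genome(species_profile("mouse_like", n_genes = 80), seed = 3)
  g <- GenomicRanges::sort(b$genes, ignore.strand = TRUE)
  expect_true(all(GenomicRanges::start(g)[-1] >
                    GenomicRanges::end(g)[-length(g)]))
  ov <- GenomicRanges::findOverlaps(b$exons, b$genes, type = "within",
                                    ignore.strand = FALSE)
  expect_equal(length(unique(S4Vectors::queryHits(ov))), length(b$exons))
})

test_that("human-like genes are longer than mouse-like genes", {
  # oracle: direct sampling from the two stated intron/exon laws
  sample_len <- function(imu, isd, n = 3000) {
    ne <- sample(4:8, n, TRUE)
    vapply(ne, function(k) sum(pmax(60, round(stats::rlnorm(k - 1, imu, isd)))) +
             k * 160, numeric(1))
  }
  withr::with_seed(11, {
    expect_gt(median(sample_len(8.0, 1.0)), median(sample_len(7.0, 0.7)))
  })
  bh <- simulate_genome(species_profile("human_like", n_genes = 250), seed = 5)
  bm <- simulate_genome(species_profile("mouse_like", n_genes = 250), seed = 5)
  expect_gt(median(IRanges::width(bh$genes)), median(IRanges::width(bm$genes)))
})

test_that("plant_motifs writes the literal grammar on both strands", {
  cfg <- simulation_config(seed = 9)
  law <- motif_law(density = 4e-5, t_len_range = c(19L, 19L),
                   gap_range = c(10L, 10L), g_range = c(20L, 20L),
                   tss_prob = 0)
  b <- simulate_genome(species_profile("human_like", n_genes = 40), seed = 2)
  pl <- plant_motifs(b, cfg, law)
  mot <- pl$truth$motifs[pl$truth$motifs$kind == "gb", ]
  expect_gt(nrow(mot), 3)
  for (i in seq_len(nrow(mot))) {
    plus_slice <- as.character(Biostrings::subseq(pl$bundle$seq[[1L]],
                                                  mot$start[i], mot$end[i]))
    if (mot$strand[i] == "+") {
      expect_match(plus_slice, "^G{20}[ACGT]{10}T{19}$")
    } else {
      # plus strand carries the reverse complement: A-run ... C-cluster
      expect_match(plus_slice, "^A{19}[ACGT]{10}C{20}$")
      sense <- extract_sense_sequence(GenomicRanges::GRanges(
        mot$chrom[i], IRanges::IRanges(mot$start[i], mot$end[i]),
        strand = "-"), pl$bundle)
      expect_match(sense, "^G{20}[ACGT]{10}T{19}$")
    }
  }
  # conservation of per-gene motif counts
  expect_equal(sum(pl$truth$genes$m_g), nrow(mot))
})

test_that("motif burden correlates with gene length", {
  b <- simulate_genome(species_profile("human_like", n_genes = 500), seed = 13)
  pl <- plant_motifs(b, simulation_config(seed = 13), motif_law(density = 4e-5))
  g <- pl$truth$genes
  expect_gt(suppressWarnings(
    cor(g$length, g$m_g, method = "spearman")), 0.3)
})

test_that("true log2 fold-changes follow the capped per-motif law", {
  b <- simulate_genome(species_profile("human_like", n_genes = 150), seed = 4)
  cfg <- simulation_config(seed = 4, kd_effect = 0.5, cap_m = 4L)
  g <- plant_motifs(b, cfg, motif_law(density = 1e-4))$truth$genes
  expect_true(any(g$m_g >= 2))
  not_up <- !g$compensatory_up
  expect_equal(g$true_lfc[not_up], -0.5 * pmin(g$m_g[not_up], 4))
  expect_true(all(g$true_lfc[g$compensatory_up] == cfg$up_effect))
  expect_true(all(g$m_g[g$compensatory_up] == 0))
  # beta = 0 implies zero truth for all non-up genes
  cfg0 <- simulation_config(seed = 4, kd_effect = 0,
                            frac_compensatory_up = 0)
  g0 <- plant_motifs(b, cfg0, motif_law(density = 1e-4))$truth$genes
  expect_true(all(g0$true_lfc == 0))
})

test_that("coverage has the stated background, bump and gain structure", {
  b <- simulate_genome(species_profile("human_like", n_genes = 15), seed = 6)
  cfg <- simulation_config(seed = 6, depth = 2)
  # no motifs: genome-wide mean = depth within 3 standard errors
  empty <- plant_motifs(b, cfg, motif_law(density = 0, tss_prob = 0))
  cov0 <- simulate_coverage(empty$bundle, empty$truth, "control", cfg)
  n <- length(cov0$plus$chr1)
  expect_lt(abs(mean(cov0$plus$chr1) - 2), 3 * sqrt(2 / n))
  # planted bumps: amplitude 50 -> max near center far above background
  law <- motif_law(density = 3e-5, frac_weak = 0, amp_strong = 50,
                   kd_gain_strong = 3, tss_prob = 0)
  pl <- plant_motifs(b, cfg, law)
  mot <- pl$truth$motifs
  expect_gt(nrow(mot), 0)
  cc <- simulate_coverage(pl$bundle, pl$truth, "control", cfg)
  ck <- simulate_coverage(pl$bundle, pl$truth, "kd", cfg)
  ratios <- vapply(seq_len(nrow(mot)), function(i) {
    tr <- if (mot$strand[i] == "+") "plus" else "minus"
    idx <- (mot$center[i] - 10):(mot$center[i] + 10)
    expect_gt(max(cc[[tr]][[1L]][idx]), 10 * cfg$depth)
    mean(ck[[tr]][[1L]][idx]) / mean(cc[[tr]][[1L]][idx])
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 3), 0.75)   # kd_gain = 3 recovered +/- 25%
})

test_that("simulated counts match negative-binomial moments", {
  genes <- data.frame(gene_id = sprintf("g%04d", 1:5000), chrom = "chr1",
                      strand = "+", start = 1, end = 2, length = 2,
                      m_g = 0L, mu0 = 100, true_lfc = 0,
                      compensatory_up = FALSE)
  truth <- structure(list(motifs = data.frame(), genes = genes),
                     class = "TruthTable")
  cfg <- simulation_config(seed = 21, nb_dispersion = 0.1, n_replicates = 2L)
  x <- as.numeric(simulate_counts(truth, cfg, "control"))   # 1e4 draws
  expect_lt(abs(mean(x) - 100), 3)
  expect_lt(abs(var(x) - (100 + 0.1 * 100^2)) / 1100, 0.05)
})

test_that("write_dataset round-trips and emits tiling bedGraph", {
  b <- simulate_genome(species_profile("human_like", n_genes = 10,
                                       chrom_length = 6e5), seed = 31)
  cfg <- simulation_config(seed = 31)
  pl <- plant_motifs(b, cfg)
  ds <- list(bundle = pl$bundle, truth = pl$truth,
             coverage = list(control = simulate_coverage(pl$bundle, pl$truth,
                                                         "control", cfg)),
             counts = list(control = simulate_counts(pl$truth, cfg, "control"),
                           kd = simulate_counts(pl$truth, cfg, "kd")))
  out <- withr::local_tempdir()
  man <- write_dataset(ds, out)
  expect_true(all(c("genome.fa", "genes.gff", "counts.tsv",
                    "cov.plus.ctrl.bedGraph") %in% man$file))
  rb <- read_genome_bundle(file.path(out, "genome.fa"),
                           file.path(out, "genes.gff"))
  expect_identical(as.character(rb$seq[[1L]]),
                   as.character(pl$bundle$seq[[1L]]))
  expect_equal(GenomicRanges::start(rb$genes),
               GenomicRanges::start(pl$bundle$genes))
  expect_equal(as.character(GenomicRanges::strand(rb$exons)),
               as.character(GenomicRanges::strand(pl$bundle$exons)))
  # bedGraph tiles the chromosome without overlap
  gr <- rtracklayer::import(file.path(out, "cov.plus.ctrl.bedGraph"),
                            format = "bedGraph")
  gr <- GenomicRanges::sort(gr)
  expect_equal(GenomicRanges::start(gr)[1L], 1L)
  expect_true(all(GenomicRanges::start(gr)[-1] ==
                    GenomicRanges::end(gr)[-length(gr)] + 1L))
  cnt <- utils::read.delim(file.path(out, "counts.tsv"))
  expect_equal(nrow(cnt), 10L)
  # byte-identical regeneration under the same seed
  out2 <- withr::local_tempdir()
  man2 <- write_dataset(ds, out2)
  expect_identical(man$md5, man2$md5)
})
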