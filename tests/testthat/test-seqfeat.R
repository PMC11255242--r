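simple_bundle <- function(seq_chr) {
  hand_bundle(seq_chr, data.frame(start = 1, end = nchar(seq_chr),
                                  strand = "+", gene_id = "g1"))
}

test_that("extract_sense_sequence respects strand and bounds", {
  b <- simple_bundle("ACGT")
  gr <- function(s, e, st) GenomicRanges::GRanges("chr1",
    IRanges::IRanges(s, e), strand = st)
  expect_equal(extract_sense_sequence(gr(1, 4, "+"), b), "ACGT")
  expect_equal(extract_sense_sequence(gr(1, 4, "-"), b), "ACGT")  # palindrome
  b2 <- simple_bundle("AAAC")
  expect_equal(extract_sense_sequence(gr(1, 4, "-"), b2), "GTTT")
  expect_error(extract_sense_sequence(gr(2, 5, "+"), b), "bounds")
})

test_that("gc_skew handles the worked cases and is antisymmetric", {
  expect_equal(gc_skew(c("GGGG", "GCGC", "GGGC", "ATAT")),
               c(1, 0, 0.5, 0))
  withr::with_seed(2, {
    for (i in 1:200) {
      s <- random_seq(sample(2:80, 1))
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s)))
      expect_equal(gc_skew(rc), -gc_skew(s), tolerance = 1e-12)
    }
  })
})

test_that("base percentages are exact and sum to 100", {
  expect_equal(base_pct("TTTT", "T"), c(T = 100))
  expect_equal(unname(base_pct("GATC", "G")), 25)
  expect_error(base_pct(character(0), "G"), "non-empty")
  withr::with_seed(3, {
    for (i in 1:50) {
      s <- random_seq(sample(1:60, 1))
      expect_equal(sum(vapply(c("A", "C", "G", "T"),
                              function(bs) base_pct(s, bs), numeric(1))),
                   100)
    }
  })
})

test_that("find_t_runs matches the regex oracle and the known motifs", {
  r <- find_t_runs("TTTTTATTTT", min_len = 4)       # the T5AT4 structure
  expect_equal(r$start, c(1L, 7L))
  expect_equal(r$length, c(5L, 4L))
  r19 <- find_t_runs(strrep("T", 19), min_len = 5)  # a T19 run
  expect_equal(r19, data.frame(start = 1L, length = 19L))
  expect_equal(nrow(find_t_runs("GCGC", 1)), 0L)
  withr::with_seed(8, {
    for (i in 1:500) {
      s <- random_seq(sample(1:300, 1), prob = c(0.2, 0.15, 0.15, 0.5))
      ml <- sample(1:6, 1)
      expect_equal(find_t_runs(s, ml), oracle_t_runs(s, ml))
    }
  })
})

test_that("T-run association looks only at the tail half", {
  seq_chr <- paste0(strrep("G", 50), strrep("C", 44), strrep("T", 6),
                    strrep("A", 100))
  b <- simple_bundle(seq_chr)
  pk_tail <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 150),
                                    strand = "+", summit = 60L)
  pk_head <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 150),
                                    strand = "+", summit = 120L)
  expect_true(associate_t_runs(pk_tail, b, min_len = 5))
  expect_false(associate_t_runs(pk_head, b, min_len = 5))
})

test_that("region features recover the planted T-run length exactly", {
  w <- small_world()
  mot <- w$truth$motifs[w$truth$motifs$kind == "gb", ]
  pk <- GenomicRanges::GRanges(mot$chrom,
    IRanges::IRanges(mot$start, mot$end), strand = mot$strand,
    summit = as.integer(mot$center))
  GenomeInfoDb::seqlengths(pk) <- GenomeInfoDb::seqlengths(w$bundle$genes)
  f <- region_features(pk, w$bundle, min_len = 5)
  expect_equal(f$max_trun, mot$t_len)
  expect_true(all(f$t_run_associated))
  expect_true(all(f$gc_skew > 0))
})

test_that("distance_to_3ss measures to the nearest same-strand acceptor", {
  seq_chr <- random_seq(5000)
  b <- hand_bundle(seq_chr,
    data.frame(start = 1, end = 3000, strand = "+", gene_id = "g1"),
    exons_df = data.frame(start = c(1, 1001), end = c(500, 3000),
                          strand = "+", gene_id = c("g1", "g1")))
  # one intron [501, 1000]; plus-strand acceptor at its right edge 1000
  pk <- function(summit) GenomicRanges::GRanges("chr1",
    IRanges::IRanges(summit - 10, summit + 10), strand = "+",
    summit = as.integer(summit))
  expect_equal(distance_to_3ss(pk(1500), b), 500)
  expect_equal(distance_to_3ss(pk(1000), b), 0)
  minus_pk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(490, 510),
                                     strand = "-", summit = 500L)
  expect_equal(distance_to_3ss(minus_pk, b), Inf)   # no minus-strand introns
})

test_that("planted mid-intron motifs sit away from acceptors", {
  w <- small_world()
  mot <- w$truth$motifs[w$truth$motifs$kind == "gb", ]
  pk <- GenomicRanges::GRanges(mot$chrom,
    IRanges::IRanges(mot$start, mot$end), strand = mot$strand,
    summit = as.integer(mot$center))
  d <- distance_to_3ss(pk, w$bundle)
  expect_gt(median(d), 100)   # margins keep plants off the splice sites
  expect_true(all(d > 0))
})

test_that("gpct_by_trun_bins bins, flags degenerate SEM, reports the trend", {
  f <- data.frame(max_trun = c(6, 7, 12, 18), g_pct = c(40, 60, 55, 20))
  gb <- gpct_by_trun_bins(f, bin_edges = c(5, 10, 15, 20, Inf))
  expect_equal(gb$bins$n, c(2L, 1L, 1L, 0L))
  expect_equal(gb$bins$mean_gpct[1L], 50)
  expect_true(is.na(gb$bins$sem[2L]))       # single-region bin flagged
  expect_true(is.na(gb$bins$mean_gpct[4L])) # empty bin undefined
})

test_that("kmer_enrichment ranks the planted k-mer first", {
  withr::with_seed(4, {
    bg <- replicate(60, random_seq(60))
    tgt <- replicate(20, paste0(random_seq(20), strrep("T", 12),
                                random_seq(20)))
    ke <- kmer_enrichment(tgt, bg, k = 6)
    expect_equal(ke$kmer[1L], "TTTTTT")
    expect_lt(ke$q[1L], 0.001)
    # reverse-complement symmetry of the top hit
    rc <- function(x) as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(x)))
    ke_rc <- kmer_enrichment(rc(tgt), rc(bg), k = 6)
    expect_equal(ke_rc$kmer[1L], "AAAAAA")
  })
  expect_error(kmer_enrichment(character(0), "ACGTAA"), "non-empty")
})

test_that("kmer_enrichment is calibrated under the null", {
  withr::with_seed(14, {
    sig <- vapply(1:5, function(i) {
      bg <- replicate(80, random_seq(80))
      tgt <- replicate(20, random_seq(80))
      min(kmer_enrichment(tgt, bg, k = 5)$q) < 0.05
    }, logical(1))
    expect_lte(sum(sig), 1)
  })
})

test_that("random region samplers are deterministic and length-matched", {
  w <- small_world()
  lens <- sample(80:200, 500, replace = TRUE)
  r1 <- sample_random_regions(w$bundle, 1000, lens, seed = 5)
  r2 <- sample_random_regions(w$bundle, 1000, lens, seed = 5)
  expect_identical(GenomicRanges::start(r1), GenomicRanges::start(r2))
  ov <- GenomicRanges::findOverlaps(r1, w$bundle$genes, type = "within",
                                    ignore.strand = TRUE)
  expect_equal(length(unique(S4Vectors::queryHits(ov))), 1000L)
  ks <- suppressWarnings(stats::ks.test(IRanges::width(r1), lens))
  expect_lt(unname(ks$statistic), 0.1)
  # T-run-anchored variant always contains a qualifying run
  rt <- sample_trun_regions(w$bundle, 80, lens, min_trun = 6, seed = 5)
  seqs <- extract_sense_sequence(rt, w$bundle)
  expect_true(all(vapply(seqs, function(s)
    nrow(find_t_runs(s, 6)) > 0, logical(1))))
})
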