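test_that("call_peaks matches the worked threshold/merge example", {
  cov <- wrap_coverage(c(0, 0, 0, 9, 9, 9, 0, 0, 0, 0))
  pk <- call_peaks(cov, peak_params(pval_cut = 1e-3, min_width = 3,
                                    fixed_lambda = 1))
  expect_equal(length(pk), 1L)
  expect_equal(GenomicRanges::start(pk), 4L)       # [3, 6) zero-based
  expect_equal(GenomicRanges::end(pk), 6L)
  expect_equal(S4Vectors::mcols(pk)$summit, 4L)    # leftmost argmax
  # at the estimated (higher) background the same block is not significant
  pk2 <- call_peaks(cov, peak_params(pval_cut = 1e-3, min_width = 3))
  expect_equal(length(pk2), 0L)
})

test_that("constant coverage yields no peaks and empty coverage no error", {
  expect_equal(length(call_peaks(wrap_coverage(rep(5L, 500)))), 0L)
  expect_equal(length(call_peaks(wrap_coverage(integer(0)))), 0L)
})

test_that("gap merging follows merge_gap exactly", {
  for (gap in c(10L, 30L, 50L, 51L, 80L)) {
    x <- integer(400)
    x[101:110] <- 50L
    x[(110 + gap + 1L):(120 + gap)] <- 50L
    pk <- call_peaks(wrap_coverage(x),
                     peak_params(pval_cut = 1e-3, merge_gap = 50L,
                                 min_width = 5L, fixed_lambda = 1))
    expect_equal(length(pk), if (gap <= 50L) 1L else 2L,
                 info = paste("gap =", gap))
  }
})

test_that("call_peaks equals the brute-force oracle on random coverage", {
  withr::with_seed(99, {
    for (case in 1:150) {
      n <- sample(200:3000, 1)
      x <- rpois(n, 1)
      for (k in seq_len(sample(0:4, 1))) {
        c0 <- sample(n, 1)
        idx <- max(1, c0 - 40):min(n, c0 + 40)
        x[idx] <- x[idx] + rpois(length(idx), 8)
      }
      params <- peak_params(bg_window = 500L, pval_cut = 1e-4,
                            merge_gap = 20L, min_width = 10L)
      pk <- call_peaks(wrap_coverage(x), params)
      orc <- oracle_call_peaks(x, pval_cut = 1e-4, bg_window = 500L,
                               merge_gap = 20L, min_width = 10L)
      if (is.null(orc)) {
        expect_equal(length(pk), 0L)
      } else {
        expect_equal(GenomicRanges::start(pk), unname(orc[, "start"]))
        expect_equal(GenomicRanges::end(pk), unname(orc[, "end"]))
        expect_equal(S4Vectors::mcols(pk)$summit, unname(orc[, "summit"]))
      }
    }
  })
})

test_that("compare_peak_sets pairs same-strand overlaps", {
  A <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200),
                              strand = "+")
  B <- GenomicRanges::GRanges(c("chr1", "chr1"),
                              IRanges::IRanges(c(151, 151), c(250, 250)),
                              strand = c("+", "-"))
  cmp <- compare_peak_sets(A, B)
  expect_equal(nrow(cmp$common), 1L)
  expect_equal(cmp$common$a, 1L)
  expect_equal(cmp$gained, 2L)
  expect_equal(length(cmp$lost), 0L)
  # identity comparison
  cmp2 <- compare_peak_sets(B, B)
  expect_equal(nrow(cmp2$common), 2L)
  expect_equal(length(cmp2$gained), 0L)
  expect_equal(length(cmp2$lost), 0L)
  # different chromosome sets are simply non-overlapping
  C <- GenomicRanges::GRanges("chr9", IRanges::IRanges(101, 200),
                              strand = "+")
  cmp3 <- compare_peak_sets(A, C)
  expect_equal(nrow(cmp3$common), 0L)
  expect_equal(cmp3$gained, 1L)
  expect_equal(cmp3$lost, 1L)
})

test_that("comparison partition invariant holds on random peak sets", {
  withr::with_seed(5, {
    for (rep in 1:20) {
      mk <- function(n) {
        st <- sort(sample(1:20000, n))
        GenomicRanges::GRanges("chr1",
          IRanges::IRanges(st, st + sample(50:300, n, TRUE)),
          strand = sample(c("+", "-"), n, TRUE))
      }
      A <- mk(50); B <- mk(50)
      cmp <- compare_peak_sets(A, B)
      expect_equal(nrow(cmp$common) + length(cmp$gained), length(B))
      # oracle: exhaustive pairwise same-strand overlap for the B side
      ovl <- sapply(seq_along(B), function(j) any(
        as.character(GenomicRanges::strand(A)) ==
          as.character(GenomicRanges::strand(B))[j] &
        GenomicRanges::start(A) <= GenomicRanges::end(B)[j] &
        GenomicRanges::end(A) >= GenomicRanges::start(B)[j]))
      expect_setequal(cmp$gained, which(!ovl))
    }
  })
})

test_that("annotate_context applies windows and precedence", {
  bundle <- hand_bundle(paste(rep("ACGT", 10000), collapse = ""),
    data.frame(start = 5001, end = 20000, strand = "+", gene_id = "gA"))
  mk_pk <- function(s, e, summit) GenomicRanges::GRanges("chr1",
    IRanges::IRanges(s, e), strand = "+", summit = summit)
  ctx <- annotate_context(mk_pk(5101, 5200, 5150), bundle, 1000, 1000)
  expect_equal(as.character(ctx$labels), "TSS")
  expect_equal(as.character(
    annotate_context(mk_pk(10001, 10100, 10050), bundle)$labels), "GB")
  expect_equal(as.character(
    annotate_context(mk_pk(19500, 19700, 19600), bundle)$labels), "TTS")
  expect_equal(as.character(
    annotate_context(mk_pk(30001, 30100, 30050), bundle)$labels),
    "intergenic")
  # opposite strand is not genic context
  pk_minus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10001, 10100),
                                     strand = "-", summit = 10050L)
  expect_equal(as.character(annotate_context(pk_minus, bundle)$labels),
               "intergenic")
  w <- small_world()
  ctx_all <- annotate_context(w$pk_kd, w$bundle)
  expect_equal(sum(ctx_all$fractions), 1)
})

test_that("peak_length_stats reports medians and the U test", {
  mk <- function(widths) GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq_along(widths) * 1000, width = widths))
  st <- peak_length_stats(mk(c(180, 180, 180)), mk(c(210, 210, 210)))
  expect_equal(st$median_a, 180)
  expect_equal(st$median_b, 210)
  same <- peak_length_stats(mk(1:10), mk(1:10))
  expect_equal(same$p_value, 1.0)
  disjoint <- peak_length_stats(mk(1:20), mk(21:40))
  expect_equal(disjoint$U, 0)
  expect_error(peak_length_stats(mk(1), GenomicRanges::GRanges()),
               "non-empty")
})

test_that("metaprofile averages, reverses minus anchors, drops edges", {
  flat <- wrap_coverage(rep(2L, 2000), rep(2L, 2000))
  anch <- data.frame(chrom = "chr1", pos = c(500, 1500), strand = "+")
  mp <- metaprofile(flat, anch, flank = 100)
  expect_equal(mp$profile, rep(2, 201))
  expect_equal(mp$n_used, 2L)
  # asymmetric deterministic pattern: minus anchor reads mirrored
  x <- integer(1000); x[501:520] <- 7L
  mp_plus <- metaprofile(wrap_coverage(x),
    data.frame(chrom = "chr1", pos = 500, strand = "+"), flank = 50)
  mp_minus <- metaprofile(wrap_coverage(integer(1000), rev(x)),
    data.frame(chrom = "chr1", pos = 501, strand = "-"), flank = 50)
  expect_equal(mp_minus$profile, mp_plus$profile)
  # edge anchors are dropped and counted; all-dropped is an error
  mp2 <- metaprofile(flat, data.frame(chrom = "chr1", pos = c(10, 500),
                                      strand = "+"), flank = 100)
  expect_equal(mp2$n_dropped, 1L)
  expect_error(metaprofile(flat, data.frame(chrom = "chr1", pos = 1,
                                            strand = "+"), flank = 100),
               "anchors")
})

test_that("planted summits produce a centred metaprofile maximum", {
  w <- small_world()
  mot <- w$truth$motifs[w$truth$motifs$kind == "gb", ]
  anch <- data.frame(chrom = mot$chrom, pos = mot$center,
                     strand = mot$strand)
  mp <- metaprofile(w$cov_kd, anch, flank = 300)
  expect_lt(abs(mp$offsets[which.max(mp$profile)]), 5)
  expect_gt(max(mp$profile), 5 * mp$profile[1L])
})
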