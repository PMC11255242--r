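#' Peak-calling parameters
#'
#' @param bg_window Width (bp) of the local background window; the local
#'   rate at a position is the maximum of the genome-wide mean and the mean
#'   over this window, which suppresses calls inside broad elevated regions.
#' @param pval_cut Poisson upper-tail cutoff for seed positions.
#' @param merge_gap Seed positions separated by gaps of at most this many
#'   bp are merged into one interval.
#' @param min_width Minimum interval width (bp) to keep.
#' @param fixed_lambda Optional fixed background rate overriding the
#'   estimated local background (useful for controlled experiments).
#' @return A list of class `PeakParams`.
#' @export
peak_params <- function(bg_window = 10000L, pval_cut = 1e-5,
                        merge_gap = 50L, min_width = 50L,
                        fixed_lambda = NULL) {
  abort_if(pval_cut <= 0 || pval_cut >= 1, "pval_cut must be in (0,1)")
  structure(list(bg_window = as.integer(bg_window), pval_cut = pval_cut,
                 merge_gap = as.integer(merge_gap),
                 min_width = as.integer(min_width),
                 fixed_lambda = fixed_lambda), class = "PeakParams")
}

# centred running mean with edge truncation, via cumulative sums
running_mean <- function(x, window) {
  n <- length(x)
  half <- window %/% 2L
  cs <- cumsum(as.double(x))
  hi <- pmin(n, seq_len(n) + half)
  lo <- pmax(1L, seq_len(n) - half)
  (cs[hi] - c(0, cs)[lo]) / (hi - lo + 1L)
}

call_peaks_vector <- function(x, params, lib_size, chrom, strand) {
  n <- length(x)
  empty <- GenomicRanges::GRanges(seqlengths = stats::setNames(n, chrom))
  if (n == 0L || sum(x) == 0) return(empty)
  lambda <- if (!is.null(params$fixed_lambda)) {
    rep(params$fixed_lambda, n)
  } else {
    pmax(mean(x), running_mean(x, params$bg_window))
  }
  seed <- which(x > 0 &
    stats::ppois(x - 1, lambda, lower.tail = FALSE) < params$pval_cut)
  if (!length(seed)) return(empty)
  grp <- cumsum(c(1L, diff(seed) > params$merge_gap + 1L))
  st <- tapply(seed, grp, min)
  en <- tapply(seed, grp, max)
  keep <- (en - st + 1L) >= params$min_width
  if (!any(keep)) return(empty)
  st <- as.integer(st[keep]); en <- as.integer(en[keep])
  summit <- mapply(function(s, e) s - 1L + which.max(x[s:e]), st, en)
  pval <- stats::ppois(x[summit] - 1, lambda[summit], lower.tail = FALSE)
  cpm <- vapply(seq_along(st),
                function(i) 1e6 * sum(x[st[i]:en[i]]) / lib_size, 0)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(st, en), strand = strand,
                         summit = as.integer(summit), intensity = cpm,
                         p_value = pval,
                         seqlengths = stats::setNames(n, chrom))
}

#' Call stranded peaks from coverage
#'
#' Scans each strand of each chromosome for positions whose count exceeds
#' the Poisson upper tail of the local background at `pval_cut`, where the
#' local background rate is `max(genome mean, mean over bg_window)` (or a
#' fixed rate if supplied). Seed positions separated by gaps of at most
#' `merge_gap` are merged; intervals narrower than `min_width` are dropped.
#' Each peak records its summit (leftmost coverage maximum), its intensity
#' in CPM (interval coverage sum over total library coverage, times 1e6)
#' and the Poisson upper-tail p-value of the summit count.
#'
#' @param cov A `StrandedCoverage`.
#' @param params A [peak_params()].
#' @return A [GenomicRanges::GRanges-class] of peaks (1-based closed
#'   intervals) with metadata columns `summit`, `intensity`, `p_value`,
#'   `name`. Empty coverage yields an empty result, not an error.
#' @examples
#' cov <- structure(list(
#'   plus = list(chr1 = c(0L, 0L, 0L, 9L, 9L, 9L, 0L, 0L, 0L, 0L)),
#'   minus = list(chr1 = integer(10)), lib_size = 27, read_length = 100),
#'   class = "StrandedCoverage")
#' call_peaks(cov, peak_params(pval_cut = 1e-3, min_width = 3,
#'                             fixed_lambda = 1))
#' @export
call_peaks <- function(cov, params = peak_params()) {
  stopifnot(inherits(cov, "StrandedCoverage"))
  res <- list()
  for (strand in c("plus", "minus")) {
    sgn <- if (strand == "plus") "+" else "-"
    for (chrom in names(cov[[strand]])) {
      res[[length(res) + 1L]] <-
        call_peaks_vector(cov[[strand]][[chrom]], params,
                          max(cov$lib_size, 1), chrom, sgn)
    }
  }
  pk <- suppressWarnings(do.call(c, res))
  pk <- GenomicRanges::sort(pk, ignore.strand = TRUE)
  if (length(pk))
    S4Vectors::mcols(pk)$name <- sprintf("peak_%05d", seq_along(pk))
  pk
}

#' Compare two stranded peak sets
#'
#' Peaks overlapping by at least one bp on the same strand are paired; each
#' peak of `B` is matched to the `A` peak with the largest overlap (ties
#' broken by leftmost `A` peak). `B` peaks with no overlapping `A` peak are
#' gained; `A` peaks with no overlapping `B` peak are lost. The identity
#' `|common| + |gained| = |B|` always holds; the `A`-side analogue holds
#' whenever the matching is injective.
#'
#' @param A,B `GRanges` peak sets on the same genome (peaks from different
#'   chromosome sets simply never overlap).
#' @return A list of class `PeakSetComparison` with `common`
#'   (data frame of indices `a`, `b`), `gained`, `lost` (integer indices)
#'   and the original sets.
#' @export
compare_peak_sets <- function(A, B) {
  # strand-aware; disjoint chromosome sets are legitimately non-overlapping
  ov <- suppressWarnings(GenomicRanges::findOverlaps(B, A))
  common <- data.frame(a = integer(0), b = integer(0))
  if (length(ov)) {
    w <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(B)[S4Vectors::queryHits(ov)],
      IRanges::ranges(A)[S4Vectors::subjectHits(ov)]))
    o <- order(S4Vectors::queryHits(ov), -w,
               GenomicRanges::start(A)[S4Vectors::subjectHits(ov)],
               S4Vectors::subjectHits(ov))
    first <- !duplicated(S4Vectors::queryHits(ov)[o])
    common <- data.frame(a = S4Vectors::subjectHits(ov)[o][first],
                         b = S4Vectors::queryHits(ov)[o][first])
  }
  gained <- setdiff(seq_along(B), common$b)
  lost <- setdiff(seq_along(A), unique(S4Vectors::subjectHits(ov)))
  structure(list(common = common, gained = gained, lost = lost,
                 A = A, B = B), class = "PeakSetComparison")
}

#' @export
print.PeakSetComparison <- function(x, ...) {
  cat(sprintf("PeakSetComparison: %d common, %d gained, %d lost (A=%d, B=%d)\n",
              nrow(x$common), length(x$gained), length(x$lost),
              length(x$A), length(x$B)))
  invisible(x)
}

#' Annotate peaks with genomic context
#'
#' Assigns each peak exactly one label among TSS, TTS, GB (genebody) and
#' intergenic, by the position of its summit relative to same-strand genes,
#' with precedence TSS > TTS > GB > intergenic. The TSS window is
#' `[TSS - tss_window, TSS + tss_window)` in transcription orientation, and
#' analogously for the TTS. Peaks on chromosomes absent from the annotation
#' are intergenic.
#'
#' @param peaks `GRanges` with a `summit` metadata column (defaults to the
#'   peak midpoint if absent).
#' @param bundle A `GenomeBundle`.
#' @param tss_window,tts_window Window half-widths in bp.
#' @return List with `labels` (factor, one per peak) and `fractions`
#'   (named numeric summing to 1 over non-empty input).
#' @export
annotate_context <- function(peaks, bundle, tss_window = 1000L,
                             tts_window = 1000L) {
  lv <- c("TSS", "TTS", "GB", "intergenic")
  if (length(peaks) == 0L)
    return(list(labels = factor(character(0), levels = lv),
                fractions = stats::setNames(rep(NA_real_, 4), lv)))
  summit <- S4Vectors::mcols(peaks)$summit %||%
    (GenomicRanges::start(peaks) + IRanges::width(peaks) %/% 2L)
  sgr <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(peaks),
                                IRanges::IRanges(summit, width = 1L),
                                strand = GenomicRanges::strand(peaks))
  genes <- bundle$genes
  tssw <- GenomicRanges::trim(suppressWarnings(
    GenomicRanges::promoters(genes, upstream = tss_window,
                             downstream = tss_window)))
  ends <- GenomicRanges::resize(genes, width = 1L, fix = "end")
  ttsw <- GenomicRanges::trim(suppressWarnings(
    GenomicRanges::promoters(ends, upstream = tts_window,
                             downstream = tts_window)))
  ovl <- function(win) {
    GenomicRanges::countOverlaps(sgr, win, ignore.strand = FALSE) > 0
  }
  lab <- rep("intergenic", length(peaks))
  lab[ovl(genes)] <- "GB"
  lab[ovl(ttsw)] <- "TTS"
  lab[ovl(tssw)] <- "TSS"
  labels <- factor(lab, levels = lv)
  list(labels = labels, fractions = prop.table(table(labels)),
       tss_window = tss_window, tts_window = tts_window)
}

#' Peak width statistics for two peak sets
#'
#' Reports per-set widths and medians and a two-tailed Mann-Whitney U test
#' on the width distributions.
#'
#' @param A,B Non-empty `GRanges` peak sets.
#' @return List with `widths_a`, `widths_b`, `median_a`, `median_b`, `U`,
#'   `p_value`.
#' @export
peak_length_stats <- function(A, B) {
  abort_if(length(A) == 0L || length(B) == 0L,
           "peak_length_stats requires two non-empty peak sets")
  wa <- IRanges::width(A); wb <- IRanges::width(B)
  mw <- mann_whitney_u(wa, wb)
  list(widths_a = wa, widths_b = wb,
       median_a = stats::median(wa), median_b = stats::median(wb),
       U = mw$U, p_value = mw$p_value)
}

#' Average coverage profile around anchor positions
#'
#' Computes the mean coverage at each offset in `[-flank, flank]` over a
#' set of stranded anchors, reading each anchor's own strand track and
#' reversing minus-strand windows so that downstream is always rightward.
#' Anchors whose window exceeds the chromosome are dropped and counted.
#'
#' @param cov A `StrandedCoverage`.
#' @param anchors `GRanges` of width-1 positions with strand, or a data
#'   frame with columns `chrom`, `pos` (1-based), `strand`.
#' @param flank Half-window in bp.
#' @return List with `profile` (length `2*flank+1`), `offsets`, `n_used`,
#'   `n_dropped`. Zero usable anchors is an error.
#' @export
metaprofile <- function(cov, anchors, flank = 500L) {
  if (methods::is(anchors, "GRanges")) {
    anchors <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(anchors)),
                          pos = GenomicRanges::start(anchors),
                          strand = as.character(GenomicRanges::strand(anchors)))
  }
  acc <- numeric(2L * flank + 1L)
  used <- 0L; dropped <- 0L
  for (i in seq_len(nrow(anchors))) {
    track <- if (anchors$strand[i] == "-") cov$minus else cov$plus
    x <- track[[anchors$chrom[i]]]
    p <- anchors$pos[i]
    if (is.null(x) || p - flank < 1L || p + flank > length(x)) {
      dropped <- dropped + 1L
      next
    }
    w <- x[(p - flank):(p + flank)]
    if (anchors$strand[i] == "-") w <- rev(w)
    acc <- acc + w
    used <- used + 1L
  }
  abort_if(used == 0L, "no usable anchors within the genome")
  list(profile = acc / used, offsets = seq.int(-flank, flank),
       n_used = used, n_dropped = dropped)
}
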