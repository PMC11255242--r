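#' Extract the sense (non-template) strand sequence of peaks
#'
#' For plus-strand peaks this is the plus-strand genome slice; for
#' minus-strand peaks it is the reverse complement, so the returned string
#' always reads 5' to 3' on the non-template strand -- the displaced strand
#' whose composition governs R-loop propensity. Ambiguity codes are
#' preserved; output is uppercase.
#'
#' @param peaks `GRanges` (1-based closed).
#' @param bundle A `GenomeBundle`.
#' @return Character vector of sequences, one per peak.
#' @export
extract_sense_sequence <- function(peaks, bundle) {
  if (length(peaks) == 0L) return(character(0))
  chrom <- as.character(GenomeInfoDb::seqnames(peaks))
  abort_if(!all(chrom %in% names(bundle$seq)),
           "peak chromosome absent from genome")
  sl <- Biostrings::width(bundle$seq)[match(chrom, names(bundle$seq))]
  abort_if(any(GenomicRanges::start(peaks) < 1L) ||
             any(GenomicRanges::end(peaks) > sl),
           "peak out of genome bounds")
  out <- character(length(peaks))
  for (i in seq_along(peaks)) {
    s <- Biostrings::subseq(bundle$seq[[chrom[i]]],
                            GenomicRanges::start(peaks)[i],
                            GenomicRanges::end(peaks)[i])
    if (as.character(GenomicRanges::strand(peaks))[i] == "-")
      s <- Biostrings::reverseComplement(s)
    out[i] <- toupper(as.character(s))
  }
  out
}

letter_counts <- function(seqs, letters) {
  Biostrings::letterFrequency(Biostrings::DNAStringSet(seqs), letters)
}

#' GC skew of sequences
#'
#' `(nG - nC) / (nG + nC)`, with 0 by convention when a sequence contains
#' neither G nor C. Ambiguous bases are ignored in both counts. Positive
#' values mark G-rich non-template strands.
#'
#' @param seq Character vector of DNA sequences.
#' @return Numeric vector in `[-1, 1]`.
#' @examples
#' gc_skew(c("GGGC", "GCGC", "ATAT"))
#' @export
gc_skew <- function(seq) {
  if (length(seq) == 0L) return(numeric(0))
  cnt <- letter_counts(seq, c("G", "C"))
  d <- cnt[, "G"] + cnt[, "C"]
  ifelse(d == 0, 0, (cnt[, "G"] - cnt[, "C"]) / d)
}

#' Percentage of a base in sequences
#'
#' `100 * count(base) / length`; ambiguous bases count toward the length
#' but not the numerator.
#'
#' @param seq Character vector of non-empty DNA sequences.
#' @param base Single base, one of A, C, G, T.
#' @return Numeric vector in `[0, 100]`.
#' @export
base_pct <- function(seq, base) {
  abort_if(length(seq) == 0L || any(nchar(seq) == 0L),
           "base_pct requires non-empty sequences")
  base <- match.arg(base, c("A", "C", "G", "T"))
  100 * letter_counts(seq, base)[, 1L] / nchar(seq)
}

#' Find maximal T-runs in a sequence
#'
#' Returns every maximal (non-extendable) run of consecutive `T` of length
#' at least `min_len`, sorted by position.
#'
#' @param seq A single DNA sequence.
#' @param min_len Minimum run length (>= 1).
#' @return Data frame with `start` (1-based offset within `seq`) and
#'   `length`.
#' @examples
#' find_t_runs("TTTTTATTTT", min_len = 4)
#' @export
find_t_runs <- function(seq, min_len = 5L) {
  abort_if(min_len < 1L, "min_len must be >= 1")
  r <- rle(strsplit(toupper(seq), "", fixed = TRUE)[[1L]] == "T")
  ends <- cumsum(r$lengths)
  keep <- r$values & r$lengths >= min_len
  data.frame(start = (ends - r$lengths + 1L)[keep],
             length = r$lengths[keep], row.names = NULL)
}

# 0-based summit offset within the sense sequence
summit_offset_sense <- function(peaks) {
  summit <- S4Vectors::mcols(peaks)$summit
  abort_if(is.null(summit), "peaks must carry a 'summit' metadata column")
  ifelse(as.character(GenomicRanges::strand(peaks)) == "-",
         GenomicRanges::end(peaks) - summit,
         summit - GenomicRanges::start(peaks))
}

#' T-run association of peaks
#'
#' A peak is T-run-associated iff the sense sequence of its tail half --
#' the part downstream of the summit in transcription orientation --
#' contains a maximal T-run of length at least `min_len`. This encodes the
#' grammar in which the G-rich element lies upstream of the summit and the
#' T-run further downstream.
#'
#' @param peaks `GRanges` with `summit` metadata.
#' @param bundle A `GenomeBundle`.
#' @param min_len Minimum T-run length.
#' @return Logical vector, one per peak.
#' @export
associate_t_runs <- function(peaks, bundle, min_len = 5L) {
  if (length(peaks) == 0L) return(logical(0))
  seqs <- extract_sense_sequence(peaks, bundle)
  off <- summit_offset_sense(peaks)
  vapply(seq_along(seqs), function(i) {
    tail <- substring(seqs[i], off[i] + 1L, nchar(seqs[i]))
    nrow(find_t_runs(tail, min_len)) > 0L
  }, logical(1))
}

#' Distance from peak summits to the nearest 3' splice site
#'
#' Intron acceptors are derived from exon gaps: the 3' end of each intron
#' in transcription orientation (intron right edge for plus-strand genes,
#' left edge for minus-strand genes). The distance is the minimum
#' `|summit - acceptor|` over all acceptors on the peak's strand, or `Inf`
#' when that strand has none.
#'
#' @param peaks `GRanges` with `summit` metadata.
#' @param bundle A `GenomeBundle`.
#' @return Numeric vector of distances in bp.
#' @export
distance_to_3ss <- function(peaks, bundle) {
  if (length(peaks) == 0L) return(numeric(0))
  introns <- intron_granges(bundle)
  istr <- as.character(GenomicRanges::strand(introns))
  acc <- ifelse(istr == "+", IRanges::end(introns), IRanges::start(introns))
  summit <- S4Vectors::mcols(peaks)$summit
  pstr <- as.character(GenomicRanges::strand(peaks))
  vapply(seq_along(peaks), function(i) {
    a <- acc[istr == pstr[i]]
    if (!length(a)) Inf else min(abs(summit[i] - a))
  }, numeric(1))
}

#' Sequence features of peak regions
#'
#' Computes, on the sense-strand sequence of each peak (whole peak by
#' default, or a fixed window centred on the summit), the GC skew, base
#' percentages, T-run inventory and distance to the nearest 3' splice
#' site, plus the T-run association flag of the tail half.
#'
#' @param peaks `GRanges` with `summit` metadata.
#' @param bundle A `GenomeBundle`.
#' @param min_len Minimum T-run length for the inventory.
#' @param window Optional window width; when given, features are computed
#'   over `summit +/- window/2` instead of the whole peak.
#' @return Data frame with one row per peak: `peak_id`, `strand`,
#'   `gc_skew`, `g_pct`, `t_pct`, `n_truns`, `max_trun`,
#'   `t_run_associated`, `dist_3ss`.
#' @export
region_features <- function(peaks, bundle, min_len = 5L, window = NULL) {
  if (!is.null(window)) {
    summit <- S4Vectors::mcols(peaks)$summit
    sl <- GenomeInfoDb::seqlengths(peaks)[
      as.character(GenomeInfoDb::seqnames(peaks))]
    half <- as.integer(window) %/% 2L
    win <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(peaks),
      IRanges::IRanges(pmax(1L, summit - half),
                       pmin(as.integer(sl), summit + half)),
      strand = GenomicRanges::strand(peaks), summit = summit)
    peaks2 <- win
  } else peaks2 <- peaks
  seqs <- extract_sense_sequence(peaks2, bundle)
  runs <- lapply(seqs, find_t_runs, min_len = min_len)
  data.frame(
    peak_id = S4Vectors::mcols(peaks)$name %||%
      sprintf("peak_%05d", seq_along(peaks)),
    strand = as.character(GenomicRanges::strand(peaks)),
    gc_skew = gc_skew(seqs),
    g_pct = base_pct(seqs, "G"),
    t_pct = base_pct(seqs, "T"),
    n_truns = vapply(runs, nrow, 0L),
    max_trun = vapply(runs, function(r) if (nrow(r)) max(r$length) else 0L, 0L),
    t_run_associated = associate_t_runs(peaks2, bundle, min_len),
    dist_3ss = distance_to_3ss(peaks2, bundle))
}

#' Mean G% binned by T-run length
#'
#' Bins regions by the length of their longest T-run and reports the mean
#' G percentage, its standard error and the bin size, together with the
#' Spearman correlation of per-region (T-run length, G%) as a monotone
#' trend statistic. Regions without a T-run are excluded.
#'
#' @param features Data frame from [region_features()] (needs `max_trun`,
#'   `g_pct`).
#' @param bin_edges Increasing left-closed bin edges; the last bin is
#'   unbounded when the final edge is `Inf`.
#' @return List with `bins` (data frame `bin`, `n`, `mean_gpct`, `sem`)
#'   and `spearman_rho`, `spearman_p`. Single-region bins report `sem` NA.
#' @export
gpct_by_trun_bins <- function(features,
                              bin_edges = c(5, 10, 15, 20, 25, Inf)) {
  f <- features[features$max_trun >= bin_edges[1L], , drop = FALSE]
  lab <- paste0("[", bin_edges[-length(bin_edges)], ",",
                bin_edges[-1L], ")")
  idx <- findInterval(f$max_trun, bin_edges)
  bins <- do.call(rbind, lapply(seq_along(lab), function(i) {
    g <- f$g_pct[idx == i]
    data.frame(bin = lab[i], n = length(g),
               mean_gpct = if (length(g)) mean(g) else NA_real_,
               sem = if (length(g) > 1L) stats::sd(g) / sqrt(length(g))
                     else NA_real_)
  }))
  ct <- if (nrow(f) >= 3L)
    suppressWarnings(stats::cor.test(f$max_trun, f$g_pct,
                                     method = "spearman")) else NULL
  list(bins = bins,
       spearman_rho = if (is.null(ct)) NA_real_ else unname(ct$estimate),
       spearman_p = if (is.null(ct)) NA_real_ else ct$p.value)
}

#' k-mer enrichment of target sequences against a background
#'
#' Counts k-mers in frame-disjoint windows (step `k`) of the target and
#' background sets and tests each k-mer's target count against the
#' background with a one-sided exact count comparison (hypergeometric
#' upper tail, i.e. one-sided Fisher), adjusting across all `4^k` tests
#' by Benjamini-Hochberg. Disjoint windows keep counts multinomial
#' (overlapping occurrences of self-overlapping words such as
#' homopolymers clump and overdisperse a naive binomial), and
#' conditioning on the combined count keeps the test calibrated when the
#' background itself is a finite sample. This is a defined, reproducible
#' stand-in for de novo motif discovery on head/tail halves.
#'
#' @param target,background Character vectors of DNA sequences.
#' @param k k-mer length; by default 6.
#' @return Data frame ranked by p then decreasing enrichment: `kmer`,
#'   `count`, `expected`, `enrichment`, `p`, `q`.
#' @export
kmer_enrichment <- function(target, background, k = 6L) {
  abort_if(length(target) == 0L || length(background) == 0L,
           "kmer_enrichment requires non-empty target and background")
  abort_if(min(nchar(target)) < k, "k exceeds the shortest target sequence")
  count_k <- function(x) {
    colSums(Biostrings::oligonucleotideFrequency(
      Biostrings::DNAStringSet(x), width = k, step = k))
  }
  tc <- count_k(target)
  bc <- count_k(background)
  n <- sum(tc); N <- sum(bc)
  p0 <- (bc + 1) / (N + length(bc))
  p <- stats::phyper(tc - 1, tc + bc, n + N - tc - bc, n,
                     lower.tail = FALSE)
  out <- data.frame(kmer = names(tc), count = as.integer(tc),
                    expected = n * p0,
                    enrichment = (tc / max(n, 1)) / p0,
                    p = p, q = bh_adjust(p), row.names = NULL)
  out[order(out$p, -out$enrichment, out$kmer), , drop = FALSE]
}

#' Sample random gene-matched regions
#'
#' Draws `n` regions uniformly from gene spans (genes weighted by length),
#' with lengths resampled from an empirical length distribution, inheriting
#' the host gene's strand. Used as the matched negative set for the
#' sequence-feature classifier. Each region's `summit` is set to its
#' midpoint.
#'
#' @param bundle A `GenomeBundle`.
#' @param n Number of regions.
#' @param length_law Numeric vector of lengths to resample from, or a
#'   function of `n` returning lengths.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return `GRanges` with `summit` and `name` metadata.
#' @export
sample_random_regions <- function(bundle, n, length_law, seed = 1L) {
  genes <- bundle$genes
  abort_if(length(genes) == 0L, "no genes in bundle")
  local_seed(seed, {
    draw_len <- if (is.function(length_law)) length_law else
      if (length(length_law) == 1L) function(m) rep(length_law, m) else
        function(m) sample(length_law, m, replace = TRUE)
    gs <- GenomicRanges::start(genes); ge <- GenomicRanges::end(genes)
    gw <- IRanges::width(genes)
    st <- en <- gi <- integer(n)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in 1:50) {
        len <- round(draw_len(1L))
        j <- sample.int(length(genes), 1L, prob = gw)
        if (len >= 1L && len <= gw[j]) {
          s <- gs[j] + sample.int(gw[j] - len + 1L, 1L) - 1L
          st[i] <- s; en[i] <- s + len - 1L; gi[i] <- j
          ok <- TRUE
          break
        }
      }
      abort_if(!ok, "genes too short for the requested length distribution")
    }
    GenomicRanges::GRanges(as.character(GenomeInfoDb::seqnames(genes))[gi],
      IRanges::IRanges(st, en), strand = GenomicRanges::strand(genes)[gi],
      summit = as.integer((st + en) %/% 2L),
      name = sprintf("rand_%05d", seq_len(n)),
      seqlengths = GenomeInfoDb::seqlengths(genes))
  })
}

#' Sample random T-run-anchored gene regions
#'
#' Draws `n` regions from gene spans that each contain a sense-strand
#' T-run of at least `min_trun`, by sampling uniformly among all such
#' maximal T-runs in the annotation and placing a region of resampled
#' length around the run, with the run starting just downstream of the
#' region midpoint (so the tail-half rule sees it). This is the matched
#' negative set for the classifier: random T-runs without selection on
#' their G context.
#'
#' @param bundle A `GenomeBundle`.
#' @param n Number of regions.
#' @param length_law Numeric vector of lengths to resample, or a function
#'   of `n`.
#' @param min_trun Minimum T-run length.
#' @param seed Integer seed.
#' @return `GRanges` with `summit` (region midpoint) and `name` metadata.
#' @export
sample_trun_regions <- function(bundle, n, length_law, min_trun = 5L,
                                seed = 1L) {
  genes <- bundle$genes
  abort_if(length(genes) == 0L, "no genes in bundle")
  runs <- list()
  for (i in seq_along(genes)) {
    s <- extract_sense_sequence(genes[i], bundle)
    tr <- find_t_runs(s, min_trun)
    if (!nrow(tr)) next
    runs[[length(runs) + 1L]] <- data.frame(gene = i, off = tr$start,
                                            len = tr$length)
  }
  abort_if(!length(runs), "no T-runs of length >= %d in gene spans", min_trun)
  runs <- do.call(rbind, runs)
  local_seed(seed, {
    draw_len <- if (is.function(length_law)) length_law else
      if (length(length_law) == 1L) function(m) rep(length_law, m) else
        function(m) sample(length_law, m, replace = TRUE)
    pick <- sample.int(nrow(runs), n, replace = TRUE)
    len <- pmax(round(draw_len(n)), runs$len[pick] + 2L)
    gi <- runs$gene[pick]
    gs <- GenomicRanges::start(genes)[gi]
    ge <- GenomicRanges::end(genes)[gi]
    gstr <- as.character(GenomicRanges::strand(genes))[gi]
    gw <- IRanges::width(genes)[gi]
    len <- pmin(len, gw)
    # sense-coordinate region start: run begins just after the midpoint
    s_start <- pmax(1L, runs$off[pick] - len %/% 2L)
    s_end <- pmin(gw, s_start + len - 1L)
    s_start <- pmax(1L, s_end - len + 1L)
    st <- ifelse(gstr == "-", ge - s_end + 1L, gs + s_start - 1L)
    en <- ifelse(gstr == "-", ge - s_start + 1L, gs + s_end - 1L)
    GenomicRanges::GRanges(as.character(GenomeInfoDb::seqnames(genes))[gi],
      IRanges::IRanges(st, en), strand = gstr,
      summit = as.integer((st + en) %/% 2L),
      name = sprintf("randt_%05d", seq_len(n)),
      seqlengths = GenomeInfoDb::seqlengths(genes))
  })
}
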