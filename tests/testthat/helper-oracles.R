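# Independent oracles. These deliberately re-derive results with different
# machinery than the package (filter-based windows, regex scans, explicit
# enumeration) so that agreement is informative.

# brute-force peak scan: exceedance -> gap-merge -> width-filter
oracle_call_peaks <- function(x, pval_cut = 1e-5, bg_window = 10000L,
                              merge_gap = 50L, min_width = 50L,
                              fixed_lambda = NULL) {
  n <- length(x)
  if (n == 0L || sum(x) == 0) return(NULL)
  lam <- if (!is.null(fixed_lambda)) rep(fixed_lambda, n) else {
    half <- bg_window %/% 2L
    w <- stats::filter(c(rep(NA, half), x, rep(NA, half)),
                       rep(1, bg_window + 1L), sides = 2L)
    cnt <- stats::filter(c(rep(NA, half), rep(1, n), rep(NA, half)),
                         rep(1, bg_window + 1L), sides = 2L)
    wm <- (w / cnt)[(half + 1L):(half + n)]
    # filter() marks edge windows NA; recompute those directly
    na <- which(is.na(wm))
    for (i in na) wm[i] <- mean(x[max(1L, i - half):min(n, i + half)])
    pmax(mean(x), wm)
  }
  seeds <- which(x > 0 & stats::ppois(x - 1, lam, lower.tail = FALSE) < pval_cut)
  if (!length(seeds)) return(NULL)
  out <- list()
  cur_start <- seeds[1L]; cur_end <- seeds[1L]
  flush <- function(s, e) {
    if (e - s + 1L >= min_width) {
      summit <- s - 1L + which.max(x[s:e])
      out[[length(out) + 1L]] <<- c(start = s, end = e, summit = summit)
    }
  }
  for (p in seeds[-1L]) {
    if (p - cur_end - 1L <= merge_gap) cur_end <- p
    else { flush(cur_start, cur_end); cur_start <- p; cur_end <- p }
  }
  flush(cur_start, cur_end)
  if (!length(out)) NULL else do.call(rbind, out)
}

# regex-based maximal T-run inventory
oracle_t_runs <- function(seq, min_len) {
  m <- gregexpr(sprintf("T{%d,}", min_len), seq)[[1L]]
  if (m[1L] == -1L) return(data.frame(start = integer(0), length = integer(0)))
  data.frame(start = as.integer(m), length = attr(m, "match.length"))
}

# quadratic-time BH reference: q_i = min over {j : p_j >= p_i} of n*p_j/rank_j
oracle_bh <- function(p) {
  n <- length(p)
  r <- rank(p, ties.method = "max")
  vapply(seq_len(n), function(i) {
    min(1, min(n * p[p >= p[i]] / r[p >= p[i]]))
  }, numeric(1))
}

# exact two-tailed Mann-Whitney p by complete enumeration of assignments
oracle_mwu_exact <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) sum(rank(pooled)[idx]) - n * (n + 1) / 2
  u_obs <- u_of(seq_len(n))
  all_u <- apply(utils::combn(n + m, n), 2L, u_of)
  lo <- mean(all_u <= u_obs); hi <- mean(all_u >= u_obs)
  list(U = u_obs, p_value = min(1, 2 * min(lo, hi)))
}

wrap_coverage <- function(plus, minus = NULL, chrom = "chr1") {
  minus <- minus %||% integer(length(plus))
  structure(list(plus = stats::setNames(list(as.integer(plus)), chrom),
                 minus = stats::setNames(list(as.integer(minus)), chrom),
                 lib_size = sum(plus) + sum(minus), read_length = 100,
                 condition = NA_character_),
            class = "StrandedCoverage")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-built bundle from explicit sequences and a gene table
hand_bundle <- function(seq_chr, genes_df, exons_df = NULL) {
  seq <- Biostrings::DNAStringSet(seq_chr)
  names(seq) <- names(seq_chr) %||% "chr1"
  genes <- GenomicRanges::GRanges(genes_df$chrom %||% "chr1",
    IRanges::IRanges(genes_df$start, genes_df$end),
    strand = genes_df$strand, gene_id = genes_df$gene_id)
  exons_df <- exons_df %||% genes_df
  exons <- GenomicRanges::GRanges(exons_df$chrom %||% "chr1",
    IRanges::IRanges(exons_df$start, exons_df$end),
    strand = exons_df$strand, gene_id = exons_df$gene_id)
  sl <- stats::setNames(Biostrings::width(seq), names(seq))
  GenomeInfoDb::seqlengths(genes) <- sl
  GenomeInfoDb::seqlengths(exons) <- sl
  structure(list(seq = seq, genes = genes, exons = exons,
                 profile = species_profile("custom", n_genes = length(genes),
                                           chrom_length = sum(sl))),
            class = "GenomeBundle")
}

random_seq <- function(n, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}
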