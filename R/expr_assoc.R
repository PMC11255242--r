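#' Median-of-ratios size factors and normalized counts
#'
#' Size factor of a sample is the median over genes of its counts divided
#' by the gene's geometric mean across samples; genes with any zero count
#' are excluded from factor estimation (they have no finite log geometric
#' mean). Factors are not rescaled further.
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @return List with `size_factors` and `normalized` (counts divided by
#'   their sample's factor).
#' @export
normalize_counts <- function(counts) {
  counts <- as.matrix(counts)
  abort_if(all(counts == 0), "all-zero count matrix")
  lgm <- rowMeans(log(counts))
  use <- is.finite(lgm)
  abort_if(!any(use), "no gene with all-positive counts; cannot estimate size factors")
  sf <- apply(counts, 2L, function(x) exp(stats::median(log(x[use]) - lgm[use])))
  list(size_factors = sf, normalized = sweep(counts, 2L, sf, "/"))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement, returned in the
#' original order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values.
#' @examples
#' bh_adjust(c(0.01, 0.04, 0.03))
#' @export
bh_adjust <- function(p) {
  abort_if(any(p < 0 | p > 1, na.rm = TRUE), "p-values must lie in [0, 1]")
  n <- length(p)
  if (n == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(n / seq.int(n, 1L) * p[o]))[ro]
  q
}

#' Two-tailed Mann-Whitney U test
#'
#' U is computed from mid-rank sums. When `min(n, m) <= 8` and the pooled
#' sample has no ties, the two-tailed p-value is exact (doubled smaller
#' tail of the null U distribution, capped at 1); otherwise a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y Non-empty numeric vectors.
#' @return List with `U` (statistic of `x`), `p_value`, and `method`
#'   (`"exact"` or `"normal"`).
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney_u <- function(x, y) {
  abort_if(length(x) == 0L || length(y) == 0L, "both samples must be non-empty")
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  if (min(n, m) <= 8L && !ties) {
    lo <- stats::pwilcox(U, n, m)
    hi <- stats::pwilcox(U - 1, n, m, lower.tail = FALSE)
    p <- min(1, 2 * min(lo, hi))
    method <- "exact"
  } else {
    mu <- n * m / 2
    tt <- table(r)
    sig2 <- n * m / 12 * ((n + m + 1) -
      sum(tt^3 - tt) / ((n + m) * (n + m - 1)))
    z <- (abs(U - mu) - 0.5) / sqrt(sig2)
    p <- if (sig2 == 0) 1 else min(1, 2 * stats::pnorm(-max(z, 0)))
    method <- "normal"
  }
  list(U = U, p_value = p, method = method)
}

#' Moment-matched negative-binomial Wald test for differential expression
#'
#' Normalizes by median-of-ratios, estimates per-gene log2 fold-changes of
#' normalized condition means (pseudo-count 0.5), and tests them with a
#' Wald z statistic whose variance uses a per-gene negative-binomial
#' dispersion: a pooled method-of-moments estimate shrunk toward a
#' `phi ~ a0 + a1/mu` trend fitted across genes (shrinkage weight
#' `df/(df + prior_df)`, with `df` the pooled residual degrees of freedom).
#' p-values are two-sided normal; q-values are Benjamini-Hochberg across
#' the tested genes. Genes with zero counts in every sample are excluded
#' and reported.
#'
#' @param counts Integer matrix, genes x samples.
#' @param condition Character/factor of length `ncol(counts)` with values
#'   `control` / `kd` (at least 2 replicates each).
#' @param prior_df Prior degrees of freedom of the dispersion shrinkage.
#' @return A `DEResult` data frame: `gene_id`, `base_mean`, `log2fc`,
#'   `dispersion`, `p`, `q`, plus attribute `excluded` (all-zero genes).
#' @export
de_test <- function(counts, condition, prior_df = 20) {
  counts <- as.matrix(counts)
  condition <- as.character(condition)
  abort_if(!all(sort(unique(condition)) == c("control", "kd")),
           "condition must contain exactly the levels control and kd")
  na <- sum(condition == "control"); nb <- sum(condition == "kd")
  abort_if(na < 2L || nb < 2L, "need >= 2 replicates per condition")
  keep <- rowSums(counts) > 0
  excluded <- rownames(counts)[!keep] %||% which(!keep)
  cnt <- counts[keep, , drop = FALSE]
  nc <- normalize_counts(cnt)$normalized
  a <- nc[, condition == "control", drop = FALSE]
  b <- nc[, condition == "kd", drop = FALSE]
  ma <- rowMeans(a); mb <- rowMeans(b)
  lfc <- log2((mb + 0.5) / (ma + 0.5))
  va <- apply(a, 1L, stats::var); vb <- apply(b, 1L, stats::var)
  mu <- (ma + mb) / 2
  pooled <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  phi_mom <- pmax(0, (pooled - mu) / mu^2)
  okm <- mu > 5
  phi_trend <- if (sum(okm) >= 10L) {
    fit <- stats::lm(phi_mom[okm] ~ I(1 / mu[okm]))
    pmax(1e-4, pmin(5, fit$coefficients[[1L]] + fit$coefficients[[2L]] / mu))
  } else rep(max(1e-4, stats::median(phi_mom)), length(mu))
  df <- na + nb - 2
  w <- df / (df + prior_df)
  phi <- w * phi_mom + (1 - w) * phi_trend
  se <- sqrt((1 / pmax(ma, 0.5) + phi) / na +
             (1 / pmax(mb, 0.5) + phi) / nb) / log(2)
  z <- lfc / se
  p <- 2 * stats::pnorm(-abs(z))
  res <- data.frame(gene_id = rownames(cnt) %||% seq_len(nrow(cnt)),
                    base_mean = mu, log2fc = lfc, dispersion = phi,
                    p = p, q = bh_adjust(p), row.names = NULL)
  attr(res, "excluded") <- excluded
  class(res) <- c("DEResult", class(res))
  res
}

#' Classify genes from a differential-expression result
#'
#' `down` iff `log2fc <= -lfc_thresh` and `q <= q_thresh`; `up`
#' symmetrically; everything else `nochange`.
#'
#' @param de A `DEResult`.
#' @param lfc_thresh,q_thresh Thresholds (defaults 1 and 0.05).
#' @return Factor with levels `down`, `nochange`, `up`, named by gene id.
#' @export
classify_genes <- function(de, lfc_thresh = 1, q_thresh = 0.05) {
  cls <- rep("nochange", nrow(de))
  cls[de$log2fc <= -lfc_thresh & de$q <= q_thresh] <- "down"
  cls[de$log2fc >= lfc_thresh & de$q <= q_thresh] <- "up"
  stats::setNames(factor(cls, levels = c("down", "nochange", "up")),
                  de$gene_id)
}

class_summary <- function(v) {
  qs <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  c(n = length(v), median = qs[2L], q1 = qs[1L], q3 = qs[3L],
    iqr = qs[3L] - qs[1L])
}

#' Associate expression classes with gene length and motif burden
#'
#' Summarizes gene length and motif (or R-loop) count per class using
#' box-plot conventions (median, IQR) and tests `down` vs `nochange` and
#' `up` vs `nochange` on both covariates with two-tailed Mann-Whitney U
#' tests. Classes with fewer than 3 genes are summarized but their tests
#' are skipped and flagged.
#'
#' @param classes Named factor from [classify_genes()].
#' @param gene_lengths,motif_counts Named numeric vectors sharing the gene
#'   ids of `classes`.
#' @return A list of class `AssociationReport` with `summaries` (data
#'   frame) and `tests` (data frame of comparisons with U, p and a
#'   `skipped` flag).
#' @export
association_report <- function(classes, gene_lengths, motif_counts) {
  ids <- names(classes)
  abort_if(is.null(ids) || !all(ids %in% names(gene_lengths)) ||
             !all(ids %in% names(motif_counts)),
           "classes and covariates must share gene ids")
  gl <- gene_lengths[ids]; mc <- motif_counts[ids]
  covs <- list(gene_length = gl, motif_count = mc)
  summaries <- do.call(rbind, lapply(names(covs), function(cv) {
    do.call(rbind, lapply(levels(classes), function(cl) {
      v <- covs[[cv]][classes == cl]
      s <- if (length(v)) class_summary(v) else
        c(n = 0, median = NA, q1 = NA, q3 = NA, iqr = NA)
      data.frame(covariate = cv, class = cl, t(s))
    }))
  }))
  tests <- do.call(rbind, lapply(names(covs), function(cv) {
    do.call(rbind, lapply(c("down", "up"), function(cl) {
      a <- covs[[cv]][classes == cl]
      b <- covs[[cv]][classes == "nochange"]
      skip <- length(a) < 3L || length(b) < 3L
      mw <- if (skip) list(U = NA_real_, p_value = NA_real_) else
        mann_whitney_u(a, b)
      data.frame(covariate = cv, comparison = paste0(cl, "_vs_nochange"),
                 n_a = length(a), n_b = length(b), U = mw$U,
                 p_value = mw$p_value, skipped = skip)
    }))
  }))
  structure(list(summaries = summaries, tests = tests,
                 classes = classes, gene_lengths = gl, motif_counts = mc),
            class = "AssociationReport")
}

#' @export
print.AssociationReport <- function(x, ...) {
  cat("AssociationReport\n")
  print(x$summaries, row.names = FALSE)
  print(x$tests, row.names = FALSE)
  invisible(x)
}

#' Contrast two species' expression/length associations
#'
#' Pairs orthologous genes (for synthetic data, a shared gene index),
#' reports per-species affected-gene counts (down and up), their ratio,
#' per-ortholog length pairs, and each species' down-vs-nochange
#' gene-length test.
#'
#' @param reportA,reportB `AssociationReport`s of the two species.
#' @param ortholog_map Data frame with columns `a` and `b`: gene ids in
#'   species A and B.
#' @return List with `counts` (per species down/up), `affected_ratio`
#'   (A over B, down + up), `length_pairs` (per-ortholog lengths),
#'   `median_length` per species over orthologs, and `length_tests`
#'   (down-vs-nochange U p-value and median difference per species).
#' @export
cross_species_compare <- function(reportA, reportB, ortholog_map) {
  abort_if(nrow(ortholog_map) == 0L, "empty ortholog map")
  one <- function(r) {
    tl <- r$tests
    row <- tl[tl$covariate == "gene_length" &
                tl$comparison == "down_vs_nochange", ]
    md <- unname(stats::median(r$gene_lengths[r$classes == "down"]) -
      stats::median(r$gene_lengths[r$classes == "nochange"]))
    list(n_down = sum(r$classes == "down"), n_up = sum(r$classes == "up"),
         p_len = unname(row$p_value), median_diff = md)
  }
  a <- one(reportA); b <- one(reportB)
  pairs <- data.frame(
    a = ortholog_map$a, b = ortholog_map$b,
    length_a = reportA$gene_lengths[ortholog_map$a],
    length_b = reportB$gene_lengths[ortholog_map$b], row.names = NULL)
  list(counts = data.frame(species = c("A", "B"),
                           n_down = c(a$n_down, b$n_down),
                           n_up = c(a$n_up, b$n_up)),
       affected_ratio = (a$n_down + a$n_up) / max(1L, b$n_down + b$n_up),
       length_pairs = pairs,
       median_length = c(A = stats::median(pairs$length_a),
                         B = stats::median(pairs$length_b)),
       length_tests = data.frame(
         species = c("A", "B"), p_len = c(a$p_len, b$p_len),
         median_diff = c(a$median_diff, b$median_diff)))
}
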