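# Support-vector classifier on (GC skew, G%, T%) with an RBF kernel,
# trained by SMO with maximal-violating-pair working-set selection.
# Self-contained because no SVM backend is assumed; n is a few hundred.

rbf_kernel <- function(X, Y, gamma) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  exp(-gamma * pmax(d2, 0))
}

svm_smo_fit <- function(X, y, C = 1, gamma = 1 / 3, eps = 1e-3,
                        max_iter = 20000L) {
  n <- nrow(X)
  K <- rbf_kernel(X, X, gamma)
  alpha <- numeric(n)
  G <- rep(-1, n)                       # gradient of the dual objective
  for (iter in seq_len(max_iter)) {
    up <- (y > 0 & alpha < C) | (y < 0 & alpha > 0)
    dn <- (y > 0 & alpha > 0) | (y < 0 & alpha < C)
    if (!any(up) || !any(dn)) break
    vg <- -y * G
    i <- which(up)[which.max(vg[up])]
    j <- which(dn)[which.min(vg[dn])]
    if (vg[i] - vg[j] < eps) break
    quad <- max(K[i, i] + K[j, j] - 2 * y[i] * y[j] * K[i, j], 1e-12)
    d <- (vg[i] - vg[j]) / quad
    lo <- -Inf; hi <- Inf
    if (y[i] > 0) { lo <- max(lo, -alpha[i]); hi <- min(hi, C - alpha[i]) }
    else          { lo <- max(lo, alpha[i] - C); hi <- min(hi, alpha[i]) }
    if (y[j] > 0) { lo <- max(lo, alpha[j] - C); hi <- min(hi, alpha[j]) }
    else          { lo <- max(lo, -alpha[j]); hi <- min(hi, C - alpha[j]) }
    d <- min(max(d, lo), hi)
    if (d == 0) break
    alpha[i] <- alpha[i] + y[i] * d
    alpha[j] <- alpha[j] - y[j] * d
    G <- G + d * y * (K[, i] - K[, j])
  }
  f0 <- y * (G + 1)                     # decision values without intercept
  free <- alpha > 1e-8 & alpha < C - 1e-8
  b <- if (any(free)) mean(y[free] - f0[free]) else {
    vg <- -y * G
    up <- (y > 0 & alpha < C) | (y < 0 & alpha > 0)
    dn <- (y > 0 & alpha > 0) | (y < 0 & alpha < C)
    (max(vg[dn], -Inf) + min(vg[up], Inf)) / 2
  }
  sv <- alpha > 1e-8
  list(sv_X = X[sv, , drop = FALSE], sv_coef = (alpha * y)[sv], b = b,
       gamma = gamma, C = C)
}

svm_decision <- function(fit, X) {
  as.numeric(rbf_kernel(X, fit$sv_X, fit$gamma) %*% fit$sv_coef + fit$b)
}

feature_matrix <- function(x) {
  cols <- c("gc_skew", "g_pct", "t_pct")
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3L)
    m <- x
  } else {
    abort_if(!all(cols %in% names(x)),
             "features must contain gc_skew, g_pct, t_pct")
    m <- as.matrix(x[, cols])
  }
  colnames(m) <- cols
  abort_if(any(!is.finite(m)), "non-finite feature values")
  m
}

#' Train the R-loop-prone region classifier
#'
#' Binary maximum-margin classifier on the three sequence features
#' (GC skew, G%, T%), separating T-run-associated R-loop regions from
#' matched random regions. Features are standardized with training-set
#' statistics; the default kernel is radial-basis with `C = 1` and
#' bandwidth `gamma = 1/(3 * pooled feature variance)` (equal to 1/3 after
#' standardization); a deterministic logistic-regression fallback is
#' available. Stratified 5-fold cross-validated accuracy and the ROC/AUC
#' of the pooled cross-validated decision scores are recorded.
#'
#' @param pos,neg Data frames (or 3-column matrices) of positive and
#'   negative feature vectors, at least 20 rows each.
#' @param kernel `"rbf"` or `"logistic"`.
#' @param C Soft-margin cost.
#' @param folds Number of CV folds.
#' @param seed Integer seed for the fold assignment.
#' @return An object of class `TrainedClassifier` with the fitted decision
#'   function, standardization, `cv_accuracy`, `cv_roc`, `cv_auc`.
#' @export
train_classifier <- function(pos, neg, kernel = c("rbf", "logistic"),
                             C = 1, folds = 5L, seed = 1L) {
  kernel <- match.arg(kernel)
  abort_if(NROW(pos) == 0L || NROW(neg) == 0L,
           "both classes must be non-empty")
  abort_if(NROW(pos) < 20L || NROW(neg) < 20L,
           "need >= 20 examples per class")
  X <- rbind(feature_matrix(pos), feature_matrix(neg))
  y <- c(rep(1, NROW(pos)), rep(-1, NROW(neg)))
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  scale[scale == 0] <- 1
  Xs <- sweep(sweep(X, 2L, center), 2L, scale, "/")
  gamma <- 1 / (3 * mean(apply(Xs, 2L, stats::var)))
  fit_fun <- function(Xtr, ytr) {
    if (kernel == "rbf") svm_smo_fit(Xtr, ytr, C = C, gamma = gamma)
    else {
      df <- data.frame(y = factor(ytr, levels = c(-1, 1)), Xtr)
      g <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
      list(glm = g)
    }
  }
  dec_fun <- function(fit, Xn) {
    if (kernel == "rbf") svm_decision(fit, Xn)
    else as.numeric(stats::predict(fit$glm, newdata = as.data.frame(Xn)))
  }
  fold <- local_seed(seed, {
    f <- integer(length(y))
    for (cl in c(-1, 1)) {
      idx <- which(y == cl)
      f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    f
  })
  cv_scores <- numeric(length(y))
  for (k in seq_len(folds)) {
    tr <- fold != k
    fit_k <- fit_fun(Xs[tr, , drop = FALSE], y[tr])
    cv_scores[!tr] <- dec_fun(fit_k, Xs[!tr, , drop = FALSE])
  }
  cv_accuracy <- mean((cv_scores > 0) == (y > 0))
  roc <- roc_points(y > 0, cv_scores)
  fit <- fit_fun(Xs, y)
  structure(list(kernel = kernel, C = C, gamma = gamma,
                 center = center, scale = scale, fit = fit,
                 dec_fun = dec_fun, cv_accuracy = cv_accuracy,
                 cv_roc = roc$points, cv_auc = roc$auc,
                 cv_scores = cv_scores, labels = y, folds = folds,
                 seed = seed),
            class = "TrainedClassifier")
}

#' @export
print.TrainedClassifier <- function(x, ...) {
  cat(sprintf("TrainedClassifier (%s, C=%g, gamma=%.4g): CV accuracy %.3f, CV AUC %.3f\n",
              x$kernel, x$C, x$gamma, x$cv_accuracy, x$cv_auc))
  invisible(x)
}

#' Decision scores or class predictions from a trained classifier
#'
#' @param object A `TrainedClassifier`.
#' @param newdata Feature data frame or 3-column matrix.
#' @param type `"score"` (decision value) or `"class"` (logical).
#' @param ... Unused.
#' @return Numeric scores or logical class calls.
#' @export
predict.TrainedClassifier <- function(object, newdata,
                                      type = c("score", "class"), ...) {
  type <- match.arg(type)
  Xn <- sweep(sweep(feature_matrix(newdata), 2L, object$center),
              2L, object$scale, "/")
  s <- object$dec_fun(object$fit, Xn)
  if (type == "score") s else s > 0
}

#' ROC curve and AUC from scores
#'
#' Sweeps the decision threshold over the (tie-grouped) unique scores and
#' integrates TPR over FPR by the trapezoid rule; with ties grouped this
#' equals the Mann-Whitney statistic `U/(n*m)` exactly.
#'
#' @param labels Logical (or coercible) true-class labels.
#' @param scores Numeric decision scores.
#' @return List with `points` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_points <- function(labels, scores) {
  labels <- as.logical(labels)
  np <- sum(labels); nn <- sum(!labels)
  abort_if(np == 0L || nn == 0L, "need both classes to compute a ROC")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  grp_last <- !duplicated(rev(s))        # last index of each tie group
  keep <- rev(grp_last)
  tpr <- cumsum(l)[keep] / np
  fpr <- cumsum(!l)[keep] / nn
  pts <- data.frame(threshold = c(Inf, s[keep]),
                    fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Evaluate a classifier on labelled feature vectors
#'
#' @param model A `TrainedClassifier`.
#' @param features Feature data frame or matrix.
#' @param labels Logical true labels (TRUE = positive).
#' @return List with `accuracy` (at decision threshold 0), `roc`, `auc`,
#'   and `confusion` (2x2 table).
#' @export
evaluate_classifier <- function(model, features, labels) {
  abort_if(NROW(features) == 0L, "empty test set")
  s <- predict(model, features)
  labels <- as.logical(labels)
  roc <- roc_points(labels, s)
  list(accuracy = mean((s > 0) == labels), roc = roc$points,
       auc = roc$auc,
       confusion = table(predicted = s > 0, truth = labels))
}

#' Scan gene sense strands for predicted R-loop-prone regions
#'
#' Slides a window along each gene's sense-strand sequence, skips windows
#' whose tail half lacks a T-run of at least `min_trun`, classifies the
#' remaining windows with the trained model, and merges overlapping or
#' adjacent positive windows into hits. Each hit records the mean decision
#' score of its windows and the longest T-run it contains. Genes shorter
#' than the window are skipped; a window longer than the chromosome skips
#' the chromosome with a warning.
#'
#' @param model A `TrainedClassifier`.
#' @param bundle A `GenomeBundle`.
#' @param window,step Window width and stride in bp.
#' @param min_trun Minimum tail T-run length for a window to be scored.
#' @return `GRanges` of merged hits with `score`, `max_trun`, `gene_id`.
#' @export
scan_genome <- function(model, bundle, window = 300L, step = 50L,
                        min_trun = 5L) {
  genes <- bundle$genes
  sl <- Biostrings::width(bundle$seq)
  if (any(window > sl)) {
    warning("window wider than chromosome(s): ",
            paste(names(bundle$seq)[window > sl], collapse = ", "),
            "; skipped")
    genes <- genes[!(as.character(GenomeInfoDb::seqnames(genes)) %in%
                       names(bundle$seq)[window > sl])]
  }
  half <- window %/% 2L
  hits <- list()
  for (i in seq_along(genes)) {
    gw <- IRanges::width(genes)[i]
    if (gw < window) next
    seq_chr <- extract_sense_sequence(genes[i], bundle)
    runs <- find_t_runs(seq_chr, min_trun)
    if (!nrow(runs)) next
    run_ir <- IRanges::IRanges(runs$start, width = runs$length)
    starts <- seq.int(1L, gw - window + 1L, by = step)
    tail_ir <- IRanges::IRanges(starts + half, starts + window - 1L)
    elig <- IRanges::countOverlaps(tail_ir, run_ir,
                                     minoverlap = min_trun) > 0L
    if (!any(elig)) next
    starts <- starts[elig]
    lf <- Biostrings::letterFrequencyInSlidingView(
      Biostrings::DNAString(seq_chr), window, c("G", "C", "T"))
    lf <- lf[starts, , drop = FALSE]
    feats <- cbind(gc_skew = ifelse(lf[, "G"] + lf[, "C"] == 0, 0,
                     (lf[, "G"] - lf[, "C"]) / (lf[, "G"] + lf[, "C"])),
                   g_pct = 100 * lf[, "G"] / window,
                   t_pct = 100 * lf[, "T"] / window)
    sc <- predict(model, feats)
    pos <- sc > 0
    if (!any(pos)) next
    win_ir <- IRanges::IRanges(starts[pos], width = window)
    merged <- IRanges::reduce(win_ir)
    ov <- IRanges::findOverlaps(win_ir, merged)
    mean_sc <- tapply(sc[pos][S4Vectors::queryHits(ov)],
                      S4Vectors::subjectHits(ov), mean)
    rov <- IRanges::findOverlaps(merged, run_ir)
    max_tr <- rep(0L, length(merged))
    if (length(rov)) {
      mx <- tapply(runs$length[S4Vectors::subjectHits(rov)],
                   S4Vectors::queryHits(rov), max)
      max_tr[as.integer(names(mx))] <- as.integer(mx)
    }
    # sense -> genomic coordinates
    gs <- GenomicRanges::start(genes)[i]; ge <- GenomicRanges::end(genes)[i]
    strand_i <- as.character(GenomicRanges::strand(genes))[i]
    if (strand_i == "-") {
      g_start <- ge - IRanges::end(merged) + 1L
      g_end <- ge - IRanges::start(merged) + 1L
    } else {
      g_start <- gs + IRanges::start(merged) - 1L
      g_end <- gs + IRanges::end(merged) - 1L
    }
    hits[[length(hits) + 1L]] <- GenomicRanges::GRanges(
      as.character(GenomeInfoDb::seqnames(genes))[i],
      IRanges::IRanges(g_start, g_end), strand = strand_i,
      score = as.numeric(mean_sc), max_trun = max_tr,
      gene_id = S4Vectors::mcols(genes)$gene_id[i],
      seqlengths = GenomeInfoDb::seqlengths(genes))
  }
  if (!length(hits))
    return(GenomicRanges::GRanges(seqlengths = GenomeInfoDb::seqlengths(genes)))
  GenomicRanges::sort(suppressWarnings(do.call(c, hits)),
                      ignore.strand = TRUE)
}

#' Count scan hits per gene
#'
#' A hit is attributed to the same-strand gene whose span contains the
#' hit's midpoint; genes without hits report zero.
#'
#' @param hits `GRanges` from [scan_genome()].
#' @param bundle A `GenomeBundle`.
#' @return Named integer vector over all genes.
#' @export
count_hits_per_gene <- function(hits, bundle) {
  genes <- bundle$genes
  gid <- S4Vectors::mcols(genes)$gene_id
  out <- stats::setNames(integer(length(genes)), gid)
  if (length(hits) == 0L) return(out)
  mid <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(hits),
    IRanges::IRanges((GenomicRanges::start(hits) +
                        GenomicRanges::end(hits)) %/% 2L, width = 1L),
    strand = GenomicRanges::strand(hits))
  ov <- GenomicRanges::findOverlaps(mid, genes)
  tb <- table(factor(gid[S4Vectors::subjectHits(ov)], levels = gid))
  out[names(tb)] <- as.integer(tb)
  out
}

#' Write a trained classifier to a plain-text model file
#'
#' Key-value header plus a support-vector table, so models are
#' reproducible across implementations. Only RBF models are serialized;
#' logistic models store their coefficients.
#'
#' @param model A `TrainedClassifier`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_classifier <- function(model, path) {
  con <- file(path, "w"); on.exit(close(con))
  kv <- c(kernel = model$kernel, C = model$C, gamma = model$gamma,
          cv_accuracy = model$cv_accuracy, cv_auc = model$cv_auc,
          center = paste(model$center, collapse = ","),
          scale = paste(model$scale, collapse = ","))
  writeLines(paste0("#", names(kv), "=", kv), con)
  if (model$kernel == "rbf") {
    writeLines(paste0("#b=", model$fit$b), con)
    tab <- cbind(coef = model$fit$sv_coef, model$fit$sv_X)
    utils::write.table(tab, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    writeLines(paste0("#coef=",
                      paste(stats::coef(model$fit$glm), collapse = ",")), con)
  }
  invisible(path)
}

#' Read a trained classifier from a model file
#'
#' @param path Model file written by [write_classifier()].
#' @return A `TrainedClassifier` (CV fields as recorded at training time).
#' @export
read_classifier <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  kv <- sub("^#", "", hdr)
  keys <- sub("=.*$", "", kv); vals <- sub("^[^=]*=", "", kv)
  get <- function(k) vals[match(k, keys)]
  num <- function(k) as.numeric(strsplit(get(k), ",")[[1L]])
  kernel <- get("kernel")
  fit <- if (kernel == "rbf") {
    body <- lines[!startsWith(lines, "#")]
    tab <- utils::read.table(text = body, header = TRUE, sep = "\t")
    list(sv_X = as.matrix(tab[, -1L, drop = FALSE]),
         sv_coef = tab[[1L]], b = as.numeric(get("b")),
         gamma = as.numeric(get("gamma")), C = as.numeric(get("C")))
  } else {
    cf <- num("coef")
    g <- list(coefficients = cf)
    list(glm = structure(g, class = c("manual_glm")))
  }
  dec_fun <- if (kernel == "rbf") {
    function(fit, Xn) svm_decision(fit, Xn)
  } else {
    function(fit, Xn) {
      cf <- fit$glm$coefficients
      as.numeric(cbind(1, Xn) %*% cf)
    }
  }
  structure(list(kernel = kernel, C = as.numeric(get("C")),
                 gamma = as.numeric(get("gamma")),
                 center = stats::setNames(num("center"),
                                          c("gc_skew", "g_pct", "t_pct")),
                 scale = stats::setNames(num("scale"),
                                         c("gc_skew", "g_pct", "t_pct")),
                 fit = fit, dec_fun = dec_fun,
                 cv_accuracy = as.numeric(get("cv_accuracy")),
                 cv_auc = as.numeric(get("cv_auc"))),
            class = "TrainedClassifier")
}
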