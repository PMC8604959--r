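#' Counts-per-million
#'
#' @param counts numeric matrix (features x samples), raw counts.
#' @param lib_sizes per-sample library sizes; defaults to column sums.
#' @return matrix of CPM values, same shape as `counts`.
#' @export
cpm <- function(counts, lib_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (any(lib_sizes <= 0)) stop("library sizes must be > 0")
  sweep(counts, 2L, lib_sizes / 1e6, "/")
}

#' Transcripts-per-million
#'
#' `TPM = 1e6 * (c/L_kb) / sum(c/L_kb)` per sample; columns sum to 1e6.
#'
#' @param counts feature x sample count matrix.
#' @param lengths feature lengths in bp.
#' @return TPM matrix.
#' @export
tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  stopifnot(length(lengths) == nrow(counts), all(lengths > 0))
  rate <- counts / (lengths / 1000)
  denom <- colSums(rate)
  if (any(denom <= 0)) stop("all-zero sample: TPM undefined")
  sweep(rate, 2L, denom / 1e6, "/")
}

#' Fragments-per-kilobase-per-million
#'
#' `FPKM = c / (L_kb * N_millions)` with `N` the per-sample library size
#' (total mapped reads, not restricted to the features quantified).
#'
#' @param counts feature x sample count matrix.
#' @param lengths feature lengths in bp.
#' @param lib_sizes per-sample library sizes; defaults to column sums.
#' @return FPKM matrix.
#' @export
fpkm <- function(counts, lengths, lib_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  stopifnot(length(lengths) == nrow(counts))
  if (any(lengths <= 0)) stop("zero-length feature")
  if (any(lib_sizes <= 0)) stop("library sizes must be > 0")
  counts / outer(lengths / 1000, lib_sizes / 1e6)
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values between-sample normalization.  For each sample
#' against the reference, genes with a zero count in either sample are
#' dropped, M (log2 ratio of depth-scaled counts) and A (mean log2
#' abundance) are computed, the most extreme 30% of M and 5% of A values
#' are trimmed symmetrically, and the factor is `2^` the precision-weighted
#' mean of the surviving M values (inverse asymptotic variances as
#' weights).  Factors are re-centred so their geometric mean is 1.
#'
#' @param counts feature x sample count matrix.
#' @param lib_sizes per-sample library sizes; defaults to column sums.
#' @param ref_sample reference column index; by default the sample whose
#'   upper quartile of depth-scaled counts is closest to the mean upper
#'   quartile.
#' @param trim_m,trim_a two-sided trim fractions for M and A (defaults
#'   0.30 and 0.05).
#' @return numeric vector of per-sample scaling factors (geometric mean 1).
#' @export
tmm_factors <- function(counts, lib_sizes = colSums(counts),
                        ref_sample = NULL, trim_m = 0.30, trim_a = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("TMM needs at least two samples")
  if (any(lib_sizes <= 0)) stop("library sizes must be > 0")
  if (is.null(ref_sample)) {
    uq <- apply(sweep(counts, 2L, lib_sizes, "/"), 2L,
                stats::quantile, probs = 0.75)
    ref_sample <- which.min(abs(uq - mean(uq)))
  }
  f <- vapply(seq_len(ncol(counts)), function(k) {
    if (k == ref_sample) return(1)
    .tmm_pair(counts[, k], counts[, ref_sample],
              lib_sizes[k], lib_sizes[ref_sample], trim_m, trim_a)
  }, numeric(1))
  f / exp(mean(log(f)))
}

## One sample vs reference TMM factor (internal).
.tmm_pair <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (length(obs) == 0L) {
    warning("no genes survive zero-filtering; TMM factor set to 1")
    return(1)
  }
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  w <- 1 / ((n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref))
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  rm_ <- rank(m, ties.method = "first")
  ra_ <- rank(a, ties.method = "first")
  keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
  if (!any(keep2)) {
    warning("no genes survive trimming; TMM factor set to 1")
    return(1)
  }
  2^(sum(m[keep2] * w[keep2]) / sum(w[keep2]))
}

#' Background-bin normalization factors for accessibility counts
#'
#' Composition normalization for ATAC-seq differential analysis: TMM is
#' computed on read counts in large genomic bins (10-kb tiles of the
#' genome) rather than on the peak counts themselves, so that factors
#' track background coverage and are not driven by signal regions.
#'
#' @param bin_counts bin x sample count matrix (10-kb genome tiles).
#' @param lib_sizes per-sample library sizes; defaults to column sums of
#'   the bin matrix.
#' @param ... passed to [tmm_factors()].
#' @return per-sample scaling factors (geometric mean 1) to be attached to
#'   the peak-level analysis.
#' @export
background_bin_factors <- function(bin_counts, lib_sizes = colSums(bin_counts),
                                   ...) {
  bin_counts <- as.matrix(bin_counts)
  keep <- rowSums(bin_counts) > 0
  if (!any(keep)) stop("all background bins are zero")
  tmm_factors(bin_counts[keep, , drop = FALSE], lib_sizes = lib_sizes, ...)
}

#' Filter features by median CPM
#'
#' Drops rows whose median CPM across all samples is below `threshold`
#' (rows exactly at the threshold are kept).  The defaults used in
#' practice are 0.7 CPM for gene expression and 1.2 CPM for accessibility.
#'
#' @param counts feature x sample count matrix.
#' @param threshold median-CPM cutoff (> 0).
#' @param lib_sizes per-sample library sizes; defaults to column sums.
#' @return `counts` restricted to surviving rows (names preserved).
#' @export
filter_by_median_cpm <- function(counts, threshold,
                                 lib_sizes = colSums(counts)) {
  stopifnot(threshold > 0)
  counts <- as.matrix(counts)
  med <- apply(cpm(counts, lib_sizes), 1L, stats::median)
  counts[med >= threshold, , drop = FALSE]
}

#' Two-group negative-binomial exact test
#'
#' Per-row differential test between exactly two groups of samples.
#' Counts are scaled to a common effective library size (library size
#' times normalization factor), a common NB dispersion is estimated by the
#' method of moments across all rows, and each row is tested with a
#' conditional exact test: given the total pseudo-count of the row, the
#' probability of a group split as or less likely than the observed one
#' under equal means (double-tail exact test; binomial conditional in the
#' Poisson limit).  P-values are BH-adjusted across tested rows and calls
#' made at `fdr < alpha` and `|log2FC| > lfc_min`.
#'
#' @param counts feature x sample count matrix.
#' @param groups factor/character of length `ncol(counts)` with exactly
#'   two levels; the log2 fold change is level 2 over level 1.
#' @param factors per-sample normalization factors (default 1).
#' @param lib_sizes per-sample library sizes; defaults to column sums.
#' @param alpha FDR threshold for calls (default 0.05).
#' @param lfc_min minimum absolute log2 fold change for calls (default 1).
#' @param prior_count added to group means before the log-ratio
#'   (default 0.5).
#' @param dispersion optional fixed common dispersion; estimated when NULL.
#' @return data.frame with `row_id`, `log2fc`, `p`, `fdr`,
#'   `call` (up/down/ns); attribute `dispersion` holds the common
#'   dispersion used.
#' @export
differential_test <- function(counts, groups, factors = NULL,
                              lib_sizes = colSums(counts), alpha = 0.05,
                              lfc_min = 1, prior_count = 0.5,
                              dispersion = NULL) {
  counts <- as.matrix(counts)
  groups <- if (is.factor(groups)) droplevels(groups) else factor(groups)
  if (nlevels(groups) != 2L)
    stop("differential_test compares exactly two groups")
  n1 <- sum(groups == levels(groups)[1L])
  n2 <- sum(groups == levels(groups)[2L])
  if (n1 < 2L || n2 < 2L) stop("each group needs at least two samples")
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  eff <- lib_sizes * factors
  if (any(eff <= 0)) stop("effective library sizes must be > 0")
  ## pseudo-counts at the geometric-mean effective depth
  common <- exp(mean(log(eff)))
  pseudo <- sweep(counts, 2L, common / eff, "*")
  g1 <- groups == levels(groups)[1L]
  m1 <- rowMeans(pseudo[, g1, drop = FALSE])
  m2 <- rowMeans(pseudo[, !g1, drop = FALSE])
  if (is.null(dispersion)) dispersion <- .moment_dispersion(pseudo, groups)
  s1 <- round(rowSums(pseudo[, g1, drop = FALSE]))
  s2 <- round(rowSums(pseudo[, !g1, drop = FALSE]))
  p <- vapply(seq_len(nrow(pseudo)), function(i) {
    .exact_nb_p(s1[i], s2[i], n1, n2, dispersion)
  }, numeric(1))
  fdr <- stats::p.adjust(p, method = "BH")
  log2fc <- log2((m2 + prior_count) / (m1 + prior_count))
  call <- ifelse(fdr < alpha & abs(log2fc) > lfc_min,
                 ifelse(log2fc > 0, "up", "down"), "ns")
  out <- data.frame(row_id = if (is.null(rownames(counts)))
                      as.character(seq_len(nrow(counts))) else rownames(counts),
                    log2fc = log2fc, p = p, fdr = fdr, call = call,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "dispersion") <- dispersion
  out
}

## Common NB dispersion by method of moments on depth-equalized counts:
## Var = mu + phi mu^2, estimated within groups and pooled over rows as a
## ratio of sums (stable for small per-row sample sizes).
.moment_dispersion <- function(pseudo, groups) {
  num <- 0; den <- 0
  for (lev in levels(groups)) {
    x <- pseudo[, groups == lev, drop = FALSE]
    m <- rowMeans(x)
    v <- apply(x, 1L, stats::var)
    num <- num + sum(v - m)
    den <- den + sum(m^2)
  }
  max(num / den, 0)
}

## Conditional double-tail exact p for group sums s1, s2 of n1, n2
## equal-depth NB samples with common dispersion phi (internal).
.exact_nb_p <- function(s1, s2, n1, n2, phi) {
  s <- s1 + s2
  if (s == 0) return(1)
  mu <- s / (n1 + n2)
  k <- 0:s
  if (phi < 1e-8) {
    lp <- stats::dbinom(k, s, n1 / (n1 + n2), log = TRUE)
  } else {
    lp <- stats::dnbinom(k, size = n1 / phi, mu = n1 * mu, log = TRUE) +
      stats::dnbinom(s - k, size = n2 / phi, mu = n2 * mu, log = TRUE)
  }
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  min(1, sum(pr[pr <= pr[s1 + 1] * (1 + 1e-10)]))
}

#' Cluster differentially expressed genes into trajectory groups
#'
#' Standardizes each gene's expression across samples to z-scores,
#' clusters genes by hierarchical agglomeration (Euclidean distance,
#' complete linkage) and cuts the tree into `k` branches (default six,
#' matching stage-restricted up/down trajectory archetypes).
#'
#' @param expr gene x sample expression matrix (TPM or similar),
#'   restricted to the genes to cluster.
#' @param k number of clusters (default 6).
#' @param stages optional factor of stage labels per sample for the
#'   per-cluster stage-mean profiles.
#' @return list with `cluster` (named integer vector gene -> cluster id),
#'   `centers` (cluster x sample z-score means), `stage_means` (cluster x
#'   stage, when `stages` given) and the `hclust` tree.
#' @export
cluster_de_genes <- function(expr, k = 6L, stages = NULL) {
  expr <- as.matrix(expr)
  if (nrow(expr) < k) stop("need at least k genes to cut k clusters")
  z <- t(scale(t(expr)))
  flat <- !is.finite(rowSums(z))
  if (any(flat)) {
    warning(sum(flat), " constant-expression gene(s): z-score set to 0")
    z[flat, ] <- 0
  }
  tree <- stats::hclust(stats::dist(z), method = "complete")
  cl <- stats::cutree(tree, k = k)
  names(cl) <- rownames(expr)
  centers <- do.call(rbind, lapply(seq_len(k), function(i)
    colMeans(z[cl == i, , drop = FALSE])))
  rownames(centers) <- seq_len(k)
  stage_means <- NULL
  if (!is.null(stages)) {
    stages <- as.factor(stages)
    stage_means <- do.call(cbind, lapply(levels(stages), function(s)
      rowMeans(centers[, stages == s, drop = FALSE])))
    colnames(stage_means) <- levels(stages)
  }
  list(cluster = cl, centers = centers, stage_means = stage_means,
       tree = tree)
}
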