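#' Hypergeometric gene-set enrichment test
#'
#' Upper-tail hypergeometric test of the overlap between a query gene list
#' and one or more gene sets within a fixed universe:
#' `p = P(X >= k)` with `X ~ Hypergeometric(N, K, n)` where `N` is the
#' universe size, `K` the set size, `n` the query size and `k` the
#' overlap.  P-values are BH-adjusted across the supplied sets.
#'
#' @param query character vector of query gene ids (must lie in the
#'   universe).
#' @param sets named list of gene-id vectors (each a subset of the
#'   universe).
#' @param universe character vector of all gene ids considered.
#' @return data.frame with `set_id`, `overlap_k`, `query_n`, `set_K`,
#'   `universe_N`, `p`, `fdr`, ordered as `sets`.
#' @export
hypergeom_test <- function(query, sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  query <- unique(query)
  if (any(!query %in% universe)) stop("query genes outside the universe")
  if (is.null(names(sets))) names(sets) <- seq_along(sets)
  n <- length(query)
  res <- do.call(rbind, lapply(names(sets), function(id) {
    set <- unique(intersect(sets[[id]], universe))
    k <- length(intersect(query, set))
    K <- length(set)
    p <- stats::phyper(k - 1, K, length(universe) - K, n, lower.tail = FALSE)
    data.frame(set_id = id, overlap_k = k, query_n = n, set_K = K,
               universe_N = length(universe), p = p,
               stringsAsFactors = FALSE)
  }))
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  res
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact conditional test via the hypergeometric distribution on the
#' table's margins; thin wrapper over [stats::fisher.test()] with the
#' counts spelled out.
#'
#' @param a,b,c,d non-negative integer cell counts, row-wise:
#'   `rbind(c(a, b), c(c, d))`.
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @return the p-value.
#' @export
fisher_2x2 <- function(a, b, c, d, alternative = "greater") {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  if (all(cells == 0)) stop("all-zero table")
  stats::fisher.test(matrix(c(a, b, c, d), 2L, byrow = TRUE),
                     alternative = alternative)$p.value
}

#' Read gene sets from a GMT file
#'
#' @param path GMT path (set name, description, then member genes, tab
#'   separated).
#' @return named list of gene-id character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(x) x[-(1:2)]),
                  vapply(parts, `[[`, character(1), 1L))
}

## Per-query overlap against merged reference intervals on one chromosome
## (internal, vectorized).  With stat "regions" returns 0/1 hit flags; with
## "bases" the total overlapping bases per query, using the cumulative
## reference coverage C(x) = ref bases in [0, x).
.query_overlap <- function(starts, lens, ref_starts, ref_ends, stat) {
  if (length(ref_starts) == 0L || length(starts) == 0L)
    return(numeric(length(starts)))
  if (stat == "regions") {
    ## overlap iff the first reference not ending at or before s starts
    ## before s+L (coordinates half-open)
    j <- findInterval(starts, ref_ends)
    nxt <- j + 1L
    hit <- nxt <= length(ref_starts)
    hit[hit] <- ref_starts[nxt[hit]] < starts[hit] + lens[hit]
    as.numeric(hit)
  } else {
    cumlen <- cumsum(ref_ends - ref_starts)
    cov_before <- function(x) {
      j <- findInterval(x, ref_starts)
      out <- numeric(length(x))
      nz <- j >= 1L
      out[nz] <- cumlen[j[nz]] - pmax(0, ref_ends[j[nz]] - x[nz])
      out
    }
    cov_before(starts + lens) - cov_before(starts)
  }
}

#' Permutation test for overlap between two region sets
#'
#' Tests whether the observed number of query regions overlapping a
#' reference set exceeds what uniform placement would give.  Each of
#' `n_perm` permutations re-places every query region uniformly at random
#' within its own chromosome, preserving its length, and counts query
#' regions overlapping at least one reference region.  The empirical
#' p-value is `(1 + #{perm >= observed}) / (n_perm + 1)` and a z-score is
#' taken against the permuted mean and sd.  Optionally the longest
#' fraction of each region set is excluded first (e.g. the top 1% longest
#' peaks, which otherwise dominate overlap counts).
#'
#' @param query,reference region data.frames.
#' @param chrom_sizes named vector of chromosome lengths covering every
#'   query chromosome.
#' @param n_perm number of permutations (default 10000).
#' @param seed optional RNG seed for bit-reproducibility.
#' @param exclude_longest_frac fraction of the longest regions to drop
#'   from each set before testing (default 0; the published comparison
#'   used 0.01).
#' @param stat overlap statistic: `"regions"` (default; number of query
#'   regions hitting the reference) or `"bases"` (total overlapping
#'   bases, a near-continuous statistic whose permutation p-values are
#'   essentially tie-free and hence uniform under the null).
#' @return list with `observed`, `permuted` (length `n_perm`), `z`,
#'   `p_perm`, `n_perm` and `stat`.
#' @export
permutation_region_overlap <- function(query, reference, chrom_sizes,
                                       n_perm = 10000L, seed = NULL,
                                       exclude_longest_frac = 0,
                                       stat = c("regions", "bases")) {
  stat <- match.arg(stat)
  validate_regions(query)
  validate_regions(reference)
  if (!is.null(seed)) set.seed(seed)
  drop_longest <- function(df) {
    if (exclude_longest_frac <= 0 || nrow(df) == 0L) return(df)
    len <- df$end - df$start
    df[len <= stats::quantile(len, 1 - exclude_longest_frac), , drop = FALSE]
  }
  query <- drop_longest(query)
  reference <- drop_longest(reference)
  if (any(!query$chrom %in% names(chrom_sizes)))
    stop("query chromosome missing from chrom_sizes")
  if (any(query$end - query$start > chrom_sizes[query$chrom]))
    stop("query region longer than its chromosome")
  ## merged reference boundaries per chromosome
  ref_by_chrom <- list()
  if (nrow(reference) > 0L) {
    mr <- as_regions(GenomicRanges::reduce(as_granges(reference),
                                           min.gapwidth = 0L))
    ref_by_chrom <- split(mr, mr$chrom)
  }
  qs <- split(query$start, query$chrom)
  ql <- split(query$end - query$start, query$chrom)
  observed <- 0
  for (chrom in names(qs)) {
    r <- ref_by_chrom[[chrom]]
    if (is.null(r)) next
    observed <- observed + sum(.query_overlap(qs[[chrom]], ql[[chrom]],
                                              r$start, r$end, stat))
  }
  ## all permutation draws at once, per chromosome
  perm_counts <- numeric(n_perm)
  for (chrom in names(qs)) {
    lens <- ql[[chrom]]
    nq <- length(lens)
    max_start <- chrom_sizes[[chrom]] - lens
    ## n_perm independent re-placements of every query region
    flat <- floor(stats::runif(n_perm * nq) * rep(max_start + 1, n_perm))
    r <- ref_by_chrom[[chrom]]
    if (is.null(r)) next
    ov <- .query_overlap(flat, rep(lens, n_perm), r$start, r$end, stat)
    perm_counts <- perm_counts +
      rowSums(matrix(ov, nrow = n_perm, byrow = TRUE))
  }
  p_perm <- (1 + sum(perm_counts >= observed)) / (n_perm + 1)
  sd_p <- stats::sd(perm_counts)
  z <- if (isTRUE(sd_p > 0)) (observed - mean(perm_counts)) / sd_p else NA_real_
  list(observed = observed, permuted = perm_counts, z = z,
       p_perm = p_perm, n_perm = n_perm, stat = stat)
}

#' TF-binding-site enrichment in cREs with covariate-matched background
#'
#' Tests, per transcription factor, whether binding sites (filtered to
#' purity strictly above `purity_min`) are enriched in foreground regions
#' (the cREs) relative to background regions (non-PIR OCRs), while
#' controlling for GC content and read count.  Background regions are
#' binned into GC-decile x read-count-decile cells; every permutation
#' draws a background set matching the foreground's covariate-cell
#' histogram exactly (with replacement; empty cells fall back to the
#' nearest non-empty cell) and counts sites per TF.  One-sided empirical
#' p-values `(1 + #{perm >= observed}) / (n_perm + 1)` are BH-adjusted
#' across TFs.
#'
#' @param sites data.frame with `tf_id`, `chrom`, `start`, `end`,
#'   `purity`.
#' @param foreground,background region data.frames.
#' @param gc_fg,gc_bg GC fraction per foreground/background region.
#' @param reads_fg,reads_bg read count per foreground/background region.
#' @param purity_min purity cutoff, strict `>` (default 0.7).
#' @param n_perm permutations (default 1000).
#' @param seed optional RNG seed.
#' @param n_bins covariate bins per axis (default 10 = deciles).
#' @return data.frame with `tf_id`, `fg_sites`, `expected_bg_sites`, `p`,
#'   `fdr`, `direction` (`enriched`/`depleted`/`none`).
#' @export
tf_site_enrichment <- function(sites, foreground, background,
                               gc_fg, gc_bg, reads_fg, reads_bg,
                               purity_min = 0.7, n_perm = 1000L,
                               seed = NULL, n_bins = 10L) {
  stopifnot(all(c("tf_id", "chrom", "start", "end", "purity") %in%
                  names(sites)),
            length(gc_fg) == nrow(foreground),
            length(gc_bg) == nrow(background),
            length(reads_fg) == nrow(foreground),
            length(reads_bg) == nrow(background))
  if (!is.null(seed)) set.seed(seed)
  sites <- sites[sites$purity > purity_min, , drop = FALSE]
  tfs <- sort(unique(sites$tf_id))
  if (length(tfs) == 0L)
    return(data.frame(tf_id = character(), fg_sites = integer(),
                      expected_bg_sites = numeric(), p = numeric(),
                      fdr = numeric(), direction = character()))
  ## covariate cells from pooled quantile breaks
  breaks <- function(v) unique(stats::quantile(v, probs = seq(0, 1,
                                                              length.out = n_bins + 1)))
  gc_br <- breaks(c(gc_fg, gc_bg))
  rd_br <- breaks(c(reads_fg, reads_bg))
  cell <- function(gc, rd) {
    paste(cut(gc, gc_br, include.lowest = TRUE, labels = FALSE),
          cut(rd, rd_br, include.lowest = TRUE, labels = FALSE))
  }
  fg_cell <- cell(gc_fg, reads_fg)
  bg_cell <- cell(gc_bg, reads_bg)
  bg_pool <- split(seq_len(nrow(background)), bg_cell)
  fg_tab <- table(fg_cell)
  ## nearest-cell fallback for foreground cells with no background members
  cell_xy <- function(lab) as.integer(strsplit(lab, " ")[[1]])
  pool_for <- vapply(names(fg_tab), function(lab) {
    if (!is.null(bg_pool[[lab]])) return(lab)
    xy <- cell_xy(lab)
    cand <- names(bg_pool)
    d <- vapply(cand, function(cl) sum((cell_xy(cl) - xy)^2), numeric(1))
    message("tf_site_enrichment: empty matched cell ", lab,
            "; falling back to nearest cell ", cand[which.min(d)])
    cand[which.min(d)]
  }, character(1))
  ## per-region per-TF site-count matrix for foreground and background
  site_reg <- regions(sites$chrom, sites$start, sites$end)
  per_region_counts <- function(region_df) {
    m <- matrix(0L, nrow(region_df), length(tfs),
                dimnames = list(NULL, tfs))
    if (nrow(region_df) == 0L) return(m)
    hits <- intersect_regions(region_df, site_reg)
    if (nrow(hits) > 0L) {
      tab <- table(hits$a_idx, factor(sites$tf_id[hits$b_idx], levels = tfs))
      m[as.integer(rownames(tab)), ] <- m[as.integer(rownames(tab)), ] +
        as.matrix(tab)
    }
    m
  }
  fg_counts <- per_region_counts(foreground)
  bg_counts <- per_region_counts(background)
  fg_sites <- colSums(fg_counts)
  ## permutations: matched background draws
  exceed <- stats::setNames(rep(0L, length(tfs)), tfs)
  exp_sum <- stats::setNames(rep(0, length(tfs)), tfs)
  for (p in seq_len(n_perm)) {
    idx <- unlist(lapply(names(fg_tab), function(lab) {
      pool <- bg_pool[[pool_for[[lab]]]]
      pool[sample.int(length(pool), fg_tab[[lab]], replace = TRUE)]
    }), use.names = FALSE)
    perm_sites <- colSums(bg_counts[idx, , drop = FALSE])
    exceed <- exceed + (perm_sites >= fg_sites)
    exp_sum <- exp_sum + perm_sites
  }
  pvals <- (1 + exceed) / (n_perm + 1)
  expected <- exp_sum / n_perm
  fdr <- stats::p.adjust(pvals, method = "BH")
  data.frame(tf_id = tfs, fg_sites = as.integer(fg_sites),
             expected_bg_sites = as.numeric(expected),
             p = as.numeric(pvals), fdr = as.numeric(fdr),
             direction = ifelse(fdr < 0.05 & fg_sites > expected,
                                "enriched", "none"),
             stringsAsFactors = FALSE, row.names = NULL)
}
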