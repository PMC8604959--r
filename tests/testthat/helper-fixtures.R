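# Shared fixtures and independent oracles, all built in code.

## One synthetic dataset per test session, generated lazily and reused.
.fixture_env <- new.env(parent = emptyenv())

sim_fixture <- function(seed = 101L) {
  key <- paste0("sim", seed)
  if (is.null(.fixture_env[[key]])) {
    dir <- file.path(tempdir(), paste0("crev2g_fix_", seed))
    sim <- simulate_dataset(simulate_config(seed = seed), dir)
    .fixture_env[[key]] <- list(dir = dir, sim = sim)
  }
  .fixture_env[[key]]
}

atlas_fixture <- function(seed = 101L) {
  key <- paste0("atlas", seed)
  if (is.null(.fixture_env[[key]])) {
    fx <- sim_fixture(seed)
    cfg <- default_config(input_dir = fx$dir, seed = seed)
    .fixture_env[[key]] <- run_atlas(cfg)
  }
  .fixture_env[[key]]
}

## O(n*m) all-pairs interval intersection oracle: every pair is examined
## explicitly (vectorized over the full n*m cross product).
brute_intersect <- function(a, b, min_overlap = 1L) {
  n <- nrow(a); m <- nrow(b)
  if (n == 0L || m == 0L)
    return(data.frame(a_idx = integer(), b_idx = integer(),
                      overlap_bp = integer()))
  ai <- rep(seq_len(n), each = m)
  bi <- rep(seq_len(m), times = n)
  ov <- pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi])
  lev <- unique(c(a$chrom, b$chrom))
  keep <- match(a$chrom, lev)[ai] == match(b$chrom, lev)[bi] &
    ov >= min_overlap
  res <- data.frame(a_idx = ai[keep], b_idx = bi[keep],
                    overlap_bp = as.integer(ov[keep]))
  res[order(res$a_idx, res$b_idx), , drop = FALSE]
}

random_regions <- function(n, chroms = c("chr1", "chr2"), size = 1e5,
                           max_len = 500L) {
  len <- sample.int(max_len, n, replace = TRUE)
  start <- floor(runif(n) * (size - len))
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = as.integer(start), end = as.integer(start + len))
}

## Exhaustive hypergeometric upper-tail oracle: enumerate all C(N, n)
## draws of the query from the universe and count overlaps >= k.
enum_hyper_p <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  in_set <- draws <= K  # wlog the set is elements 1..K
  mean(colSums(in_set) >= k)
}

## Fisher oracle: enumeration over the hypergeometric support with fixed
## margins of the 2x2 table (a b / c d).
enum_fisher_p <- function(a, b, c, d, alternative = "greater") {
  m <- a + b; n2 <- c + d; k <- a + c
  support <- max(0, k - n2):min(k, m)
  pmf <- stats::dhyper(support, m, n2, k)
  if (alternative == "greater") {
    sum(pmf[support >= a])
  } else if (alternative == "less") {
    sum(pmf[support <= a])
  } else {
    sum(pmf[pmf <= stats::dhyper(a, m, n2, k) * (1 + 1e-7)])
  }
}

## Direct-formula TMM oracle: plain-loop re-implementation of the doubly
## trimmed, precision-weighted mean of M values.
oracle_tmm_pair <- function(obs, ref, n_obs, n_ref,
                            trim_m = 0.30, trim_a = 0.05) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  p_o <- obs / n_obs; p_r <- ref / n_ref
  m <- log2(p_o / p_r)
  a <- 0.5 * log2(p_o * p_r)
  w <- 1 / ((n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref))
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  ord_m <- rank(m, ties.method = "first")
  ord_a <- rank(a, ties.method = "first")
  sel <- ord_m >= lo_m & ord_m <= hi_m & ord_a >= lo_a & ord_a <= hi_a
  2^(sum(m[sel] * w[sel]) / sum(w[sel]))
}

## Adjusted Rand index between two labelings (contingency-table formula).
ari <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  sum_comb <- function(v) sum(choose(v, 2))
  a <- sum_comb(as.vector(tab))
  b1 <- sum_comb(rowSums(tab)); b2 <- sum_comb(colSums(tab))
  exp_a <- b1 * b2 / choose(n, 2)
  max_a <- (b1 + b2) / 2
  (a - exp_a) / (max_a - exp_a)
}

## Six stage-restricted archetype profiles with Gaussian noise.
archetype_matrix <- function(genes_per_cluster = 50L, reps = 3L,
                             sigma = 0.3) {
  truth <- rep(1:6, each = genes_per_cluster)
  pat <- rbind(c(2, 0, 0), c(0, 2, 0), c(0, 0, 2),
               c(-2, 0, 0), c(0, -2, 0), c(0, 0, -2))
  m <- pat[truth, rep(1:3, each = reps)] +
    matrix(rnorm(length(truth) * 3 * reps, 0, sigma),
           length(truth), 3 * reps)
  rownames(m) <- sprintf("g%03d", seq_along(truth))
  colnames(m) <- paste0(rep(c("S1", "S2", "S3"), each = reps), "_r",
                        rep(seq_len(reps), 3))
  list(mat = m, truth = truth)
}

## Tiny hand-built gene set for atlas unit tests: one + and one - gene.
toy_gene_models <- function() {
  ex <- data.frame(
    gene_id = c("gp", "gp", "gm", "gm"),
    chrom = "chr1",
    start = c(10000L, 13000L, 40000L, 43000L),
    end = c(10500L, 13500L, 40500L, 43500L),
    strand = c("+", "+", "-", "-"))
  gene_models(ex)
}
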