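#' Expand GWAS sentinels to their LD proxies
#'
#' Filters an LD table to proxies with r-squared strictly above `r2_min`,
#' always keeping each sentinel as its own proxy (r2 = 1) when it is
#' present in the reference panel.  Sentinels flagged absent from the
#' panel contribute no proxies but are counted.
#'
#' @param ld data.frame with columns `trait`, `sentinel`, `proxy`,
#'   `chrom`, `pos` (1-based variant position), `r2`, and optionally
#'   `in_panel` (logical, default TRUE).
#' @param r2_min LD threshold, strict `>` (default 0.6).
#' @return object of class `trait_signals`: list with `table` (the
#'   filtered proxy rows) and `signals` (per trait: `n_signals`,
#'   `n_in_panel`, `n_unique_proxies`).
#' @export
expand_proxies <- function(ld, r2_min = 0.6) {
  need <- c("trait", "sentinel", "proxy", "chrom", "pos", "r2")
  stopifnot(all(need %in% names(ld)))
  if (any(ld$r2 < 0 | ld$r2 > 1, na.rm = TRUE)) stop("r2 must be in [0,1]")
  if (!"in_panel" %in% names(ld)) ld$in_panel <- TRUE
  keep <- ld$in_panel & (ld$r2 > r2_min | ld$proxy == ld$sentinel)
  tab <- ld[keep, , drop = FALSE]
  rownames(tab) <- NULL
  per_trait <- function(d, full) {
    data.frame(
      trait = full$trait[1L],
      n_signals = length(unique(full$sentinel)),
      n_in_panel = length(unique(full$sentinel[full$in_panel])),
      n_unique_proxies = length(unique(d$proxy)),
      stringsAsFactors = FALSE)
  }
  traits <- unique(ld$trait)
  signals <- do.call(rbind, lapply(traits, function(tr)
    per_trait(tab[tab$trait == tr, , drop = FALSE],
              ld[ld$trait == tr, , drop = FALSE])))
  structure(list(table = tab, signals = signals, r2_min = r2_min),
            class = "trait_signals")
}

#' @export
print.trait_signals <- function(x, ...) {
  cat("trait_signals (r2 >", x$r2_min, "):\n")
  print(x$signals, row.names = FALSE)
  invisible(x)
}

#' Locate proxies inside open chromatin
#'
#' Point-in-interval containment of proxy positions in the OCRs open in
#' each stage (half-open: a proxy at the left edge is inside, one at the
#' right edge is not).  1-based proxy positions are converted to 0-based
#' points internally.
#'
#' @param signals `trait_signals` from [expand_proxies()] (or its
#'   `table`).
#' @param atlas `ocr_atlas` with openness computed.
#' @return data.frame of hits: `trait`, `sentinel`, `proxy`, `chrom`,
#'   `pos`, `stage`, `ocr_id`.
#' @export
find_open_proxies <- function(signals, atlas) {
  tab <- if (inherits(signals, "trait_signals")) signals$table else signals
  stopifnot(inherits(atlas, "ocr_atlas"))
  empty <- data.frame(trait = character(), sentinel = character(),
                      proxy = character(), chrom = character(),
                      pos = integer(), stage = character(),
                      ocr_id = character())
  if (nrow(tab) == 0L) return(empty)
  missing_chrom <- !tab$chrom %in% atlas$ocrs$chrom
  if (any(missing_chrom)) {
    message("find_open_proxies: ", sum(missing_chrom),
            " prox(ies) on chromosomes absent from the atlas")
    tab <- tab[!missing_chrom, , drop = FALSE]
    if (nrow(tab) == 0L) return(empty)
  }
  pos0 <- tab$pos - 1L
  pts <- regions(tab$chrom, pos0, pos0 + 1L)
  hits <- intersect_regions(pts, atlas$ocrs)
  if (nrow(hits) == 0L) return(empty)
  out <- do.call(rbind, lapply(atlas$stages, function(s) {
    open_hit <- atlas$open[hits$b_idx, s]
    h <- hits[open_hit, , drop = FALSE]
    if (nrow(h) == 0L) return(NULL)
    data.frame(tab[h$a_idx, c("trait", "sentinel", "proxy", "chrom", "pos")],
               stage = s, ocr_id = atlas$ocrs$ocr_id[h$b_idx],
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Map open proxies to candidate effector genes
#'
#' Two evidence routes, both stage-matched: `distal_PIR` - the proxy's
#' OCR overlaps the other-end region of a significant interaction whose
#' bait overlaps a baited gene's promoter, implicating the bait gene;
#' `bait_OCR` - the proxy's OCR overlaps the restriction fragment
#' containing a baited gene's TSS, implicating that gene directly.
#' Duplicate (trait, sentinel, proxy, gene, stage) tuples are collapsed,
#' keeping every route that applied.
#'
#' @param hits open-proxy hits from [find_open_proxies()].
#' @param atlas classified `ocr_atlas`.
#' @param sig_ints significant interactions
#'   ([significant_interactions()]).
#' @param fm fragment map ([digest_genome()]).
#' @param gm [gene_models()] object.
#' @param promoters promoter windows with `gene_id`.
#' @param baited_genes baited gene ids; defaults to all in `promoters`.
#' @return data.frame of V2G records (pre-expression-filter): `trait`,
#'   `sentinel`, `proxy`, `stage`, `ocr_id`, `gene_id`, `route`.
#' @export
map_to_genes <- function(hits, atlas, sig_ints, fm, gm, promoters,
                         baited_genes = unique(promoters$gene_id)) {
  empty <- data.frame(trait = character(), sentinel = character(),
                      proxy = character(), stage = character(),
                      ocr_id = character(), gene_id = character(),
                      route = character())
  if (nrow(hits) == 0L) return(empty)
  ocrs <- atlas$ocrs
  ## bait fragments: the fragment containing each baited gene's TSS
  genes <- gm$genes[gm$genes$gene_id %in% baited_genes, , drop = FALSE]
  tss_pts <- regions(genes$chrom, genes$tss, genes$tss + 1L)
  fhits <- intersect_regions(tss_pts, fm)
  bait_frags <- data.frame(chrom = fm$chrom[fhits$b_idx],
                           start = fm$start[fhits$b_idx],
                           end = fm$end[fhits$b_idx],
                           gene_id = genes$gene_id[fhits$a_idx],
                           stringsAsFactors = FALSE)
  out <- list()
  for (s in unique(hits$stage)) {
    hs <- hits[hits$stage == s, , drop = FALSE]
    hocr <- ocrs[match(hs$ocr_id, ocrs$ocr_id), , drop = FALSE]
    ## route distal_PIR
    oe <- .contacted_oe(sig_ints, promoters, baited_genes, s)
    if (nrow(oe) > 0L) {
      ov <- intersect_regions(hocr, oe)
      if (nrow(ov) > 0L)
        out[[length(out) + 1L]] <- data.frame(
          hs[ov$a_idx, c("trait", "sentinel", "proxy", "stage", "ocr_id")],
          gene_id = oe$gene_id[ov$b_idx], route = "distal_PIR",
          stringsAsFactors = FALSE)
    }
    ## route bait_OCR
    if (nrow(bait_frags) > 0L) {
      ov <- intersect_regions(hocr, bait_frags)
      if (nrow(ov) > 0L)
        out[[length(out) + 1L]] <- data.frame(
          hs[ov$a_idx, c("trait", "sentinel", "proxy", "stage", "ocr_id")],
          gene_id = bait_frags$gene_id[ov$b_idx], route = "bait_OCR",
          stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty)
  rec <- unique(do.call(rbind, out))
  ## collapse duplicates keeping both routes where both apply
  key <- paste(rec$trait, rec$sentinel, rec$proxy, rec$gene_id, rec$stage)
  route <- tapply(rec$route, key, function(r)
    paste(sort(unique(r)), collapse = "+"))
  rec <- rec[!duplicated(key), , drop = FALSE]
  rec$route <- as.character(route[paste(rec$trait, rec$sentinel, rec$proxy,
                                        rec$gene_id, rec$stage)])
  rownames(rec) <- NULL
  rec
}

#' Filter V2G records to expressed genes
#'
#' Keeps records whose gene is expressed strictly above `tpm_min` in the
#' record's stage (stage expression = mean TPM over that stage's
#' replicates).  Records for genes absent from the expression table are
#' dropped with a message.
#'
#' @param records V2G records from [map_to_genes()].
#' @param tpm_mat gene x sample TPM matrix (rownames = gene ids).
#' @param samples data.frame with `sample_id`, `stage` for the TPM
#'   columns.
#' @param tpm_min expression threshold, strict `>` (default 1).
#' @return filtered records with a `gene_tpm` column added.
#' @export
filter_expressed <- function(records, tpm_mat, samples, tpm_min = 1) {
  if (nrow(records) == 0L) {
    records$gene_tpm <- numeric(0)
    return(records)
  }
  tpm_mat <- as.matrix(tpm_mat)
  stage_tpm <- vapply(unique(samples$stage), function(s) {
    cols <- intersect(colnames(tpm_mat), samples$sample_id[samples$stage == s])
    rowMeans(tpm_mat[, cols, drop = FALSE])
  }, numeric(nrow(tpm_mat)))
  missing <- !records$gene_id %in% rownames(tpm_mat)
  if (any(missing))
    message("filter_expressed: dropping ", sum(missing),
            " record(s) for genes absent from the expression table")
  records <- records[!missing, , drop = FALSE]
  if (nrow(records) == 0L) {
    records$gene_tpm <- numeric(0)
    return(records)
  }
  records$gene_tpm <- stage_tpm[cbind(match(records$gene_id,
                                            rownames(tpm_mat)),
                                      match(records$stage,
                                            colnames(stage_tpm)))]
  out <- records[records$gene_tpm > tpm_min, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-trait summary of variant-to-gene mapping
#'
#' Tabulates, for each trait, the signal counts from the LD expansion and
#' the per-stage outcome of the V2G filter chain: open proxies in
#' cis-interactions, sentinels with at least one such proxy, contacted
#' genes per stage, and unique contacted genes across stages.
#'
#' @param records filtered V2G records ([filter_expressed()]).
#' @param signals `trait_signals` from [expand_proxies()].
#' @param stages stage names in display order; defaults to those in
#'   `records`.
#' @return data.frame, one row per trait, with columns `trait`,
#'   `n_signals`, `n_in_panel`, `n_unique_proxies`, then per stage
#'   `open_proxies_cis_<stage>`, `sentinels_cis_<stage>`,
#'   `genes_<stage>`, and `n_unique_genes`.
#' @export
summarize_trait <- function(records, signals, stages = NULL) {
  stopifnot(inherits(signals, "trait_signals"))
  if (is.null(stages)) stages <- unique(records$stage)
  out <- signals$signals
  for (s in stages) {
    out[[paste0("open_proxies_cis_", s)]] <- 0L
    out[[paste0("sentinels_cis_", s)]] <- 0L
    out[[paste0("genes_", s)]] <- 0L
  }
  out$n_unique_genes <- 0L
  for (i in seq_len(nrow(out))) {
    rec <- records[records$trait == out$trait[i], , drop = FALSE]
    for (s in stages) {
      rs <- rec[rec$stage == s, , drop = FALSE]
      out[[paste0("open_proxies_cis_", s)]][i] <- length(unique(rs$proxy))
      out[[paste0("sentinels_cis_", s)]][i] <- length(unique(rs$sentinel))
      out[[paste0("genes_", s)]][i] <- length(unique(rs$gene_id))
    }
    out$n_unique_genes[i] <- length(unique(rec$gene_id))
  }
  out
}

#' Exclusive cross-trait gene overlap
#'
#' UpSet-style decomposition of the genes implicated per trait: for every
#' non-empty subset of traits, the number of genes implicated in exactly
#' that subset of traits.
#'
#' @param records filtered V2G records, or a named list of gene-id
#'   vectors per trait.
#' @return data.frame with `traits` (trait names joined by `+`),
#'   `n_traits` and `n_genes`, including zero cells, ordered by subset
#'   size then name.
#' @export
cross_trait_overlap <- function(records) {
  gene_sets <- if (is.data.frame(records)) {
    lapply(split(records$gene_id, records$trait), unique)
  } else {
    lapply(records, unique)
  }
  traits <- sort(names(gene_sets))
  if (length(traits) < 2L) stop("need at least two traits")
  genes <- unique(unlist(gene_sets))
  membership <- vapply(traits, function(tr) genes %in% gene_sets[[tr]],
                       logical(length(genes)))
  if (length(genes) == 1L) membership <- matrix(membership, nrow = 1L,
                                                dimnames = list(NULL, traits))
  key <- apply(membership, 1L, function(m) paste(traits[m], collapse = "+"))
  subsets <- unlist(lapply(seq_along(traits), function(k)
    utils::combn(traits, k, paste, collapse = "+")))
  n <- vapply(subsets, function(ss) sum(key == ss), integer(1))
  data.frame(traits = subsets,
             n_traits = lengths(strsplit(subsets, "+", fixed = TRUE)),
             n_genes = as.integer(n), row.names = NULL,
             stringsAsFactors = FALSE)
}
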