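#' Build a consensus OCR set from replicate peak calls
#'
#' All peaks from all replicates are merged transitively wherever they
#' overlap by at least one base (abutting peaks are not merged), and each
#' merged region is kept only if it is reproducible: it must overlap peaks
#' from at least half of the replicates, rounded up.  With
#' `mode = "per_stage"` (default) the denominator is the replicate count
#' of each stage and a region survives if it is reproducible in at least
#' one stage; with `mode = "global"` the denominator is the total
#' replicate count.
#'
#' @param peaks region data.frame with `sample_id` and `stage` columns;
#'   one row per peak per replicate.
#' @param mode `"per_stage"` or `"global"` reproducibility denominator.
#' @param blacklist optional region data.frame; consensus regions
#'   overlapping it are removed.
#' @return data.frame of consensus OCRs: `ocr_id` (chrom:start-end),
#'   `chrom`, `start`, `end`, plus one `support_<stage>` column per stage
#'   (number of replicates of that stage containing the region).
#' @export
build_consensus <- function(peaks, mode = c("per_stage", "global"),
                            blacklist = NULL) {
  mode <- match.arg(mode)
  validate_regions(peaks)
  stopifnot(all(c("sample_id", "stage") %in% names(peaks)))
  if (nrow(peaks) == 0L) stop("no peaks supplied")
  reps <- unique(peaks[, c("sample_id", "stage")])
  stages <- unique(reps$stage)
  ## transitive 1-bp merge: reduce with min.gapwidth = 0 keeps abutting
  ## ranges separate and chains any overlapping peaks
  merged <- as_regions(GenomicRanges::reduce(as_granges(peaks),
                                             min.gapwidth = 0L))
  merged <- merged[order(merged$chrom, merged$start), , drop = FALSE]
  rownames(merged) <- NULL
  support <- matrix(0L, nrow(merged), length(stages),
                    dimnames = list(NULL, stages))
  hits <- intersect_regions(merged, peaks)
  if (nrow(hits) > 0L) {
    key <- paste(peaks$sample_id[hits$b_idx], peaks$stage[hits$b_idx])
    for (s in stages) {
      srep <- paste(reps$sample_id[reps$stage == s], s)
      tab <- tapply(key, hits$a_idx, function(k) length(unique(k[k %in% srep])))
      support[as.integer(names(tab)), s] <- as.integer(tab)
    }
  }
  need <- ceiling(table(reps$stage)[stages] / 2)
  keep <- if (mode == "per_stage") {
    rowSums(sweep(support, 2L, need, ">=")) > 0L
  } else {
    rowSums(support) >= ceiling(nrow(reps) / 2)
  }
  out <- merged[keep, , drop = FALSE]
  support <- support[keep, , drop = FALSE]
  if (!is.null(blacklist) && nrow(blacklist) > 0L && nrow(out) > 0L) {
    bad <- unique(intersect_regions(out, blacklist)$a_idx)
    if (length(bad) > 0L) {
      out <- out[-bad, , drop = FALSE]
      support <- support[-bad, , drop = FALSE]
    }
  }
  rownames(out) <- NULL
  out <- data.frame(ocr_id = sprintf("%s:%d-%d", out$chrom, out$start, out$end),
                    out, stringsAsFactors = FALSE)
  for (s in stages) out[[paste0("support_", s)]] <- as.integer(support[, s])
  out
}

#' Quantify per-stage openness of consensus OCRs
#'
#' Computes FPKM per OCR per sample, averages within stage, and flags an
#' OCR "open" in a stage when its mean FPKM exceeds `fpkm_open`.
#'
#' @param ocrs consensus OCR data.frame from [build_consensus()].
#' @param counts OCR x sample count matrix; rows align with `ocrs`,
#'   columns named by sample id.
#' @param samples data.frame with `sample_id`, `stage` mapping columns of
#'   `counts` to stages.
#' @param lib_sizes named per-sample library sizes (total mapped reads);
#'   defaults to column sums of `counts`.
#' @param fpkm_open openness threshold on the stage-mean FPKM (default 1,
#'   strict `>`).
#' @return an `ocr_atlas` object: list with `ocrs`, `stages`, `fpkm`
#'   (OCR x sample), `mean_fpkm` and `open` (OCR x stage), and an empty
#'   `class` slot filled by [classify_ocrs()].
#' @export
quantify_openness <- function(ocrs, counts, samples,
                              lib_sizes = colSums(counts), fpkm_open = 1) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == nrow(ocrs),
            all(colnames(counts) %in% samples$sample_id))
  lengths <- ocrs$end - ocrs$start
  if (any(lengths <= 0)) stop("zero-length OCR")
  lib_sizes <- lib_sizes[colnames(counts)]
  fk <- fpkm(counts, lengths, lib_sizes)
  rownames(fk) <- ocrs$ocr_id
  stages <- unique(samples$stage)
  mean_fpkm <- vapply(stages, function(s) {
    cols <- samples$sample_id[samples$stage == s]
    rowMeans(fk[, intersect(colnames(fk), cols), drop = FALSE])
  }, numeric(nrow(fk)))
  if (is.null(dim(mean_fpkm)))
    mean_fpkm <- matrix(mean_fpkm, ncol = length(stages),
                        dimnames = list(ocrs$ocr_id, stages))
  open <- mean_fpkm > fpkm_open
  structure(list(ocrs = ocrs, stages = stages, samples = samples,
                 fpkm = fk, mean_fpkm = mean_fpkm, open = open,
                 class = NULL),
            class = "ocr_atlas")
}

#' @export
print.ocr_atlas <- function(x, ...) {
  cat("ocr_atlas:", nrow(x$ocrs), "consensus OCRs;",
      paste(x$stages, collapse = "/"), "stages\n")
  cat("open per stage:", paste(colSums(x$open), collapse = ", "), "\n")
  if (!is.null(x$class)) {
    for (s in x$stages) {
      tab <- table(factor(x$class[, s],
                          levels = c("PromoterOCR", "PIR_OCR", "NonPIR_OCR")))
      cat(sprintf("  %s: %d promoter / %d PIR / %d non-PIR\n", s,
                  tab[1L], tab[2L], tab[3L]))
    }
  }
  invisible(x)
}

#' Filter capture interactions to the significant set
#'
#' Keeps interactions with score strictly above `score_min` (the
#' CHiCAGO-style "score > 5" rule).  Interactions are carried in ibed
#' coordinates; a call at 4-fragment resolution spans its member
#' fragments, so downstream coordinate overlap automatically projects
#' 4-fragment significance onto the constituent single fragments.  With
#' `collapse_stages = TRUE` a bait/other-end pair significant in any stage
#' is returned once per stage it was tested in (the "significant in at
#' least one cell type" union reading).
#'
#' @param interactions data.frame with columns `bait_chrom`, `bait_start`,
#'   `bait_end`, `oe_chrom`, `oe_start`, `oe_end`, `score`, `resolution`
#'   (`frag1`/`frag4`) and `stage`.
#' @param score_min significance threshold, strict `>` (default 5).
#' @param collapse_stages propagate a pair's significance to every stage
#'   it appears in (default FALSE: stage-specific significance).
#' @return the significant subset, same columns.
#' @export
significant_interactions <- function(interactions, score_min = 5,
                                     collapse_stages = FALSE) {
  need <- c("bait_chrom", "bait_start", "bait_end",
            "oe_chrom", "oe_start", "oe_end", "score", "stage")
  stopifnot(all(need %in% names(interactions)))
  if (nrow(interactions) == 0L) return(interactions)
  sig <- interactions[interactions$score > score_min, , drop = FALSE]
  if (collapse_stages && nrow(sig) > 0L) {
    pair <- function(d) paste(d$bait_chrom, d$bait_start, d$bait_end,
                              d$oe_chrom, d$oe_start, d$oe_end)
    keep <- pair(interactions) %in% unique(pair(sig))
    sig <- interactions[keep, , drop = FALSE]
  }
  rownames(sig) <- NULL
  sig
}

## Other-end regions of significant interactions whose bait fragment
## overlaps the promoter window of a baited gene, per stage (internal).
## Returns oe regions with bait gene annotations.
.contacted_oe <- function(sig_ints, promoters, baited_genes, stage) {
  ints <- sig_ints[sig_ints$stage == stage, , drop = FALSE]
  if (nrow(ints) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), gene_id = character()))
  prom <- promoters[promoters$gene_id %in% baited_genes, , drop = FALSE]
  baits <- regions(ints$bait_chrom, ints$bait_start, ints$bait_end)
  hits <- intersect_regions(baits, prom)
  if (nrow(hits) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), gene_id = character()))
  data.frame(chrom = ints$oe_chrom[hits$a_idx],
             start = ints$oe_start[hits$a_idx],
             end = ints$oe_end[hits$a_idx],
             gene_id = prom$gene_id[hits$b_idx],
             stringsAsFactors = FALSE)
}

#' Classify open OCRs into promoter / PIR / non-PIR classes
#'
#' Per stage, every OCR open in that stage receives exactly one class by
#' priority: `PromoterOCR` if it overlaps any promoter window; otherwise
#' `PIR_OCR` if it overlaps (>= 1 bp) the other-end region of a
#' stage-significant interaction whose bait overlaps a baited gene's
#' promoter; otherwise `NonPIR_OCR`.  OCRs closed in a stage get `NA`
#' there.  Promoter-class and PIR-class OCRs are the putative cREs.
#'
#' @param atlas `ocr_atlas` from [quantify_openness()].
#' @param promoters promoter windows with `gene_id`
#'   ([promoter_windows()]).
#' @param sig_ints significant interactions
#'   ([significant_interactions()]).
#' @param baited_genes character vector of gene ids whose promoters were
#'   baited in the capture design; defaults to all genes in `promoters`.
#' @return the atlas with its `class` matrix (OCR x stage) filled in.
#' @export
classify_ocrs <- function(atlas, promoters, sig_ints,
                          baited_genes = unique(promoters$gene_id)) {
  stopifnot(inherits(atlas, "ocr_atlas"))
  ocrs <- atlas$ocrs
  cls <- matrix(NA_character_, nrow(ocrs), length(atlas$stages),
                dimnames = list(ocrs$ocr_id, atlas$stages))
  prom_hit <- rep(FALSE, nrow(ocrs))
  if (nrow(promoters) > 0L)
    prom_hit[unique(intersect_regions(ocrs, promoters)$a_idx)] <- TRUE
  for (s in atlas$stages) {
    oe <- .contacted_oe(sig_ints, promoters, baited_genes, s)
    pir_hit <- rep(FALSE, nrow(ocrs))
    if (nrow(oe) > 0L)
      pir_hit[unique(intersect_regions(ocrs, oe)$a_idx)] <- TRUE
    open_s <- atlas$open[, s]
    cls[open_s, s] <- ifelse(prom_hit[open_s], "PromoterOCR",
                             ifelse(pir_hit[open_s], "PIR_OCR", "NonPIR_OCR"))
  }
  atlas$class <- cls
  atlas
}

#' Map classified OCRs to the genes they regulate
#'
#' Promoter-class OCRs link to every gene whose promoter window they
#' overlap (route `promoter`); PIR-class OCRs link to the bait gene(s) of
#' the significant interaction(s) whose other-end region they overlap
#' (route `contact`).  Distances are |OCR midpoint - TSS|.
#'
#' @param atlas classified `ocr_atlas` ([classify_ocrs()]).
#' @param promoters promoter windows with `gene_id`.
#' @param sig_ints significant interactions.
#' @param gm [gene_models()] object (for TSS positions).
#' @param baited_genes baited gene ids; defaults to all in `promoters`.
#' @return list with `links` (data.frame: `gene_id`, `ocr_id`, `stage`,
#'   `route`, `distance_bp`) and `per_gene` (data.frame: `gene_id`,
#'   `stage`, `n_cre`, `mean_distance_bp`).
#' @export
gene_cre_map <- function(atlas, promoters, sig_ints, gm,
                         baited_genes = unique(promoters$gene_id)) {
  stopifnot(inherits(atlas, "ocr_atlas"), !is.null(atlas$class))
  ocrs <- atlas$ocrs
  tss <- stats::setNames(gm$genes$tss, gm$genes$gene_id)
  mid <- (ocrs$start + ocrs$end) / 2
  out <- list()
  for (s in atlas$stages) {
    cls <- atlas$class[, s]
    is_prom <- !is.na(cls) & cls == "PromoterOCR"
    if (any(is_prom)) {
      hits <- intersect_regions(ocrs[is_prom, , drop = FALSE], promoters)
      if (nrow(hits) > 0L) {
        oi <- which(is_prom)[hits$a_idx]
        out[[length(out) + 1L]] <- data.frame(
          gene_id = promoters$gene_id[hits$b_idx],
          ocr_id = ocrs$ocr_id[oi], stage = s, route = "promoter",
          distance_bp = abs(mid[oi] - tss[promoters$gene_id[hits$b_idx]]),
          stringsAsFactors = FALSE)
      }
    }
    is_pir <- !is.na(cls) & cls == "PIR_OCR"
    if (any(is_pir)) {
      oe <- .contacted_oe(sig_ints, promoters, baited_genes, s)
      if (nrow(oe) > 0L) {
        hits <- intersect_regions(ocrs[is_pir, , drop = FALSE], oe)
        if (nrow(hits) > 0L) {
          oi <- which(is_pir)[hits$a_idx]
          out[[length(out) + 1L]] <- data.frame(
            gene_id = oe$gene_id[hits$b_idx],
            ocr_id = ocrs$ocr_id[oi], stage = s, route = "contact",
            distance_bp = abs(mid[oi] - tss[oe$gene_id[hits$b_idx]]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  links <- if (length(out) > 0L) unique(do.call(rbind, out)) else
    data.frame(gene_id = character(), ocr_id = character(),
               stage = character(), route = character(),
               distance_bp = numeric())
  rownames(links) <- NULL
  per_gene <- if (nrow(links) > 0L) {
    agg <- stats::aggregate(distance_bp ~ gene_id + stage, links,
                            function(d) c(n = length(d), mean = mean(d)))
    data.frame(gene_id = agg$gene_id, stage = agg$stage,
               n_cre = as.integer(agg$distance_bp[, "n"]),
               mean_distance_bp = agg$distance_bp[, "mean"],
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = character(), stage = character(),
               n_cre = integer(), mean_distance_bp = numeric())
  }
  list(links = links, per_gene = per_gene)
}
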