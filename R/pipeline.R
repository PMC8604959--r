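#' Default pipeline configuration
#'
#' Every threshold of the analysis in one auditable list; no stage
#' hard-codes a numeric cutoff.  Defaults are the published values:
#' r-squared > 0.6 for LD proxies, interaction score > 5, TPM > 1 for
#' expression, stage-mean FPKM > 1 for openness, median-CPM filters of
#' 0.7 (expression) and 1.2 (accessibility), FDR < 0.05 with
#' |log2FC| > 1 for differential calls, footprint purity > 0.7, 10,000
#' permutations, and six expression clusters.
#'
#' @param input_dir directory of input files (layout as written by
#'   [simulate_dataset()]).
#' @param out_dir directory for results.
#' @param seed RNG seed for the permutation statistics.
#' @param ... named overrides of any threshold.
#' @return a `run_config` list.
#' @export
default_config <- function(input_dir = NULL, out_dir = NULL, seed = 1L, ...) {
  cfg <- list(input_dir = input_dir, out_dir = out_dir, seed = seed,
              r2_min = 0.6, score_min = 5, tpm_min = 1, fpkm_open = 1,
              cpm_filter_rna = 0.7, cpm_filter_atac = 1.2,
              fdr = 0.05, lfc = 1, purity_min = 0.7,
              n_perm = 10000L, k_clusters = 6L,
              promoter_upstream = 1500L, promoter_downstream = 500L,
              consensus_mode = "per_stage")
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Loads a YAML file of threshold overrides on top of
#' [default_config()], so that the ~12 coupled thresholds of a run are
#' auditable in one document.  Unknown keys are an error.
#'
#' @param path YAML file; top-level keys must be `run_config` fields.
#' @return a `run_config` list.
#' @export
read_config <- function(path) {
  over <- yaml::read_yaml(path)
  do.call(default_config, over)
}

## Read the standard input bundle from a dataset directory (internal).
read_inputs <- function(dir) {
  tsv <- function(f) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("missing input file: ", path)
    utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                      check.names = FALSE)
  }
  atac_samples <- tsv("atac_samples.tsv")
  peaks <- do.call(rbind, lapply(seq_len(nrow(atac_samples)), function(i) {
    f <- file.path(dir, "peaks", paste0(atac_samples$sample_id[i], ".bed"))
    if (!file.exists(f)) stop("missing peak file: ", f)
    df <- read_bed(f)
    df$sample_id <- atac_samples$sample_id[i]
    df$stage <- atac_samples$stage[i]
    df
  }))
  ac <- tsv("atac_counts.tsv")
  lib <- tsv("atac_lib_sizes.tsv")
  bins <- tsv("bin_counts.tsv")
  rna_samples <- tsv("rna_samples.tsv")
  rc <- tsv("rna_counts.tsv")
  rt <- tsv("rna_tpm.tsv")
  list(
    atac_samples = atac_samples,
    peaks = peaks,
    atac_counts = local({
      m <- as.matrix(ac[, atac_samples$sample_id, drop = FALSE])
      rownames(m) <- ac$ocr_id; m
    }),
    atac_regions = ac[, c("ocr_id", "chrom", "start", "end")],
    lib_sizes = stats::setNames(lib$lib_size, lib$sample_id),
    bin_counts = as.matrix(bins[, atac_samples$sample_id, drop = FALSE]),
    interactions = tsv("interactions.ibed"),
    gm = read_gtf_genes(file.path(dir, "genes.gtf")),
    fm = read_fragment_map(file.path(dir, "fragments.bed")),
    baited_genes = readLines(file.path(dir, "baited_genes.txt")),
    rna_samples = rna_samples,
    rna_counts = local({
      m <- as.matrix(rc[, rna_samples$sample_id, drop = FALSE])
      rownames(m) <- rc$gene_id; m
    }),
    rna_tpm = local({
      m <- as.matrix(rt[, rna_samples$sample_id, drop = FALSE])
      rownames(m) <- rt$gene_id; m
    }),
    traits = tsv("traits.tsv"))
}

#' Build and classify the OCR atlas from a dataset directory
#'
#' Consensus building from the replicate peak files, FPKM openness,
#' interaction significance filtering, promoter/PIR/non-PIR
#' classification and the gene-cRE map, written as TSV/BED under
#' `config$out_dir/atlas`.
#'
#' @param config a [default_config()] with `input_dir` (and optionally
#'   `out_dir`) set.
#' @param inputs optional pre-read input bundle (internal reuse).
#' @return list with the classified `atlas`, `sig_ints`, `promoters`,
#'   `gene_map` and the input bundle.
#' @export
run_atlas <- function(config, inputs = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(inputs)) inputs <- read_inputs(config$input_dir)
  consensus <- build_consensus(inputs$peaks, mode = config$consensus_mode)
  ## align the provided count rows to the consensus we just built
  idx <- match(consensus$ocr_id, rownames(inputs$atac_counts))
  if (any(is.na(idx)))
    stop("count matrix does not cover the consensus set (",
         sum(is.na(idx)), " regions missing)")
  counts <- inputs$atac_counts[idx, , drop = FALSE]
  atlas <- quantify_openness(consensus, counts, inputs$atac_samples,
                             lib_sizes = inputs$lib_sizes,
                             fpkm_open = config$fpkm_open)
  promoters <- promoter_windows(inputs$gm, config$promoter_upstream,
                                config$promoter_downstream)
  sig_ints <- significant_interactions(inputs$interactions,
                                       score_min = config$score_min)
  atlas <- classify_ocrs(atlas, promoters, sig_ints, inputs$baited_genes)
  gene_map <- gene_cre_map(atlas, promoters, sig_ints, inputs$gm,
                           inputs$baited_genes)
  if (!is.null(config$out_dir)) {
    adir <- file.path(config$out_dir, "atlas")
    dir.create(adir, recursive = TRUE, showWarnings = FALSE)
    out <- data.frame(atlas$ocrs,
                      stats::setNames(as.data.frame(atlas$mean_fpkm),
                                      paste0("fpkm_", atlas$stages)),
                      stats::setNames(as.data.frame(atlas$open),
                                      paste0("open_", atlas$stages)),
                      stats::setNames(as.data.frame(atlas$class),
                                      paste0("class_", atlas$stages)),
                      check.names = FALSE)
    utils::write.table(out, file.path(adir, "ocrs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_bed(data.frame(atlas$ocrs[, c("chrom", "start", "end")],
                         name = atlas$ocrs$ocr_id),
              file.path(adir, "ocrs.bed"))
    utils::write.table(gene_map$links, file.path(adir, "gene_cre_links.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(gene_map$per_gene, file.path(adir, "gene_cre_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(atlas = atlas, sig_ints = sig_ints, promoters = promoters,
       gene_map = gene_map, inputs = inputs)
}

#' Variant-to-gene mapping from a built atlas
#'
#' LD proxy expansion, open-proxy detection, promoter-contact gene
#' assignment (distal-PIR and bait-OCR routes), expression filtering,
#' per-trait summaries and the exclusive cross-trait gene overlap.
#'
#' @param config a [default_config()].
#' @param atlas_run result of [run_atlas()]; built on the fly if NULL.
#' @return list with `records`, `signals`, `summary`, `overlap`.
#' @export
run_v2g <- function(config, atlas_run = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(atlas_run)) atlas_run <- run_atlas(config)
  inputs <- atlas_run$inputs
  signals <- expand_proxies(inputs$traits, r2_min = config$r2_min)
  hits <- find_open_proxies(signals, atlas_run$atlas)
  records <- map_to_genes(hits, atlas_run$atlas, atlas_run$sig_ints,
                          inputs$fm, inputs$gm, atlas_run$promoters,
                          inputs$baited_genes)
  records <- filter_expressed(records, inputs$rna_tpm, inputs$rna_samples,
                              tpm_min = config$tpm_min)
  summary <- summarize_trait(records, signals,
                             stages = atlas_run$atlas$stages)
  all_traits <- unique(inputs$traits$trait)
  overlap <- if (length(all_traits) >= 2L) {
    sets <- lapply(stats::setNames(all_traits, all_traits), function(tr)
      unique(records$gene_id[records$trait == tr]))
    cross_trait_overlap(sets)
  } else NULL
  if (!is.null(config$out_dir)) {
    vdir <- file.path(config$out_dir, "v2g")
    dir.create(vdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(records, file.path(vdir, "records.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(summary, file.path(vdir, "trait_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(overlap))
      utils::write.table(overlap, file.path(vdir, "cross_trait_overlap.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(records = records, signals = signals, summary = summary,
       overlap = overlap)
}

#' Run the full pipeline end to end
#'
#' Atlas construction, RNA differential expression between consecutive
#' stages with TMM normalization, trajectory clustering of the DE genes,
#' differential accessibility with background-bin normalization,
#' variant-to-gene mapping, and a machine-readable JSON report of every
#' summary table.
#'
#' @param config a [default_config()] with `input_dir` and `out_dir`
#'   set.
#' @param simulate optional [simulate_config()]; when given, the
#'   synthetic dataset is generated into `config$input_dir` first.
#' @return list with `atlas`, `v2g`, `de`, `clusters`, `da`, `report`
#'   (also written to `out_dir/report.json`).
#' @export
run_all <- function(config, simulate = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(simulate)) simulate_dataset(simulate, config$input_dir)
  atlas_run <- run_atlas(config)
  inputs <- atlas_run$inputs
  stages <- atlas_run$atlas$stages

  ## RNA: median-CPM filter, TMM, per-contrast NB exact tests
  rc <- filter_by_median_cpm(inputs$rna_counts, config$cpm_filter_rna)
  rna_factors <- tmm_factors(rc)
  de <- list()
  for (i in seq_len(length(stages) - 1L)) {
    s1 <- stages[i]; s2 <- stages[i + 1L]
    cols <- inputs$rna_samples$stage %in% c(s1, s2)
    res <- differential_test(
      rc[, cols, drop = FALSE],
      factor(inputs$rna_samples$stage[cols], levels = c(s1, s2)),
      factors = rna_factors[cols],
      lib_sizes = colSums(inputs$rna_counts)[cols],
      alpha = config$fdr, lfc_min = config$lfc)
    de[[paste0(s1, "_vs_", s2)]] <- res
  }
  de_genes <- unique(unlist(lapply(de, function(d) d$row_id[d$call != "ns"])))

  ## trajectory clustering of DE genes on the TPM table
  clusters <- NULL
  if (length(de_genes) >= config$k_clusters) {
    clusters <- cluster_de_genes(inputs$rna_tpm[de_genes, , drop = FALSE],
                                 k = config$k_clusters,
                                 stages = inputs$rna_samples$stage)
  }

  ## ATAC: background-bin normalization, per-contrast tests
  bin_f <- background_bin_factors(inputs$bin_counts)
  acc <- filter_by_median_cpm(inputs$atac_counts, config$cpm_filter_atac)
  da <- list()
  for (i in seq_len(length(stages) - 1L)) {
    s1 <- stages[i]; s2 <- stages[i + 1L]
    cols <- inputs$atac_samples$stage %in% c(s1, s2)
    res <- differential_test(
      acc[, cols, drop = FALSE],
      factor(inputs$atac_samples$stage[cols], levels = c(s1, s2)),
      factors = bin_f[cols],
      lib_sizes = inputs$lib_sizes[cols],
      alpha = config$fdr, lfc_min = config$lfc)
    da[[paste0(s1, "_vs_", s2)]] <- res
  }

  v2g <- run_v2g(config, atlas_run)

  class_counts <- lapply(stages, function(s)
    as.list(table(factor(atlas_run$atlas$class[, s],
                         levels = c("PromoterOCR", "PIR_OCR", "NonPIR_OCR")))))
  names(class_counts) <- stages
  report <- list(
    n_consensus_ocrs = nrow(atlas_run$atlas$ocrs),
    open_per_stage = as.list(colSums(atlas_run$atlas$open)),
    class_counts = class_counts,
    n_de_genes = length(de_genes),
    de_calls = lapply(de, function(d) as.list(table(d$call))),
    da_calls = lapply(da, function(d) as.list(table(d$call))),
    trait_summary = v2g$summary,
    cross_trait_overlap = v2g$overlap)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    for (nm in names(de))
      utils::write.table(de[[nm]],
                         file.path(config$out_dir, paste0("de_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    for (nm in names(da))
      utils::write.table(da[[nm]],
                         file.path(config$out_dir, paste0("da_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(clusters))
      utils::write.table(
        data.frame(gene_id = names(clusters$cluster),
                   cluster = as.integer(clusters$cluster)),
        file.path(config$out_dir, "de_clusters.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(atlas = atlas_run, v2g = v2g, de = de, clusters = clusters, da = da,
       report = report)
}

#' Validate a synthetic dataset against its ground-truth manifest
#'
#' Re-derives the pipeline-facing facts the manifest asserts and checks
#' each one: consensus regions match the planted reproducible set;
#' openness and classes match the planted labels; planted contacts are
#' present and significant; planted V2G links survive the whole filter
#' chain and every decoy fails exactly its own filter.
#'
#' @param dir dataset directory written by [simulate_dataset()].
#' @param config optional [default_config()] for thresholds.
#' @return list with `ok` (logical) and `failures` (character vector of
#'   messages, empty when `ok`).
#' @export
validate_manifest <- function(dir, config = default_config()) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop("missing manifest: ", mf_path)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  failures <- character()
  note <- function(msg) failures <<- c(failures, msg)
  for (f in mf$files)
    if (!file.exists(file.path(dir, f))) note(paste("missing file:", f))
  if (length(failures) > 0L) return(list(ok = FALSE, failures = failures))
  config$input_dir <- dir
  config$out_dir <- NULL
  ar <- run_atlas(config)
  atlas <- ar$atlas
  reg <- mf$regions
  if (nrow(atlas$ocrs) != nrow(reg)) {
    note(sprintf("consensus has %d regions, manifest %d",
                 nrow(atlas$ocrs), nrow(reg)))
  } else {
    m <- match(reg$ocr_id, atlas$ocrs$ocr_id)
    if (any(is.na(m))) {
      note("manifest regions missing from consensus")
    } else {
      for (s in mf$stages) {
        open_ok <- atlas$open[m, s] == reg[[paste0("open_", s)]]
        if (!all(open_ok))
          note(sprintf("openness mismatch in %s: %s", s,
                       paste(reg$ocr_id[!open_ok], collapse = ", ")))
        truth_cls <- reg[[paste0("class_", s)]]
        cls_ok <- ifelse(is.na(truth_cls), is.na(atlas$class[m, s]),
                         !is.na(atlas$class[m, s]) &
                           atlas$class[m, s] == truth_cls)
        if (!all(cls_ok))
          note(sprintf("class mismatch in %s: %s", s,
                       paste(reg$ocr_id[!cls_ok], collapse = ", ")))
      }
    }
  }
  ## planted contacts significant and annotated to the right bait gene
  ints <- ar$sig_ints
  for (i in seq_len(nrow(mf$contacts))) {
    ct <- mf$contacts[i, ]
    ok <- any(ints$bait_name == ct$bait_gene & ints$stage == ct$stage &
                ints$score > config$score_min)
    if (!ok) note(sprintf("planted contact missing: %s in %s",
                          ct$bait_gene, ct$stage))
  }
  ## V2G recovery and decoy rejection
  v2g <- run_v2g(config, ar)
  rec_key <- paste(v2g$records$trait, v2g$records$proxy,
                   v2g$records$gene_id, v2g$records$stage)
  for (i in seq_len(nrow(mf$v2g_links))) {
    lk <- mf$v2g_links[i, ]
    for (s in strsplit(lk$stages, ",")[[1]]) {
      if (!paste(lk$trait, lk$proxy, lk$gene_id, s) %in% rec_key)
        note(sprintf("planted link not recovered: %s %s -> %s (%s)",
                     lk$trait, lk$proxy, lk$gene_id, s))
    }
  }
  decoy_hit <- v2g$records$proxy %in% mf$decoys$proxy
  if (any(decoy_hit))
    note(paste("decoy proxies produced records:",
               paste(unique(v2g$records$proxy[decoy_hit]), collapse = ", ")))
  list(ok = length(failures) == 0L, failures = failures)
}
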