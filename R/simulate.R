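#' Configuration for the synthetic differentiation dataset
#'
#' Parameters of the toy dataset emulating a three-stage in vitro
#' differentiation study: a small random genome, evenly spaced genes with
#' promoter windows, replicate ATAC peak sets with reproducibility noise,
#' negative-binomial count matrices with planted trajectory archetypes and
#' differential regions, a restriction-fragment map with baited promoter
#' fragments, capture interactions with planted significant contacts, and
#' GWAS-style trait tables whose planted proxies survive the whole
#' variant-to-gene filter chain while four decoy classes each violate
#' exactly one filter.
#'
#' @param seed master seed; every downstream draw flows from it.
#' @param n_chrom,chrom_length genome shape (default 2 x 1 Mb).
#' @param motif restriction motif (default `"GATC"`, DpnII).
#' @param atac_reps named replicate counts per stage (default
#'   `c(ESC = 4, HP = 4, HN = 6)`, the study design emulated).
#' @param rna_reps RNA replicates per stage (default 3).
#' @param genes_per_chrom gene slots per chromosome (default 30).
#' @param dispersion NB dispersion of all count draws (default 0.05).
#' @param dropout peak-dropout rate per replicate, capped so planted
#'   regions stay reproducible (default 0.15).
#' @param atac_lib,rna_depth nominal ATAC library size (total mapped
#'   reads) and RNA reads per TPM unit.
#' @param fpkm_open,fpkm_closed stage-mean FPKM targets for open/closed
#'   regions (8 / 0.1; the openness call is at FPKM > 1).
#' @param fpkm_da_high,fpkm_da_low FPKM targets flanking planted 4-fold
#'   differential regions (24 / 6).
#' @param tpm_high,tpm_base,tpm_low TPM archetype levels (60 / 7.5 /
#'   20 flat) and `tpm_off = 0.3` for planted not-expressed genes.
#' @param tpm_flat TPM of non-differential expressed genes (default 20).
#' @param tpm_off TPM of planted not-expressed genes (default 0.3).
#' @param score_sig,score_decoy score ranges for planted significant and
#'   decoy contacts (U(6,12) and U(0.5,4.9) around the >5 rule).
#' @return a `sim_config` list.
#' @export
simulate_config <- function(seed = 1L, n_chrom = 2L, chrom_length = 1e6,
                            motif = "GATC",
                            atac_reps = c(ESC = 4L, HP = 4L, HN = 6L),
                            rna_reps = 3L, genes_per_chrom = 30L,
                            dispersion = 0.05, dropout = 0.15,
                            atac_lib = 5e6, rna_depth = 10,
                            fpkm_open = 8, fpkm_closed = 0.1,
                            fpkm_da_high = 24, fpkm_da_low = 6,
                            tpm_high = 60, tpm_base = 7.5,
                            tpm_flat = 20, tpm_off = 0.3,
                            score_sig = c(6, 12),
                            score_decoy = c(0.5, 4.9)) {
  cfg <- as.list(environment())
  cfg$stages <- names(atac_reps)
  n_genes <- n_chrom * genes_per_chrom
  if (n_genes < 49L)
    stop("infeasible config: need at least 49 gene slots for the planted roles")
  if (chrom_length < (genes_per_chrom + 1) * 30000)
    stop("infeasible config: chromosome too short for the gene slots")
  structure(cfg, class = "sim_config")
}

## Deterministic gene/slot layout (internal).  Slot i on a chromosome is
## [i*30000 + 10000, i*30000 + 40000); auxiliary regions sit at fixed
## slot-relative offsets well clear of every promoter window.
.sim_layout <- function(cfg) {
  n_genes <- cfg$n_chrom * cfg$genes_per_chrom
  idx <- seq_len(n_genes)
  chrom <- paste0("chr", rep(seq_len(cfg$n_chrom), each = cfg$genes_per_chrom))
  slot <- rep(seq_len(cfg$genes_per_chrom) - 1L, cfg$n_chrom)
  base <- slot * 30000L + 10000L
  strand <- ifelse(idx %% 2L == 1L, "+", "-")
  tss <- ifelse(strand == "+", base + 2000L, base + 4999L)
  gene_id <- sprintf("G%03d", idx)
  ## expression roles
  cluster <- rep(NA_integer_, n_genes)
  cluster[1:36] <- ((1:36 - 1L) %% 6L) + 1L
  expr_role <- rep("flat", n_genes)
  expr_role[1:36] <- "cluster"
  expr_role[37:40] <- "off"
  ## contact roles for the PIR-slot OCR
  contact <- rep("frag1", n_genes)      # significant contact, all stages
  contact[39:40] <- "none"              # no interaction row at all
  contact[41:44] <- "decoy"             # sub-threshold score only
  contact[45:46] <- "hp_only"           # significant in HP only
  contact[47:49] <- "frag4"             # significant, 4-fragment call only
  ## planted differential-accessibility roles for the non-PIR OCR
  da <- rep("flat", n_genes)
  da[1:5] <- "esc_hp_up"; da[6:10] <- "esc_hp_down"
  da[11:15] <- "hp_hn_up"; da[16:20] <- "hp_hn_down"
  data.frame(gene_id, chrom, base, strand, tss, cluster, expr_role,
             contact, da, stringsAsFactors = FALSE)
}

## Planted OCR table from the layout (internal): one promoter, PIR-slot,
## non-PIR and closed OCR per gene, plus an irreproducible decoy peak.
.sim_ocrs <- function(layout) {
  plus <- layout$strand == "+"
  prom_start <- ifelse(plus, layout$tss - 150L, layout$tss - 149L)
  mk <- function(kind, start, len = 300L, reproducible = TRUE) {
    data.frame(gene_id = layout$gene_id, chrom = layout$chrom,
               start = as.integer(start), end = as.integer(start + len),
               kind = kind, reproducible = reproducible,
               stringsAsFactors = FALSE)
  }
  rbind(mk("promoter", prom_start),
        mk("pir", layout$base + 12000L),
        mk("nonpir", layout$base + 18000L),
        mk("closed", layout$base + 21000L),
        mk("noise", layout$base + 24000L, reproducible = FALSE))
}

## Per-stage FPKM targets per planted OCR (internal).
.sim_fpkm_targets <- function(ocrs, layout, cfg) {
  stages <- cfg$stages
  tgt <- matrix(cfg$fpkm_open, nrow(ocrs), length(stages),
                dimnames = list(NULL, stages))
  role <- layout[match(ocrs$gene_id, layout$gene_id), ]
  closed_rows <- ocrs$kind == "closed"
  tgt[closed_rows, ] <- cfg$fpkm_closed
  hp_only <- ocrs$kind == "pir" & role$contact == "hp_only"
  tgt[hp_only, ] <- cfg$fpkm_closed
  tgt[hp_only, "HP"] <- cfg$fpkm_open
  np <- ocrs$kind == "nonpir"
  set <- function(rows, esc, hp, hn) {
    tgt[rows, "ESC"] <<- esc; tgt[rows, "HP"] <<- hp; tgt[rows, "HN"] <<- hn
  }
  set(np & role$da == "esc_hp_up", cfg$fpkm_da_low, cfg$fpkm_da_high,
      cfg$fpkm_da_high)
  set(np & role$da == "esc_hp_down", cfg$fpkm_da_high, cfg$fpkm_da_low,
      cfg$fpkm_da_low)
  set(np & role$da == "hp_hn_up", cfg$fpkm_da_low, cfg$fpkm_da_low,
      cfg$fpkm_da_high)
  set(np & role$da == "hp_hn_down", cfg$fpkm_da_high, cfg$fpkm_da_high,
      cfg$fpkm_da_low)
  tgt[ocrs$kind == "noise", ] <- cfg$fpkm_open
  tgt
}

## Per-stage TPM targets per gene (internal).  Six archetypes: enriched
## (clusters 1-3) or depleted (4-6) in exactly one stage.
.sim_tpm_targets <- function(layout, cfg) {
  tgt <- matrix(cfg$tpm_flat, nrow(layout), 3L,
                dimnames = list(layout$gene_id, cfg$stages))
  for (i in seq_len(nrow(layout))) {
    cl <- layout$cluster[i]
    if (!is.na(cl)) {
      if (cl <= 3L) {
        tgt[i, ] <- cfg$tpm_base; tgt[i, cl] <- cfg$tpm_high
      } else {
        tgt[i, ] <- cfg$tpm_high; tgt[i, cl - 3L] <- cfg$tpm_base
      }
    } else if (layout$expr_role[i] == "off") {
      tgt[i, ] <- cfg$tpm_off
    }
  }
  tgt
}

rnbinom_mat <- function(n, mu, dispersion) {
  if (dispersion <= 0) return(stats::rpois(n, mu))
  stats::rnbinom(n, size = 1 / dispersion, mu = mu)
}

#' Generate the synthetic dataset
#'
#' Writes every input file the pipeline consumes, plus a ground-truth
#' manifest (`manifest.json`), into `out_dir`.  All randomness flows from
#' `config$seed`; the same configuration always produces byte-identical
#' output.
#'
#' @param config a [simulate_config()] object.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `dir`, the `manifest` (as an R list)
#'   and the planted tables used to build it.
#' @export
simulate_dataset <- function(config = simulate_config(), out_dir) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "peaks"), showWarnings = FALSE)
  set.seed(cfg$seed, kind = "Mersenne-Twister")

  ## -- genome and fragment map ------------------------------------------
  chroms <- paste0("chr", seq_len(cfg$n_chrom))
  genome <- vapply(chroms, function(ch)
    paste(sample(c("A", "C", "G", "T"), cfg$chrom_length, replace = TRUE),
          collapse = ""), character(1))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome),
    file.path(out_dir, "genome.fa"), width = 80L)
  fm <- digest_genome(genome, cfg$motif)
  write_fragment_map(fm, file.path(out_dir, "fragments.bed"))

  ## -- genes -------------------------------------------------------------
  layout <- .sim_layout(cfg)
  .sim_write_gtf(layout, file.path(out_dir, "genes.gtf"))
  gm <- .sim_gene_models(layout)
  promoters <- promoter_windows(gm)
  writeLines(layout$gene_id, file.path(out_dir, "baited_genes.txt"))

  ## -- planted OCRs and replicate peaks ---------------------------------
  ocrs <- .sim_ocrs(layout)
  stopifnot(nrow(intersect_regions(
    ocrs[ocrs$kind %in% c("pir", "nonpir", "closed", "noise"), ],
    promoters)) == 0L)
  atac_samples <- do.call(rbind, lapply(cfg$stages, function(s)
    data.frame(sample_id = sprintf("%s_rep%d", s, seq_len(cfg$atac_reps[[s]])),
               stage = s, stringsAsFactors = FALSE)))
  ## presence mask: reproducible regions start in every replicate, then
  ## lose random replicates (never below half per stage); noise peaks sit
  ## in a single replicate per stage so the consensus filter drops them
  rep_mask <- matrix(FALSE, nrow(ocrs), nrow(atac_samples),
                     dimnames = list(NULL, atac_samples$sample_id))
  rep_mask[ocrs$reproducible, ] <- TRUE
  first_rep <- atac_samples$sample_id[!duplicated(atac_samples$stage)]
  rep_mask[!ocrs$reproducible, first_rep] <- TRUE
  for (j in which(ocrs$reproducible)) {
    for (s in cfg$stages) {
      cols <- which(atac_samples$stage == s)
      r <- length(cols)
      max_drop <- r - ceiling(r / 2)
      n_drop <- min(stats::rbinom(1L, r, cfg$dropout), max_drop)
      if (n_drop > 0L)
        rep_mask[j, cols[sample.int(r, n_drop)]] <- FALSE
    }
  }
  for (i in seq_len(nrow(atac_samples))) {
    sel <- ocrs[rep_mask[, i], c("chrom", "start", "end")]
    sel <- sel[order(sel$chrom, sel$start), ]
    write_bed(sel, file.path(out_dir, "peaks",
                             paste0(atac_samples$sample_id[i], ".bed")))
  }

  ## -- consensus (must reproduce the planted reproducible set) ----------
  peaks <- do.call(rbind, lapply(seq_len(nrow(atac_samples)), function(i) {
    df <- read_bed(file.path(out_dir, "peaks",
                             paste0(atac_samples$sample_id[i], ".bed")))
    df$sample_id <- atac_samples$sample_id[i]
    df$stage <- atac_samples$stage[i]
    df
  }))
  consensus <- build_consensus(peaks)
  planted <- ocrs[ocrs$reproducible, , drop = FALSE]
  planted <- planted[order(planted$chrom, planted$start), , drop = FALSE]
  stopifnot(nrow(consensus) == nrow(planted),
            all(consensus$start == planted$start),
            all(consensus$end == planted$end))
  planted$ocr_id <- consensus$ocr_id

  ## -- ATAC counts, library sizes, background bins ----------------------
  lib_sizes <- round(cfg$atac_lib * stats::runif(nrow(atac_samples), 0.9, 1.1))
  names(lib_sizes) <- atac_samples$sample_id
  tgt <- .sim_fpkm_targets(planted, layout, cfg)
  len_kb <- (planted$end - planted$start) / 1000
  counts <- matrix(0L, nrow(planted), nrow(atac_samples),
                   dimnames = list(consensus$ocr_id, atac_samples$sample_id))
  for (i in seq_len(nrow(atac_samples))) {
    mu <- tgt[, atac_samples$stage[i]] * len_kb * lib_sizes[i] / 1e6
    counts[, i] <- rnbinom_mat(nrow(planted), mu, cfg$dispersion)
  }
  utils::write.table(
    data.frame(ocr_id = consensus$ocr_id, consensus[, c("chrom", "start", "end")],
               counts, check.names = FALSE),
    file.path(out_dir, "atac_counts.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = atac_samples$sample_id, lib_size = lib_sizes),
    file.path(out_dir, "atac_lib_sizes.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(atac_samples, file.path(out_dir, "atac_samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  bins <- do.call(rbind, lapply(chroms, function(ch)
    data.frame(chrom = ch,
               start = seq(0L, cfg$chrom_length - 10000L, by = 10000L),
               stringsAsFactors = FALSE)))
  bins$end <- bins$start + 10000L
  bin_counts <- matrix(rnbinom_mat(nrow(bins) * nrow(atac_samples), 50,
                                   cfg$dispersion),
                       nrow(bins), nrow(atac_samples),
                       dimnames = list(NULL, atac_samples$sample_id))
  utils::write.table(data.frame(bins, bin_counts, check.names = FALSE),
                     file.path(out_dir, "bin_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## -- capture interactions ---------------------------------------------
  ints <- .sim_interactions(planted, layout, gm, fm, cfg)
  utils::write.table(ints$table, file.path(out_dir, "interactions.ibed"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## -- expression ---------------------------------------------------------
  rna_samples <- do.call(rbind, lapply(cfg$stages, function(s)
    data.frame(sample_id = sprintf("%s_rna%d", s, seq_len(cfg$rna_reps)),
               stage = s, stringsAsFactors = FALSE)))
  tpm_tgt <- .sim_tpm_targets(layout, cfg)
  rna_counts <- matrix(0L, nrow(layout), nrow(rna_samples),
                       dimnames = list(layout$gene_id, rna_samples$sample_id))
  tpm_obs <- matrix(0, nrow(layout), nrow(rna_samples),
                    dimnames = list(layout$gene_id, rna_samples$sample_id))
  for (i in seq_len(nrow(rna_samples))) {
    mu <- tpm_tgt[, rna_samples$stage[i]] * cfg$rna_depth
    rna_counts[, i] <- rnbinom_mat(nrow(layout), mu, cfg$dispersion)
    tpm_obs[, i] <- tpm_tgt[, rna_samples$stage[i]] *
      exp(stats::rnorm(nrow(layout), 0, 0.1))
  }
  utils::write.table(data.frame(gene_id = layout$gene_id, rna_counts,
                                check.names = FALSE),
                     file.path(out_dir, "rna_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene_id = layout$gene_id,
                                round(tpm_obs, 4), check.names = FALSE),
                     file.path(out_dir, "rna_tpm.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(rna_samples, file.path(out_dir, "rna_samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## -- traits -------------------------------------------------------------
  tr <- .sim_traits(planted, layout, cfg)
  utils::write.table(tr$table, file.path(out_dir, "traits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## -- TF binding sites with covariates -----------------------------------
  tf <- .sim_tf_sites(planted, cfg)
  utils::write.table(tf$sites, file.path(out_dir, "tf_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gc_frac <- .region_gc(planted, genome)
  utils::write.table(
    data.frame(ocr_id = planted$ocr_id, gc = round(gc_frac, 4),
               read_count = rowSums(counts)),
    file.path(out_dir, "region_covariates.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  ## -- ground-truth manifest ----------------------------------------------
  truth_class <- .sim_truth_classes(planted, layout, cfg)
  manifest <- list(
    seed = cfg$seed,
    stages = cfg$stages,
    n_consensus = nrow(planted),
    regions = data.frame(planted[, c("ocr_id", "chrom", "start", "end",
                                     "kind", "gene_id")],
                         truth_class$open, truth_class$class,
                         stringsAsFactors = FALSE),
    de_clusters = stats::setNames(as.list(layout$cluster[!is.na(layout$cluster)]),
                                  layout$gene_id[!is.na(layout$cluster)]),
    off_genes = layout$gene_id[layout$expr_role == "off"],
    da_regions = .sim_truth_da(planted, layout),
    contacts = ints$planted,
    v2g_links = tr$links,
    decoys = tr$decoys,
    enriched_tfs = tf$enriched,
    files = c("genome.fa", "genes.gtf", "fragments.bed", "atac_counts.tsv",
              "atac_lib_sizes.tsv", "atac_samples.tsv", "bin_counts.tsv",
              "interactions.ibed", "rna_counts.tsv", "rna_tpm.tsv",
              "rna_samples.tsv", "traits.tsv", "tf_sites.tsv",
              "region_covariates.tsv", "baited_genes.txt"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(dir = out_dir, manifest = manifest, layout = layout,
                 planted = planted, gene_models = gm))
}

## GC fraction of each region from the in-memory genome (internal).
.region_gc <- function(reg, genome) {
  vapply(seq_len(nrow(reg)), function(i) {
    s <- substr(genome[[reg$chrom[i]]], reg$start[i] + 1L, reg$end[i])
    mean(strsplit(s, "")[[1]] %in% c("G", "C"))
  }, numeric(1))
}

## Gene models straight from the layout (internal).
.sim_gene_models <- function(layout) {
  ex <- do.call(rbind, lapply(seq_len(nrow(layout)), function(i) {
    g <- layout[i, ]
    offs <- if (g$strand == "+") {
      cbind(c(0L, 1500L, 2600L), c(400L, 1900L, 3000L)) + g$tss
    } else {
      g$tss + 1L - cbind(c(3000L, 1900L, 400L), c(2600L, 1500L, 0L))
    }
    data.frame(gene_id = g$gene_id, chrom = g$chrom,
               start = offs[, 1], end = offs[, 2],
               strand = g$strand, stringsAsFactors = FALSE)
  }))
  cds <- do.call(rbind, lapply(seq_len(nrow(layout)), function(i) {
    g <- layout[i, ]
    span <- if (g$strand == "+") c(g$tss + 200L, g$tss + 2800L) else
      c(g$tss + 1L - 2800L, g$tss + 1L - 200L)
    ex_g <- ex[ex$gene_id == g$gene_id, ]
    s <- pmax(ex_g$start, span[1]); e <- pmin(ex_g$end, span[2])
    keep <- s < e
    data.frame(gene_id = g$gene_id, chrom = g$chrom, start = s[keep],
               end = e[keep], stringsAsFactors = FALSE)
  }))
  gene_models(ex, cds = cds)
}

## Write the layout as a minimal GTF (internal).
.sim_write_gtf <- function(layout, path) {
  gm <- .sim_gene_models(layout)
  fmt <- function(df, type) {
    strand <- layout$strand[match(df$gene_id, layout$gene_id)]
    sprintf("%s\tcrev2g_sim\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s.t1\";",
            df$chrom, type, df$start + 1L, df$end, strand, df$gene_id,
            df$gene_id)
  }
  writeLines(c(fmt(gm$exons, "exon"), fmt(gm$cds, "CDS")), path)
}

## Interaction table + planted-contact truth (internal).
.sim_interactions <- function(planted, layout, gm, fm, cfg) {
  fm4 <- bin_fragments(fm, 4L)
  tss_frag <- function(gene) {
    g <- gm$genes[gm$genes$gene_id == gene, ]
    hit <- intersect_regions(regions(g$chrom, g$tss, g$tss + 1L), fm)
    fm[hit$b_idx[1L], c("chrom", "start", "end")]
  }
  oe_frags <- function(ocr_row, map) {
    hit <- intersect_regions(ocr_row[, c("chrom", "start", "end")], map)
    map[hit$b_idx, c("chrom", "start", "end")]
  }
  rows <- list(); truth <- list()
  pir <- planted[planted$kind == "pir", , drop = FALSE]
  for (i in seq_len(nrow(pir))) {
    gene <- pir$gene_id[i]
    role <- layout$contact[layout$gene_id == gene]
    if (role == "none") next
    bait <- tss_frag(gene)
    stages <- switch(role, hp_only = "HP", cfg$stages)
    sig <- role != "decoy"
    use_frag4 <- role == "frag4"
    oe <- if (use_frag4) oe_frags(pir[i, ], fm4)[1, , drop = FALSE] else
      oe_frags(pir[i, ], fm)
    for (s in stages) {
      score <- if (sig) stats::runif(nrow(oe), cfg$score_sig[1], cfg$score_sig[2])
        else stats::runif(nrow(oe), cfg$score_decoy[1], cfg$score_decoy[2])
      rows[[length(rows) + 1L]] <- data.frame(
        bait_chrom = bait$chrom, bait_start = bait$start, bait_end = bait$end,
        bait_name = gene, oe_chrom = oe$chrom, oe_start = oe$start,
        oe_end = oe$end, score = round(score, 3),
        resolution = if (use_frag4) "frag4" else "frag1", stage = s,
        stringsAsFactors = FALSE)
      if (sig)
        truth[[length(truth) + 1L]] <- data.frame(
          bait_gene = gene, ocr_id = pir$ocr_id[i], stage = s,
          resolution = if (use_frag4) "frag4" else "frag1",
          stringsAsFactors = FALSE)
    }
  }
  list(table = do.call(rbind, rows), planted = do.call(rbind, truth))
}

## Truth openness + class matrices per planted OCR (internal).
.sim_truth_classes <- function(planted, layout, cfg) {
  tgt <- .sim_fpkm_targets(planted, layout, cfg)
  open <- tgt > 1
  colnames(open) <- paste0("open_", cfg$stages)
  role <- layout$contact[match(planted$gene_id, layout$gene_id)]
  cls <- matrix(NA_character_, nrow(planted), length(cfg$stages),
                dimnames = list(NULL, paste0("class_", cfg$stages)))
  for (k in seq_along(cfg$stages)) {
    s <- cfg$stages[k]
    contact_sig <- role %in% c("frag1", "frag4") |
      (role == "hp_only" & s == "HP")
    lab <- ifelse(planted$kind == "promoter", "PromoterOCR",
           ifelse(planted$kind == "pir" & contact_sig, "PIR_OCR",
                  "NonPIR_OCR"))
    cls[, k] <- ifelse(open[, k], lab, NA_character_)
  }
  list(open = as.data.frame(open), class = as.data.frame(cls))
}

## Planted differential-accessibility truth (internal).
.sim_truth_da <- function(planted, layout) {
  da <- layout$da[match(planted$gene_id, layout$gene_id)]
  sel <- planted$kind == "nonpir" & da != "flat"
  data.frame(ocr_id = planted$ocr_id[sel],
             contrast = ifelse(grepl("esc_hp", da[sel]),
                               "ESC_vs_HP", "HP_vs_HN"),
             direction = ifelse(grepl("up$", da[sel]), "up", "down"),
             stringsAsFactors = FALSE)
}

## Trait tables: planted links surviving every filter plus one decoy per
## failure class per trait (internal).
.sim_traits <- function(planted, layout, cfg) {
  get_ocr <- function(gene, kind)
    planted[planted$gene_id == gene & planted$kind == kind, ][1, ]
  pos_in <- function(o) as.integer(o$start + 151L)  # 1-based, inside
  sent_pos <- function(gene) {                      # closed intergenic spot
    g <- layout[layout$gene_id == gene, ]
    list(chrom = g$chrom, pos = as.integer(g$base + 27000L))
  }
  traits <- c("BMI", "Height", "AAM")
  ## planted links: (trait, gene, kind, route); G001 shared by BMI+Height
  plan <- list(
    BMI = list(list("G001", "pir", "distal_PIR"),
               list("G050", "promoter", "bait_OCR")),
    Height = list(list("G002", "pir", "distal_PIR"),
                  list("G001", "pir", "distal_PIR"),
                  list("G045", "pir", "distal_PIR")),   # HP-only contact
    AAM = list(list("G047", "pir", "distal_PIR"),       # frag4-only call
               list("G003", "pir", "distal_PIR")))
  decoy_gene <- list(
    low_r2 = c(BMI = "G004", Height = "G005", AAM = "G006"),
    closed = c(BMI = "G007", Height = "G008", AAM = "G009"),
    no_contact = c(BMI = "G041", Height = "G042", AAM = "G043"),
    low_tpm = c(BMI = "G037", Height = "G038", AAM = "G037"))
  rows <- list(); links <- list(); decoys <- list()
  add_row <- function(trait, sentinel, proxy, chrom, pos, r2, in_panel = TRUE)
    rows[[length(rows) + 1L]] <<- data.frame(
      trait = trait, sentinel = sentinel, proxy = proxy, chrom = chrom,
      pos = pos, r2 = r2, in_panel = in_panel, stringsAsFactors = FALSE)
  for (trait in traits) {
    k <- 0L
    for (lk in plan[[trait]]) {
      k <- k + 1L
      gene <- lk[[1]]; kind <- lk[[2]]; route <- lk[[3]]
      o <- get_ocr(gene, kind)
      sentinel <- sprintf("rs_%s_S%d", trait, k)
      proxy <- sprintf("rs_%s_P%d", trait, k)
      sp <- sent_pos(gene)
      add_row(trait, sentinel, sentinel, sp$chrom, sp$pos, 1)
      add_row(trait, sentinel, proxy, o$chrom, pos_in(o), round(stats::runif(1, 0.75, 0.95), 3))
      role <- layout$contact[layout$gene_id == gene]
      stages <- if (identical(role, "hp_only")) "HP" else cfg$stages
      links[[length(links) + 1L]] <- data.frame(
        trait = trait, sentinel = sentinel, proxy = proxy,
        chrom = o$chrom, pos = pos_in(o), ocr_id = o$ocr_id,
        gene_id = gene, route = route,
        stages = paste(stages, collapse = ","), stringsAsFactors = FALSE)
    }
    for (cls in names(decoy_gene)) {
      gene <- decoy_gene[[cls]][[trait]]
      kind <- if (cls == "closed") "closed" else "pir"
      o <- get_ocr(gene, kind)
      sentinel <- sprintf("rs_%s_D_%s", trait, cls)
      proxy <- sprintf("rs_%s_Dp_%s", trait, cls)
      r2 <- if (cls == "low_r2") 0.5 else 0.9
      sp <- sent_pos(gene)
      add_row(trait, sentinel, sentinel, sp$chrom, sp$pos, 1)
      add_row(trait, sentinel, proxy, o$chrom, pos_in(o), r2)
      decoys[[length(decoys) + 1L]] <- data.frame(
        class = cls, trait = trait, sentinel = sentinel, proxy = proxy,
        chrom = o$chrom, pos = pos_in(o), ocr_id = o$ocr_id,
        gene_id = gene, stringsAsFactors = FALSE)
    }
    ## one sentinel absent from the reference panel
    np <- sprintf("rs_%s_NP", trait)
    sp <- sent_pos("G060")
    add_row(trait, np, np, sp$chrom, sp$pos, 1, in_panel = FALSE)
  }
  list(table = do.call(rbind, rows),
       links = do.call(rbind, links),
       decoys = do.call(rbind, decoys))
}

## TF binding sites: two TFs concentrated in cREs, three null (internal).
.sim_tf_sites <- function(planted, cfg) {
  cre <- planted[planted$kind %in% c("promoter", "pir"), , drop = FALSE]
  all_ocr <- planted[planted$kind != "noise", , drop = FALSE]
  site_at <- function(reg, tf, purity)
    data.frame(tf_id = tf, chrom = reg$chrom, start = reg$start + 10L,
               end = reg$start + 25L, purity = round(purity, 3),
               stringsAsFactors = FALSE)
  rows <- list()
  enriched <- c("TF_ENR1", "TF_ENR2")
  for (tf in enriched) {
    sel <- cre[stats::runif(nrow(cre)) < 0.6, , drop = FALSE]
    rows[[length(rows) + 1L]] <-
      site_at(sel, tf, stats::runif(nrow(sel), 0.75, 0.95))
  }
  for (tf in c("TF_NULL1", "TF_NULL2", "TF_NULL3")) {
    sel <- all_ocr[stats::runif(nrow(all_ocr)) < 0.3, , drop = FALSE]
    rows[[length(rows) + 1L]] <-
      site_at(sel, tf, stats::runif(nrow(sel), 0.5, 0.95))
  }
  list(sites = do.call(rbind, rows), enriched = enriched)
}

#' Pairwise r-squared from phased haplotypes
#'
#' Computes the squared haplotype correlation
#' `r2 = (p_AB - p_A p_B)^2 / (p_A (1-p_A) p_B (1-p_B))` for every pair
#' of variants in a binary haplotype matrix.  Monomorphic variants give
#' `NA`.
#'
#' @param haps haplotype x variant 0/1 matrix (>= 2 variants).
#' @return symmetric variant x variant matrix of r-squared values.
#' @export
ld_from_haplotypes <- function(haps) {
  haps <- as.matrix(haps)
  if (ncol(haps) < 2L) stop("need at least two variants")
  if (!all(haps %in% c(0, 1))) stop("haplotypes must be 0/1")
  p <- colMeans(haps)
  pab <- crossprod(haps) / nrow(haps)
  num <- (pab - outer(p, p))^2
  den <- outer(p * (1 - p), p * (1 - p))
  r2 <- num / den
  r2[den == 0] <- NA_real_
  diag(r2) <- ifelse(p > 0 & p < 1, 1, NA_real_)
  r2
}
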