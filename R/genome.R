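#' In silico restriction digest of a genome
#'
#' Cuts each chromosome immediately 5' of every occurrence of the
#' recognition motif (DpnII-style blunt cutting at `^GATC`), so every
#' fragment except the first on a chromosome begins with the motif.  The
#' fragments tile each chromosome exactly: within a chromosome they are
#' adjacent and their union covers `[0, chrom_length)`.
#'
#' @param sequence_by_chrom named character vector of chromosome sequences
#'   (case-insensitive), e.g. from [read_genome_fasta()].
#' @param motif recognition sequence, default `"GATC"` (DpnII).
#' @return A fragment map: region data.frame with columns `chrom`, `start`,
#'   `end`, `frag_id` (integer, unique genome-wide, in coordinate order)
#'   and attribute `motif`.
#' @examples
#' digest_genome(c(chrA = "AAAGATCAAAGATCAA"))  # fragments [0,3) [3,10) [10,16)
#' @export
digest_genome <- function(sequence_by_chrom, motif = "GATC") {
  stopifnot(length(motif) == 1L, nzchar(motif))
  if (length(sequence_by_chrom) == 0L)
    stop("no chromosome sequences supplied")
  if (is.null(names(sequence_by_chrom)) || any(!nzchar(names(sequence_by_chrom))))
    stop("sequences must be named by chromosome")
  if (any(!nzchar(sequence_by_chrom)))
    stop("empty chromosome sequence")
  motif <- toupper(motif)
  per_chrom <- lapply(names(sequence_by_chrom), function(chrom) {
    seq <- toupper(sequence_by_chrom[[chrom]])
    len <- nchar(seq)
    if (nchar(motif) > len) {
      cuts <- integer()
    } else {
      m <- Biostrings::matchPattern(motif, Biostrings::DNAString(seq))
      cuts <- IRanges::start(m) - 1L  # 0-based motif offsets = cut sites
      cuts <- cuts[cuts > 0L]              # a cut at 0 yields no fragment
    }
    bounds <- unique(c(0L, cuts, len))
    data.frame(chrom = chrom,
               start = bounds[-length(bounds)],
               end = bounds[-1L],
               stringsAsFactors = FALSE)
  })
  fm <- do.call(rbind, per_chrom)
  fm$frag_id <- seq_len(nrow(fm))
  validate_regions(fm)
  attr(fm, "motif") <- motif
  fm
}

#' Bin a fragment map into super-fragments
#'
#' Merges consecutive groups of `k` restriction fragments per chromosome
#' into super-fragments (the 4-fragment resolution used to improve
#' detection of long-distance capture interactions).  Binning is anchored
#' at the first fragment of each chromosome; a trailing group of fewer
#' than `k` fragments is kept as its own bin.
#'
#' @param fm fragment map from [digest_genome()].
#' @param k fragments per bin (default 4); `k = 1` is the identity.
#' @return fragment map of super-fragments with columns `chrom`, `start`,
#'   `end`, `frag_id` and `n_members`.
#' @export
bin_fragments <- function(fm, k = 4L) {
  if (k < 1L) stop("k must be >= 1")
  k <- as.integer(k)
  validate_regions(fm)
  pieces <- lapply(split(fm, fm$chrom)[unique(fm$chrom)], function(d) {
    d <- d[order(d$start), , drop = FALSE]
    grp <- (seq_len(nrow(d)) - 1L) %/% k
    data.frame(chrom = d$chrom[1L],
               start = tapply(d$start, grp, min),
               end = tapply(d$end, grp, max),
               n_members = as.integer(table(grp)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out <- out[order(match(out$chrom, unique(fm$chrom)), out$start), , drop = FALSE]
  out$frag_id <- seq_len(nrow(out))
  attr(out, "motif") <- attr(fm, "motif")
  out[, c("chrom", "start", "end", "frag_id", "n_members")]
}

#' Gene models
#'
#' A light container for gene structures: a `genes` table (one row per
#' gene: `gene_id`, `chrom`, `strand`, `tss`) and an `exons` table
#' (`gene_id`, `chrom`, `start`, `end`), optionally a `cds` table of the
#' same shape.  The TSS is the 5' end of the first exon on the annotated
#' strand.  Exons of a gene must be non-overlapping.
#'
#' @param exons exon region data.frame with a `gene_id` column.
#' @param strand named character vector (`+`/`-`) per gene_id, or a
#'   `strand` column in `exons`.
#' @param cds optional CDS region data.frame with `gene_id`.
#' @return object of class `gene_models`.
#' @export
gene_models <- function(exons, strand = NULL, cds = NULL) {
  validate_regions(exons)
  stopifnot("gene_id" %in% names(exons))
  if (is.null(strand)) {
    stopifnot("strand" %in% names(exons))
    strand <- tapply(exons$strand, exons$gene_id, function(s) s[1L])
    strand <- stats::setNames(as.character(strand), names(strand))
  }
  ids <- unique(exons$gene_id)
  if (any(!ids %in% names(strand)))
    stop("strand missing for some genes")
  if (any(!strand[ids] %in% c("+", "-")))
    stop("unknown strand; must be '+' or '-'")
  genes <- do.call(rbind, lapply(ids, function(g) {
    ex <- exons[exons$gene_id == g, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) > 1L && any(ex$start[-1L] < ex$end[-nrow(ex)]))
      stop("overlapping exons for gene ", g)
    tss <- if (strand[[g]] == "+") ex$start[1L] else ex$end[nrow(ex)] - 1L
    data.frame(gene_id = g, chrom = ex$chrom[1L], strand = strand[[g]],
               tss = as.integer(tss), stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL
  structure(list(genes = genes,
                 exons = exons[, c("gene_id", "chrom", "start", "end")],
                 cds = if (!is.null(cds)) cds[, c("gene_id", "chrom", "start", "end")]),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,", nrow(x$exons), "exons",
      if (!is.null(x$cds)) paste0("(", nrow(x$cds), " CDS segments)"), "\n")
  invisible(x)
}

#' Read gene models from a GTF file
#'
#' Uses `rtracklayer::import()` and keeps `exon` and `CDS` features,
#' grouping by the `gene_id` attribute.  GTF 1-based closed coordinates
#' are converted to the package's 0-based half-open convention.
#'
#' @param path GTF path.
#' @return [gene_models()] object.
#' @export
read_gtf_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  if (!"gene_id" %in% names(S4Vectors::mcols(gr)))
    stop("GTF must carry a gene_id attribute")
  grab <- function(type) {
    sel <- gr[gr$type == type]
    if (length(sel) == 0L) return(NULL)
    data.frame(gene_id = sel$gene_id,
               chrom = as.character(GenomicRanges::seqnames(sel)),
               start = GenomicRanges::start(sel) - 1L,
               end = GenomicRanges::end(sel),
               strand = as.character(GenomicRanges::strand(sel)),
               stringsAsFactors = FALSE)
  }
  ex <- grab("exon")
  if (is.null(ex)) stop("GTF contains no exon features")
  gene_models(ex, cds = grab("CDS"))
}

#' Promoter windows around gene TSSs
#'
#' Strand-aware promoter window, by default -1500/+500 bp around the TSS:
#' on the plus strand `[tss-upstream, tss+downstream)`, mirrored on the
#' minus strand, clipped at position 0.
#'
#' @param gm [gene_models()] object (or its `genes` data.frame).
#' @param upstream,downstream window extent in bp (defaults 1500 / 500).
#' @return region data.frame with a `gene_id` column.
#' @export
promoter_windows <- function(gm, upstream = 1500L, downstream = 500L) {
  genes <- if (inherits(gm, "gene_models")) gm$genes else gm
  stopifnot(all(c("gene_id", "chrom", "strand", "tss") %in% names(genes)))
  if (any(!genes$strand %in% c("+", "-"))) stop("unknown strand")
  if (any(genes$tss < 0L)) stop("tss must be >= 0")
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - upstream, genes$tss - downstream)
  end <- ifelse(plus, genes$tss + downstream, genes$tss + upstream)
  regions(genes$chrom, pmax(0L, start), end, gene_id = genes$gene_id)
}

.feature_levels <- c("Promoter", "5UTR", "CDS", "3UTR",
                     "FirstIntron", "OtherIntron", "Intergenic")

## Build the ranked feature table for a gene_models object (internal).
## Rank 1 = Promoter ... 6 = OtherIntron; Intergenic is the absence of overlap.
feature_table <- function(gm, upstream = 1500L, downstream = 500L) {
  prom <- promoter_windows(gm, upstream, downstream)
  feats <- list(data.frame(prom[, c("chrom", "start", "end")], rank = 1L))
  genes <- gm$genes
  for (g in genes$gene_id) {
    ex <- gm$exons[gm$exons$gene_id == g, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    strand <- genes$strand[genes$gene_id == g]
    if (!is.null(gm$cds)) {
      cds <- gm$cds[gm$cds$gene_id == g, , drop = FALSE]
      if (nrow(cds) > 0L) {
        feats[[length(feats) + 1L]] <-
          data.frame(cds[, c("chrom", "start", "end")], rank = 3L)
        cds_lo <- min(cds$start); cds_hi <- max(cds$end)
        ## UTRs: exonic sequence outside the CDS span, 5' vs 3' by strand
        utr <- function(lo, hi, rank) {
          s <- pmax(ex$start, lo); e <- pmin(ex$end, hi)
          keep <- s < e
          if (!any(keep)) return(NULL)
          data.frame(chrom = ex$chrom[keep], start = s[keep], end = e[keep],
                     rank = rank)
        }
        left <- utr(0L, cds_lo, if (strand == "+") 2L else 4L)
        right <- utr(cds_hi, .Machine$integer.max, if (strand == "+") 4L else 2L)
        if (!is.null(left)) feats[[length(feats) + 1L]] <- left
        if (!is.null(right)) feats[[length(feats) + 1L]] <- right
      }
    }
    if (nrow(ex) > 1L) {
      istart <- ex$end[-nrow(ex)]
      iend <- ex$start[-1L]
      keep <- istart < iend
      if (any(keep)) {
        introns <- data.frame(chrom = ex$chrom[1L], start = istart[keep],
                              end = iend[keep])
        ## first intron on the annotated strand: leftmost (+) or rightmost (-)
        first_i <- if (strand == "+") 1L else nrow(introns)
        introns$rank <- 6L
        introns$rank[first_i] <- 5L
        feats[[length(feats) + 1L]] <- introns
      }
    }
  }
  out <- do.call(rbind, feats)
  rownames(out) <- NULL
  out
}

#' Hierarchical genomic feature annotation
#'
#' Assigns each query region exactly one feature label using the fixed
#' hierarchy Promoter > 5'UTR > CDS > 3'UTR > first intron > other introns
#' > intergenic: among all gene features the region overlaps by at least
#' one base, the highest-priority label wins; regions overlapping nothing
#' are `Intergenic`.  Query strand is ignored (ATAC peaks are unstranded);
#' promoter windows are gene-strand-aware.
#'
#' @param query region data.frame.
#' @param gm [gene_models()] object.
#' @param upstream,downstream promoter window extents (see
#'   [promoter_windows()]).
#' @return factor of feature labels, one per query row, with levels
#'   `Promoter, 5UTR, CDS, 3UTR, FirstIntron, OtherIntron, Intergenic`.
#' @export
annotate_feature <- function(query, gm, upstream = 1500L, downstream = 500L) {
  validate_regions(query)
  feats <- feature_table(gm, upstream, downstream)
  rank <- rep(7L, nrow(query))
  if (nrow(feats) > 0L && nrow(query) > 0L) {
    hits <- intersect_regions(query, feats)
    if (nrow(hits) > 0L) {
      best <- tapply(feats$rank[hits$b_idx], hits$a_idx, min)
      rank[as.integer(names(best))] <- as.integer(best)
    }
  }
  factor(.feature_levels[rank], levels = .feature_levels)
}

#' Write a fragment map as BED4
#'
#' @param fm fragment map ([digest_genome()] / [bin_fragments()]).
#' @param path output path; fragment ids become the BED name column.
#' @return `path`, invisibly.
#' @export
write_fragment_map <- function(fm, path) {
  write_bed(data.frame(fm[, c("chrom", "start", "end")], name = fm$frag_id),
            path)
}

#' Read a fragment map from BED4
#'
#' @param path BED4 path (name column = fragment id).
#' @return fragment map data.frame.
#' @export
read_fragment_map <- function(path) {
  df <- read_bed(path, keep_name = TRUE)
  df$frag_id <- as.integer(df$name)
  df$name <- NULL
  df
}
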