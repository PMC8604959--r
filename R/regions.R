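#' Genomic regions in crev2g
#'
#' All coordinates in this package are 0-based, half-open (BED convention):
#' a region covers bases `start .. end-1`.  Regions are plain data frames
#' with at least the columns `chrom`, `start`, `end`; extra columns are
#' carried along untouched.  1-based formats (GTF, VCF-style positions) are
#' converted at their readers.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open.
#' @param ... further columns recycled alongside the coordinates.
#' @return A `data.frame` with columns `chrom`, `start`, `end` (and `...`).
#' @examples
#' regions("chr1", 0L, 100L)
#' @export
regions <- function(chrom, start, end, ...) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   ...,
                   stringsAsFactors = FALSE)
  validate_regions(df)
  df
}

#' Validate a region data frame
#'
#' Checks the coordinate invariants `0 <= start < end` and non-empty
#' chromosome names; stops with an informative error otherwise.
#'
#' @param df a data.frame with `chrom`, `start`, `end` columns.
#' @return `df`, invisibly.
#' @export
validate_regions <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0L) return(invisible(df))
  if (any(is.na(df$chrom)) || any(!nzchar(df$chrom)))
    stop("region chromosome names must be non-empty")
  if (any(is.na(df$start)) || any(is.na(df$end)))
    stop("region coordinates must not be NA")
  if (any(df$start < 0L))
    stop("region start coordinates must be >= 0")
  if (any(df$start >= df$end))
    stop("malformed region: start must be < end (0-based half-open)")
  invisible(df)
}

## 0-based half-open data.frame -> 1-based closed GRanges (internal)
as_granges <- function(df) {
  validate_regions(df)
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

## GRanges -> 0-based half-open data.frame (internal)
as_regions <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Report all overlapping pairs between two region sets
#'
#' The in-house equivalent of a `bedtools intersect` pass: every pair of
#' regions from `a` and `b` whose overlap is at least `min_overlap` bases
#' is reported exactly once, with the overlap width in bases.
#'
#' @param a,b region data frames (see [regions()]).
#' @param min_overlap minimum overlap in bases for a pair to be reported
#'   (default 1; abutting half-open regions share 0 bases and are never
#'   reported).
#' @return data.frame with columns `a_idx`, `b_idx` (row indices into `a`
#'   and `b`) and `overlap_bp`, ordered by (`a_idx`, `b_idx`).
#' @examples
#' a <- regions("chr1", 0L, 10L)
#' b <- regions("chr1", c(9L, 10L), c(20L, 30L))
#' intersect_regions(a, b)   # only the 1-bp overlap with [9,20)
#' @export
intersect_regions <- function(a, b, min_overlap = 1L) {
  stopifnot(min_overlap >= 1L)
  validate_regions(a)
  validate_regions(b)
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(data.frame(a_idx = integer(), b_idx = integer(),
                      overlap_bp = integer()))
  ## per-chromosome IRanges overlap (lighter than whole-genome GRanges
  ## for the many small queries this package makes)
  ai <- integer(); bi <- integer()
  for (chrom in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == chrom)
    ib <- which(b$chrom == chrom)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(a$start[ia] + 1L, a$end[ia]),
      IRanges::IRanges(b$start[ib] + 1L, b$end[ib]),
      minoverlap = min_overlap)
    ai <- c(ai, ia[S4Vectors::queryHits(hits)])
    bi <- c(bi, ib[S4Vectors::subjectHits(hits)])
  }
  ov <- pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi])
  out <- data.frame(a_idx = ai, b_idx = bi, overlap_bp = as.integer(ov))
  out <- out[order(out$a_idx, out$b_idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a BED3+ file of regions
#'
#' Tolerant reader for BED-like files: the first three columns are taken as
#' `chrom`, `start`, `end`; anything beyond (narrowPeak scores, names, ...)
#' is ignored unless `keep_name = TRUE`, in which case column 4 is kept as
#' `name`.
#'
#' @param path file path.
#' @param keep_name keep the 4th column as `name` if present.
#' @return region data.frame.
#' @export
read_bed <- function(path, keep_name = FALSE) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  df <- regions(raw[[1]], raw[[2]], raw[[3]])
  if (keep_name && ncol(raw) >= 4L) df$name <- as.character(raw[[4]])
  df
}

#' Write regions to a BED file
#'
#' @param df region data.frame; if a `name` column is present a BED4 file
#'   is written, otherwise BED3.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  validate_regions(df)
  cols <- df[, c("chrom", "start", "end")]
  if ("name" %in% names(df)) cols$name <- df$name
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a genome FASTA file
#'
#' @param path FASTA path.
#' @return named character vector of uppercase chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}
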