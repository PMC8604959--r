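make_peaks <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(chrom = "chr1", start = r[[1]], end = r[[2]],
               sample_id = r[[3]], stage = r[[4]],
               stringsAsFactors = FALSE)))
}

test_that("consensus merges >=1bp overlaps and applies the half rule", {
  # two replicates, same stage: [0,10) and [9,20) merge into [0,20)
  pk <- make_peaks(list(0L, 10L, "r1", "S"), list(9L, 20L, "r2", "S"))
  cons <- build_consensus(pk)
  expect_equal(cons[, c("start", "end")], data.frame(start = 0L, end = 20L),
               ignore_attr = TRUE)
  expect_equal(cons$support_S, 2L)

  # present in 1 of 4 replicates: dropped
  pk2 <- rbind(make_peaks(list(0L, 10L, "r1", "S")),
               make_peaks(list(100L, 110L, "r1", "S"),
                          list(100L, 112L, "r2", "S"),
                          list(101L, 111L, "r3", "S")),
               data.frame(chrom = "chr1", start = 500L, end = 510L,
                          sample_id = "r4", stage = "S"))
  cons2 <- build_consensus(pk2)
  expect_equal(cons2$start, 100L)   # singleton regions at 0 and 500 dropped
  expect_equal(cons2$support_S, 3L)

  # transitive chain merges into one region
  pk3 <- make_peaks(list(0L, 10L, "r1", "S"), list(9L, 15L, "r2", "S"),
                    list(14L, 30L, "r1", "S"))
  cons3 <- build_consensus(pk3)
  expect_equal(cons3[, c("start", "end")], data.frame(start = 0L, end = 30L),
               ignore_attr = TRUE)

  # abutting peaks do not merge
  pk4 <- make_peaks(list(0L, 10L, "r1", "S"), list(10L, 20L, "r1", "S"),
                    list(0L, 10L, "r2", "S"), list(10L, 20L, "r2", "S"))
  expect_equal(nrow(build_consensus(pk4)), 2L)

  expect_error(build_consensus(pk[0, ]), "no peaks")
})

test_that("consensus regions are pairwise non-overlapping (property)", {
  set.seed(21)
  pk <- do.call(rbind, lapply(1:4, function(r) {
    d <- random_regions(150, chroms = "chr1", size = 2e4, max_len = 300L)
    d$sample_id <- paste0("r", r); d$stage <- "S"
    d
  }))
  cons <- build_consensus(pk)
  self <- intersect_regions(cons, cons)
  expect_true(all(self$a_idx == self$b_idx))
})

test_that("FPKM openness uses length, library size and stage means", {
  ocrs <- data.frame(ocr_id = c("o1", "o2"), chrom = "chr1",
                     start = c(0L, 5000L), end = c(1000L, 5200L))
  counts <- matrix(c(100L, 0L, 300L, 0L), 2, 2,
                   dimnames = list(NULL, c("a1", "a2")))
  samples <- data.frame(sample_id = c("a1", "a2"), stage = "S")
  at <- quantify_openness(ocrs, counts, samples,
                          lib_sizes = c(a1 = 1e6, a2 = 1e6))
  # count 100, length 1000 bp, libsize 1e6 -> FPKM 100
  expect_equal(at$fpkm["o1", "a1"], 100)
  expect_equal(at$mean_fpkm["o1", "S"], 200)
  expect_true(at$open["o1", "S"])
  # all-zero counts -> FPKM 0, not open
  expect_equal(at$mean_fpkm["o2", "S"], 0)
  expect_false(at$open["o2", "S"])
  # scale invariance: doubling counts and library sizes leaves FPKM alone
  at2 <- quantify_openness(ocrs, counts * 2L, samples,
                           lib_sizes = c(a1 = 2e6, a2 = 2e6))
  expect_equal(at2$fpkm, at$fpkm)
  expect_error(quantify_openness(ocrs, counts, samples,
                                 lib_sizes = c(a1 = 0, a2 = 1)),
               "> 0")
})

test_that("interaction significance is strict and stage-aware", {
  ints <- data.frame(bait_chrom = "chr1", bait_start = 0L, bait_end = 100L,
                     oe_chrom = "chr1", oe_start = c(500L, 700L, 900L),
                     oe_end = c(600L, 800L, 1000L),
                     score = c(5.0, 5.01, 8), resolution = "frag1",
                     stage = c("ESC", "ESC", "HP"))
  sig <- significant_interactions(ints)
  expect_equal(sig$score, c(5.01, 8))          # score 5.0 excluded (strict >)
  expect_equal(nrow(significant_interactions(ints[0, ])), 0L)
  # collapse_stages propagates a pair significant anywhere
  ints2 <- rbind(ints[3, ], transform(ints[3, ], score = 2, stage = "ESC"))
  expect_equal(nrow(significant_interactions(ints2)), 1L)
  expect_equal(nrow(significant_interactions(ints2, collapse_stages = TRUE)),
               2L)
})

test_that("classification priority is Promoter > PIR > NonPIR per stage", {
  gm <- toy_gene_models()        # gp tss 10000 (+), window [8500,10500)
  prom <- promoter_windows(gm)
  ocrs <- data.frame(
    ocr_id = c("in_prom_and_contact", "in_contact", "plain", "closed"),
    chrom = "chr1",
    start = c(10300L, 20000L, 30000L, 35000L),
    end = c(10450L, 20200L, 30200L, 35200L))
  counts <- matrix(c(50L, 50L, 50L, 0L), 4, 1,
                   dimnames = list(NULL, "a1"))
  samples <- data.frame(sample_id = "a1", stage = "ESC")
  at <- quantify_openness(ocrs, counts, samples, lib_sizes = c(a1 = 1e6))
  ints <- data.frame(
    bait_chrom = "chr1", bait_start = 9900L, bait_end = 10100L,
    oe_chrom = "chr1", oe_start = c(10350L, 19950L), oe_end = c(10500L, 20100L),
    score = 6, resolution = "frag1", stage = "ESC")
  at <- classify_ocrs(at, prom, significant_interactions(ints))
  expect_equal(unname(at$class[, "ESC"]),
               c("PromoterOCR", "PIR_OCR", "NonPIR_OCR", NA))
  # every open OCR gets exactly one class: the classes partition the open set
  expect_equal(sum(!is.na(at$class[, "ESC"])), sum(at$open[, "ESC"]))
  # raising score_min can only shrink the PIR set
  at20 <- classify_ocrs(at, prom, significant_interactions(ints, 20))
  expect_lte(sum(at20$class[, "ESC"] == "PIR_OCR", na.rm = TRUE),
             sum(at$class[, "ESC"] == "PIR_OCR", na.rm = TRUE))
})

test_that("gene-cRE map links both routes with correct distances", {
  gm <- toy_gene_models()
  prom <- promoter_windows(gm)
  ocrs <- data.frame(ocr_id = c("p", "d"), chrom = "chr1",
                     start = c(9900L, 20000L), end = c(10100L, 20200L))
  counts <- matrix(c(50L, 50L), 2, 1, dimnames = list(NULL, "a1"))
  samples <- data.frame(sample_id = "a1", stage = "ESC")
  at <- quantify_openness(ocrs, counts, samples, lib_sizes = c(a1 = 1e6))
  ints <- data.frame(bait_chrom = "chr1", bait_start = 9900L,
                     bait_end = 10100L, oe_chrom = "chr1",
                     oe_start = 19950L, oe_end = 20100L, score = 7,
                     resolution = "frag1", stage = "ESC")
  at <- classify_ocrs(at, prom, significant_interactions(ints))
  map <- gene_cre_map(at, prom, significant_interactions(ints), gm)
  expect_setequal(map$links$route, c("promoter", "contact"))
  # promoter OCR centred on the TSS -> distance 0
  expect_equal(map$links$distance_bp[map$links$route == "promoter"], 0)
  expect_equal(map$links$distance_bp[map$links$route == "contact"],
               abs(20100 - 10000))
  pg <- map$per_gene[map$per_gene$gene_id == "gp", ]
  expect_equal(pg$n_cre, 2L)
})

test_that("planted classes are recovered exactly on synthetic data", {
  fx <- sim_fixture()
  ar <- atlas_fixture()
  reg <- fx$sim$manifest$regions
  m <- match(reg$ocr_id, ar$atlas$ocrs$ocr_id)
  expect_false(anyNA(m))
  for (s in c("ESC", "HP", "HN")) {
    expect_equal(unname(ar$atlas$open[m, s]), reg[[paste0("open_", s)]])
    truth <- reg[[paste0("class_", s)]]
    got <- unname(ar$atlas$class[m, s])
    expect_equal(is.na(got), is.na(truth))
    expect_equal(got[!is.na(truth)], truth[!is.na(truth)])
  }
})
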