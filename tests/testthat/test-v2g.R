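toy_ld <- function() {
  data.frame(
    trait = "T1",
    sentinel = c("s1", "s1", "s1", "s2", "s3"),
    proxy = c("s1", "p1", "p2", "s2", "s3"),
    chrom = "chr1",
    pos = c(100L, 200L, 300L, 400L, 500L),
    r2 = c(1, 0.60, 0.8, 1, 1),
    in_panel = c(TRUE, TRUE, TRUE, TRUE, FALSE))
}

test_that("proxy expansion applies strict r2 and panel membership", {
  sig <- expand_proxies(toy_ld())
  # r2 = 0.60 excluded (strict >), sentinels kept as their own proxies
  expect_false("p1" %in% sig$table$proxy)
  expect_true(all(c("s1", "p2", "s2") %in% sig$table$proxy))
  # sentinel not in panel contributes no proxies but is counted
  expect_false("s3" %in% sig$table$proxy)
  expect_equal(sig$signals$n_signals, 3L)
  expect_equal(sig$signals$n_in_panel, 2L)
  # a sentinel with no LD partners has exactly one proxy: itself
  expect_equal(sum(sig$table$sentinel == "s2"), 1L)
  # shared proxies are counted once per trait
  ld2 <- rbind(toy_ld(),
               data.frame(trait = "T1", sentinel = "s2", proxy = "p2",
                          chrom = "chr1", pos = 300L, r2 = 0.9,
                          in_panel = TRUE))
  expect_equal(expand_proxies(ld2)$signals$n_unique_proxies,
               length(unique(c("s1", "p2", "s2", "p2"))))
  expect_error(expand_proxies(transform(toy_ld(), r2 = r2 * 2)), "r2")
})

make_toy_atlas <- function(open_stages = list(o1 = c("ESC", "HP", "HN"))) {
  ocrs <- data.frame(ocr_id = names(open_stages), chrom = "chr1",
                     start = seq(100L, by = 1000L,
                                 length.out = length(open_stages)),
                     end = seq(100L, by = 1000L,
                               length.out = length(open_stages)) + 100L)
  samples <- data.frame(sample_id = c("e1", "h1", "n1"),
                        stage = c("ESC", "HP", "HN"))
  counts <- matrix(0L, nrow(ocrs), 3, dimnames = list(NULL, samples$sample_id))
  for (i in seq_len(nrow(ocrs)))
    counts[i, match(open_stages[[i]], samples$stage)] <- 1000L
  quantify_openness(ocrs, counts, samples,
                    lib_sizes = c(e1 = 1e6, h1 = 1e6, n1 = 1e6))
}

test_that("open-proxy containment is half-open and stage-resolved", {
  at <- make_toy_atlas(list(o1 = "HP"))     # OCR [100, 200), open in HP only
  tab <- data.frame(trait = "T", sentinel = "s", proxy = c("pl", "pr", "pm"),
                    chrom = "chr1", pos = c(101L, 200L, 150L),
                    r2 = 0.9, in_panel = TRUE)
  hits <- find_open_proxies(tab, at)
  # pos 101 (1-based) is the left edge base 100: contained; pos 200 is
  # base 199: contained; pos 201 would be outside
  expect_setequal(hits$proxy, c("pl", "pr", "pm"))
  expect_true(all(hits$stage == "HP"))
  # pos 100 is base 99 (before the OCR) and pos 201 is base 200 (the
  # excluded right edge): only the middle proxy remains
  tab2 <- transform(tab, pos = c(100L, 201L, 150L))
  hits2 <- find_open_proxies(tab2, at)
  expect_setequal(hits2$proxy, "pm")
  # chromosome absent from the atlas: no hit, message
  expect_message(
    h3 <- find_open_proxies(transform(tab, chrom = "chrZ"), at),
    "absent")
  expect_equal(nrow(h3), 0L)
})

test_that("V2G routes, expression filter and summaries work end to end", {
  fx <- sim_fixture()
  ar <- atlas_fixture()
  cfg <- default_config(input_dir = fx$dir)
  v <- run_v2g(cfg, ar)
  links <- fx$sim$manifest$v2g_links
  rec_key <- paste(v$records$trait, v$records$proxy, v$records$gene_id,
                   v$records$stage)
  # every planted link recovered in every expected stage, with its route
  for (i in seq_len(nrow(links))) {
    for (s in strsplit(links$stages[i], ",")[[1]]) {
      j <- which(v$records$trait == links$trait[i] &
                   v$records$proxy == links$proxy[i] &
                   v$records$gene_id == links$gene_id[i] &
                   v$records$stage == s)
      expect_length(j, 1L)
      expect_match(v$records$route[j], links$route[i], fixed = TRUE)
    }
  }
  # no decoy class yields a record; check each class individually
  decoys <- fx$sim$manifest$decoys
  for (cls in c("low_r2", "closed", "no_contact", "low_tpm")) {
    bad <- decoys$proxy[decoys$class == cls]
    expect_length(bad, 3L)
    expect_false(any(v$records$proxy %in% bad),
                 label = paste("decoy class", cls, "rejected"))
  }
  # all reported genes are expressed above threshold in their stage
  expect_true(all(v$records$gene_tpm > cfg$tpm_min))
  # summary invariants
  s <- v$summary
  expect_true(all(s$n_in_panel <= s$n_signals))
  for (st in c("ESC", "HP", "HN")) {
    expect_true(all(s[[paste0("sentinels_cis_", st)]] <=
                      s[[paste0("open_proxies_cis_", st)]]))
    expect_true(all(s[[paste0("genes_", st)]] <= s$n_unique_genes))
  }
  expect_true(all(s$n_unique_genes <=
                    s$genes_ESC + s$genes_HP + s$genes_HN))
})

test_that("V2G filter chain is monotone in its thresholds", {
  fx <- sim_fixture()
  ar <- atlas_fixture()
  base <- run_v2g(default_config(input_dir = fx$dir), ar)
  rec_id <- function(v) paste(v$records$trait, v$records$proxy,
                              v$records$gene_id, v$records$stage)
  tight_tpm <- run_v2g(default_config(input_dir = fx$dir, tpm_min = 30), ar)
  expect_true(all(rec_id(tight_tpm) %in% rec_id(base)))
  tight_r2 <- run_v2g(default_config(input_dir = fx$dir, r2_min = 0.92), ar)
  expect_true(all(rec_id(tight_r2) %in% rec_id(base)))
  inf_tpm <- run_v2g(default_config(input_dir = fx$dir, tpm_min = Inf), ar)
  expect_equal(nrow(inf_tpm$records), 0L)
})

test_that("trait summary enumerates a toy fixture by hand", {
  at <- make_toy_atlas(list(o1 = c("ESC", "HP")))
  # records built directly: sentinel s1 yields records in ESC and HP,
  # sentinel s2 yields none
  rec <- data.frame(trait = "T", sentinel = "s1", proxy = "p1",
                    stage = c("ESC", "HP"), ocr_id = "o1",
                    gene_id = "G", route = "distal_PIR", gene_tpm = 5)
  ld <- data.frame(trait = "T", sentinel = c("s1", "s1", "s2"),
                   proxy = c("s1", "p1", "s2"), chrom = "chr1",
                   pos = c(1L, 150L, 900L), r2 = c(1, 0.9, 1),
                   in_panel = TRUE)
  s <- summarize_trait(rec, expand_proxies(ld), stages = c("ESC", "HP", "HN"))
  expect_equal(s$sentinels_cis_ESC, 1L)
  expect_equal(s$sentinels_cis_HP, 1L)
  expect_equal(s$sentinels_cis_HN, 0L)
  expect_equal(s$n_unique_genes, 1L)
  # no records: all contact columns zero
  s0 <- summarize_trait(rec[0, ], expand_proxies(ld),
                        stages = c("ESC", "HP", "HN"))
  expect_equal(s0$genes_ESC + s0$genes_HP + s0$genes_HN, 0L)
})

test_that("cross-trait overlap matches power-set enumeration", {
  sets <- list(A = c("g1", "g2", "g3"), B = c("g2", "g4"), C = c("g5"))
  ov <- cross_trait_overlap(sets)
  expect_equal(ov$n_genes[ov$traits == "A"], 2L)      # g1, g3 exclusive
  expect_equal(ov$n_genes[ov$traits == "A+B"], 1L)    # g2
  expect_equal(ov$n_genes[ov$traits == "C"], 1L)
  expect_equal(ov$n_genes[ov$traits == "A+B+C"], 0L)
  expect_equal(sum(ov$n_genes), length(unique(unlist(sets))))
  # randomized sets against a brute-force power-set oracle
  set.seed(19)
  for (i in 1:5) {
    rs <- lapply(stats::setNames(1:3, c("t1", "t2", "t3")), function(j)
      sample(paste0("g", 1:12), sample(0:8, 1)))
    ov2 <- cross_trait_overlap(rs)
    genes <- unique(unlist(rs))
    for (row in seq_len(nrow(ov2))) {
      members <- strsplit(ov2$traits[row], "+", fixed = TRUE)[[1]]
      want <- sum(vapply(genes, function(g) {
        inn <- vapply(names(rs), function(tr) g %in% rs[[tr]], logical(1))
        setequal(names(rs)[inn], members)
      }, logical(1)))
      expect_equal(ov2$n_genes[row], want)
    }
  }
  # disjoint sets: only singleton cells populated
  ov3 <- cross_trait_overlap(list(A = "g1", B = "g2"))
  expect_equal(ov3$n_genes[ov3$n_traits > 1], 0L)
  expect_error(cross_trait_overlap(list(A = "g1")), "two traits")
})
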