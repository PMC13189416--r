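test_that("representative transcript selection maximizes baseline expression", {
  tss <- data.frame(
    chrom = "chr1", tss_pos = c(100, 200, 300, 400, 500),
    strand = "+",
    gene_id = c("g1", "g2", "g2", "g3", "g3"),
    transcript_id = c("t1", "t2a", "t2b", "T2", "T1"),
    baseline_expr = c(1, 10, 7, 5, 5), stringsAsFactors = FALSE)
  rep <- select_representative_transcript(tss)
  expect_equal(nrow(rep), 3)
  expect_equal(rep$transcript_id[rep$gene_id == "g1"], "t1")
  expect_equal(rep$transcript_id[rep$gene_id == "g2"], "t2a")
  # tie resolves to the lexicographically smallest transcript id
  expect_equal(rep$transcript_id[rep$gene_id == "g3"], "T1")
})

test_that("window assignment distinguishes proximal from distal binding", {
  tss <- data.frame(chrom = "chrS", tss_pos = 100000, strand = "+",
                    gene_id = "g1", transcript_id = "t1",
                    baseline_expr = 5, stringsAsFactors = FALSE)
  peak_at <- function(s, e) GenomicRanges::GRanges(
    "chrS", IRanges::IRanges(start = s + 1L, end = e))  # 0-based [s, e)
  # peak inside +/-1kb
  b <- assign_windows(peak_at(100500, 100600), tss)
  expect_true(b$bound_proximal); expect_false(b$bound_distal)
  # peak past the proximal zone: distal only
  b <- assign_windows(peak_at(101500, 101600), tss)
  expect_false(b$bound_proximal); expect_true(b$bound_distal)
  # peak beyond +/-50kb: unbound
  b <- assign_windows(peak_at(151001, 151101), tss)
  expect_false(b$bound_proximal); expect_false(b$bound_distal)
  # inclusive boundary: peak covering exactly tss + 1000
  b <- assign_windows(peak_at(101000, 101001), tss)
  expect_true(b$bound_proximal)
  expect_warning(
    assign_windows(GenomicRanges::GRanges("chrZ",
                                          IRanges::IRanges(1, 10)), tss),
    "absent from annotation")
})

test_that("window assignment equals the brute-force overlap oracle", {
  set.seed(12)
  n_genes <- 120; n_peaks <- 200
  tss <- data.frame(
    chrom = sample(c("chr1", "chr2"), n_genes, replace = TRUE),
    tss_pos = sample.int(2e6, n_genes), strand = "+",
    gene_id = sprintf("g%03d", seq_len(n_genes)),
    transcript_id = sprintf("g%03d.t", seq_len(n_genes)),
    baseline_expr = 1, stringsAsFactors = FALSE)
  starts <- sample.int(2e6, n_peaks)
  peak_df <- data.frame(
    chrom = sample(c("chr1", "chr2"), n_peaks, replace = TRUE),
    start = starts, end = starts + sample(50:2000, n_peaks, replace = TRUE))
  peaks <- GenomicRanges::GRanges(
    peak_df$chrom, IRanges::IRanges(start = peak_df$start + 1L,
                                    end = peak_df$end))
  got <- assign_windows(peaks, tss)
  want <- assign_windows_oracle(peak_df, tss)
  expect_identical(got$bound_proximal, want$bound_proximal)
  expect_identical(got$bound_distal, want$bound_distal)
})

test_that("the one-sided exact test matches enumeration and fisher.test", {
  # tiny balanced table checked against full enumeration
  expect_equal(fisher_one_sided(1, 2, 2, 4), fisher_enum_oracle(1, 2, 2, 4),
               tolerance = 1e-12)
  # extreme table: minimum possible p for its margins
  expect_equal(fisher_one_sided(3, 3, 3, 10), fisher_enum_oracle(3, 3, 3, 10),
               tolerance = 1e-12)
  expect_equal(fisher_one_sided(3, 3, 3, 10), 1 / choose(10, 3),
               tolerance = 1e-12)
  # agreement with stats::fisher.test on the 2x2 layout
  for (cfg in list(c(5, 20, 30, 100), c(0, 10, 50, 200), c(8, 12, 9, 40))) {
    tab <- matrix(c(cfg[1], cfg[2] - cfg[1],
                    cfg[3] - cfg[1],
                    (cfg[4] - cfg[2]) - (cfg[3] - cfg[1])),
                  2, byrow = TRUE)
    expect_equal(fisher_one_sided(cfg[1], cfg[2], cfg[3], cfg[4]),
                 stats::fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-10)
  }
  # monotone decreasing in T_p at fixed margins; bounded in [0, 1]
  ps <- vapply(0:10, function(tp) fisher_one_sided(tp, 10, 30, 100),
               numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
  expect_true(all(ps >= 0 & ps <= 1))
  expect_error(fisher_one_sided(5, 4, 10, 20), "exceeds set size")
  expect_error(fisher_one_sided(0, 10, 3, 8), "not contained")
})

test_that("enrichment counts, ratio and invariances follow the definition", {
  genes <- sprintf("g%04d", 1:1500)
  bound <- setNames(rep(FALSE, 1500), genes)
  bound[1:150] <- TRUE                    # background rate 10%
  set <- c(genes[1:30], genes[200:269])   # 30 bound of 100
  res <- binding_enrichment(bound, set, genes, window = "proximal")
  expect_equal(res[, c("T_p", "T_n", "A_p", "A_n")],
               data.frame(T_p = 30, T_n = 100, A_p = 150, A_n = 1500))
  expect_equal(res$ratio, 3)
  # whole background against itself: ratio exactly 1
  expect_equal(binding_enrichment(bound, genes, genes)$ratio, 1)
  # duplicating every gene in set and background leaves the ratio fixed
  genes2 <- c(genes, paste0(genes, "_dup"))
  bound2 <- setNames(c(bound, bound), genes2)
  res2 <- binding_enrichment(bound2, c(set, paste0(set, "_dup")), genes2)
  expect_equal(res2$ratio, res$ratio)
  expect_error(binding_enrichment(bound, character(0), genes), "empty")
  expect_error(binding_enrichment(bound, "not_there", genes),
               "not within background")
})

test_that("the enrichment report covers sets, windows and DEG directions", {
  toy <- make_peaks_and_annotation(500, 0.5, 0.1, seed = 13)
  background <- toy$tss$gene_id
  deg <- list(up = toy$foreground[1:20], down = setdiff(background,
                                                        toy$foreground)[1:20])
  rep <- enrichment_report(list(fg = toy$foreground, deg_0h_1h = deg),
                           toy$peaks, toy$tss, background)
  # 1 plain set x 2 windows + 1 DEG set x 3 directions x 2 windows
  expect_equal(nrow(rep), 2 + 6)
  expect_setequal(unique(rep$direction[rep$set == "deg_0h_1h"]),
                  c("all", "up", "down"))
  expect_true(all(rep$p_value >= 0 & rep$p_value <= 1))
  # the enriched foreground is detected in the proximal window
  expect_lt(rep$p_value[rep$set == "fg" & rep$window == "proximal"], 0.05)
  rep_adj <- enrichment_report(list(fg = toy$foreground), toy$peaks, toy$tss,
                               background, adjust = TRUE)
  expect_true("padj" %in% names(rep_adj))
})

test_that("BED peaks round-trip through 0-based half-open files", {
  gr <- GenomicRanges::GRanges("chrS",
                               IRanges::IRanges(start = c(101, 501),
                                                end = c(300, 700)))
  bed <- tempfile(fileext = ".bed")
  write_peaks_bed(gr, bed)
  lines <- readLines(bed)
  expect_equal(strsplit(lines[1], "\t")[[1]][2:3], c("100", "300"))
  back <- read_peaks(bed)
  expect_equal(GenomicRanges::start(back), c(101, 501))
  expect_equal(GenomicRanges::end(back), c(300, 700))
})
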