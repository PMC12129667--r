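toy_scan <- function(llr, pos = NULL, chrom = "1") {
  n <- length(llr)
  tibble::tibble(
    id = sprintf("t%03d", seq_len(n)),
    chrom = rep_len(chrom, n),
    pos = if (is.null(pos)) as.integer(seq_len(n) * 1000) else as.integer(pos),
    llr = llr
  )
}

test_that("percentile outliers match a brute-force sort oracle", {
  withr::with_seed(91, llr <- round(stats::rchisq(100, 1), 6))
  sc <- toy_scan(llr)
  out <- percentile_outliers(sc, q = 0.99)
  thr <- sort(llr)[100 - 1]  # type-7 0.99 quantile of 100 values
  expect_true(all(out$llr >= attr(out, "percentile_threshold")))
  expect_setequal(out$id, sc$id[sc$llr >= stats::quantile(llr, 0.99)])

  # half-zero scan at q = 0.5 keeps every nonzero SNP
  sc2 <- toy_scan(c(rep(0, 50), stats::runif(50, 1, 5)))
  out2 <- percentile_outliers(sc2, q = 0.5)
  expect_true(all(sc2$id[sc2$llr > 0] %in% out2$id))

  # degenerate all-equal scan warns and keeps everything
  expect_warning(out3 <- percentile_outliers(toy_scan(rep(2, 10))), "tie")
  expect_equal(nrow(out3), 10)
  expect_error(percentile_outliers(sc, q = 1), "\\(0, 1\\)")
})

test_that("window support keeps pairs at exactly the boundary distance", {
  # a lone outlier far from the rest is removed
  sc <- toy_scan(c(5, 6, 7), pos = c(1e6, 1.05e6, 2e6))
  out <- window_support_filter(sc, window_bp = 1e5)
  expect_setequal(out$id, c("t001", "t002"))

  # exactly 100,000 bp apart: boundary inclusive
  sc2 <- toy_scan(c(5, 6), pos = c(1e6, 1.1e6))
  expect_equal(nrow(window_support_filter(sc2, 1e5)), 2)
  sc3 <- toy_scan(c(5, 6), pos = c(1e6, 1.100001e6))
  expect_equal(nrow(window_support_filter(sc3, 1e5)), 0)

  # same position on different chromosomes does not count as support
  sc4 <- toy_scan(c(5, 6), pos = c(1e6, 1e6), chrom = c("1", "2"))
  expect_equal(nrow(window_support_filter(sc4, 1e5)), 0)

  # hand-enumerated 12-outlier layout
  pos <- c(0.1, 0.15, 0.18, 1.0, 3.0, 3.05, 3.08, 3.2, 5.0, 7.0, 7.09, 9.0) * 1e6
  sc5 <- toy_scan(rep(5, 12), pos = pos)
  out5 <- window_support_filter(sc5, 1e5)
  # brute-force oracle over all pairs
  keep <- vapply(seq_along(pos), function(i) {
    any(abs(pos[-i] - pos[i]) <= 1e5)
  }, logical(1))
  expect_setequal(out5$id, sc5$id[keep])
})

test_that("local-maximum filter keeps window maxima with a position tie rule", {
  # isolated outlier retained
  expect_equal(nrow(local_maximum_filter(toy_scan(5, pos = 1e6), 1e5)), 1)

  # three clustered outliers 5 < 7 < 9: only the maximum survives
  sc <- toy_scan(c(5, 9, 7), pos = c(1e6, 1.02e6, 1.04e6))
  out <- local_maximum_filter(sc, 1e5)
  expect_equal(out$id, "t002")

  # equal statistics 50 kb apart: lower position wins
  sc2 <- toy_scan(c(4, 4), pos = c(2e6, 2.05e6))
  out2 <- local_maximum_filter(sc2, 1e5)
  expect_equal(out2$pos, 2e6)
})

test_that("wide peaks collapse by chaining and report the run maximum", {
  # SNPs spaced beyond the chain distance: one peak each
  sc <- toy_scan(c(5, 6, 7), pos = c(1e6, 3e6, 6e6))
  pk <- collapse_wide_peaks(sc, chain_bp = 1e6)
  expect_equal(nrow(pk), 3)

  # a 6 Mb run each within the chain distance of the next: one peak
  pos <- seq(1e6, 7e6, by = 0.5e6)
  withr::with_seed(95, llr <- stats::runif(length(pos), 1, 10))
  sc2 <- toy_scan(llr, pos = pos)
  pk2 <- collapse_wide_peaks(sc2, chain_bp = 1e6)
  expect_equal(nrow(pk2), 1)
  expect_equal(pk2$top_llr, max(llr))
  expect_equal(pk2$top_snp, sc2$id[which.max(llr)])
  expect_equal(pk2$start, 1e6)
  expect_equal(pk2$end, 7e6)

  # empty input
  expect_equal(nrow(collapse_wide_peaks(toy_scan(numeric(0)))), 0)
})

test_that("top candidates are ordered with deterministic tie-breaks", {
  pk <- tibble::tibble(
    chrom = c("2", "1", "1"), start = c(1L, 1L, 9L), end = c(5L, 5L, 12L),
    top_snp = c("a", "b", "c"), top_llr = c(7, 7, 9),
    top_pos = c(3L, 2L, 10L), n_snps = 1L
  )
  cand <- top_candidates(pk, n = 10)
  expect_equal(nrow(cand), 3)            # fewer peaks than requested
  expect_equal(cand$top_snp, c("c", "b", "a"))  # llr desc, then chrom/pos
  expect_equal(cand$rank, 1:3)
  expect_error(top_candidates(pk, n = 0), ">= 1")
})

test_that("pipeline composition is idempotent and anchored in the outlier set", {
  g <- null_scan_fixture(n_snps = 4000, seed = 97)
  scan <- scan_genome(g, "JEJ", "CHS")
  out99 <- percentile_outliers(scan, 0.99)
  cand <- select_candidates(scan, n = 10)
  # every candidate top SNP is a member of the 99th-percentile set
  expect_true(all(cand$top_snp %in% out99$id))

  # re-running the peak stages on the surviving SNPs returns the same set
  surv <- scan[scan$id %in% cand$top_snp, , drop = FALSE]
  again <- surv |>
    local_maximum_filter() |>
    collapse_wide_peaks() |>
    top_candidates(n = 10)
  expect_setequal(again$top_snp, cand$top_snp)
})

test_that("candidates recover well-separated planted sweeps", {
  panel <- simulate_panel(sim_params(30000, seed = 99))
  sweep_at <- as.integer(seq(1500, 28500, length.out = 10))
  for (s in sweep_at) {
    target <- if (panel$root_freqs[s] < 0.5) {
      min(0.95, panel$root_freqs[s] + 0.3)
    } else {
      max(0.05, panel$root_freqs[s] - 0.3)
    }
    panel <- inject_sweep(panel, s, target_freq = target)
  }
  g <- sample_genotypes(panel, seed = 100)
  scan <- scan_genome(g, "JEJ", "CHS")
  cand <- select_candidates(scan, n = 10)
  sweep_pos <- g$variants$pos[sweep_at]
  sweep_chr <- g$variants$chrom[sweep_at]
  near <- vapply(seq_len(nrow(cand)), function(i) {
    any(sweep_chr == cand$chrom[i] & abs(sweep_pos - cand$top_pos[i]) <= 1e5)
  }, logical(1))
  expect_gte(sum(near), 8)
})

test_that("gene annotation equals a naive interval-overlap oracle", {
  genes <- tibble::tibble(
    chrom = c("1", "1", "1", "2", "2"),
    start = c(100L, 500L, 450L, 100L, 900L),
    end = c(200L, 600L, 550L, 300L, 1000L),
    gene = c("G1", "G2", "G3", "G4", "G5")
  )
  cand <- tibble::tibble(
    chrom = c("1", "1", "1", "2", "2", "3"),
    top_pos = c(150L, 500L, 100L, 300L, 899L, 1L),
    top_snp = sprintf("s%d", 1:6)
  )
  ann <- annotate_candidates(cand, genes)
  expect_equal(ann$genes[1], "G1")
  expect_equal(ann$genes[2], "G2,G3")   # overlapping genes both attached
  expect_equal(ann$genes[3], "G1")      # start coordinate inclusive
  expect_equal(ann$genes[4], "G4")      # end coordinate inclusive
  expect_equal(ann$genes[5], "intergenic")
  expect_equal(ann$genes[6], "intergenic")

  # brute-force O(n*m) oracle
  for (i in seq_len(nrow(cand))) {
    hits <- genes$gene[genes$chrom == cand$chrom[i] &
                         genes$start <= cand$top_pos[i] &
                         genes$end >= cand$top_pos[i]]
    expected <- if (length(hits)) paste(hits, collapse = ",") else "intergenic"
    expect_equal(ann$genes[i], expected)
  }

  expect_error(annotate_candidates(cand, dplyr::mutate(genes, end = start - 1L)),
               "Malformed")
})

test_that("GFF3 gene intervals are read with 1-based inclusive coordinates", {
  skip_if_not_installed("rtracklayer")
  gff <- c(
    "##gff-version 3",
    "1\ttest\tgene\t100\t200\t.\t+\t.\tID=gene1;Name=G1",
    "1\ttest\texon\t100\t150\t.\t+\t.\tID=exon1;Parent=gene1",
    "2\ttest\tgene\t900\t1000\t.\t-\t.\tID=gene2;Name=G5"
  )
  path <- file.path(withr::local_tempdir(), "toy.gff3")
  writeLines(gff, path)
  genes <- read_genes_gff(path)
  expect_equal(nrow(genes), 2)
  expect_equal(genes$start, c(100L, 900L))
  expect_equal(genes$end, c(200L, 1000L))
  expect_equal(genes$gene, c("G1", "G5"))
})

test_that("BED export converts to 0-based half-open at write time", {
  pk <- tibble::tibble(chrom = "1", start = 100L, end = 200L,
                       top_snp = "x", top_llr = 5, top_pos = 150L,
                       n_snps = 3L)
  bed <- peaks_to_bed(pk)
  expect_equal(bed$start, 99L)
  expect_equal(bed$end, 200L)
})
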