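#' Percentile outliers of a scan
#'
#' Retains SNPs whose statistic is at least the empirical `q`-quantile of all
#' scanned statistics (zeros included in the quantile base; membership uses
#' `>=`, so exact ties at the threshold are kept).
#'
#' @param scan A scan table with `id`, `chrom`, `pos`, `llr` columns.
#' @param q Percentile in `(0, 1)`; default 0.99.
#' @return An outlier tibble (same columns) with the threshold in attribute
#'   `"percentile_threshold"`.
#' @export
percentile_outliers <- function(scan, q = 0.99) {
  if (q <= 0 || q >= 1) abort("`q` must be in (0, 1).")
  llr <- scan$llr
  if (length(llr) == 0) abort("Empty scan.")
  thr <- unname(quantile(llr, q, na.rm = TRUE, type = 7))
  out <- scan[!is.na(llr) & llr >= thr, , drop = FALSE]
  if (nrow(out) == nrow(scan)) {
    warn("All statistics tie at the percentile threshold; retaining every SNP.")
  }
  attr(out, "percentile_threshold") <- thr
  out
}

#' Window-support filter
#'
#' Retains outliers that have at least one *other* outlier on the same
#' chromosome within `window_bp` bases (boundary inclusive): an isolated
#' outlier with no nearby support is discarded as likely noise.
#'
#' @param outliers Outlier tibble from [percentile_outliers()].
#' @param window_bp Half-window in bp; default 100,000 (a 200 kb window).
#' @return The filtered outlier tibble.
#' @export
window_support_filter <- function(outliers, window_bp = 1e5) {
  if (nrow(outliers) == 0) return(outliers)
  keep <- vapply(seq_len(nrow(outliers)), function(i) {
    same <- outliers$chrom == outliers$chrom[i]
    near <- abs(outliers$pos - outliers$pos[i]) <= window_bp
    sum(same & near) >= 2  # itself plus at least one other
  }, logical(1))
  res <- outliers[keep, , drop = FALSE]
  attr(res, "percentile_threshold") <- attr(outliers, "percentile_threshold")
  res
}

#' Local-maximum filter
#'
#' Retains outliers whose statistic is strictly greater than every other
#' outlier's within `window_bp` on the same chromosome. Exact ties within a
#' window retain the lower-position SNP.
#'
#' @inheritParams window_support_filter
#' @return The filtered outlier tibble.
#' @export
local_maximum_filter <- function(outliers, window_bp = 1e5) {
  if (nrow(outliers) == 0) return(outliers)
  keep <- vapply(seq_len(nrow(outliers)), function(i) {
    same <- outliers$chrom == outliers$chrom[i] &
      abs(outliers$pos - outliers$pos[i]) <= window_bp
    same[i] <- FALSE
    if (!any(same)) return(TRUE)
    li <- outliers$llr[i]
    lo <- outliers$llr[same]
    po <- outliers$pos[same]
    all(li > lo | (li == lo & outliers$pos[i] < po))
  }, logical(1))
  res <- outliers[keep, , drop = FALSE]
  attr(res, "percentile_threshold") <- attr(outliers, "percentile_threshold")
  res
}

#' Collapse surviving SNPs into peaks
#'
#' Single-linkage chaining: consecutive surviving SNPs on one chromosome
#' within `chain_bp` of each other join one peak, so that a wide signal
#' (e.g. a low-recombination region spanning several megabases) is reported
#' once, represented by its top SNP.
#'
#' @param snps Outlier tibble (will be sorted by coordinate).
#' @param chain_bp Merge distance in bp; default 1,000,000.
#' @return A tibble of peaks: `chrom`, `start`, `end` (1-based inclusive
#'   span of members), `top_snp`, `top_llr`, `top_pos`, `n_snps`.
#' @export
collapse_wide_peaks <- function(snps, chain_bp = 1e6) {
  if (nrow(snps) == 0) {
    return(tibble(chrom = character(0), start = integer(0), end = integer(0),
                  top_snp = character(0), top_llr = numeric(0),
                  top_pos = integer(0), n_snps = integer(0)))
  }
  snps <- arrange(snps, .data$chrom, .data$pos)
  new_peak <- c(TRUE, diff(snps$pos) > chain_bp |
                  snps$chrom[-1] != snps$chrom[-nrow(snps)])
  snps$peak_id <- cumsum(new_peak)
  snps |>
    group_by(.data$peak_id) |>
    summarise(
      chrom = .data$chrom[1],
      start = min(.data$pos), end = max(.data$pos),
      top_snp = .data$id[which.max(.data$llr)],
      top_llr = max(.data$llr),
      top_pos = .data$pos[which.max(.data$llr)],
      n_snps = dplyr::n(), .groups = "drop"
    ) |>
    select(-"peak_id")
}

#' Top candidate peaks
#'
#' Orders peaks by descending top statistic (ties broken by chromosome then
#' position, for determinism) and keeps the first `n`.
#'
#' @param peaks Peak tibble from [collapse_wide_peaks()].
#' @param n Number of candidates requested; default 10.
#' @return The candidate tibble with a `rank` column.
#' @export
top_candidates <- function(peaks, n = 10) {
  if (n < 1) abort("`n` must be >= 1.")
  out <- peaks |>
    arrange(desc(.data$top_llr), .data$chrom, .data$top_pos) |>
    head(n)
  out$rank <- seq_len(nrow(out))
  select(out, "rank", dplyr::everything())
}

#' Run the full peak-selection pipeline
#'
#' Fixed composition: percentile outliers -> window support -> local maximum
#' -> wide-peak collapse -> top n. Re-running the pipeline on its own output
#' returns the same candidates.
#'
#' @param scan A scan table (calibrated or not; `llr` is used for ranking,
#'   and `p_calibrated` is carried through when present).
#' @param q Outlier percentile.
#' @param window_bp Half-window for support and local-maximum rules.
#' @param chain_bp Peak merge distance.
#' @param n Number of candidates.
#' @return Candidate tibble as in [top_candidates()], with `p_calibrated` of
#'   the top SNP joined in when available.
#' @export
select_candidates <- function(scan, q = 0.99, window_bp = 1e5,
                              chain_bp = 1e6, n = 10) {
  out <- scan |>
    percentile_outliers(q = q) |>
    window_support_filter(window_bp = window_bp) |>
    local_maximum_filter(window_bp = window_bp) |>
    collapse_wide_peaks(chain_bp = chain_bp) |>
    top_candidates(n = n)
  if ("p_calibrated" %in% names(scan)) {
    out <- left_join(
      out, select(scan, top_snp = "id", "p_calibrated"), by = "top_snp"
    )
  }
  out
}

#' Annotate candidate SNPs with overlapping genes
#'
#' A SNP is annotated with every gene interval containing it (1-based
#' inclusive coordinates, so a SNP exactly at a gene's start or end is
#' inside); SNPs in no gene are labelled "intergenic".
#'
#' @param candidates Candidate tibble with `chrom` and `top_pos`.
#' @param genes Gene interval tibble with `chrom`, `start`, `end`, `gene`
#'   (e.g. from [read_genes_gff()]).
#' @return `candidates` with a `genes` column (comma-separated names).
#' @export
annotate_candidates <- function(candidates, genes) {
  if (!all(c("chrom", "start", "end", "gene") %in% names(genes))) {
    abort("`genes` needs columns chrom, start, end, gene.")
  }
  if (any(genes$end < genes$start)) abort("Malformed gene intervals.")
  candidates$genes <- vapply(seq_len(nrow(candidates)), function(i) {
    hit <- genes$chrom == candidates$chrom[i] &
      genes$start <= candidates$top_pos[i] &
      genes$end >= candidates$top_pos[i]
    if (any(hit)) paste(genes$gene[hit], collapse = ",") else "intergenic"
  }, character(1))
  candidates
}

#' Read gene intervals from a GFF3 file
#'
#' Extracts `gene` features with 1-based inclusive coordinates.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble: `chrom`, `start`, `end`, `gene`.
#' @export
read_genes_gff <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("Package 'rtracklayer' is required to read GFF3 files.")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  nm <- gr$Name
  if (is.null(nm)) nm <- gr$ID
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    gene = as.character(nm)
  )
}

#' Convert peaks to BED intervals
#'
#' BED uses 0-based half-open coordinates; the conversion happens here, at
#' write time, while all internal coordinates stay 1-based inclusive.
#'
#' @param peaks Peak tibble with `chrom`, `start`, `end`.
#' @return A tibble with BED columns `chrom`, `start` (0-based), `end`.
#' @export
peaks_to_bed <- function(peaks) {
  tibble(
    chrom = peaks$chrom,
    start = peaks$start - 1L,
    end = peaks$end,
    name = peaks$top_snp %||% rep(".", nrow(peaks)),
    score = peaks$top_llr %||% rep(0, nrow(peaks))
  )
}
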