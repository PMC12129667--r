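#' Manhattan-style plot of a selection scan
#'
#' @param scan A scan table from [scan_genome()] (calibrated or not).
#' @param candidates Optional candidate tibble; top SNPs are circled.
#' @param q Percentile whose threshold is drawn as a dashed line.
#' @return A ggplot object.
#' @export
plot_scan_manhattan <- function(scan, candidates = NULL, q = 0.99) {
  thr <- unname(quantile(scan$llr, q, na.rm = TRUE))
  scan$cum_pos <- cumulative_positions(scan)
  p <- ggplot2::ggplot(scan, ggplot2::aes(x = .data$cum_pos, y = .data$llr,
                                          colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.4, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::labs(x = "genomic position", y = "likelihood ratio") +
    ggplot2::theme_minimal()
  if (!is.null(candidates) && nrow(candidates) > 0) {
    hits <- scan[scan$id %in% candidates$top_snp, , drop = FALSE]
    p <- p + ggplot2::geom_point(
      data = hits, shape = 1, size = 3, colour = "black"
    )
  }
  p
}

cumulative_positions <- function(scan) {
  offsets <- scan |>
    group_by(.data$chrom) |>
    summarise(len = max(.data$pos), .groups = "drop") |>
    mutate(offset = cumsum(dplyr::lag(.data$len, default = 0)))
  scan |>
    left_join(offsets, by = "chrom") |>
    mutate(cum_pos = .data$pos + .data$offset) |>
    dplyr::pull(.data$cum_pos)
}

#' QQ plot of calibrated scan statistics
#'
#' Plots nonzero statistics (corrected when available) against the
#' chi-square(1) quantiles expected under the point-mass/chi-square mixture
#' null.
#'
#' @param scan A calibrated scan table with `llr` (and optionally
#'   `llr_corrected`).
#' @return A ggplot object.
#' @export
plot_calibration_qq <- function(scan) {
  obs <- if ("llr_corrected" %in% names(scan)) scan$llr_corrected else scan$llr
  obs <- sort(obs[!is.na(obs) & obs > 0])
  n <- length(obs)
  expd <- qchisq((seq_len(n) - 0.5) / n, df = 1)
  df <- tibble(expected = expd, observed = obs)
  ggplot2::ggplot(df, ggplot2::aes(.data$expected, .data$observed)) +
    ggplot2::geom_point(size = 0.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "chi-square(1) quantile (upper half)",
                  y = "observed statistic") +
    ggplot2::theme_minimal()
}

#' PCA scatter of genotype principal components
#'
#' @param pca A `geno_pca` object.
#' @param axes Two axis indices to display.
#' @return A ggplot object.
#' @export
plot_pca <- function(pca, axes = c(1, 2)) {
  stopifnot(inherits(pca, "geno_pca"))
  cols <- paste0("PC", axes)
  ggplot2::ggplot(pca$scores, ggplot2::aes(
    x = .data[[cols[1]]], y = .data[[cols[2]]], colour = .data$population
  )) +
    ggplot2::geom_point() +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.scan_table <- function(object, ...) plot_scan_manhattan(object, ...)

#' @exportS3Method ggplot2::autoplot
autoplot.geno_pca <- function(object, ...) plot_pca(object, ...)
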