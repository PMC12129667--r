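#' Per-population alternate-allele frequencies
#'
#' Frequencies are computed over non-missing calls. A population with zero
#' called genotypes at a site gets `NA` frequency there.
#'
#' @param geno A [geno_matrix()].
#' @return A tidy tibble with one row per variant x population: `id`,
#'   `chrom`, `pos`, `population`, `freq`, `allele_count`, `n_haplotypes`.
#' @export
allele_frequencies <- function(geno) {
  stopifnot(inherits(geno, "geno_matrix"))
  pops <- unique(geno$samples$population)
  v <- geno$variants
  out <- lapply(pops, function(p) {
    g <- geno$calls[geno$samples$population == p, , drop = FALSE]
    ac <- colSums(g, na.rm = TRUE)
    nh <- 2L * colSums(!is.na(g))
    tibble(
      id = v$id, chrom = v$chrom, pos = v$pos, population = p,
      freq = unname(ifelse(nh > 0, ac / nh, NA_real_)),
      allele_count = unname(as.integer(ac)), n_haplotypes = unname(nh)
    )
  })
  bind_rows(out)
}

freq_matrix <- function(freqs) {
  # long FreqTable -> variants x populations matrix (input variant order)
  pops <- unique(freqs$population)
  ids <- unique(freqs$id)
  mat <- vapply(pops, function(p) {
    sub <- freqs[freqs$population == p, ]
    sub$freq[match(ids, sub$id)]
  }, numeric(length(ids)))
  rownames(mat) <- ids
  mat
}

#' Weir-Cockerham FST between two populations
#'
#' Computes the Weir & Cockerham (1984) variance components a (between
#' populations), b (between individuals within populations), and c (within
#' individuals) per SNP, and the multi-SNP estimate as the ratio of averages
#' `sum(a) / sum(a + b + c)` - not the average of per-SNP ratios.
#'
#' @param geno A [geno_matrix()].
#' @param pops Character vector of exactly two population labels.
#' @return A `wc_fst` object; use [tidy()] for per-variant components and
#'   [glance()] for the overall estimate.
#' @export
wc_fst <- function(geno, pops) {
  stopifnot(inherits(geno, "geno_matrix"))
  if (length(pops) != 2) abort("`pops` must name exactly two populations.")
  if (!all(pops %in% geno$samples$population)) {
    abort("Both populations must be present in the sample table.")
  }
  comp <- lapply(pops, function(p) {
    g <- geno$calls[geno$samples$population == p, , drop = FALSE]
    if (nrow(g) < 2) abort("Each population needs >= 2 samples.")
    n_called <- colSums(!is.na(g))
    list(
      n = n_called,
      p = ifelse(n_called > 0, colSums(g, na.rm = TRUE) / (2 * n_called), NA_real_),
      h = ifelse(n_called > 0, colSums(g == 1, na.rm = TRUE) / n_called, NA_real_)
    )
  })
  n1 <- comp[[1]]$n; n2 <- comp[[2]]$n
  p1 <- comp[[1]]$p; p2 <- comp[[2]]$p
  h1 <- comp[[1]]$h; h2 <- comp[[2]]$h
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  components <- tibble(
    id = geno$variants$id, chrom = geno$variants$chrom,
    pos = geno$variants$pos, a = unname(a), b = unname(b), c = unname(cc),
    defined = unname(is.finite(a + b + cc) & (a + b + cc) != 0)
  )
  denom <- sum((a + b + cc)[components$defined])
  est <- if (denom > 0) sum(a[components$defined]) / denom else NA_real_
  structure(
    list(pop1 = pops[1], pop2 = pops[2], estimate = est,
         n_used = sum(components$defined), components = components,
         undefined = denom <= 0 || !is.finite(denom)),
    class = "wc_fst"
  )
}

#' @export
print.wc_fst <- function(x, ...) {
  cat(sprintf("<wc_fst> %s vs %s: FST = %s (%d SNPs)\n",
              x$pop1, x$pop2,
              if (x$undefined) "undefined" else format(x$estimate, digits = 4),
              x$n_used))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.wc_fst <- function(x, ...) x$components

#' @exportS3Method generics::glance
glance.wc_fst <- function(x, ...) {
  tibble(pop1 = x$pop1, pop2 = x$pop2, fst = x$estimate,
         n_snps_used = x$n_used, undefined = x$undefined)
}

#' Pairwise FST table
#'
#' Convenience wrapper computing [wc_fst()] for every pair of populations,
#' mirroring the layout of a published divergence table (POP1, POP2,
#' estimate).
#'
#' @param geno A [geno_matrix()].
#' @param pops Populations to include (default: all).
#' @return A tibble with one row per population pair.
#' @export
fst_pairs <- function(geno, pops = NULL) {
  pops <- pops %||% unique(geno$samples$population)
  pairs <- utils::combn(pops, 2, simplify = FALSE)
  bind_rows(lapply(pairs, function(pr) glance(wc_fst(geno, pr))))
}

#' Windowed nucleotide diversity and effective population size
#'
#' Per non-overlapping window of `window_bp` bases, computes
#' `pi = sum_sites 2 p (1 - p) * 2n / (2n - 1) / window_bp`
#' (the unbiased per-site heterozygosity, matching the pairwise-difference
#' definition in expectation for unphased genotypes) and the neutral-theory
#' point estimate `Ne = pi / (4 mu)`.
#'
#' @param geno A [geno_matrix()].
#' @param window_bp Window length in bp (>= 1). A single genome-scale window
#'   (e.g. 2.5e8) yields per-chromosome values.
#' @param population Optional population label to subset samples.
#' @param mu Mutation rate per site per generation.
#' @return A tibble: `chrom`, `start`, `end` (1-based inclusive), `n_snps`,
#'   `pi`, `ne_estimate`, `mu`.
#' @export
windowed_pi <- function(geno, window_bp, population = NULL, mu = 1.25e-8) {
  stopifnot(inherits(geno, "geno_matrix"))
  if (window_bp < 1) abort("`window_bp` must be >= 1.")
  if (!is.null(population)) {
    geno <- subset_geno(
      geno, sample_ids = geno$samples$sample_id[
        geno$samples$population == population]
    )
  }
  g <- geno$calls
  n_called <- colSums(!is.na(g))
  nh <- 2 * n_called
  p <- ifelse(nh > 0, colSums(g, na.rm = TRUE) / nh, NA_real_)
  site_pi <- ifelse(nh > 1, 2 * p * (1 - p) * nh / (nh - 1), 0)
  v <- geno$variants
  win <- (v$pos - 1L) %/% as.integer(window_bp)
  agg <- tibble(chrom = v$chrom, win = win, site_pi = site_pi) |>
    group_by(.data$chrom, .data$win) |>
    summarise(
      n_snps = dplyr::n(),
      pi = sum(.data$site_pi, na.rm = TRUE) / window_bp,
      .groups = "drop"
    ) |>
    mutate(
      start = .data$win * as.integer(window_bp) + 1L,
      end = (.data$win + 1L) * as.integer(window_bp),
      ne_estimate = ne_from_pi(.data$pi, mu),
      mu = mu
    ) |>
    select("chrom", "start", "end", "n_snps", "pi", "ne_estimate", "mu") |>
    arrange(.data$chrom, .data$start)
  agg
}

#' Effective population size from nucleotide diversity
#'
#' Neutral-theory point estimate `Ne = pi / (4 mu)`.
#'
#' @param pi Per-site nucleotide diversity (>= 0).
#' @param mu Mutation rate per site per generation (> 0).
#' @return Effective population size (same length as `pi`).
#' @export
ne_from_pi <- function(pi, mu = 1.25e-8) {
  if (any(mu <= 0)) abort("`mu` must be > 0.")
  if (any(pi < 0, na.rm = TRUE)) abort("`pi` must be >= 0.")
  pi / (4 * mu)
}

#' Convert generations to years
#'
#' @param generations Number of generations (> 0).
#' @param generation_time Years per generation (> 0); 27 years is the
#'   standard value for East Asian populations.
#' @return Years.
#' @export
generations_to_years <- function(generations, generation_time = 27) {
  if (any(generations <= 0) || any(generation_time <= 0)) {
    abort("Both arguments must be > 0.")
  }
  generations * generation_time
}

#' Genotype principal-component analysis
#'
#' Dosages are centered by `2 p` and scaled by `sqrt(2 p (1 - p))` per
#' variant (monomorphic variants dropped); missing calls are mean-imputed
#' before standardization. Scores are eigenvectors of the sample-by-sample
#' covariance scaled by the square root of their eigenvalues.
#'
#' @param geno A [geno_matrix()].
#' @param k Number of axes (`k <= min(samples - 1, variants)`).
#' @return A `geno_pca` object; [tidy()] returns per-sample scores,
#'   [glance()] the eigenvalues.
#' @export
pca_genotypes <- function(geno, k = 10) {
  stopifnot(inherits(geno, "geno_matrix"))
  g <- geno$calls
  n <- nrow(g)
  p <- colMeans(g, na.rm = TRUE) / 2
  keep <- is.finite(p) & p > 0 & p < 1
  if (!any(keep)) abort("All variants are monomorphic; PCA is undefined.")
  if (k > min(n - 1, sum(keep))) {
    abort("`k` exceeds min(samples - 1, informative variants).")
  }
  g <- g[, keep, drop = FALSE]
  p <- p[keep]
  x <- sweep(g, 2, 2 * p, `-`)
  x[is.na(x)] <- 0
  x <- sweep(x, 2, sqrt(2 * p * (1 - p)), `/`)
  cov <- tcrossprod(x) / ncol(x)
  eig <- eigen(cov, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  scores <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(vals[seq_len(k)]), k)
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(
    list(
      scores = bind_cols(
        geno$samples,
        as_tibble(scores)
      ),
      eigenvalues = vals,
      k = k, n_variants_used = ncol(x)
    ),
    class = "geno_pca"
  )
}

#' @export
print.geno_pca <- function(x, ...) {
  cat(sprintf("<geno_pca> %d samples, %d axes (of %d variants)\n",
              nrow(x$scores), x$k, x$n_variants_used))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.geno_pca <- function(x, ...) x$scores

#' @exportS3Method generics::glance
glance.geno_pca <- function(x, ...) {
  tibble(axis = seq_along(x$eigenvalues), eigenvalue = x$eigenvalues,
         prop_var = x$eigenvalues / sum(x$eigenvalues))
}
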