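#' Per-variant QC statistics
#'
#' Computes, across all samples jointly: the minor-allele frequency over
#' non-missing calls and the one-sided heterozygote-excess exact-test
#' p-value.
#'
#' @param geno A [geno_matrix()].
#' @return A tibble: `id`, `chrom`, `pos`, `maf`, `exchet_p`, and genotype
#'   counts `n_AA`, `n_Aa`, `n_aa`.
#' @export
variant_qc <- function(geno) {
  stopifnot(inherits(geno, "geno_matrix"))
  g <- geno$calls
  n_aa0 <- colSums(g == 0, na.rm = TRUE)
  n_het <- colSums(g == 1, na.rm = TRUE)
  n_aa2 <- colSums(g == 2, na.rm = TRUE)
  n_called <- n_aa0 + n_het + n_aa2
  p_alt <- ifelse(n_called > 0, (n_het + 2 * n_aa2) / (2 * n_called), NA_real_)
  maf <- pmin(p_alt, 1 - p_alt)
  tibble(
    id = geno$variants$id, chrom = geno$variants$chrom,
    pos = geno$variants$pos, maf = unname(maf),
    exchet_p = unname(exchet_test(n_aa0, n_het, n_aa2)),
    n_AA = unname(n_aa0), n_Aa = unname(n_het), n_aa = unname(n_aa2)
  )
}

#' Minor-allele-frequency filter
#'
#' Retains variants whose minor-allele frequency, computed across all samples
#' jointly, is at least `threshold`.
#'
#' @param geno A [geno_matrix()].
#' @param threshold MAF threshold in `[0, 0.5)`; the study default is 0.01.
#' @return A filtered `geno_matrix` with attribute `"filter_report"`, a
#'   one-row tibble of removed/retained counts.
#' @export
maf_filter <- function(geno, threshold = 0.01) {
  stopifnot(inherits(geno, "geno_matrix"))
  if (threshold < 0 || threshold >= 0.5) abort("`threshold` must be in [0, 0.5).")
  if (n_variants(geno) == 0) abort("Empty genotype matrix.")
  qc <- variant_qc(geno)
  keep <- !is.na(qc$maf) & qc$maf >= threshold
  out <- subset_geno(geno, variant_ids = qc$id[keep])
  attr(out, "filter_report") <- tibble(
    filter = "maf", threshold = threshold,
    removed = sum(!keep), retained = sum(keep)
  )
  out
}

#' One-sided exact test for heterozygote excess
#'
#' Exact conditional test of Hardy-Weinberg equilibrium against heterozygote
#' excess: given the allele counts, the heterozygote count follows the exact
#' conditional (Levene/Haldane) distribution, and the p-value is the
#' probability of observing at least as many heterozygotes as seen. This is
#' the semantics of the `ExcHet` site annotation. Computed with the standard
#' ratio recurrence on the heterozygote count; vectorized over sites.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (non-negative, total >= 1).
#' @return P-values in `(0, 1]`; a site with no heterozygotes has p = 1.
#' @export
exchet_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) abort("Genotype counts must be >= 0.")
  n <- length(n_AA)
  stopifnot(length(n_Aa) == n, length(n_aa) == n)
  vapply(seq_len(n), function(i) {
    exchet_one(n_AA[i], n_Aa[i], n_aa[i])
  }, numeric(1))
}

exchet_one <- function(n_AA, n_Aa, n_aa) {
  n_tot <- n_AA + n_Aa + n_aa
  if (n_tot < 1) abort("Total genotype count must be >= 1.")
  n_a <- 2 * n_AA + n_Aa    # minor-allele-count convention is irrelevant:
  n_b <- 2 * n_aa + n_Aa    # the distribution is symmetric in the alleles
  rare <- min(n_a, n_b)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)  # feasible het counts share parity
  # unnormalized probabilities via the ratio recurrence:
  # P(h + 2) / P(h) = 4 * nAA(h) * naa(h) / ((h + 2) * (h + 1))
  lp <- numeric(length(hets))
  for (j in seq_along(lp)[-1]) {
    h <- hets[j - 1]
    n_hom_a <- (n_a - h) / 2
    n_hom_b <- (n_b - h) / 2
    lp[j] <- lp[j - 1] +
      log(4 * n_hom_a * n_hom_b) - log((h + 2) * (h + 1))
  }
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  min(1, sum(pr[hets >= n_Aa]))
}

#' Remove variants failing the heterozygote-excess filter
#'
#' Drops variants whose one-sided exact-test p-value is `<= alpha`
#' (default 1e-6, the conventional site-filter cutoff).
#'
#' @param geno A [geno_matrix()].
#' @param alpha P-value threshold in `(0, 1)`.
#' @return A filtered `geno_matrix` with a `"filter_report"` attribute.
#' @export
apply_exchet_filter <- function(geno, alpha = 1e-6) {
  stopifnot(inherits(geno, "geno_matrix"))
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  qc <- variant_qc(geno)
  keep <- qc$exchet_p > alpha
  out <- subset_geno(geno, variant_ids = qc$id[keep])
  attr(out, "filter_report") <- tibble(
    filter = "exchet", threshold = alpha,
    removed = sum(!keep), retained = sum(keep)
  )
  out
}

k0_em_pair <- function(g1, g2, p, tol = 1e-8, max_iter = 200) {
  # composite-likelihood MLE of (k0, k1, k2) for one pair, frequencies fixed:
  # per-site genotype-pair probabilities under 0/1/2 shared alleles, EM on
  # the mixture weights. Deterministic given the genotypes and frequencies.
  both <- !is.na(g1) & !is.na(g2)
  g1 <- g1[both]; g2 <- g2[both]; p <- p[both]
  q <- 1 - p
  hw <- function(g) ifelse(g == 2, p^2, ifelse(g == 1, 2 * p * q, q^2))
  bern <- function(x) ifelse(x == 1, p, ifelse(x == 0, q, 0))
  p0 <- hw(g1) * hw(g2)
  p1 <- p * bern(g1 - 1) * bern(g2 - 1) + q * bern(g1) * bern(g2)
  p2 <- hw(g1) * (g1 == g2)
  k <- c(1, 1, 1) / 3
  for (it in seq_len(max_iter)) {
    denom <- k[1] * p0 + k[2] * p1 + k[3] * p2
    w <- cbind(k[1] * p0, k[2] * p1, k[3] * p2) / denom
    k_new <- colMeans(w)
    if (max(abs(k_new - k)) < tol) {
      k <- k_new
      break
    }
    k <- k_new
  }
  list(k0 = min(1, max(0, k[1])), n = length(g1))
}

sample_alt_freqs <- function(geno) {
  pmin(pmax(colMeans(geno$calls, na.rm = TRUE) / 2, 1e-6), 1 - 1e-6)
}

#' Pairwise K0 relatedness estimates
#'
#' Estimates `K0 = P(IBD = 0)` for every sample pair by maximizing the
#' composite likelihood of the observed genotype pairs over the
#' identity-by-descent mixture (0, 1, or 2 alleles shared), with per-site
#' genotype-pair probabilities conditioned on the sample allele frequencies.
#' The estimate is deterministic given genotypes and frequencies, and is
#' truncated to `[0, 1]`. Identical genomes and parent-offspring pairs give
#' K0 near 0; unrelated pairs near 1. Stable from roughly a thousand
#' informative SNPs upward (an opposite-homozygote count alone would need
#' tens of thousands).
#'
#' @param geno A [geno_matrix()].
#' @return A tibble with `sample_1`, `sample_2`, `k0`, `n_snps` (sites called
#'   in both samples).
#' @export
pairwise_k0 <- function(geno) {
  stopifnot(inherits(geno, "geno_matrix"))
  g <- geno$calls
  p <- sample_alt_freqs(geno)
  ids <- geno$samples$sample_id
  n <- length(ids)
  pairs <- utils::combn(n, 2)
  res <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    est <- k0_em_pair(g[i1, ], g[i2, ], p)
    tibble(sample_1 = ids[i1], sample_2 = ids[i2],
           k0 = est$k0, n_snps = est$n)
  })
  bind_rows(res)
}

#' K0 for one sample pair
#'
#' @param geno A [geno_matrix()].
#' @param pair Character vector of two sample ids.
#' @return One-row tibble as in [pairwise_k0()].
#' @export
estimate_k0 <- function(geno, pair) {
  stopifnot(inherits(geno, "geno_matrix"))
  if (length(pair) != 2 || !all(pair %in% geno$samples$sample_id)) {
    abort("`pair` must name two samples present in the matrix.")
  }
  g <- geno$calls[match(pair, geno$samples$sample_id), , drop = FALSE]
  both <- !is.na(g[1, ]) & !is.na(g[2, ])
  if (sum(both) < 100) {
    abort("Fewer than 100 SNPs called in both samples; K0 is unreliable.")
  }
  est <- k0_em_pair(g[1, ], g[2, ], sample_alt_freqs(geno))
  tibble(sample_1 = pair[1], sample_2 = pair[2], k0 = est$k0, n_snps = est$n)
}

#' Iteratively prune related samples
#'
#' Computes all pairwise K0 values, flags pairs against the threshold, and
#' removes one member per flagged pair (the later sample in input order, for
#' determinism), repeating until no flagged pairs remain.
#'
#' The conventional reading of K0 is that *low* values indicate relatedness
#' (two relatives rarely sit in IBS state 0), so the default comparator flags
#' pairs with `k0 < threshold`. Published pipelines have stated the opposite
#' direction for the same threshold; the comparator is therefore exposed
#' rather than hard-wired.
#'
#' @param geno A [geno_matrix()].
#' @param threshold K0 threshold in `(0, 1)`; default 0.75.
#' @param comparator `"less"` (default: flag `k0 < threshold` as related) or
#'   `"greater"` (flag `k0 > threshold`).
#' @return A list: `geno` (pruned matrix), `retained` and `excluded` sample
#'   ids, `n_iterations`, and the final `k0` table.
#' @export
prune_related <- function(geno, threshold = 0.75,
                          comparator = c("less", "greater")) {
  stopifnot(inherits(geno, "geno_matrix"))
  if (threshold <= 0 || threshold >= 1) abort("`threshold` must be in (0, 1).")
  comparator <- match.arg(comparator)
  input_order <- geno$samples$sample_id
  excluded <- character(0)
  current <- geno
  iter <- 0L
  repeat {
    iter <- iter + 1L
    k0 <- pairwise_k0(current)
    flagged <- if (comparator == "less") k0$k0 < threshold else k0$k0 > threshold
    if (!any(flagged)) break
    drop <- unique(vapply(which(flagged), function(i) {
      pr <- c(k0$sample_1[i], k0$sample_2[i])
      pr[which.max(match(pr, input_order))]
    }, character(1)))
    excluded <- c(excluded, drop)
    current <- subset_geno(
      current, sample_ids = setdiff(current$samples$sample_id, drop)
    )
    if (n_samples(current) < 2) break
  }
  list(
    geno = current, retained = current$samples$sample_id,
    excluded = excluded, n_iterations = iter, k0 = k0
  )
}

#' Detect allele flips between two merged panels
#'
#' Flags variants at which one panel is fixed (within tolerance `eps`) for
#' the reference allele and the other fixed for the alternate allele - the
#' fixed-difference signature of allele-coding (strand/flip) errors between
#' merged datasets.
#'
#' @param freqs_a,freqs_b Per-variant alternate-allele frequencies for the
#'   two panels: either named numeric vectors or tibbles with `id` and
#'   `freq` columns. Only the shared variant set is examined.
#' @param eps Tolerance around 0/1 for "fixed" (default 0: exactly fixed).
#' @return A tibble of flagged variants (`id`, `freq_a`, `freq_b`) with the
#'   applied rule stored in attribute `"rule"`.
#' @export
detect_allele_flips <- function(freqs_a, freqs_b, eps = 0) {
  fa <- as_freq_vector(freqs_a)
  fb <- as_freq_vector(freqs_b)
  shared <- intersect(names(fa), names(fb))
  if (length(shared) == 0) abort("The panels share no variants.")
  fa <- fa[shared]; fb <- fb[shared]
  flagged <- (fa <= eps & fb >= 1 - eps) | (fa >= 1 - eps & fb <= eps)
  flagged[is.na(flagged)] <- FALSE
  out <- tibble(id = shared[flagged], freq_a = unname(fa[flagged]),
                freq_b = unname(fb[flagged]))
  attr(out, "rule") <- sprintf(
    "one panel fixed REF, other fixed ALT (tolerance eps = %g)", eps
  )
  out
}

as_freq_vector <- function(x) {
  if (is_tibble(x) || is.data.frame(x)) {
    setNames(x$freq, x$id)
  } else if (is.numeric(x) && !is.null(names(x))) {
    x
  } else {
    abort("Frequencies must be a named vector or a tibble with id/freq.")
  }
}

#' Panel allele frequencies for flip detection
#'
#' @param geno A [geno_matrix()].
#' @param sample_ids Samples forming the panel.
#' @return Tibble with `id`, `freq` over the given samples.
#' @export
panel_frequencies <- function(geno, sample_ids) {
  g <- geno$calls[match(sample_ids, geno$samples$sample_id), , drop = FALSE]
  nh <- 2 * colSums(!is.na(g))
  tibble(
    id = geno$variants$id,
    freq = unname(ifelse(nh > 0, colSums(g, na.rm = TRUE) / nh, NA_real_))
  )
}
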