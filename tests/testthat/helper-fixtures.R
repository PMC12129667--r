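# Small in-code fixtures shared across test files.

# Build a geno_matrix from a dosage matrix (samples x variants) and a
# population label per sample; synthetic coordinates at 3 kb spacing.
make_geno <- function(calls, populations, spacing_bp = 3000, chrom = "1") {
  calls <- as.matrix(calls)
  n <- nrow(calls)
  m <- ncol(calls)
  geno_matrix(
    calls,
    samples = tibble::tibble(
      sample_id = sprintf("s%03d", seq_len(n)),
      population = rep_len(populations, n)
    ),
    variants = tibble::tibble(
      id = sprintf("v%04d", seq_len(m)),
      chrom = chrom,
      pos = as.integer((seq_len(m) - 1L) * spacing_bp + 1L),
      ref = "A", alt = "C"
    )
  )
}

# Two-population genotypes drawn from explicit per-population frequencies.
sample_two_pop_geno <- function(freq1, freq2, n1, n2, seed = 1) {
  m <- length(freq1)
  withr::with_seed(seed, {
    g1 <- matrix(stats::rbinom(n1 * m, 2, rep(freq1, each = n1)), nrow = n1)
    g2 <- matrix(stats::rbinom(n2 * m, 2, rep(freq2, each = n2)), nrow = n2)
  })
  make_geno(rbind(g1, g2), c(rep("P1", n1), rep("P2", n2)))
}

# Independent oracle for the heterozygote-excess exact test: direct
# log-factorial evaluation of the conditional (Levene/Haldane) distribution,
# P(het = h | allele counts) = n! nA! nB! 2^h / (nAA! h! nBB! (2n)!).
exchet_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_a <- 2 * n_AA + n_Aa
  n_b <- 2 * n_aa + n_Aa
  rare <- min(n_a, n_b)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    haa <- (n_a - h) / 2
    hbb <- (n_b - h) / 2
    lfactorial(n) + lfactorial(n_a) + lfactorial(n_b) + h * log(2) -
      lfactorial(haa) - lfactorial(h) - lfactorial(hbb) - lfactorial(2 * n)
  }, numeric(1))
  pr <- exp(logp)
  sum(pr[hets >= n_Aa]) / sum(pr)
}

# Scan scenario used by several scan/peak tests: a null Balding-Nichols
# panel at the default study conditions.
null_scan_fixture <- function(n_snps = 3000, seed = 42) {
  panel <- simulate_panel(sim_params(n_snps = n_snps, seed = seed))
  sample_genotypes(panel, seed = seed + 1)
}
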