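#' Simulation parameters for a drift-structured SNP panel
#'
#' Defines the study conditions the generator emulates: three populations
#' related by a star-like drift tree (a focal island population, a mainland
#' sister population, and a more diverged outgroup), ancestral allele
#' frequencies, per-branch Balding-Nichols drift, optional loci with excess
#' focal drift, and diploid sample sizes.
#'
#' Defaults mirror the cohort the analysis is designed for: sample sizes of
#' 57 / 84 / 50 diploid individuals, branch drift chosen so that pairwise
#' Weir-Cockerham FST lands on the observed scale (focal-sister about 0.0035,
#' sister-outgroup about 0.0045), and a mutation rate of 1.25e-8 per site per
#' generation.
#'
#' @param n_snps Number of biallelic SNPs.
#' @param population_names Labels for (focal, sister, outgroup).
#' @param branch_drift Named numeric: Balding-Nichols `F` per branch
#'   (focal, sister, outgroup); all must be `>= 0` and `< 1`.
#' @param root_freq_law Ancestral frequency law: either
#'   `list(law = "uniform", lo, hi)` with `0 < lo < hi < 1`, or
#'   `list(law = "beta", a, b)` truncated away from exact 0/1.
#' @param sample_sizes Named integer vector of diploid individuals per
#'   population (each `>= 2`).
#' @param n_selected Number of loci given excess focal drift.
#' @param selection_boost Multiplier (`>= 1`) on the focal branch drift at
#'   selected loci.
#' @param cluster_size Selected loci are placed in runs of consecutive SNPs of
#'   this length, so that a selection signal spans a window rather than a
#'   single site (the peak rules require within-window support).
#' @param mu Mutation rate per site per generation.
#' @param spacing_bp Inter-SNP spacing for synthetic coordinates.
#' @param snps_per_chrom SNPs per synthetic chromosome.
#' @param seed Integer seed; every downstream draw is a pure function of the
#'   parameters and this seed.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_snps,
                       population_names = c("JEJ", "KOR", "CHS"),
                       branch_drift = c(focal = 0.004, sister = 0.003,
                                        outgroup = 0.006),
                       root_freq_law = list(law = "uniform", lo = 0.05, hi = 0.95),
                       sample_sizes = c(focal = 57, sister = 84, outgroup = 50),
                       n_selected = 0,
                       selection_boost = 1,
                       cluster_size = 3,
                       mu = 1.25e-8,
                       spacing_bp = 3000,
                       snps_per_chrom = 1e5,
                       seed = 1L) {
  if (length(n_snps) != 1 || n_snps < 1) abort("`n_snps` must be a positive count.")
  if (length(population_names) != 3) abort("Exactly 3 populations are modelled.")
  if (any(branch_drift < 0) || any(branch_drift >= 1)) {
    abort("Branch drift parameters must lie in [0, 1).")
  }
  if (selection_boost < 1) abort("`selection_boost` must be >= 1.")
  if (any(sample_sizes < 2)) abort("Sample sizes must be >= 2.")
  if (n_selected < 0 || n_selected > n_snps) {
    abort("`n_selected` must lie in [0, n_snps].")
  }
  law <- root_freq_law$law %||% "uniform"
  if (law == "uniform") {
    lo <- root_freq_law$lo; hi <- root_freq_law$hi
    if (!(lo > 0 && hi < 1 && lo < hi)) {
      abort("Uniform root frequencies need 0 < lo < hi < 1.")
    }
  } else if (law == "beta") {
    if (!(root_freq_law$a > 0 && root_freq_law$b > 0)) {
      abort("Beta root law needs positive shape parameters.")
    }
  } else {
    abort("`root_freq_law$law` must be 'uniform' or 'beta'.")
  }
  structure(
    list(
      n_snps = as.integer(n_snps), population_names = population_names,
      branch_drift = branch_drift, root_freq_law = root_freq_law,
      sample_sizes = sample_sizes, n_selected = as.integer(n_selected),
      selection_boost = selection_boost, cluster_size = as.integer(cluster_size),
      mu = mu, spacing_bp = as.integer(spacing_bp),
      snps_per_chrom = as.integer(snps_per_chrom), seed = as.integer(seed)
    ),
    class = "sim_params"
  )
}

bn_draw <- function(p0, f) {
  # Balding-Nichols step: Beta with mean p0 and variance f * p0 (1 - p0).
  # f = 0 is the zero-drift identity.
  out <- p0
  pos <- f > 0
  if (any(pos)) {
    a <- p0[pos] * (1 - f[pos]) / f[pos]
    b <- (1 - p0[pos]) * (1 - f[pos]) / f[pos]
    out[pos] <- rbeta(sum(pos), a, b)
  }
  out
}

#' Simulate population allele frequencies under Balding-Nichols drift
#'
#' Draws ancestral frequencies from the configured root law and, for each
#' population, a Balding-Nichols Beta step around the root with per-branch
#' drift variance `F * p0 * (1 - p0)`. Selected loci use
#' `F_focal * selection_boost` on the focal branch. The Beta parametrization
#' keeps frequencies strictly inside (0, 1) without clipping.
#'
#' @param params A [sim_params()] object.
#' @return A `sim_panel`: list with `root_freqs`, `pop_freqs` (matrix,
#'   SNPs x populations), `selected_loci` (integer indices), and `params`.
#' @export
simulate_panel <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  withr::with_seed(params$seed, {
    m <- params$n_snps
    law <- params$root_freq_law
    p0 <- if (law$law == "uniform") {
      runif(m, law$lo, law$hi)
    } else {
      pmin(pmax(rbeta(m, law$a, law$b), 1e-4), 1 - 1e-4)
    }
    selected <- integer(0)
    if (params$n_selected > 0) {
      n_clusters <- ceiling(params$n_selected / params$cluster_size)
      block <- m %/% n_clusters
      if (block < params$cluster_size) {
        abort("Too many selected loci for the panel size.")
      }
      # one cluster per equal-sized genome block, at a random offset,
      # guaranteeing disjoint, well-separated signals
      starts <- (seq_len(n_clusters) - 1L) * block +
        sample.int(block - params$cluster_size + 1L, n_clusters,
                   replace = TRUE)
      selected <- unlist(lapply(starts, function(s) {
        s + seq_len(params$cluster_size) - 1L
      }))
      selected <- head(selected, params$n_selected)
    }
    fd <- params$branch_drift
    f_focal <- rep(fd[["focal"]], m)
    f_focal[selected] <- fd[["focal"]] * params$selection_boost
    pop_freqs <- cbind(
      bn_draw(p0, f_focal),
      bn_draw(p0, rep(fd[["sister"]], m)),
      bn_draw(p0, rep(fd[["outgroup"]], m))
    )
    colnames(pop_freqs) <- params$population_names
    structure(
      list(root_freqs = p0, pop_freqs = pop_freqs,
           selected_loci = sort(selected), params = params),
      class = "sim_panel"
    )
  })
}

#' @export
print.sim_panel <- function(x, ...) {
  cat(sprintf(
    "<sim_panel> %d SNPs, %d populations, %d selected loci (seed %d)\n",
    length(x$root_freqs), ncol(x$pop_freqs), length(x$selected_loci),
    x$params$seed
  ))
  invisible(x)
}

#' Inject a deterministic selective sweep into a simulated panel
#'
#' Sets the focal-population frequency at one SNP to a target value (a
#' completed or ongoing sweep) and shifts a configurable number of flanking
#' SNPs part of the way toward the same target, emulating the hitchhiking
#' footprint of a selected region without modelling linkage explicitly.
#'
#' @param panel A `sim_panel`.
#' @param snp Index of the causal SNP.
#' @param target_freq Focal-population frequency at the causal SNP.
#' @param flank Number of SNPs on each side to drag along.
#' @param flank_frac Fraction of the causal displacement applied to flanks.
#'   Flank frequencies move by `flank_frac * (target_freq - root_freq[snp])`
#'   (clamped to (0.01, 0.99)), so the causal SNP always carries the largest
#'   displacement of the cluster.
#' @return The modified `sim_panel`; the causal SNP and flanks are appended to
#'   `selected_loci`, and the causal index is stored as attribute
#'   `"causal_snp"`.
#' @export
inject_sweep <- function(panel, snp, target_freq, flank = 4, flank_frac = 0.45) {
  stopifnot(inherits(panel, "sim_panel"))
  m <- length(panel$root_freqs)
  if (snp < 1 || snp > m) abort("`snp` out of range.")
  if (target_freq <= 0 || target_freq >= 1) abort("`target_freq` must be in (0,1).")
  focal <- 1L
  displacement <- target_freq - panel$root_freqs[snp]
  panel$pop_freqs[snp, focal] <- target_freq
  idx <- setdiff(
    intersect(seq(snp - flank, snp + flank), seq_len(m)), snp
  )
  p <- panel$pop_freqs[idx, focal]
  panel$pop_freqs[idx, focal] <- pmin(0.99, pmax(0.01, p + flank_frac * displacement))
  panel$selected_loci <- sort(union(panel$selected_loci, c(snp, idx)))
  attr(panel, "causal_snp") <- as.integer(snp)
  panel
}

#' Sample diploid genotypes from a simulated panel
#'
#' Each individual's dosage at each SNP is Binomial(2, population frequency).
#' Variants are placed on synthetic chromosomes at fixed spacing so that
#' windowed peak rules operate on realistic coordinates.
#'
#' @param panel A `sim_panel` from [simulate_panel()].
#' @param sizes Named diploid sample sizes per population; defaults to the
#'   panel's parameters.
#' @param seed Integer seed.
#' @return A [geno_matrix()] whose samples carry population labels
#'   matching the panel's population names.
#' @export
sample_genotypes <- function(panel, sizes = NULL, seed = 1L) {
  stopifnot(inherits(panel, "sim_panel"))
  params <- panel$params
  sizes <- sizes %||% params$sample_sizes
  if (any(sizes < 1)) abort("Sample sizes must be positive.")
  pops <- params$population_names
  m <- nrow(panel$pop_freqs)
  withr::with_seed(as.integer(seed), {
    calls <- do.call(rbind, lapply(seq_along(pops), function(i) {
      n <- sizes[[i]]
      matrix(
        rbinom(n * m, 2L, rep(panel$pop_freqs[, i], each = n)),
        nrow = n, ncol = m
      )
    }))
  })
  sample_ids <- unlist(lapply(seq_along(pops), function(i) {
    sprintf("%s_%03d", pops[i], seq_len(sizes[[i]]))
  }))
  samples <- tibble(
    sample_id = sample_ids,
    population = rep(pops, times = unname(sizes[seq_along(pops)]))
  )
  idx <- seq_len(m) - 1L
  chrom <- as.character(idx %/% params$snps_per_chrom + 1L)
  pos <- (idx %% params$snps_per_chrom) * params$spacing_bp + 1L
  variants <- tibble(
    id = sprintf("snp_%06d", seq_len(m)),
    chrom = chrom, pos = as.integer(pos), ref = "A", alt = "C"
  )
  g <- geno_matrix(calls, samples, variants)
  attr(g, "panel") <- panel
  g
}

#' Phenotype-model parameters
#'
#' @param causal_snp Variant id of the causal SNP (must exist in the genotype
#'   matrix passed to [simulate_phenotype()]).
#' @param beta_per_allele Phenotype units per alternate allele; the default
#'   -10 emulates a roughly 10-unit (mm Hg) decrease per selected allele.
#' @param intercept Baseline phenotype value.
#' @param covariate_laws Named list of `c(mean, sd)` for age (years), height
#'   (cm), weight (kg), and dive_duration (s); defaults describe an aging
#'   female diving cohort (mean age 65).
#' @param covariate_effects Named numeric, phenotype units per covariate unit.
#' @param noise_sd Residual standard deviation (> 0).
#' @param seed Integer seed.
#' @return A `pheno_params` list.
#' @export
pheno_params <- function(causal_snp,
                         beta_per_allele = -10,
                         intercept = 60,
                         covariate_laws = list(
                           age = c(mean = 65, sd = 8),
                           height = c(mean = 157, sd = 6),
                           weight = c(mean = 60, sd = 8),
                           dive_duration = c(mean = 30, sd = 12)
                         ),
                         covariate_effects = c(
                           age = 0.25, height = -0.05, weight = 0.15,
                           dive_duration = 0.05
                         ),
                         noise_sd = 8,
                         seed = 1L) {
  if (noise_sd <= 0) abort("`noise_sd` must be > 0.")
  structure(
    list(causal_snp = causal_snp, beta_per_allele = beta_per_allele,
         intercept = intercept, covariate_laws = covariate_laws,
         covariate_effects = covariate_effects, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "pheno_params"
  )
}

#' Simulate a quantitative phenotype with an additive genetic effect
#'
#' Phenotype = intercept + beta * dosage(causal SNP) + sum of covariate
#' effects + Gaussian noise. Covariates are drawn independently from their
#' configured laws (dive duration is truncated at 5 s from below).
#'
#' @param geno A [geno_matrix()].
#' @param params A [pheno_params()] object.
#' @param sample_ids Samples to phenotype (default: all).
#' @return A tibble with columns `sample_id`, `phenotype`, `age`, `height`,
#'   `weight`, `dive_duration`, `population`.
#' @export
simulate_phenotype <- function(geno, params, sample_ids = NULL) {
  stopifnot(inherits(geno, "geno_matrix"), inherits(params, "pheno_params"))
  if (!params$causal_snp %in% geno$variants$id) {
    abort(sprintf("Causal SNP '%s' not present in the genotype matrix.",
                  params$causal_snp))
  }
  ids <- sample_ids %||% geno$samples$sample_id
  si <- match(ids, geno$samples$sample_id)
  if (anyNA(si)) abort("Unknown sample id in `sample_ids`.")
  dos <- geno$calls[si, params$causal_snp]
  dos[is.na(dos)] <- 0
  n <- length(ids)
  withr::with_seed(params$seed, {
    cl <- params$covariate_laws
    covs <- tibble(
      age = rnorm(n, cl$age[["mean"]], cl$age[["sd"]]),
      height = rnorm(n, cl$height[["mean"]], cl$height[["sd"]]),
      weight = rnorm(n, cl$weight[["mean"]], cl$weight[["sd"]]),
      dive_duration = pmax(5, rnorm(n, cl$dive_duration[["mean"]],
                                    cl$dive_duration[["sd"]]))
    )
    eff <- params$covariate_effects
    lin <- params$intercept + params$beta_per_allele * dos +
      as.matrix(covs) %*% eff[colnames(covs)]
    phenotype <- drop(lin) + rnorm(n, 0, params$noise_sd)
  })
  tibble(
    sample_id = ids, phenotype = phenotype,
    age = covs$age, height = covs$height, weight = covs$weight,
    dive_duration = covs$dive_duration,
    population = geno$samples$population[si]
  )
}

#' Inject genotype artifacts: allele flips and related sample pairs
#'
#' Two artifact classes the QC stage must catch are planted with known ground
#' truth:
#'
#' * **Allele flips.** At `n_flips` sites that are monomorphic across all
#'   samples, genotypes of a designated sample subset ("panel B", by default
#'   the second half of the samples) are recoded as `2 - g`, producing an
#'   apparent fixed difference between the two panels - the signature of a
#'   strand/allele coding error between merged datasets.
#' * **Related pairs.** For `n_related_pairs` disjoint sample pairs, the
#'   second member's genotypes are replaced by a Mendelian child of the first:
#'   at each SNP one allele is copied from the template and one is drawn from
#'   the template's population frequency, yielding a parent-offspring-like
#'   pair with near-zero K0.
#'
#' @param geno A [geno_matrix()].
#' @param n_flips Number of allele flips to plant (requires at least that
#'   many monomorphic sites).
#' @param n_related_pairs Number of related pairs (at most half the samples).
#' @param seed Integer seed.
#' @param panel_b Sample ids forming panel B; default second half.
#' @return The modified `geno_matrix`, with attribute `"injected"`: a list
#'   with `flips` (variant ids), `pairs` (tibble of template/relative ids),
#'   and `panel_b`.
#' @export
inject_artifacts <- function(geno, n_flips = 0, n_related_pairs = 0,
                             seed = 1L, panel_b = NULL) {
  stopifnot(inherits(geno, "geno_matrix"))
  n <- n_samples(geno)
  if (n_related_pairs > floor(n / 2)) {
    abort("`n_related_pairs` exceeds floor(samples / 2).")
  }
  if (n_flips > n_variants(geno)) abort("`n_flips` exceeds the number of SNPs.")
  panel_b <- panel_b %||% geno$samples$sample_id[(floor(n / 2) + 1L):n]
  bi <- match(panel_b, geno$samples$sample_id)
  injected <- list(flips = character(0),
                   pairs = tibble(template = character(0),
                                  relative = character(0)),
                   panel_b = panel_b)
  withr::with_seed(as.integer(seed), {
    if (n_related_pairs > 0) {
      picks <- sample.int(n, 2L * n_related_pairs)
      templates <- picks[seq_len(n_related_pairs)]
      relatives <- picks[n_related_pairs + seq_len(n_related_pairs)]
      freqs <- allele_frequencies(geno)
      for (k in seq_len(n_related_pairs)) {
        tmpl <- templates[k]
        pop <- geno$samples$population[tmpl]
        pf <- freqs$freq[freqs$population == pop]
        g_t <- geno$calls[tmpl, ]
        from_template <- ifelse(g_t == 2L, 1L,
                                ifelse(g_t == 0L, 0L,
                                       rbinom(length(g_t), 1L, 0.5)))
        from_pop <- rbinom(length(pf), 1L, pf)
        child <- from_template + from_pop
        child[is.na(g_t)] <- NA_integer_
        geno$calls[relatives[k], ] <- child
      }
      injected$pairs <- tibble(
        template = geno$samples$sample_id[templates],
        relative = geno$samples$sample_id[relatives]
      )
    }
    if (n_flips > 0) {
      p_all <- colMeans(geno$calls, na.rm = TRUE) / 2
      mono <- which(p_all %in% c(0, 1))
      if (length(mono) < n_flips) {
        abort(sprintf(
          "Need %d monomorphic sites to plant flips, found %d.",
          n_flips, length(mono)
        ))
      }
      flip_at <- sort(sample(mono, n_flips))
      geno$calls[bi, flip_at] <- 2L - geno$calls[bi, flip_at]
      injected$flips <- geno$variants$id[flip_at]
    }
  })
  attr(geno, "injected") <- injected
  geno
}
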