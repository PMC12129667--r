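#' Covariate-adjusted additive association for one SNP
#'
#' Ordinary least squares of the untransformed phenotype on an intercept,
#' the alternate-allele dosage (additive coding 0/1/2), the configured
#' covariates, optionally age squared, and optionally principal-component
#' scores. The genotype coefficient is reported with a t-based two-sided
#' p-value on residual degrees of freedom. Complete-case analysis.
#'
#' @param dosage Named numeric vector of dosages (names = sample ids), or a
#'   [geno_matrix()] together with `snp`.
#' @param phenotypes Tibble with `sample_id`, `phenotype`, and the covariate
#'   columns.
#' @param pcs Optional PCA scores (a `geno_pca` object or a tibble with
#'   `sample_id` and `PC*` columns).
#' @param covariates Covariate column names to adjust for.
#' @param include_age_squared Add an `age^2` term (common in blood-pressure
#'   models to absorb non-linear age effects); the genotype coefficient
#'   keeps its per-allele interpretation.
#' @param snp Variant id when `dosage` is a `geno_matrix`.
#' @return An `assoc_fit` object; [tidy()] gives the one-row association
#'   record (`id`, `beta`, `se`, `t_stat`, `p_value`, `n_used`,
#'   `model_terms`).
#' @export
ols_additive <- function(dosage, phenotypes, pcs = NULL,
                         covariates = c("age", "height", "weight",
                                        "dive_duration"),
                         include_age_squared = FALSE, snp = NULL) {
  if (inherits(dosage, "geno_matrix")) {
    if (is.null(snp)) abort("Provide `snp` when passing a geno_matrix.")
    vec <- dosage$calls[, snp]
    names(vec) <- dosage$samples$sample_id
    dosage <- vec
  } else {
    snp <- snp %||% "snp"
  }
  df <- as_tibble(phenotypes)
  if (!all(c("sample_id", "phenotype") %in% names(df))) {
    abort("`phenotypes` needs `sample_id` and `phenotype` columns.")
  }
  missing_cov <- setdiff(covariates, names(df))
  if (length(missing_cov) > 0) {
    abort(paste("Missing covariate columns:", paste(missing_cov, collapse = ", ")))
  }
  df$dosage <- unname(dosage[df$sample_id])
  if (!is.null(pcs)) {
    sc <- if (inherits(pcs, "geno_pca")) pcs$scores else as_tibble(pcs)
    pc_cols <- grep("^PC[0-9]+$", names(sc), value = TRUE)
    df <- left_join(df, sc[, c("sample_id", pc_cols)], by = "sample_id")
  } else {
    pc_cols <- character(0)
  }
  terms <- c("dosage", covariates, pc_cols)
  if (include_age_squared) {
    df$age_sq <- df$age^2
    terms <- c(terms, "age_sq")
  }
  use <- complete.cases(df[, c("phenotype", terms)])
  df <- df[use, , drop = FALSE]
  if (nrow(df) < 20) abort("Fewer than 20 complete cases.")
  if (var(df$phenotype) == 0) {
    return(structure(
      list(record = tibble(
        id = snp, beta = 0, se = NA_real_, t_stat = NA_real_, p_value = 1,
        n_used = nrow(df), model_terms = paste(terms, collapse = "+")
      ), fit = NULL, zero_variance = TRUE),
      class = "assoc_fit"
    ))
  }
  fml <- stats::as.formula(paste("phenotype ~", paste(terms, collapse = " + ")))
  mm <- model.matrix(fml, data = df)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    dropped <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    abort(paste0("Design matrix is rank deficient; collinear term(s): ",
                 paste(dropped, collapse = ", ")))
  }
  fit <- lm(fml, data = df)
  sm <- summary(fit)$coefficients
  structure(
    list(record = tibble(
      id = snp,
      beta = sm["dosage", "Estimate"],
      se = sm["dosage", "Std. Error"],
      t_stat = sm["dosage", "t value"],
      p_value = sm["dosage", "Pr(>|t|)"],
      n_used = nrow(df),
      model_terms = paste(terms, collapse = "+")
    ), fit = fit, zero_variance = FALSE),
    class = "assoc_fit"
  )
}

#' @export
print.assoc_fit <- function(x, ...) {
  r <- x$record
  cat(sprintf("<assoc_fit> %s: beta = %.3f (SE %.3f), p = %.3g, n = %d\n",
              r$id, r$beta, r$se, r$p_value, r$n_used))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.assoc_fit <- function(x, ...) x$record

#' @exportS3Method generics::glance
glance.assoc_fit <- function(x, ...) {
  if (is.null(x$fit)) return(tibble(r_squared = NA_real_, df_residual = NA_integer_))
  tibble(r_squared = summary(x$fit)$r.squared,
         df_residual = x$fit$df.residual)
}

#' Bonferroni per-test threshold
#'
#' @param alpha Family-wise level in `(0, 1)`.
#' @param m Number of tests (`>= 1`).
#' @return `alpha / m` (0.05 over 10 candidates gives 0.005).
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  if (m < 1) abort("`m` must be >= 1.")
  alpha / m
}

#' Median-based genomic-control inflation factor
#'
#' Back-transforms two-sided p-values to chi-square(1) statistics and takes
#' the ratio of their median to the chi-square(1) median. Values near 1
#' indicate adequately controlled population structure.
#'
#' @param p_values P-values in `(0, 1]` (at least 100).
#' @return The inflation factor lambda.
#' @export
gc_lambda_median <- function(p_values) {
  p <- p_values[!is.na(p_values)]
  if (length(p) < 100) abort("At least 100 p-values are required.")
  if (any(p <= 0 | p > 1)) abort("P-values must lie in (0, 1].")
  stats_chisq <- qchisq(p, df = 1, lower.tail = FALSE)
  median(stats_chisq) / qchisq(0.5, df = 1)
}

#' Unpaired two-group comparison
#'
#' Two-sided unpaired t-test (pooled variance by default; Welch via
#' `welch = TRUE`) with per-group summaries.
#'
#' @param values Numeric measurements.
#' @param labels Group labels (exactly two groups, each with >= 2 values).
#' @param welch Use the Welch unequal-variance test.
#' @return A one-row tibble: group names, means, sds, ns, `t_stat`,
#'   `p_value`.
#' @export
ttest_groups <- function(values, labels, welch = FALSE) {
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]; labels <- as.character(labels[ok])
  groups <- unique(labels)
  if (length(groups) != 2) abort("Exactly two groups are required.")
  n1 <- sum(labels == groups[1]); n2 <- sum(labels == groups[2])
  if (min(n1, n2) < 2) abort("Each group needs >= 2 observations.")
  v1 <- values[labels == groups[1]]
  v2 <- values[labels == groups[2]]
  if (sd(values) == 0) {
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- t.test(v1, v2, var.equal = !welch)
  }
  tibble(
    group_1 = groups[1], group_2 = groups[2],
    mean_1 = mean(v1), mean_2 = mean(v2),
    sd_1 = sd(v1), sd_2 = sd(v2), n_1 = n1, n_2 = n2,
    t_stat = unname(tt$statistic), p_value = tt$p.value,
    method = if (welch) "welch" else "pooled"
  )
}

#' Two-stage selection-plus-association report
#'
#' Stage two of the design: each candidate top SNP from the selection scan is
#' tested for additive association with the phenotype, adjusting for the
#' covariates and the leading principal components of the analyzed samples'
#' genotypes; significance is declared at the Bonferroni threshold
#' `alpha / n_candidates`. Restricting the association to scan candidates
#' shrinks the multiple-testing burden from genome-wide to a handful of
#' SNPs.
#'
#' @param geno A post-QC [geno_matrix()].
#' @param phenotypes Phenotype/covariate tibble (see [simulate_phenotype()]
#'   for the expected columns).
#' @param candidates Candidate tibble from [select_candidates()].
#' @param alpha Family-wise level; default 0.05.
#' @param n_pcs Number of principal components to adjust for (computed on
#'   the analyzed samples' genotypes); default 10.
#' @param covariates Covariate columns.
#' @param include_age_squared Add the age-squared covariate.
#' @param within_population Optional population label: re-run the test
#'   within that population only (reported in `within` element).
#' @return A `two_stage` object: list with `results` (one row per candidate:
#'   association record plus `significant`), `threshold`, `alpha`,
#'   `n_candidates`, and optionally `within`.
#' @export
run_two_stage <- function(geno, phenotypes, candidates, alpha = 0.05,
                          n_pcs = 10,
                          covariates = c("age", "height", "weight",
                                         "dive_duration"),
                          include_age_squared = FALSE,
                          within_population = NULL) {
  stopifnot(inherits(geno, "geno_matrix"))
  if (nrow(candidates) == 0) {
    return(structure(
      list(results = tibble(), threshold = NA_real_, alpha = alpha,
           n_candidates = 0L),
      class = "two_stage"
    ))
  }
  ids <- intersect(phenotypes$sample_id, geno$samples$sample_id)
  sub <- subset_geno(geno, sample_ids = ids)
  pcs <- if (n_pcs > 0) pca_genotypes(sub, k = n_pcs) else NULL
  thr <- bonferroni_threshold(alpha, nrow(candidates))
  one_pass <- function(pheno_tbl, pcs_obj) {
    bind_rows(lapply(candidates$top_snp, function(snp) {
      rec <- tryCatch(
        tidy(ols_additive(sub, pheno_tbl, pcs = pcs_obj,
                          covariates = covariates,
                          include_age_squared = include_age_squared,
                          snp = snp)),
        error = function(e) tibble(
          id = snp, beta = NA_real_, se = NA_real_, t_stat = NA_real_,
          p_value = NA_real_, n_used = 0L,
          model_terms = conditionMessage(e)
        )
      )
      rec
    }))
  }
  pheno_use <- phenotypes[phenotypes$sample_id %in% ids, , drop = FALSE]
  results <- one_pass(pheno_use, pcs)
  results$significant <- !is.na(results$p_value) & results$p_value <= thr
  results <- left_join(
    select(candidates, id = "top_snp", "rank", "chrom", "top_pos", "top_llr"),
    results, by = "id"
  )
  out <- list(results = results, threshold = thr, alpha = alpha,
              n_candidates = nrow(candidates))
  if (!is.null(within_population)) {
    keep <- pheno_use$sample_id[pheno_use$population == within_population]
    sub_w <- subset_geno(sub, sample_ids = keep)
    pcs_w <- if (n_pcs > 0) {
      k_w <- min(n_pcs, length(keep) - 2)
      pca_genotypes(sub_w, k = k_w)
    } else NULL
    sub <- sub_w
    res_w <- one_pass(pheno_use[pheno_use$sample_id %in% keep, ], pcs_w)
    res_w$significant <- !is.na(res_w$p_value) & res_w$p_value <= thr
    out$within <- list(population = within_population, results = res_w)
  }
  structure(out, class = "two_stage")
}

#' @export
print.two_stage <- function(x, ...) {
  cat(sprintf(
    "<two_stage> %d candidates, Bonferroni threshold %.4g (alpha %.3g)\n",
    x$n_candidates, x$threshold, x$alpha
  ))
  if (x$n_candidates > 0) {
    cat(sprintf("  significant: %d\n", sum(x$results$significant, na.rm = TRUE)))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.two_stage <- function(x, ...) x$results

#' @exportS3Method generics::glance
glance.two_stage <- function(x, ...) {
  tibble(
    n_candidates = x$n_candidates, alpha = x$alpha, threshold = x$threshold,
    n_significant = if (x$n_candidates > 0)
      sum(x$results$significant, na.rm = TRUE) else 0L
  )
}

#' End-to-end two-stage pipeline
#'
#' Composes the full analysis in the fixed order: heterozygote-excess filter,
#' optional allele-flip removal (when two merged panels are identified),
#' MAF filter, relatedness pruning, genome-wide selection scan, calibration,
#' peak selection, and candidate association.
#'
#' @param geno A [geno_matrix()].
#' @param phenotypes Optional phenotype tibble; when `NULL` the pipeline
#'   stops after peak selection.
#' @param focal,outgroup Population labels for the scan.
#' @param maf,exchet_alpha,k0_threshold QC thresholds.
#' @param prune Run relatedness pruning (skip for speed when samples are
#'   known unrelated).
#' @param q,window_bp,chain_bp,n_top Peak-selection parameters.
#' @param alpha Association family-wise level.
#' @param n_pcs Principal components for association.
#' @param ... Passed to [run_two_stage()].
#' @return A list with elements `geno` (post-QC), `scan` (calibrated),
#'   `calibration`, `candidates`, and (when phenotypes are given)
#'   `association`.
#' @export
divescan_pipeline <- function(geno, phenotypes = NULL, focal, outgroup,
                              maf = 0.01, exchet_alpha = 1e-6,
                              k0_threshold = 0.75, prune = TRUE,
                              q = 0.99, window_bp = 1e5, chain_bp = 1e6,
                              n_top = 10, alpha = 0.05, n_pcs = 10, ...) {
  geno <- apply_exchet_filter(geno, alpha = exchet_alpha)
  geno <- maf_filter(geno, threshold = maf)
  if (prune) {
    geno <- prune_related(geno, threshold = k0_threshold)$geno
  }
  scan <- scan_genome(geno, focal = focal, outgroup = outgroup)
  cal <- calibrate_llrs(scan)
  candidates <- select_candidates(cal$scan, q = q, window_bp = window_bp,
                                  chain_bp = chain_bp, n = n_top)
  out <- list(geno = geno, scan = cal$scan, calibration = cal$calibration,
              candidates = candidates)
  if (!is.null(phenotypes) && nrow(candidates) > 0) {
    out$association <- run_two_stage(
      geno, phenotypes, candidates, alpha = alpha, n_pcs = n_pcs, ...
    )
  }
  out
}
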